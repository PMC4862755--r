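#' Matching tolerances for control lead SNPs
#'
#' Tolerance windows used to draw control lead SNPs with genetic
#' properties matched to a test lead: LD block size (+/- 5 SNPs), minor
#' allele frequency (+/- 0.1), distance to the nearest gene (+/- 25 kb,
#' applied only when the lead lies outside a gene), number of genes
#' within +/- 500 kb (+/- 3), and presence on the genotyping array.
#'
#' @param block_size Block-size window (SNP count).
#' @param maf MAF window.
#' @param dist_to_gene Gene-distance window in bp.
#' @param n_genes_500kb Gene-count window.
#' @param require_on_array Require controls to be on the array.
#' @return A `match_tolerances` list.
#' @export
match_tolerances <- function(block_size = 5, maf = 0.1, dist_to_gene = 25000,
                             n_genes_500kb = 3, require_on_array = TRUE) {
  tol <- list(block_size = block_size, maf = maf,
              dist_to_gene = dist_to_gene, n_genes_500kb = n_genes_500kb,
              require_on_array = require_on_array)
  if (any(unlist(tol[1:4]) < 0)) stop("tolerances must be >= 0")
  class(tol) <- "match_tolerances"
  tol
}

#' Find matched control lead candidates for one test lead
#'
#' Filters a candidate pool to SNPs satisfying every tolerance window
#' around the test lead's covariates. The lead itself and any SNP
#' belonging to a test locus are excluded.
#'
#' @param lead One-row `data.frame` with the lead's covariates
#'   (`block_size`, `maf`, `dist_to_nearest_gene`, `n_genes_500kb`,
#'   `on_array`).
#' @param pool Candidate variants `data.frame` with the same covariate
#'   columns and `id`.
#' @param tol A [match_tolerances()].
#' @param exclude Character vector of SNP ids never eligible (test-locus
#'   members).
#' @return The subset of `pool` eligible as controls.
#' @export
match_controls <- function(lead, pool, tol = match_tolerances(),
                           exclude = character(0)) {
  ok <- abs(pool$block_size - lead$block_size) <= tol$block_size &
    abs(pool$maf - lead$maf) <= tol$maf &
    abs(pool$n_genes_500kb - lead$n_genes_500kb) <= tol$n_genes_500kb
  if (lead$dist_to_nearest_gene > 0) {
    ok <- ok & abs(pool$dist_to_nearest_gene - lead$dist_to_nearest_gene) <=
      tol$dist_to_gene
  }
  if (tol$require_on_array) ok <- ok & pool$on_array
  ok <- ok & !(pool$id %in% c(lead$id, exclude))
  out <- pool[ok, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no matched control candidates for lead ", lead$id)
  }
  out
}

#' Count loci overlapping an annotation
#'
#' A locus counts once if at least one member SNP lies inside at least
#' one annotation interval, regardless of how many members overlap.
#'
#' @param loci List of `locus` objects.
#' @param annotation `GRanges` annotation set.
#' @param variants Variants `data.frame` giving `chrom`/`pos` per `id`.
#' @return Integer count of overlapping loci.
#' @export
count_locus_overlaps <- function(loci, annotation, variants) {
  hit <- snps_in_annotation(annotation, variants$chrom, variants$pos)
  names(hit) <- variants$id
  sum(vapply(loci, function(l) any(hit[l$members], na.rm = TRUE), logical(1)))
}

#' Matched-control permutation enrichment of loci in an annotation
#'
#' Tests whether test loci overlap an annotation more often than
#' expected, against a null built from matched control lead SNPs. Each
#' permutation samples, independently per test lead and with
#' replacement across permutations, one matched control lead; the
#' control lead is expanded into a locus by the same LD rule as the
#' test loci (`r2 > 0.8`) and locus-level overlaps are counted. The
#' z-score uses the sample SD of the null counts (denominator n-1); the
#' empirical p-value carries the add-one correction and is never zero.
#'
#' @param test_loci List of `locus` objects.
#' @param pool Candidate variants `data.frame` (covariates populated).
#' @param panel An [ld_panel()].
#' @param annotation `GRanges` annotation set.
#' @param variants Variants `data.frame` for all SNP coordinates and
#'   the test leads' covariates.
#' @param tol A [match_tolerances()].
#' @param n_perm Number of permutations (default 1e5).
#' @param seed Integer seed.
#' @param snp_hit Optional precomputed logical vector (named by SNP id)
#'   of SNP-in-annotation membership; computed from `annotation` when
#'   missing.
#' @return An `enrichment_result` list: `observed`, `null_mean`,
#'   `null_sd`, `z`, `empirical_p`, `n_perm`, `degenerate`.
#' @export
permutation_enrichment <- function(test_loci, pool, panel, annotation,
                                   variants, tol = match_tolerances(),
                                   n_perm = 1e5, seed = 1L,
                                   snp_hit = NULL) {
  stopifnot(n_perm >= 1)
  if (is.null(snp_hit)) {
    snp_hit <- snps_in_annotation(annotation, variants$chrom, variants$pos)
    names(snp_hit) <- variants$id
  }
  observed <- sum(vapply(test_loci,
                         function(l) any(snp_hit[l$members], na.rm = TRUE),
                         logical(1)))
  exclude <- unlist(lapply(test_loci, `[[`, "members"))

  r2_thr <- test_loci[[1]]$r2_threshold
  pool_locus_hit <- expanded_locus_hits(panel, snp_hit, r2_thr)

  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  null_counts <- integer(n_perm)
  for (l in test_loci) {
    lead_row <- variants[match(l$lead, variants$id), , drop = FALSE]
    cands <- match_controls(lead_row, pool, tol, exclude = exclude)
    cand_hit <- pool_locus_hit[cands$id]
    cand_hit[is.na(cand_hit)] <- snp_hit[cands$id[is.na(cand_hit)]]
    draws <- sample.int(length(cand_hit), n_perm, replace = TRUE)
    null_counts <- null_counts + as.integer(cand_hit[draws])
  }
  enrichment_result(observed, null_counts)
}

# For every SNP known to the panel: does its expanded locus
# (itself plus partners with r2 > r2_min) contain an annotation hit?
# One pass over the panel's adjacency, shared by all permutations.
expanded_locus_hits <- function(panel, snp_hit, r2_min) {
  out <- snp_hit[match(panel$ids, names(snp_hit))]
  names(out) <- panel$ids
  out[is.na(out)] <- FALSE
  if (panel$kind == "table") {
    sel <- panel$adj$r2 > r2_min
    hit_partner <- out[panel$adj$b[sel]]
    out[unique(panel$adj$a[sel][hit_partner])] <- TRUE
  } else {
    for (i in seq_along(panel$ids)) {
      if (out[i]) next
      members <- ld_partners(panel, panel$ids[i], r2_min)
      out[i] <- any(out[match(members, panel$ids)], na.rm = TRUE)
    }
  }
  out
}

enrichment_result <- function(observed, null_counts) {
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (!degenerate) {
    (observed - null_mean) / null_sd
  } else if (observed == null_mean) 0 else sign(observed - null_mean) * Inf
  structure(list(
    observed = observed, null_mean = null_mean, null_sd = null_sd,
    z = z, empirical_p = empirical_p(observed, null_counts),
    n_perm = length(null_counts), degenerate = degenerate
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("permutation enrichment: observed", x$observed,
      "null", sprintf("%.2f +/- %.2f", x$null_mean, x$null_sd),
      "z", sprintf("%.2f", x$z),
      "empirical p", format(x$empirical_p), "\n")
  invisible(x)
}

#' Motif-disruption enrichment over matched controls
#'
#' Counts test loci containing a member SNP that lies inside an
#' enhancer and within a motif instance of an expressed transcription
#' factor, and compares against the matched-control null. Motif sets
#' should be pre-filtered to expressed TFs (`tf_expressed`).
#'
#' @param test_loci,pool,panel,variants,tol,n_perm,seed As in
#'   [permutation_enrichment()].
#' @param enhancers `GRanges` of enhancer intervals.
#' @param motifs List of motif instance sets, each a list with `motif`,
#'   `tf`, `instances` (`GRanges`) and `tf_expressed` (logical); only
#'   expressed sets contribute.
#' @return An `enrichment_result`.
#' @export
motif_disruption_enrichment <- function(test_loci, pool, panel, enhancers,
                                        motifs, variants,
                                        tol = match_tolerances(),
                                        n_perm = 1e5, seed = 1L) {
  expressed <- Filter(function(m) isTRUE(m$tf_expressed), motifs)
  motif_gr <- if (length(expressed) > 0) {
    do.call(c, lapply(expressed, `[[`, "instances"))
  } else GenomicRanges::GRanges()
  in_enh <- snps_in_annotation(enhancers, variants$chrom, variants$pos)
  in_motif <- snps_in_annotation(motif_gr, variants$chrom, variants$pos)
  snp_hit <- in_enh & in_motif
  names(snp_hit) <- variants$id
  permutation_enrichment(test_loci, pool, panel, annotation = NULL,
                         variants = variants, tol = tol, n_perm = n_perm,
                         seed = seed, snp_hit = snp_hit)
}

#' Shuffle motif instances across the genome
#'
#' Re-places every motif instance uniformly at random on the genome,
#' preserving the instance count and lengths; chromosomes are chosen
#' with probability proportional to length. Used as a negative control
#' for [motif_disruption_enrichment()].
#'
#' @param motifs List of motif instance sets (see
#'   [motif_disruption_enrichment()]).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param seed Integer seed.
#' @return The motif list with shuffled `instances`.
#' @export
shuffle_motif_instances <- function(motifs, chrom_lengths, seed = 1L) {
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  lapply(motifs, function(m) {
    gr <- m$instances
    n <- length(gr)
    if (n == 0) return(m)
    widths <- GenomicRanges::width(gr)
    chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    max_start <- chrom_lengths[chrom] - widths
    start0 <- floor(stats::runif(n) * pmax(1, max_start))
    m$instances <- annotation_set(chrom, start0, start0 + widths)
    m
  })
}
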