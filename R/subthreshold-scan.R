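#' Sliding-threshold enrichment curve
#'
#' For a grid of -log10(p) cutoffs, compares the proportion of
#' annotation-overlapping (foreground) SNPs with p-values more
#' significant than the cutoff against the proportion among all SNPs:
#' `fold(c) = [#\{fg, p < 10^-c\} / #fg] / [#\{all, p < 10^-c\} / #all]`.
#' "More significant than" is strict. Fold is `NA` at cutoffs where no
#' background SNP passes.
#'
#' @param snps Summary-statistics `data.frame` (`chrom`, `pos`,
#'   `pvalue`).
#' @param annotation `GRanges` annotation set defining the foreground.
#' @param grid_max,grid_step -log10(p) grid from 0 to `grid_max` in
#'   steps of `grid_step` (defaults 10 and 0.1).
#' @return A `data.frame`: `threshold` (-log10 p cutoff), `n_fg_below`,
#'   `n_fg_total`, `n_bg_below`, `n_bg_total`, `fold`.
#' @export
enrichment_curve <- function(snps, annotation, grid_max = 10,
                             grid_step = 0.1) {
  if (any(is.na(snps$pvalue))) stop("every SNP needs a p-value")
  fg <- snps_in_annotation(annotation, snps$chrom, snps$pos)
  if (!any(fg)) stop("empty foreground: no SNP overlaps the annotation")
  thresholds <- seq(0, grid_max, by = grid_step)
  nlp <- -log10(snps$pvalue)
  n_fg_total <- sum(fg)
  n_bg_total <- nrow(snps)
  n_fg_below <- vapply(thresholds, function(c) sum(nlp[fg] > c), integer(1))
  n_bg_below <- vapply(thresholds, function(c) sum(nlp > c), integer(1))
  fold <- ifelse(n_bg_below > 0,
                 (n_fg_below / n_fg_total) / (n_bg_below / n_bg_total),
                 NA_real_)
  data.frame(threshold = thresholds, n_fg_below = n_fg_below,
             n_fg_total = n_fg_total, n_bg_below = n_bg_below,
             n_bg_total = n_bg_total, fold = fold)
}

#' Exclusion zones for the sub-threshold scan
#'
#' @param radius_bp Removal radius around known-locus members
#'   (default 1 Mb, inclusive).
#' @param masked_regions Optional `GRanges` of regions removed outright
#'   (e.g. the extended MHC/HLA region, whose dense low-p SNPs skew
#'   enrichment).
#' @return An `exclusion_zones` list.
#' @export
exclusion_zones <- function(radius_bp = 1e6, masked_regions = NULL) {
  stopifnot(radius_bp >= 0)
  structure(list(radius_bp = radius_bp, masked_regions = masked_regions),
            class = "exclusion_zones")
}

#' Apply exclusion zones to summary statistics
#'
#' Removes SNPs within the radius of any known-locus member and SNPs
#' inside any masked region.
#'
#' @param snps Summary-statistics `data.frame`.
#' @param zones An [exclusion_zones()].
#' @param known_members `data.frame` of known-locus member SNPs
#'   (`chrom`, `pos`); may be empty.
#' @return The filtered `data.frame`.
#' @export
apply_exclusions <- function(snps, zones = exclusion_zones(),
                             known_members = NULL) {
  out <- snps
  if (!is.null(known_members) && nrow(known_members) > 0) {
    out <- exclude_near_known(out, known_members, zones$radius_bp)
  }
  if (!is.null(zones$masked_regions) && length(zones$masked_regions) > 0 &&
      nrow(out) > 0) {
    masked <- snps_in_annotation(zones$masked_regions, out$chrom, out$pos)
    out <- out[!masked, , drop = FALSE]
  }
  out
}

#' Enrichment curves for feature-refined enhancer subsets
#'
#' Recomputes the enrichment curve for subsets of the base annotation
#' passing a per-enhancer mean-signal cutoff, one curve per refinement.
#'
#' @param snps Summary-statistics `data.frame`.
#' @param base_annotation `GRanges` of enhancers.
#' @param refinements Named list; each element is a list with `track`
#'   (signal `GRanges`) and `cutoff` (enhancers with mean signal >=
#'   cutoff are retained).
#' @param grid_max,grid_step Grid parameters (see
#'   [enrichment_curve()]).
#' @return Named list of curve `data.frame`s, one per refinement.
#' @export
refined_subset_curves <- function(snps, base_annotation, refinements,
                                  grid_max = 10, grid_step = 0.1) {
  lapply(stats::setNames(names(refinements), names(refinements)),
         function(nm) {
    ref <- refinements[[nm]]
    means <- vapply(seq_along(base_annotation), function(i)
      average_signal(ref$track, base_annotation[i]), numeric(1))
    subset <- base_annotation[means >= ref$cutoff]
    if (length(subset) == 0) {
      stop("refinement '", nm, "' (cutoff ", ref$cutoff,
           ") empties the enhancer set")
    }
    enrichment_curve(snps, subset, grid_max, grid_step)
  })
}

#' Assign a replication p-value to a sub-threshold locus
#'
#' Looks up the locus representative and its strong-LD partners
#' (`r2 > 0.8`) in replication summary statistics covering one or more
#' traits; the assigned p-value is the minimum over partners of the
#' minimum over traits. Absence from the replication data is a value
#' (`NA`), not an error.
#'
#' @param representative Representative SNP id.
#' @param panel An [ld_panel()].
#' @param replication_stats `data.frame` with column `id` and one or
#'   more p-value columns (one per trait).
#' @param trait_cols Names of the p-value columns; defaults to every
#'   column except `id`.
#' @return The replication p-value, or `NA` if no partner is present.
#' @export
assign_replication_p <- function(representative, panel, replication_stats,
                                 trait_cols = setdiff(names(replication_stats),
                                                      "id")) {
  partners <- representative
  if (representative %in% panel$ids) {
    partners <- union(representative,
                      ld_partners(panel, representative, 0.8))
  }
  rows <- replication_stats[replication_stats$id %in% partners, trait_cols,
                            drop = FALSE]
  vals <- unlist(rows)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else min(vals)
}
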