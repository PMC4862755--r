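#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the
#' statistical structure of the study inputs at desk scale: block-wise
#' exchangeable LD, Beta-distributed minor allele frequencies, 59
#' tissues with partially shared enhancer activity coupled to
#' expression, Poisson 4C coverage with power-law distance decay.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len_bp Chromosome length in bp.
#' @param n_snps Total SNP count.
#' @param ld_block_len_bp LD block length; SNPs in the same block share
#'   a single pairwise r-squared.
#' @param within_block_r2 Pairwise r-squared inside a block (0 across
#'   blocks).
#' @param maf_shape1,maf_shape2 Beta shape parameters; MAF is
#'   `0.5 * Beta(shape1, shape2)` truncated to (0.005, 0.5].
#' @param n_genes_per_chrom Genes placed per chromosome.
#' @param gene_len_bp Gene body length.
#' @param n_tissues Number of tissues with matched enhancer calls and
#'   expression (default 59).
#' @param enhancer_count Enhancers in the reference tissue.
#' @param enhancer_len_bp Enhancer length.
#' @param enhancer_sharing Probability an enhancer is also active in
#'   each non-reference tissue.
#' @param expression_effect_delta Log-scale expression shift of an
#'   enhancer's target gene in tissues where the enhancer is active,
#'   in units of the expression noise SD.
#' @param expression_noise_sd SD of log-expression noise.
#' @param fourc_scale,fourc_exponent 4C decay `lambda(d) = scale *
#'   (1 + d)^(-exponent)` with `d` the distance to the viewpoint in bp.
#' @param fragend_spacing_bp Spacing between 4C fragment ends
#'   (default 264, the median restriction-fragment spacing).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 4L,
                       chrom_len_bp = 10e6,
                       n_snps = 10000L,
                       ld_block_len_bp = 20000L,
                       within_block_r2 = 0.9,
                       maf_shape1 = 1, maf_shape2 = 1,
                       n_genes_per_chrom = 150L,
                       gene_len_bp = 10000L,
                       n_tissues = 59L,
                       enhancer_count = 400L,
                       enhancer_len_bp = 2000L,
                       enhancer_sharing = 0.3,
                       expression_effect_delta = 3,
                       expression_noise_sd = 1,
                       fourc_scale = 1000,
                       fourc_exponent = 0.5,
                       fragend_spacing_bp = 264L) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len_bp = chrom_len_bp, n_snps = as.integer(n_snps),
    ld_block_len_bp = ld_block_len_bp, within_block_r2 = within_block_r2,
    maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    gene_len_bp = gene_len_bp, n_tissues = as.integer(n_tissues),
    enhancer_count = as.integer(enhancer_count),
    enhancer_len_bp = enhancer_len_bp,
    enhancer_sharing = enhancer_sharing,
    expression_effect_delta = expression_effect_delta,
    expression_noise_sd = expression_noise_sd,
    fourc_scale = fourc_scale, fourc_exponent = fourc_exponent,
    fragend_spacing_bp = fragend_spacing_bp
  )
  stopifnot(
    cfg$n_chrom > 0, cfg$n_snps > 0, cfg$chrom_len_bp > 0,
    cfg$within_block_r2 >= 0, cfg$within_block_r2 <= 1,
    cfg$enhancer_sharing >= 0, cfg$enhancer_sharing <= 1,
    cfg$expression_noise_sd > 0, cfg$fourc_exponent > 0
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate variants, block LD and gene annotation
#'
#' Places SNPs uniformly on chromosomes, assigns exchangeable block LD
#' (pairwise `within_block_r2` inside non-overlapping
#' `ld_block_len_bp` windows, 0 across blocks), draws MAF from a scaled
#' Beta distribution, places genes, and computes the matching
#' covariates: LD block size, distance to the nearest gene (0 inside a
#' gene) and number of genes within +/- 500 kb. Every other SNP is
#' flagged as present on the genotyping array.
#'
#' @param config A [sim_config()].
#' @return A list: `variants` (variants `data.frame` plus `block` and
#'   `block_size` columns), `panel` (an [ld_panel()]), `genes` (a
#'   `GRanges` with `name` and `tss`).
#' @export
simulate_variants_and_ld <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps > config$n_chrom * config$chrom_len_bp / 2) {
    stop("n_snps exceeds available positions")
  }
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)

  per_chrom <- diff(round(seq(0, config$n_snps, length.out = config$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(config$chrom_len_bp - 1L, k))
  }))
  n <- length(pos)
  block <- paste0(chrom, "_b", pos %/% config$ld_block_len_bp)
  block_size <- as.integer(ave(seq_len(n), block, FUN = length))
  maf <- 0.5 * stats::rbeta(n, config$maf_shape1, config$maf_shape2)
  maf <- pmin(0.5, pmax(0.005, maf))
  id <- sprintf("rs%06d", seq_len(n))

  # genes: jittered grid placement, fixed length, TSS at the 5' end.
  # The grid bounds the largest intergenic gap so the distance-to-gene
  # covariate stays densely populated for control matching.
  gene_chrom <- rep(paste0("chr", seq_len(config$n_chrom)),
                    each = config$n_genes_per_chrom)
  gap <- floor(config$chrom_len_bp / config$n_genes_per_chrom)
  jitter_max <- max(1, gap - config$gene_len_bp)
  gene_start <- unlist(lapply(seq_len(config$n_chrom), function(i) {
    (seq_len(config$n_genes_per_chrom) - 1L) * gap +
      sample.int(jitter_max, config$n_genes_per_chrom, replace = TRUE)
  }))
  genes <- annotation_set(
    chrom = gene_chrom, start = gene_start,
    end = gene_start + config$gene_len_bp,
    name = sprintf("gene%04d", seq_along(gene_chrom))
  )
  S4Vectors::mcols(genes)$tss <- GenomicRanges::start(genes)
  S4Vectors::mcols(genes)$strand_char <- "+"

  snp_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  dist_to_gene <- rep(NA_integer_, n)
  hit <- GenomicRanges::countOverlaps(snp_gr, genes) > 0
  dist_to_gene[hit] <- 0L
  nearest <- GenomicRanges::distanceToNearest(snp_gr, genes)
  dist_to_gene[!hit] <- S4Vectors::mcols(nearest)$distance[!hit]
  win <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pmax(1, pos - 5e5), pos + 5e5))
  n_genes_500kb <- GenomicRanges::countOverlaps(win, genes)

  variants <- data.frame(
    id = id, chrom = chrom, pos = pos, maf = maf,
    on_array = seq_len(n) %% 2L == 1L,
    dist_to_nearest_gene = dist_to_gene,
    n_genes_500kb = n_genes_500kb,
    block = block, block_size = block_size,
    stringsAsFactors = FALSE
  )

  panel <- ld_panel(r2_table = block_r2_table(id, block, config$within_block_r2),
                    ids = id)
  list(variants = variants, panel = panel, genes = genes)
}

# all within-block pairs at a single r2
block_r2_table <- function(id, block, r2) {
  if (r2 == 0) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      r2 = numeric(0), stringsAsFactors = FALSE))
  }
  by_block <- split(id, block)
  pairs <- lapply(by_block, function(ids) {
    k <- length(ids)
    if (k < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(id1 = character(0), id2 = character(0), r2 = numeric(0)))
  }
  out$r2 <- r2
  rownames(out) <- NULL
  out
}

#' Simulate GWAS summary statistics with planted signals
#'
#' Draws an association z-statistic per SNP: `z ~ Normal(ncp, 1)` with
#' `ncp = 0` for null SNPs, and converts to two-sided p-values
#' `p = 2 * (1 - pnorm(|z|))`. LD partners of a planted SNP receive
#' correlated z-statistics under the single-causal-variant model
#' `z_partner = r * z_lead + sqrt(1 - r^2) * eps`.
#'
#' @param variants Variants `data.frame` (from
#'   [simulate_variants_and_ld()]).
#' @param planted `data.frame` with columns `id` and `ncp` (>= 0).
#' @param panel An [ld_panel()].
#' @param seed Integer seed.
#' @return A summary-statistics `data.frame`: `id`, `chrom`, `pos`,
#'   `pvalue`, `z`.
#' @export
simulate_gwas <- function(variants, planted = NULL, panel = NULL, seed = 1L) {
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  n <- nrow(variants)
  z <- stats::rnorm(n)
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$ncp < 0)) stop("ncp must be >= 0")
    miss <- setdiff(planted$id, variants$id)
    if (length(miss) > 0) stop("planted loci reference unknown SNPs: ",
                               paste(miss, collapse = ", "))
    lead_idx <- match(planted$id, variants$id)
    z[lead_idx] <- stats::rnorm(nrow(planted)) + planted$ncp
    if (!is.null(panel)) {
      for (i in seq_len(nrow(planted))) {
        lead <- planted$id[i]
        if (!lead %in% panel$ids) next
        for (p in ld_partners(panel, lead, 0)) {
          pi <- match(p, variants$id)
          if (is.na(pi)) next
          r2 <- panel_r2(panel, lead, p)
          z[pi] <- sqrt(r2) * z[lead_idx[i]] + sqrt(1 - r2) * stats::rnorm(1)
        }
      }
    }
  }
  data.frame(
    id = variants$id, chrom = variants$chrom, pos = variants$pos,
    pvalue = 2 * stats::pnorm(-abs(z)), z = z,
    stringsAsFactors = FALSE
  )
}

#' Simulate tissue enhancer panels, signal tracks and expression
#'
#' Places enhancers in the reference tissue, shares each with every
#' other tissue independently with probability `enhancer_sharing`
#' (the reference column is always active), links each enhancer to its
#' nearest gene, and shifts that gene's log-expression upward by
#' `expression_effect_delta * expression_noise_sd` in tissues where the
#' enhancer is active. A fraction of enhancers is flagged "strong";
#' an H3K27ac-like track is elevated inside strong enhancers and a
#' percent-methylation track is depressed inside them.
#'
#' @param config A [sim_config()].
#' @param genes Gene `GRanges` (from [simulate_variants_and_ld()]).
#' @param seed Integer seed.
#' @return A list: `enhancers` (reference-tissue `GRanges` with `name`,
#'   `strong`, `target_gene`), `activity` (logical matrix enhancers x
#'   tissues, first column the reference), `tissue_sets` (list of
#'   per-tissue `GRanges`), `expression` (`data.frame`: `gene`, one
#'   column per tissue, plus a differentiated-cardiomyocyte column
#'   `CM`), `h3k27ac` and `methylation` signal tracks, and `truth`
#'   (the planted enhancer-gene links).
#' @export
simulate_tissue_panels <- function(config, genes, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)

  n_enh <- config$enhancer_count
  # non-overlapping placement: sample slots on a grid twice the
  # enhancer length, so intervals (and their signal segments) never
  # collide
  slot_bp <- 2 * config$enhancer_len_bp
  slots_per_chrom <- floor(config$chrom_len_bp / slot_bp) - 1L
  if (n_enh > slots_per_chrom * config$n_chrom) {
    stop("enhancer_count exceeds available non-overlapping slots")
  }
  slot <- sample.int(slots_per_chrom * config$n_chrom, n_enh)
  chrom <- paste0("chr", (slot - 1L) %/% slots_per_chrom + 1L)
  start <- ((slot - 1L) %% slots_per_chrom) * slot_bp
  enh <- annotation_set(chrom, start, start + config$enhancer_len_bp,
                        name = sprintf("enh%04d", seq_len(n_enh)),
                        label = "reference_enhancers")
  strong <- stats::runif(n_enh) < 0.5
  S4Vectors::mcols(enh)$strong <- strong

  nearest <- GenomicRanges::distanceToNearest(enh, genes)
  target <- rep(NA_character_, n_enh)
  target[S4Vectors::queryHits(nearest)] <-
    S4Vectors::mcols(genes)$name[S4Vectors::subjectHits(nearest)]
  S4Vectors::mcols(enh)$target_gene <- target

  tissues <- c("T_ref", sprintf("T%02d", seq_len(config$n_tissues - 1)))
  activity <- matrix(FALSE, n_enh, length(tissues),
                     dimnames = list(S4Vectors::mcols(enh)$name, tissues))
  activity[, 1] <- TRUE
  activity[, -1] <- stats::runif(n_enh * (length(tissues) - 1)) <
    config$enhancer_sharing
  tissue_sets <- lapply(tissues, function(t) enh[activity[, t]])
  names(tissue_sets) <- tissues

  gene_names <- S4Vectors::mcols(genes)$name
  delta <- config$expression_effect_delta * config$expression_noise_sd
  log_expr <- matrix(
    stats::rnorm(length(gene_names) * length(tissues), mean = 2,
                 sd = config$expression_noise_sd),
    nrow = length(gene_names), dimnames = list(gene_names, tissues))
  for (e in seq_len(n_enh)) {
    g <- target[e]
    if (is.na(g)) next
    log_expr[g, activity[e, ]] <- log_expr[g, activity[e, ]] + delta
  }
  expression <- data.frame(gene = gene_names, exp(log_expr),
                           CM = exp(stats::rnorm(length(gene_names), 2,
                                                 config$expression_noise_sd)),
                           check.names = FALSE, stringsAsFactors = FALSE)

  # signal tracks over enhancer footprints: elevated acetylation and
  # depressed methylation inside strong enhancers
  h3k27ac <- signal_track(
    chrom = as.character(GenomicRanges::seqnames(enh)),
    start = GenomicRanges::start(enh) - 1L,
    end = GenomicRanges::end(enh),
    value = ifelse(strong, stats::rgamma(n_enh, shape = 8, rate = 1),
                   stats::rgamma(n_enh, shape = 2, rate = 1))
  )
  methylation <- signal_track(
    chrom = as.character(GenomicRanges::seqnames(enh)),
    start = GenomicRanges::start(enh) - 1L,
    end = GenomicRanges::end(enh),
    value = ifelse(strong, stats::runif(n_enh, 5, 30),
                   stats::runif(n_enh, 50, 95))
  )

  list(
    enhancers = enh, activity = activity, tissue_sets = tissue_sets,
    expression = expression, h3k27ac = h3k27ac, methylation = methylation,
    truth = data.frame(enhancer = S4Vectors::mcols(enh)$name,
                       gene = target, stringsAsFactors = FALSE)
  )
}

#' Simulate allele-specific read counts
#'
#' Balanced SNPs draw reference reads from `Binomial(depth, 0.5)`;
#' imbalanced SNPs (a fraction `allele_imbalance_frac`) from
#' `Binomial(depth, imbalance_ratio)`. Unique-position counts are
#' fabricated alongside (bounded by the read counts).
#'
#' @param n_snps Number of SNPs.
#' @param depth_dist Function of `n` returning integer depths
#'   (default ~ Poisson(60)).
#' @param allele_imbalance_frac Fraction of truly imbalanced SNPs.
#' @param imbalance_ratio Reference-allele probability at imbalanced
#'   SNPs, in (0, 1).
#' @param seed Integer seed.
#' @return An allele-counts `data.frame` with a logical `imbalanced`
#'   truth column.
#' @export
simulate_allele_counts <- function(n_snps, depth_dist = function(n)
                                     stats::rpois(n, 60),
                                   allele_imbalance_frac = 0,
                                   imbalance_ratio = 0.7, seed = 1L) {
  if (imbalance_ratio <= 0 || imbalance_ratio >= 1) {
    stop("imbalance_ratio must lie in (0, 1)")
  }
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  depth <- pmax(1L, as.integer(depth_dist(n_snps)))
  imbalanced <- stats::runif(n_snps) < allele_imbalance_frac
  prob <- ifelse(imbalanced, imbalance_ratio, 0.5)
  ref <- stats::rbinom(n_snps, depth, prob)
  alt <- depth - ref
  data.frame(
    snp = sprintf("snp%05d", seq_len(n_snps)),
    ref_reads = ref, alt_reads = alt,
    ref_unique_pos = pmin(ref, 3L + stats::rpois(n_snps, 3)),
    alt_unique_pos = pmin(alt, 3L + stats::rpois(n_snps, 3)),
    imbalanced = imbalanced,
    stringsAsFactors = FALSE
  )
}

#' Simulate a 4C-seq fragment-end coverage profile
#'
#' Fragment ends are placed at regular spacing on both sides of the
#' viewpoint. Counts are Poisson with a power-law decay mean
#' `lambda(d) = scale * (1 + d)^(-exponent)`, multiplied by `fold`
#' inside planted peak windows.
#'
#' @param viewpoint List with `chrom` and `pos` (1-based).
#' @param n_per_side Fragment ends per side (default 2000, covering
#'   ~528 kb per side at the default spacing, past the proximal 500 kb
#'   reporting window).
#' @param spacing_bp Fragment-end spacing (default 264 bp).
#' @param scale,exponent Decay parameters.
#' @param peaks Optional `data.frame` with columns `offset_bp` (signed
#'   offset of the peak center from the viewpoint), `width_bp` and
#'   `fold`.
#' @param seed Integer seed.
#' @return A fragend `data.frame`: `position`, `count`, `side`
#'   (`"upstream"` / `"downstream"`), `distance`.
#' @export
simulate_fourc <- function(viewpoint, n_per_side = 2000, spacing_bp = 264L,
                           scale = 1000, exponent = 0.5, peaks = NULL,
                           seed = 1L) {
  stopifnot(exponent > 0, scale > 0)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  offs <- spacing_bp * seq_len(n_per_side)
  position <- c(rev(viewpoint$pos - offs), viewpoint$pos + offs)
  distance <- abs(position - viewpoint$pos)
  lambda <- scale * (1 + distance)^(-exponent)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      center <- viewpoint$pos + peaks$offset_bp[i]
      w <- peaks$width_bp[i] / 2
      inside <- position >= center - w & position <= center + w
      lambda[inside] <- lambda[inside] * peaks$fold[i]
    }
  }
  data.frame(
    position = position,
    count = stats::rpois(length(position), lambda),
    side = ifelse(position < viewpoint$pos, "upstream", "downstream"),
    distance = distance,
    stringsAsFactors = FALSE
  )
}
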