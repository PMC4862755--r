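#' Linking configuration
#'
#' @param window_bp Maximum enhancer-midpoint to gene-TSS distance
#'   (default 500 kb).
#' @param min_rpkm Minimum expression required in both the reference
#'   tissue and the differentiated-cardiomyocyte column (default 1).
#' @param alpha Significance level for a link (default 0.05).
#' @param ref_tissue,cm_col Names of the reference-tissue and
#'   cardiomyocyte expression columns.
#' @return A `link_config` list.
#' @export
link_config <- function(window_bp = 5e5, min_rpkm = 1, alpha = 0.05,
                        ref_tissue = "T_ref", cm_col = "CM") {
  stopifnot(window_bp > 0, alpha > 0, alpha < 1)
  structure(list(window_bp = window_bp, min_rpkm = min_rpkm, alpha = alpha,
                 ref_tissue = ref_tissue, cm_col = cm_col),
            class = "link_config")
}

#' Candidate target genes of an enhancer
#'
#' Genes whose TSS lies within the distance window of the enhancer
#' midpoint and whose expression reaches `min_rpkm` in both required
#' expression columns.
#'
#' @param enhancer A length-1 `GRanges`.
#' @param genes Gene `GRanges` with `name` and `tss` metadata columns.
#' @param expression Expression `data.frame` (`gene` + tissue columns).
#' @param cfg A [link_config()].
#' @return Character vector of candidate gene names.
#' @export
candidate_genes <- function(enhancer, genes, expression,
                            cfg = link_config()) {
  stopifnot(length(enhancer) == 1)
  mid <- (GenomicRanges::start(enhancer) + GenomicRanges::end(enhancer)) / 2
  same_chrom <- as.character(GenomicRanges::seqnames(genes)) ==
    as.character(GenomicRanges::seqnames(enhancer))
  near <- same_chrom &
    abs(S4Vectors::mcols(genes)$tss - mid) <= cfg$window_bp
  cand <- S4Vectors::mcols(genes)$name[near]
  rows <- expression[match(cand, expression$gene), , drop = FALSE]
  keep <- !is.na(rows$gene) &
    rows[[cfg$ref_tissue]] >= cfg$min_rpkm &
    rows[[cfg$cm_col]] >= cfg$min_rpkm
  cand[keep]
}

#' Rank test linking an enhancer to a candidate gene
#'
#' Splits the expression of a candidate gene across tissues by whether
#' the enhancer is active there, and applies a one-sided rank test for
#' greater expression in active tissues. A gene with a degenerate
#' split (all tissues active, or none) is skipped.
#'
#' @param active Logical vector: enhancer activity per tissue.
#' @param expression_values Numeric expression per tissue, aligned with
#'   `active`.
#' @param cfg A [link_config()].
#' @return A list: `pvalue`, `linked` (`pvalue < alpha`), `skipped`,
#'   `reason`.
#' @export
link_test <- function(active, expression_values, cfg = link_config()) {
  if (length(active) != length(expression_values)) {
    stop("activity and expression vectors differ in length")
  }
  if (all(active) || !any(active)) {
    return(list(pvalue = NA_real_, linked = FALSE, skipped = TRUE,
                reason = "degenerate split: enhancer active in all or no tissues"))
  }
  rs <- rank_sum(expression_values[active], expression_values[!active],
                 alternative = "greater")
  list(pvalue = rs$pvalue, linked = rs$pvalue < cfg$alpha, skipped = FALSE,
       reason = NA_character_)
}

#' Link an enhancer to its candidate genes
#'
#' Runs [candidate_genes()] then [link_test()] for each candidate.
#'
#' @param enhancer A length-1 `GRanges`.
#' @param active Logical activity vector across tissues (names must
#'   match the expression tissue columns).
#' @param genes Gene `GRanges` with `name` and `tss`.
#' @param expression Expression `data.frame`.
#' @param cfg A [link_config()].
#' @return A `data.frame`: `gene`, `pvalue`, `linked`, `skipped`.
#' @export
link_enhancer <- function(enhancer, active, genes, expression,
                          cfg = link_config()) {
  cand <- candidate_genes(enhancer, genes, expression, cfg)
  if (length(cand) == 0) {
    return(data.frame(gene = character(0), pvalue = numeric(0),
                      linked = logical(0), skipped = logical(0)))
  }
  tissues <- names(active)
  res <- lapply(cand, function(g) {
    expr <- as.numeric(expression[match(g, expression$gene), tissues])
    link_test(active, expr, cfg)
  })
  data.frame(
    gene = cand,
    pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
    linked = vapply(res, `[[`, logical(1), "linked"),
    skipped = vapply(res, `[[`, logical(1), "skipped"),
    stringsAsFactors = FALSE
  )
}

#' Nearest-gene baseline target assignment
#'
#' The commonly applied baseline: the `k` genes with the smallest
#' TSS distance from the enhancer midpoint, within `max_dist_bp`,
#' optionally requiring minimum expression in a reference column. Ties
#' at equal distance break lexicographically by gene name.
#'
#' @param enhancer A length-1 `GRanges`.
#' @param genes Gene `GRanges` with `name` and `tss`.
#' @param k Number of genes (default 1).
#' @param max_dist_bp Maximum distance (default 1 Mb).
#' @param expression Optional expression `data.frame` for the
#'   expression filter.
#' @param min_rpkm,ref_tissue Expression filter parameters (used only
#'   when `expression` is supplied).
#' @return Character vector of up to `k` gene names.
#' @export
nearest_gene_baseline <- function(enhancer, genes, k = 1, max_dist_bp = 1e6,
                                  expression = NULL, min_rpkm = 1,
                                  ref_tissue = "T_ref") {
  stopifnot(length(enhancer) == 1)
  mid <- (GenomicRanges::start(enhancer) + GenomicRanges::end(enhancer)) / 2
  same_chrom <- as.character(GenomicRanges::seqnames(genes)) ==
    as.character(GenomicRanges::seqnames(enhancer))
  d <- abs(S4Vectors::mcols(genes)$tss - mid)
  ok <- same_chrom & d <= max_dist_bp
  nm <- S4Vectors::mcols(genes)$name[ok]
  d <- d[ok]
  if (!is.null(expression)) {
    rows <- expression[match(nm, expression$gene), , drop = FALSE]
    keep <- !is.na(rows$gene) & rows[[ref_tissue]] >= min_rpkm
    nm <- nm[keep]
    d <- d[keep]
  }
  ord <- order(d, nm)
  utils::head(nm[ord], k)
}

#' 2x2 phenotype-enrichment counts for linked genes
#'
#' Builds the 2x2 table (linked vs background genes, relevant phenotype
#' vs not) handed to [fisher_exact()] and [fold_ratio()]. Genes absent
#' from the phenotype table count as having no phenotype.
#'
#' @param linked_genes Character vector of linked gene names
#'   (non-empty).
#' @param phenotype_table `data.frame` with columns `gene` and
#'   `has_phenotype` (logical).
#' @param background_genes Character vector of background gene names.
#' @return A list: `table` (2x2 matrix), `fold`, `fisher`
#'   (`test_result`).
#' @export
phenotype_enrichment_counts <- function(linked_genes, phenotype_table,
                                        background_genes) {
  if (length(linked_genes) == 0) stop("linked gene set is empty")
  has_pheno <- function(g) {
    hit <- phenotype_table$has_phenotype[match(g, phenotype_table$gene)]
    !is.na(hit) & hit
  }
  a <- sum(has_pheno(linked_genes))
  b <- length(linked_genes) - a
  c_ <- sum(has_pheno(background_genes))
  d <- length(background_genes) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("linked", "background"),
                                c("phenotype", "no_phenotype")))
  list(table = tab,
       fold = fold_ratio(a, length(linked_genes), c_,
                         length(background_genes)),
       fisher = fisher_exact(a, b, c_, d))
}
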