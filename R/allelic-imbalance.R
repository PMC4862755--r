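#' Heterozygosity call from allele-specific reads
#'
#' Without genotypes, a SNP is considered heterozygous when reads
#' carrying each allele map to at least `min_unique_pos` unique
#' positions (default 3, inclusive).
#'
#' @param ref_unique_pos,alt_unique_pos Unique mapping positions per
#'   allele.
#' @param min_unique_pos Threshold (default 3).
#' @return Logical vector.
#' @export
call_heterozygous <- function(ref_unique_pos, alt_unique_pos,
                              min_unique_pos = 3) {
  ref_unique_pos >= min_unique_pos & alt_unique_pos >= min_unique_pos
}

#' Allelic imbalance binomial test
#'
#' Two-sided exact binomial test of the reference read count against
#' equal mapping to both alleles (`p0 = 0.5`), applied only to SNPs
#' with more than `min_total_reads_exclusive` reads (strictly greater;
#' default 21). SNPs at or below the read threshold are not tested
#' (`NA`).
#'
#' @param ref_reads,alt_reads Read counts per allele (vectors).
#' @param min_total_reads_exclusive Read-depth threshold, exclusive
#'   (default 21).
#' @param null_prob Null reference-allele probability (default 0.5).
#' @return Numeric vector of p-values; `NA` where not tested.
#' @export
imbalance_test <- function(ref_reads, alt_reads,
                           min_total_reads_exclusive = 21,
                           null_prob = 0.5) {
  stopifnot(null_prob > 0, null_prob < 1)
  n <- ref_reads + alt_reads
  p <- rep(NA_real_, length(n))
  idx <- which(n > min_total_reads_exclusive)
  p[idx] <- vapply(idx, function(i)
    stats::binom.test(ref_reads[i], n[i], p = null_prob)$p.value, numeric(1))
  p
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, applied across the
#' family of tested SNPs (the intended family is all heterozygous
#' enhancer-overlapping SNPs).
#'
#' @param pvalues Numeric vector of p-values (NA-free).
#' @return Adjusted p-values in the input order.
#' @export
correct_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' Allelic imbalance analysis of an allele-counts table
#'
#' Calls heterozygotes, tests imbalance at sufficiently covered SNPs,
#' and adjusts p-values by Benjamini-Hochberg across the tested family.
#'
#' @param counts Allele-counts `data.frame` (see [read_table()] schema
#'   `allele_counts`).
#' @param fdr_alpha FDR level used for the `significant` flag
#'   (default 0.05).
#' @param min_unique_pos,min_total_reads_exclusive,null_prob Test
#'   parameters (see [call_heterozygous()], [imbalance_test()]).
#' @return The input with added columns `het`, `n`, `pvalue`, `p_adj`,
#'   `significant`, `direction`.
#' @export
analyze_imbalance <- function(counts, fdr_alpha = 0.05, min_unique_pos = 3,
                              min_total_reads_exclusive = 21,
                              null_prob = 0.5) {
  out <- counts
  out$het <- call_heterozygous(counts$ref_unique_pos, counts$alt_unique_pos,
                               min_unique_pos)
  out$n <- counts$ref_reads + counts$alt_reads
  out$pvalue <- NA_real_
  testable <- out$het
  out$pvalue[testable] <- imbalance_test(
    counts$ref_reads[testable], counts$alt_reads[testable],
    min_total_reads_exclusive, null_prob)
  out$p_adj <- NA_real_
  tested <- !is.na(out$pvalue)
  out$p_adj[tested] <- correct_fdr(out$pvalue[tested])
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr_alpha
  out$direction <- ifelse(counts$ref_reads > counts$alt_reads, "ref",
                          ifelse(counts$alt_reads > counts$ref_reads,
                                 "alt", "equal"))
  out
}

#' Direction tallies of allele-specific reads
#'
#' Summarizes heterozygous SNPs: how many have more reference than
#' alternate reads (and vice versa, and ties), and the median
#' reference-minus-alternate difference.
#'
#' @param counts Allele-counts `data.frame`.
#' @param min_unique_pos Heterozygosity threshold (default 3).
#' @return A list: `n_het`, `ref_gt_alt`, `alt_gt_ref`, `equal`,
#'   `median_diff`.
#' @export
imbalance_summary <- function(counts, min_unique_pos = 3) {
  het <- call_heterozygous(counts$ref_unique_pos, counts$alt_unique_pos,
                           min_unique_pos)
  d <- counts$ref_reads[het] - counts$alt_reads[het]
  list(
    n_het = sum(het),
    ref_gt_alt = sum(d > 0),
    alt_gt_ref = sum(d < 0),
    equal = sum(d == 0),
    median_diff = if (length(d) > 0) stats::median(d) else NA_real_
  )
}
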