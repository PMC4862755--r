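test_that("r-squared from haplotypes matches hand arithmetic and cor^2", {
  expect_equal(r2_from_haplotypes(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(r2_from_haplotypes(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(r2_from_haplotypes(c(1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0)),
               0.4)
  expect_error(r2_from_haplotypes(c(0, 0, 0), c(0, 1, 0)), "monomorphic")
  set.seed(21)
  for (rep in 1:30) {
    a <- rbinom(20, 1, 0.5); b <- rbinom(20, 1, 0.5)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(r2_from_haplotypes(a, b), oracle_r2(a, b), tolerance = 1e-12)
  }
})

test_that("locus expansion uses strict r2 > threshold and matches brute force", {
  tab <- data.frame(id1 = c("a", "a", "a"), id2 = c("b", "c", "d"),
                    r2 = c(0.9, 0.8, 0.79))
  panel <- ld_panel(r2_table = tab)
  loc <- expand_locus("a", panel)
  expect_setequal(loc$members, c("a", "b"))  # 0.8 boundary excluded
  expect_error(expand_locus("zz", panel), "absent")

  # haplotype panel vs all-pairs recomputation
  set.seed(33)
  nsnp <- 30
  hap <- matrix(rbinom(40 * nsnp, 1, 0.5), nrow = 40,
                dimnames = list(NULL, paste0("s", 1:nsnp)))
  hap <- hap[, apply(hap, 2, function(x) length(unique(x)) == 2)]
  panel_h <- ld_panel(haplotypes = hap)
  lead <- colnames(hap)[1]
  loc <- expand_locus(lead, panel_h, r2_min = 0.1)
  brute <- colnames(hap)[vapply(colnames(hap), function(s)
    s == lead || oracle_r2(hap[, lead], hap[, s]) > 0.1, logical(1))]
  expect_setequal(loc$members, brute)
})

test_that("merged loci are disjoint and shared members split evenly", {
  panel <- toy_panel(list(c("l1", "l2")), r2 = 0.9)
  l1 <- structure(list(lead = "l1", members = c("l1", "x"),
                       r2_threshold = 0.8), class = "locus")
  l2 <- structure(list(lead = "l2", members = c("l2", "y"),
                       r2_threshold = 0.8), class = "locus")
  merged <- merge_and_deduplicate(list(l1, l2), panel)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$members, c("l1", "l2", "x", "y"))

  # shared member between non-merged loci: ~50/50 over seeds, always
  # exactly one holder
  panel2 <- toy_panel(list("a", "b"), r2 = 0)
  la <- structure(list(lead = "a", members = c("a", "shared"),
                       r2_threshold = 0.8), class = "locus")
  lb <- structure(list(lead = "b", members = c("b", "shared"),
                       r2_threshold = 0.8), class = "locus")
  got_a <- vapply(1:400, function(s) {
    out <- merge_and_deduplicate(list(la, lb), panel2, seed = s)
    holders <- sum(vapply(out, function(l) "shared" %in% l$members,
                          logical(1)))
    expect_equal(holders, 1)
    "shared" %in% out[[1]]$members
  }, logical(1))
  expect_gt(mean(got_a), 0.4)
  expect_lt(mean(got_a), 0.6)

  # disjoint loci pass through unchanged
  out <- merge_and_deduplicate(list(la), panel2, seed = 1)
  expect_setequal(out[[1]]$members, c("a", "shared"))
})

test_that("exclusion radius is inclusive and matches a distance filter", {
  snps <- data.frame(id = c("near", "far", "edge"), chrom = "chr1",
                     pos = c(2e6 - 999999, 2e6 + 1000001, 2e6 + 1000000),
                     stringsAsFactors = FALSE)
  known <- data.frame(chrom = "chr1", pos = 2e6)
  kept <- exclude_near_known(snps, known)
  expect_equal(kept$id, "far")

  set.seed(44)
  snps2 <- data.frame(id = paste0("s", 1:300),
                      chrom = sample(c("chr1", "chr2"), 300, TRUE),
                      pos = sample.int(5e6, 300), stringsAsFactors = FALSE)
  known2 <- data.frame(chrom = c("chr1", "chr2"), pos = c(1e6, 4e6))
  kept2 <- exclude_near_known(snps2, known2, radius_bp = 3e5)
  brute <- vapply(seq_len(nrow(snps2)), function(i) {
    !any(known2$chrom == snps2$chrom[i] &
           abs(known2$pos - snps2$pos[i]) <= 3e5)
  }, logical(1))
  expect_equal(kept2$id, snps2$id[brute])
})

test_that("LD pruning keeps the strongest SNP per correlated group", {
  panel <- toy_panel(list(c("a", "b")), r2 = 0.3)
  snps <- data.frame(id = c("a", "b"), chrom = "chr1", pos = c(100, 200),
                     pvalue = c(1e-5, 5e-5), stringsAsFactors = FALSE)
  loci <- define_subthreshold_loci(snps, panel)
  expect_equal(loci$representative, "a")
  expect_setequal(loci$members[[1]], c("a", "b"))

  panel_low <- toy_panel(list(c("a", "b")), r2 = 0.1)
  loci2 <- define_subthreshold_loci(snps, panel_low)
  expect_equal(nrow(loci2), 2)

  # p-value filter is strict
  snps3 <- data.frame(id = "a", chrom = "chr1", pos = 1, pvalue = 1e-4)
  expect_equal(nrow(define_subthreshold_loci(snps3, panel_low)), 0)
})

test_that("pruning matches the exhaustive oracle and is order-invariant", {
  set.seed(55)
  for (rep in 1:8) {
    nsnp <- 40
    ids <- sprintf("s%02d", 1:nsnp)
    blocks <- split(ids, sample(rep(1:10, length.out = nsnp)))
    panel <- toy_panel(blocks, r2 = 0.5)
    snps <- data.frame(id = ids, chrom = "chr1", pos = seq_len(nsnp) * 100,
                       pvalue = runif(nsnp) * 1e-4,
                       stringsAsFactors = FALSE)
    got <- sort(define_subthreshold_loci(snps, panel)$representative)
    r2f <- function(x, y) panel_r2(panel, x, y)
    expect_equal(got, oracle_prune(ids, snps$pvalue, r2f))
    # permuted input rows give the identical surviving set
    perm <- snps[sample.int(nsnp), , drop = FALSE]
    expect_equal(sort(define_subthreshold_loci(perm, panel)$representative),
                 got)
  }
})

test_that("causal-candidate filter retains the 80% boundary inclusively", {
  # max -log10 p = 5; 4.0 is exactly 80% and is retained, 3.9 is not
  ids <- c("top", "boundary", "below", "nop")
  p <- c(1e-5, 1e-4, 10^-3.9, NA)
  expect_setequal(causal_candidate_filter(ids, p), c("top", "boundary"))
  expect_equal(causal_candidate_filter("solo", 0.02), "solo")
  expect_error(causal_candidate_filter("x", NA_real_), "p-value")
})
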