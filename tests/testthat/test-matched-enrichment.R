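make_pool <- function(n = 200, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("p%03d", 1:n), chrom = "chr1",
    pos = sort(sample.int(1e6, n)),
    maf = runif(n, 0.05, 0.5),
    on_array = rep(c(TRUE, FALSE), length.out = n),
    dist_to_nearest_gene = sample(0:60000, n, replace = TRUE),
    n_genes_500kb = sample(3:12, n, replace = TRUE),
    block_size = sample(1:15, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

test_that("control matching enforces every tolerance window", {
  pool <- data.frame(
    id = c("good", "bad_maf", "off_array", "in_locus"),
    chrom = "chr1", pos = 1:4,
    maf = c(0.39, 0.12, 0.30, 0.30),
    on_array = c(TRUE, TRUE, FALSE, TRUE),
    dist_to_nearest_gene = c(74000, 50000, 50000, 50000),
    n_genes_500kb = c(7, 4, 4, 4),
    block_size = c(14, 10, 10, 10), stringsAsFactors = FALSE)
  lead <- data.frame(id = "lead", maf = 0.30, on_array = TRUE,
                     dist_to_nearest_gene = 50000, n_genes_500kb = 4,
                     block_size = 10)
  got <- match_controls(lead, pool, exclude = "in_locus")
  expect_equal(got$id, "good")

  # distance window only applies when the lead is outside a gene
  lead_in_gene <- lead
  lead_in_gene$dist_to_nearest_gene <- 0
  pool2 <- pool[pool$id == "good", , drop = FALSE]
  pool2$dist_to_nearest_gene <- 900000
  expect_equal(match_controls(lead_in_gene, pool2)$id, "good")

  empty_pool <- pool[pool$id == "off_array", , drop = FALSE]
  expect_error(match_controls(lead, empty_pool), "lead")
})

test_that("control matching equals a brute-force filter on random pools", {
  pool <- make_pool(300, seed = 12)
  tol <- match_tolerances()
  for (k in 1:20) {
    lead <- pool[sample.int(nrow(pool), 1), ]
    got <- tryCatch(match_controls(lead, pool, tol)$id, error = function(e) character(0))
    brute <- pool$id[
      abs(pool$block_size - lead$block_size) <= 5 &
        abs(pool$maf - lead$maf) <= 0.1 &
        abs(pool$n_genes_500kb - lead$n_genes_500kb) <= 3 &
        (lead$dist_to_nearest_gene == 0 |
           abs(pool$dist_to_nearest_gene - lead$dist_to_nearest_gene) <= 25000) &
        pool$on_array & pool$id != lead$id]
    expect_setequal(got, brute)
  }
})

test_that("locus overlap counting is locus-level, not SNP-level", {
  variants <- data.frame(id = c("a", "b", "c", "d"), chrom = "chr1",
                         pos = c(15, 16, 17, 500),
                         stringsAsFactors = FALSE)
  ann <- annotation_set("chr1", 10, 20)
  loci <- list(
    structure(list(lead = "a", members = c("a", "b", "c"),
                   r2_threshold = 0.8), class = "locus"),
    structure(list(lead = "d", members = "d", r2_threshold = 0.8),
              class = "locus"))
  expect_equal(count_locus_overlaps(loci, ann, variants), 1)
  whole <- annotation_set("chr1", 0, 1000)
  expect_equal(count_locus_overlaps(loci, whole, variants), 2)

  # brute-force double loop on random input
  set.seed(31)
  iv <- random_intervals(30, chroms = "chr1", max_pos = 900)
  v2 <- data.frame(id = sprintf("v%02d", 1:40), chrom = "chr1",
                   pos = sample.int(950, 40), stringsAsFactors = FALSE)
  rloci <- lapply(1:10, function(i) {
    structure(list(lead = v2$id[i],
                   members = sample(v2$id, sample(1:4, 1)),
                   r2_threshold = 0.8), class = "locus")
  })
  brute <- sum(vapply(rloci, function(l) {
    any(vapply(l$members, function(m) {
      i <- match(m, v2$id)
      length(oracle_overlap(iv$df, v2$chrom[i], v2$pos[i])) > 0
    }, logical(1)))
  }, logical(1)))
  expect_equal(count_locus_overlaps(rloci, iv$gr, v2), brute)
})

test_that("permutation null moments and empirical p follow the formulas", {
  res <- subthresh:::enrichment_result(4, c(1, 2, 3))
  expect_equal(res$z, 2)           # sample sd of {1,2,3} is 1
  expect_equal(res$empirical_p, 1 / 4)
  flat <- subthresh:::enrichment_result(2, c(2, 2, 2))
  expect_true(flat$degenerate)
  expect_equal(flat$z, 0)
  above <- subthresh:::enrichment_result(3, c(2, 2, 2))
  expect_true(is.infinite(above$z) && above$z > 0)
})

test_that("enrichment detects annotation covering the test loci", {
  sim <- simulate_variants_and_ld(sim_config(seed = 2, n_snps = 2000,
                                             n_chrom = 2))
  v <- sim$variants
  set.seed(8)
  leads <- sample(v$id[v$on_array], 10)
  test_loci <- lapply(leads, expand_locus, panel = sim$panel)
  # annotation tiling every test lead: observed count is maximal
  lead_pos <- v[match(leads, v$id), ]
  ann <- annotation_set(lead_pos$chrom, lead_pos$pos - 1, lead_pos$pos + 1)
  res <- permutation_enrichment(test_loci, v, sim$panel, ann, v,
                                n_perm = 500, seed = 3)
  expect_equal(res$observed, 10)
  expect_gt(res$z, 2)
  expect_lt(res$empirical_p, 0.05)
})

test_that("motif shuffling preserves counts and lengths, and seeds repeat", {
  motifs <- list(list(motif = "M1", tf = "TF1", tf_expressed = TRUE,
                      instances = annotation_set(
                        c("chr1", "chr1", "chr2"), c(10, 50, 100),
                        c(25, 60, 130))))
  lens <- c(15, 10, 30)
  sh1 <- shuffle_motif_instances(motifs, c(chr1 = 1e4, chr2 = 1e4), seed = 5)
  sh2 <- shuffle_motif_instances(motifs, c(chr1 = 1e4, chr2 = 1e4), seed = 5)
  expect_equal(sort(GenomicRanges::width(sh1[[1]]$instances)), sort(lens))
  expect_equal(GenomicRanges::start(sh1[[1]]$instances),
               GenomicRanges::start(sh2[[1]]$instances))
  sh3 <- shuffle_motif_instances(motifs, c(chr1 = 1e4, chr2 = 1e4), seed = 6)
  expect_false(identical(GenomicRanges::start(sh1[[1]]$instances),
                         GenomicRanges::start(sh3[[1]]$instances)))
})

test_that("motif-disruption statistic counts enhancer+motif SNPs by locus", {
  v <- data.frame(id = c("a", "b", "c", "d", "e", "f"), chrom = "chr1",
                  pos = c(15, 55, 300, 400, 500, 600),
                  maf = 0.3, on_array = TRUE, dist_to_nearest_gene = 0,
                  n_genes_500kb = 5, block_size = 3, stringsAsFactors = FALSE)
  enh <- annotation_set("chr1", c(10, 50), c(20, 60))
  motifs <- list(
    list(motif = "M1", tf = "TF1", tf_expressed = TRUE,
         instances = annotation_set("chr1", 12, 18)),
    list(motif = "M2", tf = "TF2", tf_expressed = FALSE,
         instances = annotation_set("chr1", 52, 58)))
  loci <- lapply(c("a", "b", "c"), function(i)
    structure(list(lead = i, members = i, r2_threshold = 0.8),
              class = "locus"))
  panel <- toy_panel(list("a", "b", "c", "d", "e", "f"), r2 = 0)
  res <- motif_disruption_enrichment(loci, v, panel, enh, motifs, v,
                                     n_perm = 50, seed = 1)
  # only SNP "a" is in an enhancer AND in an expressed-TF motif;
  # "b" sits in a motif of a non-expressed TF
  expect_equal(res$observed, 1)
})
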