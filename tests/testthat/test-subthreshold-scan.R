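test_that("enrichment fold follows the proportion-ratio definition", {
  # 10 of 100 foreground below cutoff; 100 of 10000 genome-wide -> fold 10
  set.seed(41)
  n <- 10000
  pos <- seq_len(n) * 100
  pvalue <- rep(0.5, n)
  pvalue[1:100] <- 1e-6          # below a -log p = 5 cutoff
  snps <- data.frame(id = paste0("s", 1:n), chrom = "chr1", pos = pos,
                     pvalue = pvalue, stringsAsFactors = FALSE)
  # foreground = first 10 hits + 90 nulls
  fg_idx <- c(1:10, 201:290)
  ann <- annotation_set("chr1", pos[fg_idx] - 1, pos[fg_idx])
  curve <- enrichment_curve(snps, ann)
  row5 <- curve[curve$threshold == 5, ]
  expect_equal(row5$n_fg_below, 10)
  expect_equal(row5$n_fg_total, 100)
  expect_equal(row5$n_bg_below, 100)
  expect_equal(row5$fold, 10)
  # fold(0) = 1 when every SNP has p < 1
  expect_equal(curve$fold[curve$threshold == 0], 1)
  # undefined where no background SNP passes
  expect_true(is.na(curve$fold[curve$threshold == 9]))
})

test_that("annotation covering every SNP gives fold 1 throughout", {
  set.seed(42)
  snps <- data.frame(id = paste0("s", 1:500), chrom = "chr1",
                     pos = seq_len(500) * 10, pvalue = runif(500),
                     stringsAsFactors = FALSE)
  ann <- annotation_set("chr1", 0, 1e6)
  curve <- enrichment_curve(snps, ann)
  defined <- !is.na(curve$fold)
  expect_true(all(abs(curve$fold[defined] - 1) < 1e-12))
  # row order invariance
  shuf <- snps[sample.int(500), ]
  expect_equal(enrichment_curve(shuf, ann), curve)
  # empty foreground errors
  far <- annotation_set("chr9", 0, 10)
  expect_error(enrichment_curve(snps, far), "foreground")
})

test_that("null-data folds stay within binomial sampling bounds", {
  sim <- simulate_variants_and_ld(sim_config(seed = 51))
  g <- simulate_gwas(sim$variants, seed = 51)
  cfg <- sim_config(seed = 51)
  tp <- simulate_tissue_panels(cfg, sim$genes, seed = 52)
  curve <- enrichment_curve(g, tp$enhancers)
  check <- curve[curve$n_bg_below >= 100, ]
  p_fg <- check$n_fg_total[1] / check$n_bg_total[1]
  # fg_below ~ Binomial(n_bg_below, p_fg) under the null
  zscores <- (check$n_fg_below - check$n_bg_below * p_fg) /
    sqrt(check$n_bg_below * p_fg * (1 - p_fg))
  expect_lt(max(abs(zscores)), 4)
})

test_that("exclusions remove masked regions and known-locus windows", {
  snps <- data.frame(id = c("in_mask", "near_locus", "clean"),
                     chrom = c("chr6", "chr1", "chr1"),
                     pos = c(30e6, 1.5e6, 4e6),
                     pvalue = c(1e-6, 1e-6, 1e-6), stringsAsFactors = FALSE)
  zones <- exclusion_zones(
    radius_bp = 1e6,
    masked_regions = annotation_set("chr6", 24182924, 34537546))
  known <- data.frame(chrom = "chr1", pos = 1e6)
  out <- apply_exclusions(snps, zones, known)
  expect_equal(out$id, "clean")
  # empty zones are the identity
  out2 <- apply_exclusions(snps, exclusion_zones(masked_regions = NULL),
                           known_members = NULL)
  expect_equal(out2, snps)
  # curve after exclusion equals curve on manually filtered input
  set.seed(6)
  snps3 <- data.frame(id = paste0("s", 1:400), chrom = "chr6",
                      pos = sort(sample.int(50e6, 400)),
                      pvalue = runif(400), stringsAsFactors = FALSE)
  manual <- snps3[!(snps3$pos >= 24182925 & snps3$pos <= 34537546), ]
  auto <- apply_exclusions(snps3, zones, known_members = NULL)
  expect_equal(auto$id, manual$id)
})

test_that("refined enhancer subsets tighten or reproduce the base curve", {
  sim <- simulate_variants_and_ld(sim_config(seed = 61, n_snps = 4000))
  cfg <- sim_config(seed = 61)
  tp <- simulate_tissue_panels(cfg, sim$genes, seed = 62)
  v <- sim$variants
  in_strong <- snps_in_annotation(
    tp$enhancers[S4Vectors::mcols(tp$enhancers)$strong], v$chrom, v$pos)
  planted <- data.frame(id = v$id[in_strong][1:15], ncp = 4)
  g <- simulate_gwas(v, planted, sim$panel, seed = 63)

  # cutoff -Inf keeps every enhancer: identical to the base curve
  refs <- list(all = list(track = tp$h3k27ac, cutoff = -Inf))
  base <- enrichment_curve(g, tp$enhancers)
  expect_equal(refined_subset_curves(g, tp$enhancers, refs)$all, base)

  # high-acetylation refinement concentrates the planted signal
  refs2 <- list(strong = list(track = tp$h3k27ac, cutoff = 4))
  refined <- refined_subset_curves(g, tp$enhancers, refs2)$strong
  i <- which(base$threshold == 4)
  expect_gte(refined$fold[i], base$fold[i])

  refs3 <- list(impossible = list(track = tp$h3k27ac, cutoff = 1e9))
  expect_error(refined_subset_curves(g, tp$enhancers, refs3), "empties")
})

test_that("replication p is the min over LD partners and traits", {
  panel <- toy_panel(list(c("rep", "pA", "pB")), r2 = 0.9)
  stats <- data.frame(id = c("rep", "pA", "pB"),
                      qrs = c(0.2, 0.04, NA),
                      cornell = c(0.5, 0.3, 0.6), stringsAsFactors = FALSE)
  expect_equal(assign_replication_p("rep", panel, stats), 0.04)
  # single trait, single SNP
  solo <- data.frame(id = "rep", qrs = 0.7)
  panel_solo <- toy_panel(list("rep"), r2 = 0)
  expect_equal(assign_replication_p("rep", panel_solo, solo), 0.7)
  # absent from replication data is a value, not an error
  empty <- data.frame(id = "other", qrs = 0.1)
  expect_true(is.na(assign_replication_p("rep", panel_solo, empty)))
})
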