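#' Pipeline configuration
#'
#' Global parameters shared by the pipeline stages. Can be read from a
#' YAML file with [read_pipeline_config()].
#'
#' @param seed Integer master seed; every stochastic stage derives its
#'   seed from it.
#' @param p_subthreshold Sub-threshold cutoff (default 1e-4).
#' @param p_gws Genome-wide significance cutoff (default 5e-8).
#' @param exclusion_radius_bp Radius around known loci (default 1 Mb).
#' @param n_perm Permutations for enrichment stages (default 1e5).
#' @param sim A [sim_config()] for the simulate stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, p_subthreshold = 1e-4, p_gws = 5e-8,
                            exclusion_radius_bp = 1e6, n_perm = 1e5,
                            sim = sim_config(seed = seed)) {
  stopifnot(p_gws > 0, p_gws < p_subthreshold, p_subthreshold < 1,
            n_perm >= 1)
  structure(list(seed = as.integer(seed), p_subthreshold = p_subthreshold,
                 p_gws = p_gws, exclusion_radius_bp = exclusion_radius_bp,
                 n_perm = n_perm, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys match [pipeline_config()]
#'   arguments, with simulation parameters under `sim`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (is.null(sim_args$seed) && !is.null(y$seed)) sim_args$seed <- y$seed
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run pipeline stages end to end on synthetic data
#'
#' Chains the analysis stages on a synthetic input bundle, writing each
#' stage's outputs (TSV/JSON) under `out_dir` together with a log of
#' seeds and parameters. Re-running with the same configuration
#' reproduces the outputs. Stages later in the chain require the
#' outputs of earlier ones and fail with an error naming the missing
#' stage.
#'
#' Stages: `simulate` (generate the input bundle), `loci` (sub-threshold
#' locus definition), `enrich` (matched-control enrichment of
#' significant loci in enhancers), `scan` (sliding-threshold
#' enrichment curve), `link` (enhancer-gene linking), `imbalance`
#' (allelic imbalance), `fourc` (4C peak calling), `evidence`
#' (power projection and summary counts).
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stage names, in order.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "loci", "enrich", "scan",
                                    "link", "imbalance", "fourc",
                                    "evidence"),
                         out_dir = tempfile("pipeline")) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "loci", "enrich", "scan", "link", "imbalance",
             "fourc", "evidence")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(..., "\n", file = log_path, append = TRUE)
  results <- list()
  need <- function(what, stage) {
    if (!exists(what, envir = state)) {
      stop("stage '", stage, "' requires output of stage 'simulate'",
           if (what == "loci_table") " and 'loci'" else "",
           "; run it first")
    }
    get(what, envir = state)
  }

  for (stage in stages) {
    log_line(format(Sys.time()), "stage", stage, "seed", config$seed)
    if (stage == "simulate") {
      sim <- simulate_bundle(config)
      assign("sim", sim, envir = state)
      write_table(sim$variants, file.path(out_dir, "variants.tsv"))
      write_table(sim$gwas, file.path(out_dir, "summary_stats.tsv"))
      write_intervals(sim$tissues$enhancers,
                      file.path(out_dir, "enhancers.bed"))
      write_table(sim$tissues$expression, file.path(out_dir, "expression.tsv"))
      write_table(sim$allele_counts, file.path(out_dir, "allele_counts.tsv"))
      write_table(sim$fourc, file.path(out_dir, "fourc_fragends.tsv"))
      jsonlite::write_json(
        list(seed = config$seed,
             n_snps = nrow(sim$variants),
             n_enhancers = length(sim$tissues$enhancers),
             planted = sim$planted),
        file.path(out_dir, "simulate_manifest.json"),
        auto_unbox = TRUE, digits = NA)
      results$simulate <- sim
    } else if (stage == "loci") {
      sim <- need("sim", stage)
      loci <- define_subthreshold_loci(sim$gwas, sim$panel,
                                       p_max = config$p_subthreshold)
      in_enh <- snps_in_annotation(
        sim$tissues$enhancers,
        sim$variants$chrom[match(loci$representative, sim$variants$id)],
        sim$variants$pos[match(loci$representative, sim$variants$id)])
      loci$overlaps_enhancer <- in_enh
      assign("loci_table", loci, envir = state)
      flat <- loci
      flat$members <- vapply(flat$members, paste, character(1),
                             collapse = ",")
      write_table(flat, file.path(out_dir, "subthreshold_loci.tsv"))
      results$loci <- loci
    } else if (stage == "enrich") {
      sim <- need("sim", stage)
      gws <- sim$gwas[sim$gwas$pvalue < config$p_gws, , drop = FALSE]
      if (nrow(gws) == 0) stop("no genome-wide significant loci to test")
      pruned <- define_subthreshold_loci(gws, sim$panel, p_max = 1)
      test_loci <- lapply(pruned$representative, expand_locus,
                          panel = sim$panel)
      res <- permutation_enrichment(
        test_loci, pool = sim$variants, panel = sim$panel,
        annotation = sim$tissues$enhancers, variants = sim$variants,
        n_perm = config$n_perm, seed = config$seed + 1L)
      jsonlite::write_json(unclass(res),
                           file.path(out_dir, "enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      results$enrich <- res
    } else if (stage == "scan") {
      sim <- need("sim", stage)
      curve <- enrichment_curve(sim$gwas, sim$tissues$enhancers)
      write_table(curve, file.path(out_dir, "enrichment_curve.tsv"))
      results$scan <- curve
    } else if (stage == "link") {
      sim <- need("sim", stage)
      if (is.null(sim$tissues$expression)) {
        stop("stage 'link' requires the expression matrix")
      }
      enh <- sim$tissues$enhancers
      links <- do.call(rbind, lapply(seq_along(enh), function(i) {
        df <- link_enhancer(enh[i], sim$tissues$activity[i, ], sim$genes,
                            sim$tissues$expression)
        if (nrow(df) > 0) df$enhancer <- S4Vectors::mcols(enh)$name[i]
        df
      }))
      write_table(links, file.path(out_dir, "gene_links.tsv"))
      results$link <- links
    } else if (stage == "imbalance") {
      sim <- need("sim", stage)
      imb <- analyze_imbalance(sim$allele_counts)
      write_table(imb, file.path(out_dir, "allelic_imbalance.tsv"))
      results$imbalance <- imb
    } else if (stage == "fourc") {
      sim <- need("sim", stage)
      fc <- call_fourc_peaks(sim$fourc, viewpoint_pos = sim$fourc_viewpoint)
      write_table(fc$fragends, file.path(out_dir, "fourc_profile.tsv"))
      write_table(fc$peaks, file.path(out_dir, "fourc_peaks.tsv"))
      results$fourc <- fc
    } else if (stage == "evidence") {
      sim <- need("sim", stage)
      power <- required_n_for_power(
        alpha = config$p_gws, power_current = 0.1276, n_current = 68900,
        power_target = 0.8)
      ev <- list(
        n_snps = nrow(sim$variants),
        n_subthreshold_snps = sum(sim$gwas$pvalue < config$p_subthreshold),
        power_projection = power
      )
      jsonlite::write_json(ev, file.path(out_dir, "evidence.json"),
                           auto_unbox = TRUE, digits = NA)
      results$evidence <- ev
    }
  }
  invisible(results)
}

# one synthetic input bundle under a pipeline config: variants + LD,
# GWAS with signals planted in enhancers, tissue panels, allele counts,
# one 4C profile with a planted contact
simulate_bundle <- function(config) {
  sim <- simulate_variants_and_ld(config$sim)
  tissues <- simulate_tissue_panels(config$sim, sim$genes,
                                    seed = config$sim$seed + 1L)
  in_enh <- snps_in_annotation(tissues$enhancers, sim$variants$chrom,
                               sim$variants$pos)
  restore <- local_rng(config$sim$seed + 2L)
  enh_snps <- sim$variants$id[in_enh]
  n_plant <- min(20L, length(enh_snps))
  planted <- data.frame(
    id = if (n_plant > 0) sample(enh_snps, n_plant) else character(0),
    ncp = rep(6, n_plant), stringsAsFactors = FALSE)
  restore()
  gwas <- simulate_gwas(sim$variants, planted, sim$panel,
                        seed = config$sim$seed + 3L)
  counts <- simulate_allele_counts(2000, allele_imbalance_frac = 0.1,
                                   seed = config$sim$seed + 4L)
  viewpoint <- list(chrom = "chr1", pos = 5e6)
  fourc <- simulate_fourc(
    viewpoint, n_per_side = 2000,
    spacing_bp = config$sim$fragend_spacing_bp,
    scale = config$sim$fourc_scale, exponent = config$sim$fourc_exponent,
    peaks = data.frame(offset_bp = 2e5, width_bp = 6000, fold = 50),
    seed = config$sim$seed + 5L)
  list(variants = sim$variants, panel = sim$panel, genes = sim$genes,
       tissues = tissues, planted = planted, gwas = gwas,
       allele_counts = counts, fourc = fourc,
       fourc_viewpoint = viewpoint$pos)
}
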