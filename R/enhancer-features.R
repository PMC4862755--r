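#' Mean signal over an interval
#'
#' Per-base mean of a signal track over a genomic interval; bases not
#' covered by any track segment count as 0 (bedGraph sparse semantics).
#'
#' @param track Signal track `GRanges` with `score` (see
#'   [signal_track()]).
#' @param interval A length-1 `GRanges`.
#' @return The per-base mean.
#' @export
average_signal <- function(track, interval) {
  stopifnot(length(interval) == 1)
  w <- GenomicRanges::width(interval)
  if (w < 1) stop("zero-length interval")
  ov <- suppressWarnings(GenomicRanges::findOverlaps(interval, track))
  if (length(ov) == 0) return(0)
  seg <- track[S4Vectors::subjectHits(ov)]
  inter_w <- pmin(GenomicRanges::end(seg), GenomicRanges::end(interval)) -
    pmax(GenomicRanges::start(seg), GenomicRanges::start(interval)) + 1
  sum(inter_w * S4Vectors::mcols(seg)$score) / w
}

#' Compare a functional feature between two enhancer groups
#'
#' Reports the ratio of group medians (foreground over background) and
#' a two-sided Mann-Whitney U p-value via [rank_sum()].
#'
#' @param fg_values,bg_values Numeric feature values for the foreground
#'   (e.g. trait-overlapping enhancers) and background groups.
#' @param feature Feature name carried into the result.
#' @return A `data.frame` row: `feature`, `fold_change`, `u_statistic`,
#'   `pvalue`, `n_fg`, `n_bg`. `fold_change` is `NA` (with a warning)
#'   when the background median is zero.
#' @export
compare_feature <- function(fg_values, bg_values, feature = "feature") {
  if (length(fg_values) < 1 || length(bg_values) < 1) {
    stop("both groups must be non-empty")
  }
  med_bg <- stats::median(bg_values)
  fold <- if (med_bg == 0) {
    warning("background median is 0: fold change undefined")
    NA_real_
  } else stats::median(fg_values) / med_bg
  rs <- rank_sum(fg_values, bg_values, alternative = "two.sided")
  data.frame(
    feature = feature, fold_change = fold, u_statistic = rs$statistic,
    pvalue = rs$pvalue, n_fg = length(fg_values), n_bg = length(bg_values),
    stringsAsFactors = FALSE
  )
}

#' Call tissue-specific CpG methylation
#'
#' Classifies a CpG as hypomethylated (or hypermethylated) in the
#' reference tissue when its percent methylation differs from the mean
#' of the comparison tissues by both (i) `sd_multiple` standard
#' deviations of the comparison tissues and (ii) at least
#' `min_abs_diff_pp` percentage points. Both criteria are inclusive.
#'
#' @param ref_value Percent methylation in the reference tissue.
#' @param comparison_values Percent methylation in >= 2 comparison
#'   (non-reference) tissues.
#' @param sd_multiple SD criterion multiplier (default 2).
#' @param min_abs_diff_pp Minimum absolute difference in percentage
#'   points (default 15).
#' @return `"hypo"`, `"hyper"` or `"neither"`.
#' @export
call_tissue_specific_methylation <- function(ref_value, comparison_values,
                                             sd_multiple = 2,
                                             min_abs_diff_pp = 15) {
  if (is.na(ref_value)) stop("reference methylation value is missing")
  if (length(comparison_values) < 2) {
    stop("need >= 2 comparison tissues to define an SD")
  }
  stopifnot(sd_multiple > 0, min_abs_diff_pp >= 0)
  m <- mean(comparison_values)
  s <- stats::sd(comparison_values)
  need <- max(sd_multiple * s, min_abs_diff_pp)
  if (m - ref_value >= need) "hypo"
  else if (ref_value - m >= need) "hyper"
  else "neither"
}

#' Most conserved fixed-width window of an enhancer
#'
#' Scans all 1-bp start offsets and returns the window with the
#' greatest mean track value (ties broken leftmost). Enhancers shorter
#' than the window fall back to the whole-enhancer mean, flagged via
#' the `truncated` field.
#'
#' @param track Signal track `GRanges` with `score` (e.g. per-base
#'   conservation).
#' @param enhancer A length-1 `GRanges`.
#' @param window_bp Window width (default 100).
#' @return A list: `start` (1-based window start), `score` (window
#'   mean), `truncated`.
#' @export
best_conserved_window <- function(track, enhancer, window_bp = 100) {
  stopifnot(length(enhancer) == 1, window_bp >= 1)
  w <- GenomicRanges::width(enhancer)
  vals <- per_base_values(track, enhancer)
  if (w < window_bp) {
    return(list(start = GenomicRanges::start(enhancer), score = mean(vals),
                truncated = TRUE))
  }
  cs <- cumsum(c(0, vals))
  means <- (cs[(window_bp + 1):(w + 1)] - cs[1:(w - window_bp + 1)]) / window_bp
  # leftmost maximum, robust to cumsum rounding noise
  best <- which(means >= max(means) - 1e-9)[1]
  list(start = GenomicRanges::start(enhancer) + best - 1L,
       score = means[best], truncated = FALSE)
}

# per-base signal values across a single interval (uncovered bases = 0)
per_base_values <- function(track, interval) {
  w <- GenomicRanges::width(interval)
  vals <- numeric(w)
  ov <- GenomicRanges::findOverlaps(interval, track)
  if (length(ov) > 0) {
    seg <- track[S4Vectors::subjectHits(ov)]
    lo <- pmax(GenomicRanges::start(seg), GenomicRanges::start(interval))
    hi <- pmin(GenomicRanges::end(seg), GenomicRanges::end(interval))
    off <- GenomicRanges::start(interval) - 1L
    for (i in seq_along(seg)) {
      vals[(lo[i] - off):(hi[i] - off)] <- S4Vectors::mcols(seg)$score[i]
    }
  }
  vals
}

#' Size-matched empirical test of enhancer conservation
#'
#' Tests whether foreground enhancers have greater best-window
#' conservation than expected for background enhancers of similar
#' length. The statistic is the median over foreground enhancers of
#' their best-window scores; each null set draws, per foreground
#' enhancer, one background enhancer whose length is within
#' `size_tolerance_bp`. The empirical p-value carries the add-one
#' correction.
#'
#' @param fg_enhancers,bg_enhancers `GRanges` of foreground and
#'   background enhancers.
#' @param track Conservation signal track.
#' @param window_bp Window width (default 100).
#' @param n_control_sets Number of size-matched null sets
#'   (default 1000).
#' @param size_tolerance_bp Length-matching tolerance (default 1000).
#' @param seed Integer seed.
#' @return A list: `observed` (median fg score), `empirical_p`,
#'   `null_values`.
#' @export
size_matched_conservation_test <- function(fg_enhancers, bg_enhancers, track,
                                           window_bp = 100,
                                           n_control_sets = 1000,
                                           size_tolerance_bp = 1000,
                                           seed = 1L) {
  fg_scores <- vapply(seq_along(fg_enhancers), function(i)
    best_conserved_window(track, fg_enhancers[i], window_bp)$score, numeric(1))
  bg_scores <- vapply(seq_along(bg_enhancers), function(i)
    best_conserved_window(track, bg_enhancers[i], window_bp)$score, numeric(1))
  fg_len <- GenomicRanges::width(fg_enhancers)
  bg_len <- GenomicRanges::width(bg_enhancers)
  cand <- lapply(seq_along(fg_enhancers), function(i) {
    idx <- which(abs(bg_len - fg_len[i]) <= size_tolerance_bp)
    if (length(idx) == 0) {
      stop("no size-matched background enhancer for foreground enhancer ", i)
    }
    idx
  })
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  null_values <- vapply(seq_len(n_control_sets), function(k) {
    stats::median(bg_scores[vapply(cand, function(idx)
      idx[sample.int(length(idx), 1)], integer(1))])
  }, numeric(1))
  list(observed = stats::median(fg_scores),
       empirical_p = empirical_p(stats::median(fg_scores), null_values),
       null_values = null_values)
}

#' Cross-tissue activity of an enhancer
#'
#' An enhancer is active in another tissue iff it intersects that
#' tissue's enhancer calls by at least 1 bp.
#'
#' @param enhancer A length-1 `GRanges`.
#' @param other_tissue_sets Named list of per-tissue `GRanges`.
#' @return A list: `active` (named logical vector) and `count`.
#' @export
cross_tissue_activity <- function(enhancer, other_tissue_sets) {
  stopifnot(length(enhancer) == 1)
  active <- vapply(other_tissue_sets, function(s)
    suppressWarnings(GenomicRanges::countOverlaps(enhancer, s)) > 0,
    logical(1))
  list(active = active, count = sum(active))
}
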