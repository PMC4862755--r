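#' Running-window 4C coverage
#'
#' Smooths raw fragment-end counts by a centered running mean over
#' `window` fragment ends; the window truncates at profile edges (no
#' padding).
#'
#' @param counts Numeric vector of raw fragend counts, in genomic
#'   order.
#' @param window Odd window size in fragends (default 21).
#' @return Numeric vector of smoothed values, same length.
#' @export
windowed_coverage <- function(counts, window = 21) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(counts)
  if (n == 0) stop("empty profile")
  h <- (window - 1) / 2
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Monotone decay background for a 4C profile side
#'
#' Least-squares non-increasing fit of the smoothed 4C signal as a
#' function of distance to the viewpoint (pool-adjacent-violators),
#' modeling the monotone decay of contact probability in an
#' unstructured chromatin fiber. Each side of the viewpoint is fitted
#' independently by the caller.
#'
#' @param values Smoothed values for one side, ordered by increasing
#'   distance to the viewpoint.
#' @return Fitted non-increasing values.
#' @export
fit_monotone_background <- function(values) {
  n <- length(values)
  if (n < 2) return(values)
  # non-increasing fit = negated non-decreasing isotonic fit
  -stats::isoreg(seq_len(n), -values)$yf
}

#' Call 4C interaction peaks on one profile
#'
#' Smooths the profile, fits the monotone background independently on
#' each side of the viewpoint, and flags fragends whose residual
#' exceeds `Q3 + q * IQR` of that side's residual distribution.
#' Consecutive significant fragends merge into one peak.
#'
#' @param profile Fragend `data.frame` (`position`, `count`), positions
#'   strictly increasing; the viewpoint must lie between the two sides.
#' @param viewpoint_pos Viewpoint position (1-based).
#' @param window Running-window size (default 21).
#' @param q Exceedance multiplier (default 5).
#' @return A list: `fragends` (per-fragend `data.frame` with `smoothed`,
#'   `background`, `residual`, `significant`) and `peaks` (`data.frame`
#'   with `start`, `end` (0-based half-open span of member fragends),
#'   `side`, `max_exceedance`, `n_fragends`).
#' @export
call_fourc_peaks <- function(profile, viewpoint_pos, window = 21, q = 5) {
  stopifnot(q > 0)
  if (any(diff(profile$position) <= 0)) {
    stop("fragend positions must be strictly increasing")
  }
  side <- ifelse(profile$position < viewpoint_pos, "upstream", "downstream")
  out <- profile
  out$side <- side
  out$smoothed <- NA_real_
  out$background <- NA_real_
  for (s in unique(side)) {
    idx <- which(side == s)
    sm <- windowed_coverage(profile$count[idx], window)
    dist_order <- order(abs(profile$position[idx] - viewpoint_pos))
    bg <- numeric(length(idx))
    bg[dist_order] <- fit_monotone_background(sm[dist_order])
    out$smoothed[idx] <- sm
    out$background[idx] <- bg
  }
  out$residual <- out$smoothed - out$background
  out$significant <- FALSE
  out$threshold <- NA_real_
  for (s in unique(side)) {
    idx <- which(side == s)
    r <- out$residual[idx]
    thr <- stats::quantile(r, 0.75, names = FALSE) + q * stats::IQR(r)
    out$threshold[idx] <- thr
    out$significant[idx] <- r > thr
  }
  peaks <- merge_significant_runs(out)
  list(fragends = out, peaks = peaks)
}

# merge runs of consecutive significant fragends (per side) into peaks
merge_significant_runs <- function(fr) {
  sig <- which(fr$significant)
  if (length(sig) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      side = character(0), max_exceedance = numeric(0),
                      n_fragends = integer(0)))
  }
  run_id <- cumsum(c(1, diff(sig) != 1 |
                       fr$side[sig[-1]] != fr$side[sig[-length(sig)]]))
  runs <- split(sig, run_id)
  do.call(rbind, lapply(runs, function(idx) {
    data.frame(
      start = fr$position[idx[1]] - 1L,
      end = fr$position[idx[length(idx)]],
      side = fr$side[idx[1]],
      max_exceedance = max(fr$residual[idx] - fr$threshold[idx]),
      n_fragends = length(idx),
      stringsAsFactors = FALSE
    )
  }))
}

#' Annotate peaks with promoter interactions
#'
#' Flags peaks intersecting an annotated promoter, defined strand-aware
#' as the `promoter_upstream_bp` window upstream of a gene TSS
#' (including the TSS base). Reporting is limited to peaks within
#' `proximal_bp` of the viewpoint.
#'
#' @param peaks Peak `data.frame` from [call_fourc_peaks()] (same
#'   chromosome as the viewpoint).
#' @param genes `data.frame` with columns `name`, `tss` (1-based) and
#'   `strand` (`"+"`/`"-"`).
#' @param viewpoint_pos Viewpoint position.
#' @param promoter_upstream_bp Promoter window upstream of the TSS
#'   (default 2500).
#' @param proximal_bp Reporting window around the viewpoint
#'   (default 500 kb).
#' @return `peaks` filtered to the proximal window, with a
#'   `promoter_hit` column (gene name or `NA`).
#' @export
annotate_promoter_interactions <- function(peaks, genes, viewpoint_pos,
                                           promoter_upstream_bp = 2500,
                                           proximal_bp = 5e5) {
  if (nrow(peaks) == 0) {
    peaks$promoter_hit <- character(0)
    return(peaks)
  }
  # keep peaks intersecting the +/- proximal window around the viewpoint
  win_lo <- viewpoint_pos - proximal_bp
  win_hi <- viewpoint_pos + proximal_bp
  prox <- peaks[peaks$end >= win_lo & peaks$start + 1 <= win_hi, ,
                drop = FALSE]
  prom_lo <- ifelse(genes$strand == "+", genes$tss - promoter_upstream_bp,
                    genes$tss)
  prom_hi <- ifelse(genes$strand == "+", genes$tss,
                    genes$tss + promoter_upstream_bp)
  prox$promoter_hit <- NA_character_
  for (i in seq_len(nrow(prox))) {
    # peak is 0-based half-open: 1-based span [start+1, end]
    hits <- which(prom_lo <= prox$end[i] & prom_hi >= prox$start[i] + 1)
    if (length(hits) > 0) prox$promoter_hit[i] <- genes$name[hits[1]]
  }
  prox
}
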