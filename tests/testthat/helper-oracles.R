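# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs, plus tiny fixture builders.

# linear-scan point-in-interval query over a plain data.frame of
# 0-based half-open intervals
oracle_overlap <- function(intervals, chrom, pos) {
  hit <- intervals$chrom == chrom &
    intervals$start <= (pos - 1) & (pos - 1) < intervals$end
  which(hit)
}

# r-squared via squared Pearson correlation of 0/1 haplotype vectors
# (algebraically equal to D^2 / (pA qA pB qB), computed by a different
# route)
oracle_r2 <- function(a, b) stats::cor(a, b)^2

# set-based clumping oracle: precompute the full pairwise conflict
# matrix, then repeatedly promote the strongest remaining SNP to
# survivor and discard everything conflicting with it
oracle_prune <- function(ids, pvalues, r2_fun, thr = 0.2) {
  n <- length(ids)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) conflict[i, j] <- r2_fun(ids[i], ids[j]) > thr
    }
  }
  alive <- rep(TRUE, n)
  survivors <- character(0)
  ord <- order(pvalues, ids)
  for (i in ord) {
    if (!alive[i]) next
    survivors <- c(survivors, ids[i])
    alive[conflict[i, ]] <- FALSE
  }
  sort(survivors)
}

# minimum-likelihood two-sided Fisher exact p by full enumeration of
# the hypergeometric support
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimum-likelihood two-sided binomial p by full support enumeration
oracle_binom2 <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# L2 monotone (non-increasing) regression by enumerating all
# contiguous segmentations (n <= ~10), keeping those with
# non-increasing segment means, and minimizing the SSE
oracle_pava_dec <- function(y) {
  n <- length(y)
  if (n == 1) return(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    means <- vapply(seq_len(length(bounds) - 1), function(i)
      mean(y[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    if (any(diff(means) > 1e-12)) next
    fit <- rep(means, diff(bounds))
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# textbook Benjamini-Hochberg step-up, written independently of
# p.adjust: sort ascending, p_(i) * m / i, cumulative min from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small exchangeable-block LD panel fixture: `blocks` is a list of
# character vectors of SNP ids; all within-block pairs share r2
toy_panel <- function(blocks, r2) {
  pairs <- do.call(rbind, lapply(blocks, function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(id1 = character(0), id2 = character(0))
  }
  pairs$r2 <- rep(r2, length.out = nrow(pairs))
  ld_panel(r2_table = pairs, ids = unlist(blocks))
}

# random interval set on one small genome, as both data.frame and GRanges
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 1000,
                             max_len = 50) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = start + len,
                   stringsAsFactors = FALSE)
  list(df = df, gr = annotation_set(df$chrom, df$start, df$end))
}
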