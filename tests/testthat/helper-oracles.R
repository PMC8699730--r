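# Independent reference implementations (brute-force oracles) used to check
# the package's vectorized/compiled paths, plus small fixture builders.

# per-pixel binning loop mirroring the documented radial-average contract
oracle_radial_average <- function(power2d, n_bins) {
  m <- nrow(power2d); n <- ncol(power2d)
  edges <- seq(0, 0.5, length.out = n_bins + 1)
  sums <- rep(0, n_bins); counts <- rep(0L, n_bins)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      fr <- (i - (floor(m / 2) + 1)) / m
      fc <- (j - (floor(n / 2) + 1)) / n
      r <- sqrt(fr^2 + fc^2)
      if (r > 0.5) next
      b <- findInterval(r, edges, rightmost.closed = TRUE)
      sums[b] <- sums[b] + power2d[i, j]
      counts[b] <- counts[b] + 1L
    }
  }
  ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
}

# two-pass per-pixel temporal standard deviation
oracle_std_map <- function(frames) {
  d <- dim(frames)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- frames[i, j, ]
      out[i, j] <- sqrt(sum((v - mean(v))^2) / (length(v) - 1))
    }
  }
  out
}

# pairwise-concordance AUC (ties count 1/2)
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# smooth random OPD map: low-pass filtered white noise, peak-normalized
random_smooth_opd <- function(n, amplitude_nm = 200, corr = 0.04, seed = 1) {
  set.seed(seed)
  f1 <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) / n
  lp <- exp(-outer(f1^2, f1^2, "+") / (2 * corr^2))
  x <- Re(fft(lp * fft(matrix(rnorm(n^2), n)), inverse = TRUE)) / n^2
  x <- x - min(x)
  x * amplitude_nm / max(x)
}

make_disk_mask <- function(n, radius = NULL) {
  radius <- radius %||% (n / 2 - 2)
  phasefluct::cell_mask(
    outer((seq_len(n) - (n + 1) / 2)^2, (seq_len(n) - (n + 1) / 2)^2, "+") <=
      radius^2,
    center = c((n + 1) / 2, (n + 1) / 2), radius_px = radius)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
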