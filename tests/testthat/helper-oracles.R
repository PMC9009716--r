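# Literal, loop-based reference implementations used as independent
# oracles for the vectorised/optimised package code.

oracle_local_maxima <- function(x) {
  out <- integer(0)
  for (i in seq_along(x)) {
    if (i > 1 && i < length(x) && x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      out <- c(out, i)
    }
  }
  out
}

# topographic prominence by sample-by-sample outward walk
oracle_prominence <- function(x, p) {
  lo_l <- Inf
  j <- p - 1
  while (j >= 1) {
    if (x[j] > x[p]) break
    lo_l <- min(lo_l, x[j])
    j <- j - 1
  }
  lo_r <- Inf
  j <- p + 1
  while (j <= length(x)) {
    if (x[j] > x[p]) break
    lo_r <- min(lo_r, x[j])
    j <- j + 1
  }
  x[p] - max(lo_l, lo_r)
}

# full peak detection from first principles: all local maxima ->
# prominence floor vs max dynamic range -> greedy distance filter
oracle_detect_peaks <- function(x, min_dist = 3, prom_frac = 0.05,
                                window = 38) {
  cand <- oracle_local_maxima(x)
  if (!length(cand)) return(integer(0))
  mdr <- -Inf
  for (m in cand) {
    lo <- min(x[max(1, m - window):min(length(x), m + window)])
    mdr <- max(mdr, x[m] - lo)
  }
  prom <- vapply(cand, function(p) oracle_prominence(x, p), numeric(1))
  keep <- cand[prom >= prom_frac * mdr - 1e-9 * max(mdr, 1)]
  if (!length(keep)) return(integer(0))
  ord <- keep[order(-x[keep], keep)]
  acc <- integer(0)
  for (p in ord) {
    if (!length(acc) || all(abs(acc - p) >= min_dist)) acc <- c(acc, p)
  }
  sort(acc)
}

# moving mean, window k covering k/2 before through k/2 - 1 after
oracle_movmean <- function(x, k = 10) {
  n <- length(x)
  before <- k %/% 2
  after <- k - before - 1
  out <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - before)
    hi <- min(n, i + after)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1)
  }
  out
}

oracle_outlier_flags <- function(len, window = 11, low = 0.5, high = 2.0) {
  n <- length(len)
  half <- window %/% 2
  out <- logical(n)
  for (i in 1:n) {
    med <- median(len[max(1, i - half):min(n, i + half)])
    out[i] <- len[i] < low * med || len[i] > high * med
  }
  out
}

# random short test series: random walk plus oscillation plus noise
random_series <- function(n) {
  drift <- cumsum(rnorm(n, 0, 0.3))
  osc <- runif(1, 0, 3) * sin(2 * pi * (1:n) / runif(1, 5, 25))
  drift + osc + rnorm(n, 0, 0.2)
}
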