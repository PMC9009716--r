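test_that("max dynamic range matches the closed form on a sine", {
  t <- 0:999
  a <- 120
  x <- 200 + a * sin(2 * pi * t / 60)  # 20 ms period at 3000 fps
  expect_lt(abs(max_dynamic_range(x, 12.5, 3000) - 2 * a), 0.05 * a)
  expect_error(max_dynamic_range(seq_len(100) * 1.0), "local maximum")
})

test_that("max dynamic range with a trend matches an exhaustive scan", {
  t <- 0:999
  a <- 100
  d <- 30
  x <- a * sin(2 * pi * t / 50) + d * t / 999
  got <- max_dynamic_range(x, 12.5, 3000)
  expect_gte(got, 2 * a - 1)
  expect_lte(got, 2 * a + d + 1)
  # brute force over all local maxima
  w <- 38
  brute <- max(vapply(oracle_local_maxima(x), function(m) {
    x[m] - min(x[max(1, m - w):min(length(x), m + w)])
  }, numeric(1)))
  expect_equal(got, brute)
})

test_that("the minimum peak distance is enforced with earlier-peak ties", {
  tri <- function(center, n, height = 100, halfwidth = 12) {
    pmax(0, height * (1 - abs(seq_len(n) - center) / halfwidth))
  }
  x3 <- pmax(tri(25, 60), tri(28, 60))
  expect_equal(detect_peaks(x3, peak_config(), 3000), c(25L, 28L))
  x2 <- pmax(tri(25, 60), tri(27, 60))
  expect_equal(detect_peaks(x2, peak_config(), 3000), 25L)
})

test_that("ripples below 5% of the max dynamic range are rejected", {
  # main oscillation: range 200; flat shelf carries calibrated bumps
  per <- 20
  sine <- 100 + 100 * sin(2 * pi * (0:(20 * per + per / 4)) / per)
  shelf <- rep(100, 600)
  bump_at <- c(150, 300, 450)
  add_bumps <- function(h) {
    s <- shelf
    for (c0 in bump_at) {
      idx <- (c0 - 5):(c0 + 5)
      s[idx] <- pmax(s[idx], 100 + h * (1 - abs(idx - c0) / 5))
    }
    c(sine, s)
  }
  x_low <- add_bumps(0.04 * 200)
  x_high <- add_bumps(0.06 * 200)
  bumps <- length(sine) + bump_at
  expect_false(any(bumps %in% detect_peaks(x_low, peak_config(), 3000)))
  expect_true(all(bumps %in% detect_peaks(x_high, peak_config(), 3000)))
  # cross-check the calibration against the from-scratch prominence
  for (b in bumps) {
    expect_equal(oracle_prominence(x_low, b), 8)
    expect_equal(oracle_prominence(x_high, b), 12)
  }
})

test_that("strictly monotone series yield no peaks", {
  expect_identical(detect_peaks(cumsum(runif(50, 0.1, 1))), integer(0))
})

test_that("cycles are built between consecutive peaks", {
  x <- rep(0, 45)
  x[c(10, 20, 31)] <- 100
  x[15] <- -5; x[25] <- -7
  cyc <- build_cycles(c(10L, 20L, 31L), x)
  expect_equal(cyc$start_frame, c(10L, 20L))
  expect_equal(cyc$end_frame, c(20L, 31L))
  expect_equal(cyc$length_frames, c(10L, 11L))
  expect_equal(cyc$min_frame, c(15L, 25L))
  expect_equal(nrow(build_cycles(c(10L), x)), 0L)
})

test_that("the cycle minimum is the earliest argmin on ties", {
  x <- 100 + 100 * cos(2 * pi * (0:40) / 20)  # minima midway between peaks
  cyc <- build_cycles(c(1L, 21L, 41L), x)
  expect_equal(cyc$min_frame, c(11L, 31L))
  # flat-bottomed trough: earliest of the two equal minima
  y <- c(10, 5, 0, 0, 5, 10)
  x2 <- c(0, 10, y, 10, 0)
  cyc2 <- build_cycles(c(2L, 9L), x2)
  inner <- 3:8
  expect_equal(cyc2$min_frame, inner[which.min(x2[inner])])
  expect_equal(cyc2$min_frame, 5L)
})

test_that("cycles overlapping damaged frames are excluded", {
  x <- rep(c(100, 60, 20, 60), 10)
  peaks <- seq(1L, 37L, by = 4L)
  cyc <- build_cycles(peaks, x)
  mask0 <- rep(FALSE, 40)
  expect_true(all(exclude_damaged(cyc, mask0)$valid))

  mask1 <- mask0
  mask1[10] <- TRUE  # inside cycle 3 ([9, 13))
  out1 <- exclude_damaged(cyc, mask1)
  expect_equal(which(!out1$valid), 3L)
  expect_equal(out1$exclusion_reason[3], "damaged")

  mask2 <- mask0
  mask2[12:14] <- TRUE  # spans the boundary at frame 13
  out2 <- exclude_damaged(cyc, mask2)
  expect_equal(which(!out2$valid), c(3L, 4L))
})

test_that("outlier flagging follows the local-median rule", {
  mk <- function(lens) {
    start <- cumsum(c(1L, lens))
    tibble::tibble(cycle_index = seq_along(lens),
                   start_frame = start[-length(start)],
                   min_frame = start[-length(start)] + 1L,
                   end_frame = start[-1],
                   length_frames = as.integer(lens),
                   valid = TRUE, exclusion_reason = NA_character_)
  }
  expect_true(all(remove_outlier_cycles(mk(rep(10, 30)))$valid))

  lens <- rep(10, 21); lens[11] <- 25  # 2.5x the local median
  out <- remove_outlier_cycles(mk(lens))
  expect_equal(which(!out$valid), 11L)
  expect_equal(out$exclusion_reason[11], "outlier")
  expect_identical(!out$valid, oracle_outlier_flags(lens))

  drift <- round(10 * seq(0.9, 1.1, length.out = 40))
  expect_true(all(remove_outlier_cycles(mk(drift))$valid))
  expect_false(any(oracle_outlier_flags(drift)))

  # a genuine F0 halving sits on the inclusive-keep boundary
  halving <- c(rep(c(7, 8), 15), rep(15, 30))
  expect_true(all(remove_outlier_cycles(mk(halving))$valid))
})

test_that("peak detection matches the brute-force oracle on short series", {
  set.seed(42)
  for (i in 1:200) {
    x <- random_series(sample(30:150, 1))
    expect_identical(detect_peaks(x, peak_config(), 3000),
                     oracle_detect_peaks(x))
  }
})

test_that("valid and excluded cycles tile the peak sequence", {
  rec <- generate_gaw(synth_config(damaged_runs = list(c(1000, 15)),
                                   seed = 33))
  peaks <- detect_peaks(rec$total, peak_config(), rec$frame_rate)
  cyc <- detect_cycles(rec)
  expect_equal(nrow(cyc), length(peaks) - 1L)
  expect_equal(cyc$start_frame, peaks[-length(peaks)])
  expect_equal(cyc$end_frame, peaks[-1])
  expect_true(all(cyc$start_frame < cyc$min_frame &
                    cyc$min_frame < cyc$end_frame))
  expect_true(all(cyc$length_frames >= 3))
  # pure function of its inputs
  expect_identical(cyc, detect_cycles(rec))
})
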