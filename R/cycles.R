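#' Peak-detection configuration
#'
#' Constants for maximum-based cycle detection: retained peaks must be at
#' least `min_peak_distance_frames` apart (3 frames = 1 ms at 3000 fps)
#' and have a topographic prominence of at least `prominence_fraction`
#' (5%) of the recording's maximum dynamic range, the largest distance
#' between a local peak and a close local minimum (within
#' `dynamic_range_window_ms`, 12.5 ms). The relative prominence floor
#' accommodates the large amplitude differences between recordings and
#' the general amplitude rise along the flow ramp.
#'
#' @param min_peak_distance_frames minimum retained peak separation.
#' @param prominence_fraction prominence floor as a fraction of the
#'   maximum dynamic range.
#' @param dynamic_range_window_ms half-window (ms) used when measuring
#'   the maximum dynamic range around each local peak.
#' @return an object of class `peak_config`.
#' @export
peak_config <- function(min_peak_distance_frames = 3L,
                        prominence_fraction = 0.05,
                        dynamic_range_window_ms = 12.5) {
  if (min_peak_distance_frames <= 0 || prominence_fraction <= 0 ||
      dynamic_range_window_ms <= 0) {
    stop("all peak_config values must be positive")
  }
  structure(list(min_peak_distance_frames = as.integer(min_peak_distance_frames),
                 prominence_fraction = prominence_fraction,
                 dynamic_range_window_ms = dynamic_range_window_ms),
            class = "peak_config")
}

# interior local maxima; on plateaus the earliest sample is reported
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# topographic prominence of each candidate peak: walk outward until a
# strictly higher sample is reached (or the series end), take the lowest
# valley on each side, prominence = height - the higher of the two.
# Valleys between consecutive candidate maxima are precomputed; a sample
# exceeding both neighbouring maxima would itself be a local maximum, so
# walking candidate-to-candidate is exact.
peak_prominences <- function(x, peaks) {
  k <- length(peaks)
  n <- length(x)
  if (k == 0) return(numeric(0))
  valley <- if (k > 1) {
    vapply(seq_len(k - 1),
           function(j) min(x[peaks[j]:peaks[j + 1]]), numeric(1))
  } else numeric(0)
  ledge <- min(x[1:peaks[1]])
  redge <- min(x[peaks[k]:n])
  vapply(seq_len(k), function(j) {
    h <- x[peaks[j]]
    lo_l <- Inf
    i <- j - 1
    while (i >= 1) {
      lo_l <- min(lo_l, valley[i])
      if (x[peaks[i]] > h) break
      i <- i - 1
    }
    if (i < 1) lo_l <- min(lo_l, ledge)
    lo_r <- Inf
    i <- j
    while (i <= k - 1) {
      lo_r <- min(lo_r, valley[i])
      if (x[peaks[i + 1]] > h) break
      i <- i + 1
    }
    if (i > k - 1) lo_r <- min(lo_r, redge)
    h - max(lo_l, lo_r)
  }, numeric(1))
}

#' Maximum dynamic range of a GAW
#'
#' The largest distance between a local peak and a close local minimum:
#' for every interior local maximum the minimum value within
#' `window_ms` of it is subtracted from the peak value, and the maximum
#' over peaks is returned. The window is `round(window_ms * frame_rate /
#' 1000)` frames to each side (38 frames at 3000 fps, rounding half up).
#'
#' @param gaw numeric area series.
#' @param window_ms half-window in milliseconds (default 12.5).
#' @param frame_rate frames per second.
#' @return the maximum dynamic range (same units as `gaw`).
#' @export
max_dynamic_range <- function(gaw, window_ms = 12.5, frame_rate = 3000) {
  peaks <- local_maxima(gaw)
  if (!length(peaks)) {
    stop("no interior local maximum: signal is flat or monotone")
  }
  w <- as.integer(round_half_up(window_ms * frame_rate / 1000))
  n <- length(gaw)
  max(vapply(peaks, function(m) {
    gaw[m] - min(gaw[max(1L, m - w):min(n, m + w)])
  }, numeric(1)))
}

#' Detect oscillation maxima
#'
#' Finds interior local maxima of the total GAW, keeps those whose
#' topographic prominence reaches `prominence_fraction` of the
#' recording's [max_dynamic_range()], then greedily enforces the minimum
#' peak distance: peaks are processed in decreasing height (earlier index
#' wins exact ties) and a peak is dropped if a retained peak lies closer
#' than `min_peak_distance_frames`. Separation exactly equal to the
#' minimum distance is kept. Fully deterministic.
#'
#' @param gaw numeric area series.
#' @param cfg a [peak_config()].
#' @param frame_rate frames per second (needed for the dynamic-range
#'   window).
#' @return sorted integer vector of retained peak frame indices (1-based;
#'   possibly empty).
#' @export
detect_peaks <- function(gaw, cfg = peak_config(), frame_rate = 3000) {
  cand <- local_maxima(gaw)
  if (!length(cand)) return(integer(0))
  mdr <- max_dynamic_range(gaw, cfg$dynamic_range_window_ms, frame_rate)
  prom <- peak_prominences(gaw, cand)
  thr <- cfg$prominence_fraction * mdr
  keep <- cand[prom >= thr - 1e-9 * max(mdr, 1)]
  if (!length(keep)) return(integer(0))
  ord <- keep[order(-gaw[keep], keep)]
  accepted <- integer(0)
  for (p in ord) {
    if (!length(accepted) ||
        all(abs(accepted - p) >= cfg$min_peak_distance_frames)) {
      accepted <- c(accepted, p)
    }
  }
  sort(accepted)
}

#' Build maximum-to-maximum cycles
#'
#' One cycle per consecutive peak pair, sharing its end boundary with the
#' next cycle's start (half-open `[start_frame, end_frame)` intervals).
#' The internal minimum is the argmin of the GAW strictly between the two
#' peaks, earliest index on ties.
#'
#' @param peaks sorted peak indices from [detect_peaks()].
#' @param gaw numeric area series.
#' @return a tibble with columns `cycle_index`, `start_frame`,
#'   `min_frame`, `end_frame`, `length_frames`, `valid`,
#'   `exclusion_reason` (empty when fewer than 2 peaks).
#' @export
build_cycles <- function(peaks, gaw) {
  empty <- tibble::tibble(cycle_index = integer(0), start_frame = integer(0),
                          min_frame = integer(0), end_frame = integer(0),
                          length_frames = integer(0), valid = logical(0),
                          exclusion_reason = character(0))
  if (length(peaks) < 2) return(empty)
  k <- length(peaks) - 1L
  s <- peaks[seq_len(k)]
  e <- peaks[seq_len(k) + 1L]
  m <- vapply(seq_len(k), function(i) {
    inner <- (s[i] + 1L):(e[i] - 1L)
    inner[which.min(gaw[inner])]
  }, integer(1))
  tibble::tibble(cycle_index = seq_len(k), start_frame = as.integer(s),
                 min_frame = m, end_frame = as.integer(e),
                 length_frames = as.integer(e - s), valid = TRUE,
                 exclusion_reason = NA_character_)
}

#' Exclude cycles overlapping damaged frames
#'
#' Any cycle whose half-open frame interval `[start_frame, end_frame)`
#' contains at least one damaged frame is invalidated with reason
#' `"damaged"`. A damaged run spanning a cycle boundary invalidates both
#' neighbouring cycles.
#'
#' @param cycles cycle tibble from [build_cycles()].
#' @param damaged_mask logical vector covering the series.
#' @return the cycle tibble with updated `valid` / `exclusion_reason`.
#' @export
exclude_damaged <- function(cycles, damaged_mask) {
  if (!nrow(cycles)) return(cycles)
  bad <- vapply(seq_len(nrow(cycles)), function(i) {
    any(damaged_mask[cycles$start_frame[i]:(cycles$end_frame[i] - 1L)])
  }, logical(1))
  cycles$valid[bad] <- FALSE
  cycles$exclusion_reason[bad] <- "damaged"
  cycles
}

#' Flag outlier cycles against the local median length
#'
#' Each cycle length is compared with the median length over a window of
#' cycles centred on it (shrunk at the boundaries). Cycles strictly
#' shorter than `low` times or strictly longer than `high` times the
#' local median are flagged as outliers. All medians are computed from
#' the original lengths in a single pass. The default bounds (0.5x / 2x)
#' flag double- and half-period detection glitches while keeping a
#' genuine F0 halving: a step from alternating 7-8 frame cycles to 15
#' frame cycles sits exactly on the inclusive boundary and is retained.
#'
#' @param cycles cycle tibble.
#' @param window window size in cycles (default 11).
#' @param low,high relative bounds on length vs the local median.
#' @return the cycle tibble with updated `valid` / `exclusion_reason`.
#' @export
remove_outlier_cycles <- function(cycles, window = 11L, low = 0.5,
                                  high = 2.0) {
  n <- nrow(cycles)
  if (!n) return(cycles)
  len <- cycles$length_frames
  half <- window %/% 2L
  out <- vapply(seq_len(n), function(i) {
    med <- stats::median(len[max(1L, i - half):min(n, i + half)])
    len[i] < low * med || len[i] > high * med
  }, logical(1))
  hit <- out & cycles$valid
  cycles$valid[hit] <- FALSE
  cycles$exclusion_reason[hit] <- "outlier"
  cycles
}

#' Full cycle detection for one recording
#'
#' Convenience wrapper: [detect_peaks()] on the total GAW,
#' [build_cycles()], [exclude_damaged()], [remove_outlier_cycles()].
#'
#' @param record a [gaw_record()].
#' @param cfg a [peak_config()].
#' @param outlier_window,outlier_low,outlier_high outlier-rule settings,
#'   see [remove_outlier_cycles()].
#' @return a cycle tibble.
#' @export
detect_cycles <- function(record, cfg = peak_config(), outlier_window = 11L,
                          outlier_low = 0.5, outlier_high = 2.0) {
  stopifnot(inherits(record, "gaw_record"))
  peaks <- detect_peaks(record$total, cfg, record$frame_rate)
  cycles <- build_cycles(peaks, record$total)
  cycles <- exclude_damaged(cycles, record$damaged_mask)
  remove_outlier_cycles(cycles, outlier_window, outlier_low, outlier_high)
}
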