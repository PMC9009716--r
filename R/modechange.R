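#' Mode-change detector configuration
#'
#' A vibratory mode change is a sustained jump or drop of the local
#' fundamental frequency. The per-cycle LF0 sequence of valid cycles is
#' smoothed with a ten-point moving average, the first and last five
#' smoothed values are excluded, and a change counts as a mode change
#' when the smoothed LF0 rises or falls by at least `delta_threshold`
#' (50 Hz) within `span_window` (ten) cycles and stays shifted for at
#' least `sustain_cycles` (five) consecutive cycles. Events within
#' `boundary_guard` cycles of either end are discarded, since changes
#' extremely early or late in the signal cannot be told apart from
#' onset/offset effects.
#'
#' @param smooth_window moving-average window in cycles (default 10).
#' @param edge_exclude smoothed values dropped at each end (default 5).
#' @param delta_threshold minimum sustained LF0 change in Hz (default 50,
#'   large enough to be clearly audible, small enough to keep smaller
#'   genuine events).
#' @param span_window the change must be reached within this many cycles
#'   (default 10).
#' @param sustain_cycles the shifted level must hold for at least this
#'   many consecutive cycles (default 5).
#' @param boundary_guard events this close (cycles, on the smoothed
#'   trace) to either end are discarded (default 10).
#' @param method `"mean"` (default) or `"median"` smoothing.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(smooth_window = 10L, edge_exclude = 5L,
                            delta_threshold = 50, span_window = 10L,
                            sustain_cycles = 5L, boundary_guard = 10L,
                            method = c("mean", "median")) {
  method <- match.arg(method)
  vals <- c(smooth_window, edge_exclude, delta_threshold, span_window,
            sustain_cycles, boundary_guard)
  if (any(vals <= 0)) stop("all detector_config values must be positive")
  structure(list(smooth_window = as.integer(smooth_window),
                 edge_exclude = as.integer(edge_exclude),
                 delta_threshold = delta_threshold,
                 span_window = as.integer(span_window),
                 sustain_cycles = as.integer(sustain_cycles),
                 boundary_guard = as.integer(boundary_guard),
                 method = method),
            class = "detector_config")
}

# moving window mean/median with the asymmetric even-window convention
# (window k covers k/2 points before through k/2 - 1 after the current
# one), shrunk at the boundaries
moving_stat <- function(x, k, fun) {
  n <- length(x)
  before <- k %/% 2L
  after <- k - before - 1L
  vapply(seq_len(n), function(i) {
    fun(x[max(1L, i - before):min(n, i + after)])
  }, numeric(1))
}

#' Smooth a per-cycle LF0 sequence
#'
#' Applies a centred ten-point moving average (shrunk at the boundaries;
#' for the even default window the centre sits between points, so the
#' window covers five cycles before through four after) to the LF0
#' sequence of valid cycles, then drops the first and last
#' `edge_exclude` values. The attribute `"offset"` records how the
#' smoothed indices map back to positions in the input sequence
#' (`input_position = smoothed_index + offset`).
#'
#' @param lf0 numeric LF0 sequence (valid cycles, in time order).
#' @param cfg a [detector_config()].
#' @return smoothed numeric vector with attribute `offset`.
#' @export
smooth_lf0 <- function(lf0, cfg = detector_config()) {
  n <- length(lf0)
  if (n < cfg$smooth_window + 2L * cfg$edge_exclude) {
    stop("LF0 sequence too short to smooth: ", n, " values, need at least ",
         cfg$smooth_window + 2L * cfg$edge_exclude)
  }
  fun <- if (cfg$method == "mean") mean else stats::median
  sm <- moving_stat(lf0, cfg$smooth_window, fun)
  out <- sm[(cfg$edge_exclude + 1L):(n - cfg$edge_exclude)]
  attr(out, "offset") <- cfg$edge_exclude
  out
}

#' Detect sustained LF0 jumps and drops
#'
#' Operates on a smoothed LF0 trace. Index `i` is a candidate if for some
#' `j` with `0 < j - i <= span_window` the trace has moved by at least
#' `delta_threshold` Hz and at least `sustain_cycles` consecutive values
#' from `j` onward stay at least `delta_threshold` away from the level at
#' `i`, on the same side. Overlapping candidates (within `span_window` of
#' each other) are merged into one event anchored at the point of
#' steepest change; events within `boundary_guard` of either trace end
#' are discarded. Events are reported in time order.
#'
#' @param smoothed smoothed LF0 trace from [smooth_lf0()] (plain numeric
#'   vectors are accepted too, e.g. to probe the detector directly).
#' @param cfg a [detector_config()].
#' @return a tibble with one row per event: `smooth_index` (position in
#'   the smoothed trace), `seq_index` (position in the un-smoothed valid
#'   cycle sequence), `direction` (`"up"`/`"down"`).
#' @export
detect_mode_changes <- function(smoothed, cfg = detector_config()) {
  s <- as.numeric(smoothed)
  offset <- attr(smoothed, "offset")
  if (is.null(offset)) offset <- 0L
  m <- length(s)
  thr <- cfg$delta_threshold - 1e-9
  empty <- tibble::tibble(smooth_index = integer(0), seq_index = integer(0),
                          direction = character(0))
  if (m < 2) return(empty)
  cand <- integer(0)
  cdir <- numeric(0)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):min(i + cfg$span_window, m)) {
      d <- s[j] - s[i]
      if (abs(d) >= thr) {
        hi <- j + cfg$sustain_cycles - 1L
        if (hi <= m) {
          seg <- s[j:hi] - s[i]
          ok <- if (d > 0) all(seg >= thr) else all(seg <= -thr)
          if (ok) {
            cand <- c(cand, i)
            cdir <- c(cdir, sign(d))
            break
          }
        }
      }
    }
  }
  if (!length(cand)) return(empty)
  grp <- cumsum(c(1, diff(cand) > cfg$span_window))
  rows <- lapply(split(seq_along(cand), grp), function(g) {
    lo <- min(cand[g])
    hi <- min(max(cand[g]) + cfg$span_window, m - 1L)
    ks <- lo:hi
    steep <- ks[which.max(abs(s[ks + 1L] - s[ks]))]
    tibble::tibble(smooth_index = steep + 1L,
                   direction = if (cdir[g[1]] > 0) "up" else "down")
  })
  ev <- dplyr::bind_rows(rows)
  ev <- ev[ev$smooth_index > cfg$boundary_guard &
             ev$smooth_index <= m - cfg$boundary_guard, , drop = FALSE]
  ev$seq_index <- as.integer(ev$smooth_index + offset)
  ev[order(ev$smooth_index), c("smooth_index", "seq_index", "direction")]
}

#' Characterize a detected mode change
#'
#' Computes the medians of LF0, DR, OD and CD over the up-to-10 valid
#' cycles immediately before and from the event cycle onward, plus the
#' airflow at the event. Flow follows the linear ramp of the recording:
#' `flow_start + (flow_end - flow_start) * min(t_stim / ramp_duration,
#' 1)` where `t_stim` is the event time measured from stimulation onset
#' (the `onset_frame` offset plus the event time within the segment).
#' Medians with no valid cycle on their side are `NA`.
#'
#' @param seq_index event position within the valid-cycle sequence.
#' @param direction `"up"` or `"down"` from the detector.
#' @param cycles cycle tibble.
#' @param params parameter tibble from [cycle_parameters()].
#' @param record the [gaw_record()].
#' @param n_context maximum cycles per side (default 10).
#' @return one-row tibble: `event_cycle`, `event_time_s`, `direction`,
#'   `lf0_before`, `lf0_after`, `dr_before`, `dr_after`, `od_before`,
#'   `od_after`, `cd_before`, `cd_after`, `flow_at_event`.
#' @export
characterize_event <- function(seq_index, direction, cycles, params, record,
                               n_context = 10L) {
  stopifnot(inherits(record, "gaw_record"))
  vrows <- which(cycles$valid)
  if (seq_index < 1 || seq_index > length(vrows)) {
    stop("seq_index outside the valid-cycle sequence")
  }
  before <- vrows[seq(max(1L, seq_index - n_context), length.out =
                        min(n_context, seq_index - 1L))]
  after <- vrows[seq_index:min(length(vrows), seq_index + n_context - 1L)]
  med <- function(v, rows) {
    if (!length(rows)) return(NA_real_)
    stats::median(v[rows], na.rm = TRUE)
  }
  row <- vrows[seq_index]
  event_time <- (cycles$start_frame[row] - 1L) / record$frame_rate
  ramp <- record$flow_ramp
  t_stim <- record$onset_frame / record$frame_rate + event_time
  flow <- ramp$flow_start + (ramp$flow_end - ramp$flow_start) *
    min(t_stim / ramp$ramp_duration, 1)
  tibble::tibble(event_cycle = cycles$cycle_index[row],
                 event_time_s = event_time,
                 direction = direction,
                 lf0_before = med(params$lf0, before),
                 lf0_after = med(params$lf0, after),
                 dr_before = med(params$dr, before),
                 dr_after = med(params$dr, after),
                 od_before = med(params$od, before),
                 od_after = med(params$od, after),
                 cd_before = med(params$cd, before),
                 cd_after = med(params$cd, after),
                 flow_at_event = flow)
}

#' Analyse one recording end to end
#'
#' Runs the full per-recording pipeline: onset/offset trimming, the
#' minimum-duration inclusion filter, cycle detection with damaged and
#' outlier exclusion, the seven cycle parameters, LF0 smoothing and
#' mode-change detection with event characterization. Recordings that
#' fail a stage are returned with `included = FALSE` and a `reason`
#' rather than an error, so grid runs always complete.
#'
#' @param record a [gaw_record()].
#' @param peak_cfg a [peak_config()].
#' @param det_cfg a [detector_config()].
#' @param trim apply [trim_onset_offset()] first (default TRUE).
#' @return a list of class `gaw_analysis`: `recording_id`, `condition`,
#'   `included`, `reason`, `cycles`, `params`, `lf0_smooth`, `events`
#'   (tibble, one row per detected mode change).
#' @export
analyze_recording <- function(record, peak_cfg = peak_config(),
                              det_cfg = detector_config(), trim = TRUE) {
  stopifnot(inherits(record, "gaw_record"))
  out <- list(recording_id = record$recording_id,
              condition = record$condition, included = FALSE, reason = NA_character_,
              cycles = NULL, params = NULL, lf0_smooth = NULL,
              events = empty_events())
  class(out) <- "gaw_analysis"
  if (trim) {
    k <- 2 * round_half_up(0.010 * record$frame_rate)
    if (length(record$total) <= k) {
      out$reason <- "too short to trim"
      return(out)
    }
    record <- trim_onset_offset(record)
  }
  if (!passes_inclusion(record)) {
    out$reason <- "below minimum continuous phonation length"
    return(out)
  }
  out$included <- TRUE
  cycles <- detect_cycles(record, peak_cfg)
  out$cycles <- cycles
  out$params <- cycle_parameters(cycles, record)
  lf0 <- out$params$lf0[cycles$valid]
  if (length(lf0) < det_cfg$smooth_window + 2L * det_cfg$edge_exclude) {
    out$reason <- "too few valid cycles for mode-change detection"
    return(out)
  }
  out$lf0_smooth <- smooth_lf0(lf0, det_cfg)
  found <- detect_mode_changes(out$lf0_smooth, det_cfg)
  if (nrow(found)) {
    # the moving average localises an abrupt step only to within half a
    # window; refine each anchor on the raw LF0: estimate the pre and
    # post levels from regions clear of the boundary, then snap to the
    # first cycle that sits (and stays, for two more cycles) closer to
    # the post level, so the before/after context windows are not
    # contaminated
    half <- det_cfg$smooth_window %/% 2L
    n_lf0 <- length(lf0)
    found$seq_index <- vapply(found$seq_index, function(si) {
      pre_level <- stats::median(lf0[max(1L, si - 4L * half):max(1L, si - half - 1L)])
      post_level <- stats::median(lf0[min(n_lf0, si + half + 1L):min(n_lf0, si + 4L * half)])
      if (pre_level == post_level) return(si)
      lo <- max(2L, si - 2L * half)
      hi <- min(n_lf0 - 1L, si + half)
      for (k in lo:hi) {
        run <- lf0[k:min(n_lf0, k + 2L)]
        if (all(abs(run - post_level) < abs(run - pre_level))) {
          return(as.integer(k))
        }
      }
      si
    }, integer(1))
    out$events <- dplyr::bind_rows(lapply(seq_len(nrow(found)), function(i) {
      characterize_event(found$seq_index[i], found$direction[i],
                         cycles, out$params, record)
    }))
  }
  out
}

empty_events <- function() {
  tibble::tibble(event_cycle = integer(0), event_time_s = numeric(0),
                 direction = character(0), lf0_before = numeric(0),
                 lf0_after = numeric(0), dr_before = numeric(0),
                 dr_after = numeric(0), od_before = numeric(0),
                 od_after = numeric(0), cd_before = numeric(0),
                 cd_after = numeric(0), flow_at_event = numeric(0))
}
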