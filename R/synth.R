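#' Configuration for the synthetic phonation generator
#'
#' Describes one synthetic glottal-area recording. The generator is
#' phenomenological: it concatenates maximum-to-maximum pulses whose
#' nominal length follows a piecewise-constant F0 schedule, whose
#' peak-to-trough amplitude follows a linear ramp (emulating linearly
#' rising airflow), and whose shape is a skewed raised cosine
#' parameterised by the open-duration : closing-duration (OD:CD) split.
#' Cycle-length jitter, amplitude shimmer, left-right phase lag, additive
#' noise and short runs of damaged frames are all programmable.
#'
#' Defaults emulate the in vivo study conditions this package targets:
#' 3000 fps video, a 1.5 s stimulation epoch with flow rising 300 to
#' 1400 mL/s, F0 near 400 Hz in the falsetto-like mode (OD close to CD)
#' dropping to near 200 Hz in the chest-like mode (CD clearly longer
#' than OD) with a simultaneous amplitude gain, and mild jitter/shimmer
#' that is boosted in a window before each programmed transition (the
#' pre-event instability seen in real recordings).
#'
#' @param frame_rate frames per second.
#' @param duration segment length in seconds; `duration * frame_rate`
#'   must be a whole number of frames.
#' @param f0_schedule list of `c(start_time_s, f0_hz)` pairs defining a
#'   piecewise-constant F0 trajectory; the first start time must be 0.
#'   Steps are realised at cycle boundaries, never mid-cycle.
#' @param transition_times times (s) of programmed mode-change events;
#'   on and after the first one the post-transition pulse shape
#'   (`od_cd_ratio_post`) and amplitude gain (`amplitude_jump`) apply.
#' @param amplitude_start,amplitude_end peak-to-trough amplitude
#'   (pixel^2) at segment start/end (linear ramp).
#' @param amplitude_jump multiplicative amplitude gain applied after the
#'   first transition (chest-like oscillation is wider; default 1.4).
#' @param od_cd_ratio_pre,od_cd_ratio_post OD:CD ratio of the pulse
#'   before/after the first transition (1 = symmetric; 0.5 = CD twice OD).
#' @param jitter_sd cycle-length perturbation (fraction of cycle length).
#' @param shimmer_sd amplitude perturbation (fraction of amplitude).
#' @param perturbation_boost numeric `c(window_s, multiplier)`: jitter
#'   and shimmer are multiplied by `multiplier` within `window_s` seconds
#'   before each programmed transition.
#' @param phase_lag left-minus-right timing offset as a fraction of the
#'   cycle in `[-0.5, 0.5]`; positive = left-side phase lead.
#' @param left_right_split fraction of the area assigned to the left
#'   partial GAW, in (0, 1).
#' @param noise_sd additive measurement noise (pixel^2), split between
#'   the partials so `left + right == total` holds exactly.
#' @param damaged_runs list of `c(start_frame, length)` (1-based start,
#'   length <= 20) runs of corrupted frames; values there are zeroed and
#'   flagged in the mask.
#' @param baseline minimum area (posterior-gap residual, pixel^2, >= 0).
#' @param seed integer seed; identical seeds give identical records.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(frame_rate = 3000,
                         duration = 1.5,
                         f0_schedule = list(c(0, 400)),
                         transition_times = numeric(0),
                         amplitude_start = 800,
                         amplitude_end = 3500,
                         amplitude_jump = 1.4,
                         od_cd_ratio_pre = 1,
                         od_cd_ratio_post = 0.5,
                         jitter_sd = 0.01,
                         shimmer_sd = 0.03,
                         perturbation_boost = c(window = 0.08, multiplier = 4),
                         phase_lag = 0,
                         left_right_split = 0.5,
                         noise_sd = 5,
                         damaged_runs = list(),
                         baseline = 20,
                         seed = NULL) {
  n <- duration * frame_rate
  if (abs(n - round(n)) > 1e-8) {
    stop("duration * frame_rate must be a whole number of frames")
  }
  sched <- do.call(rbind, lapply(f0_schedule, function(p) {
    if (length(p) != 2) stop("each f0_schedule entry must be (start_time, f0)")
    data.frame(time = p[1], f0 = p[2])
  }))
  sched <- sched[order(sched$time), , drop = FALSE]
  if (sched$time[1] != 0) stop("f0_schedule must start at time 0")
  if (any(sched$f0 <= 0) || any(sched$f0 >= frame_rate / 2)) {
    stop("every f0 must be > 0 and < frame_rate / 2")
  }
  if (jitter_sd < 0 || shimmer_sd < 0) stop("jitter_sd and shimmer_sd must be >= 0")
  if (phase_lag < -0.5 || phase_lag > 0.5) stop("phase_lag must be in [-0.5, 0.5]")
  if (left_right_split <= 0 || left_right_split >= 1) {
    stop("left_right_split must be in (0, 1)")
  }
  if (baseline < 0) stop("baseline must be >= 0")
  for (run in damaged_runs) {
    if (length(run) != 2 || run[2] > 20 || run[2] < 1) {
      stop("each damaged run must be (start_frame, length) with length <= 20")
    }
  }
  structure(
    list(frame_rate = frame_rate, duration = duration,
         f0_schedule = f0_schedule, .schedule = sched,
         transition_times = sort(transition_times),
         amplitude_start = amplitude_start, amplitude_end = amplitude_end,
         amplitude_jump = amplitude_jump,
         od_cd_ratio_pre = od_cd_ratio_pre,
         od_cd_ratio_post = od_cd_ratio_post,
         jitter_sd = jitter_sd, shimmer_sd = shimmer_sd,
         perturbation_boost = unname(perturbation_boost),
         phase_lag = phase_lag, left_right_split = left_right_split,
         noise_sd = noise_sd, damaged_runs = damaged_runs,
         baseline = baseline, seed = seed),
    class = "synth_config")
}

# skewed raised-cosine pulse: 1 at u = 0 and u = L, 0 at the internal
# minimum u = m; u may be fractional (phase-shifted partials)
pulse_shape <- function(u, len, m) {
  ifelse(u <= m,
         0.5 + 0.5 * cos(pi * u / m),
         0.5 - 0.5 * cos(pi * (u - m) / (len - m)))
}

#' Generate a synthetic GAW recording
#'
#' Builds the total and left/right partial glottal area series cycle by
#' cycle from a [synth_config()]. Cycle boundaries accumulate a
#' continuous phase so that the configured F0 is honoured on average
#' even when `frame_rate / f0` is not a whole number of frames. The two
#' partials are phase-shifted copies of the pulse (by `+-phase_lag/2`
#' cycles) and the total is their sum, so area is conserved exactly,
#' including under additive noise.
#'
#' Ground truth for testing is attached as `attr(record, "truth")`: a
#' list with the per-cycle table (`cycles`), the programmed transition
#' times, and the generating config.
#'
#' @param config a [synth_config()].
#' @return a [gaw_record()].
#' @export
generate_gaw <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fr <- config$frame_rate
  if (any(config$.schedule$f0 > fr / 4)) {
    stop("f0 implies cycles shorter than 4 frames, undetectable under the ",
         "3-frame minimum peak distance")
  }
  n <- as.integer(round(config$duration * fr))
  with_seed(config$seed, {
    sched <- config$.schedule
    tt <- config$transition_times
    first_tt <- if (length(tt)) tt[1] else Inf
    pw <- config$perturbation_boost[1]
    pm <- config$perturbation_boost[2]
    split <- config$left_right_split
    left <- numeric(n)
    right <- numeric(n)
    cyc_start <- integer(0); cyc_end <- integer(0)
    cyc_f0 <- numeric(0); cyc_amp <- numeric(0); cyc_post <- logical(0)
    b <- 0
    repeat {
      s <- as.integer(floor(b + 0.5))
      if (s >= n) break
      t0 <- b / fr
      f0 <- sched$f0[findInterval(t0, sched$time)]
      boost <- if (length(tt) && any(t0 >= (tt - pw) & t0 < tt)) pm else 1
      jit <- if (config$jitter_sd > 0) {
        stats::rnorm(1, 0, config$jitter_sd * boost)
      } else 0
      len_real <- fr / f0 * max(0.25, 1 + jit)
      e <- as.integer(floor(b + len_real + 0.5))
      if (e - s < 4L) e <- s + 4L
      len <- e - s
      post <- t0 >= first_tt
      ratio <- if (post) config$od_cd_ratio_post else config$od_cd_ratio_pre
      shim <- if (config$shimmer_sd > 0) {
        stats::rnorm(1, 0, config$shimmer_sd * boost)
      } else 0
      t_mid <- min((b + len_real / 2) / fr, config$duration)
      amp <- (config$amplitude_start +
                (config$amplitude_end - config$amplitude_start) *
                  t_mid / config$duration) *
        (if (post) config$amplitude_jump else 1) * max(0, 1 + shim)
      m <- min(max(round(len / (1 + ratio)), 1L), len - 1L)
      idx_hi <- min(e, n)
      u <- (s:(idx_hi - 1L)) - s
      shift <- config$phase_lag * len / 2
      phi_l <- pulse_shape((u + shift) %% len, len, m)
      phi_r <- pulse_shape((u - shift) %% len, len, m)
      rows <- (s + 1L):idx_hi
      left[rows] <- split * (config$baseline + amp * phi_l)
      right[rows] <- (1 - split) * (config$baseline + amp * phi_r)
      cyc_start <- c(cyc_start, s + 1L)
      cyc_end <- c(cyc_end, e + 1L)
      cyc_f0 <- c(cyc_f0, f0)
      cyc_amp <- c(cyc_amp, amp)
      cyc_post <- c(cyc_post, post)
      b <- b + max(len_real, 4)
    }
    if (config$noise_sd > 0) {
      nz <- stats::rnorm(n, 0, config$noise_sd)
      left <- left + split * nz
      right <- right + (1 - split) * nz
    }
    left <- pmax(left, 0)
    right <- pmax(right, 0)
    mask <- rep(FALSE, n)
    for (run in config$damaged_runs) {
      rows <- run[1]:min(run[1] + run[2] - 1L, n)
      mask[rows] <- TRUE
      left[rows] <- 0
      right[rows] <- 0
    }
    rec <- gaw_record(total = left + right, left = left, right = right,
                      frame_rate = fr, damaged_mask = mask,
                      recording_id = "synthetic")
    attr(rec, "truth") <- list(
      cycles = tibble::tibble(start_frame = cyc_start, end_frame = cyc_end,
                              f0 = cyc_f0, amplitude = cyc_amp,
                              post_transition = cyc_post),
      transition_times = tt,
      config = config)
    rec
  })
}

default_onset_rule <- function(sln, rln_left, rln_right) {
  (rln_left + rln_right) >= 3 + 2 * sln
}

default_event_rule <- function(sln, rln_left, rln_right) {
  sln >= 1 & pmin(rln_left, rln_right) >= 4 & abs(rln_left - rln_right) <= 2
}

#' Configuration for a stimulation-condition grid
#'
#' A full study visits 5 SLN levels x 8 left RLN levels x 8 right RLN
#' levels = 320 cells. `onset_rule` decides which cells phonate at all
#' (by default phonation needs enough combined adduction relative to the
#' vocal-fold tension, so low-RLN / high-SLN cells stay silent);
#' `event_rule` decides which phonating cells contain a programmed mode
#' change (by default cells with SLN >= 1 and strong, nearly symmetric
#' RLN activation). Cells with SLN = 0 never contain programmed events,
#' regardless of `event_rule`.
#'
#' @param sln_levels,rln_levels integer level vectors (defaults 0:4 and
#'   0:7 giving the full 320-cell grid).
#' @param onset_rule,event_rule vectorised predicates
#'   `function(sln, rln_left, rln_right)`.
#' @param base_config [synth_config()] supplying shared generator
#'   settings (perturbation, noise, amplitude ramp, ...); per-cell F0
#'   schedules, durations and transitions are filled in by
#'   [generate_grid()].
#' @param damaged_prob probability that a cell receives one short run of
#'   damaged frames.
#' @param seed integer master seed; per-cell seeds are derived from it.
#' @return an object of class `grid_config`.
#' @export
grid_config <- function(sln_levels = 0:4, rln_levels = 0:7,
                        onset_rule = default_onset_rule,
                        event_rule = default_event_rule,
                        base_config = synth_config(),
                        damaged_prob = 0.3,
                        seed = 1L) {
  structure(list(sln_levels = sln_levels, rln_levels = rln_levels,
                 onset_rule = onset_rule, event_rule = event_rule,
                 base_config = base_config, damaged_prob = damaged_prob,
                 seed = seed),
            class = "grid_config")
}

#' Generate a grid of synthetic recordings
#'
#' Emits one element per condition cell: a [gaw_record()] for phonating
#' cells or a `gaw_no_phonation` marker otherwise. F0 before a mode
#' change rises with SLN level (vocal-fold tension); after a programmed
#' event it drops to roughly half. SLN = 0 cells get a slow upward F0
#' drift with rising flow instead of a constant pitch. Phonation onset
#' is delayed at higher SLN levels, shortening the phonating segment.
#'
#' The programmed ground truth is attached as `attr(value, "truth")`, a
#' tibble with one row per cell (condition, phonation, event flag and
#' transition time).
#'
#' @param config a [grid_config()].
#' @return a list of 320 cells (class `gaw_grid`).
#' @export
generate_grid <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  cells <- expand.grid(rln_right = config$rln_levels,
                       rln_left = config$rln_levels,
                       sln = config$sln_levels)
  cells <- cells[, c("sln", "rln_left", "rln_right")]
  base <- config$base_config
  fr <- base$frame_rate
  out <- vector("list", nrow(cells))
  truth <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sln <- cells$sln[i]; rl <- cells$rln_left[i]; rr <- cells$rln_right[i]
    id <- sprintf("sln%d_L%d_R%d", sln, rl, rr)
    phonates <- isTRUE(config$onset_rule(sln, rl, rr))
    has_event <- phonates && sln > 0 && isTRUE(config$event_rule(sln, rl, rr))
    cell_seed <- as.integer((config$seed + 7919 * i) %% 2147483647L)
    if (!phonates) {
      out[[i]] <- structure(
        list(condition = list(sln = sln, rln_left = rl, rln_right = rr),
             recording_id = id),
        class = "gaw_no_phonation")
      truth[[i]] <- tibble::tibble(sln = sln, rln_left = rl, rln_right = rr,
                                   recording_id = id, phonates = FALSE,
                                   has_event = FALSE,
                                   transition_time = NA_real_,
                                   onset_frame = NA_real_)
      next
    }
    onset_time <- 0.1 + 0.03 * sln
    duration <- round((1.5 - onset_time) * fr) / fr
    res <- with_seed(cell_seed, {
      trans <- if (has_event) stats::runif(1, 0.30, duration - 0.35) else numeric(0)
      f0_pre <- 340 + 15 * sln
      f0_post <- 200 + 12 * sln
      sched <- if (sln == 0) {
        # gentle upward drift with rising flow, never an abrupt step
        lapply(0:3, function(k) c(k * duration / 4, 240 + 15 * k))
      } else if (has_event) {
        list(c(0, f0_pre), c(trans, f0_post))
      } else {
        list(c(0, f0_pre))
      }
      dmg <- list()
      if (stats::runif(1) < config$damaged_prob) {
        len <- sample(5:18, 1)
        start <- sample.int(as.integer(duration * fr) - len - 10L, 1) + 5L
        dmg <- list(c(start, len))
      }
      lag <- 0.04 * (rr - rl) # asymmetric adduction -> phase asymmetry
      list(trans = trans,
           cfg = synth_config(
             frame_rate = fr, duration = duration, f0_schedule = sched,
             transition_times = trans,
             amplitude_start = base$amplitude_start,
             amplitude_end = base$amplitude_end,
             amplitude_jump = base$amplitude_jump,
             od_cd_ratio_pre = base$od_cd_ratio_pre,
             od_cd_ratio_post = base$od_cd_ratio_post,
             jitter_sd = base$jitter_sd, shimmer_sd = base$shimmer_sd,
             perturbation_boost = base$perturbation_boost,
             phase_lag = max(-0.4, min(0.4, lag)),
             left_right_split = base$left_right_split,
             noise_sd = base$noise_sd, damaged_runs = dmg,
             baseline = base$baseline,
             seed = sample.int(2147483646L, 1)))
    })
    rec <- generate_gaw(res$cfg)
    rec$condition <- list(sln = sln, rln_left = rl, rln_right = rr)
    rec$onset_frame <- round(onset_time * fr)
    rec$recording_id <- id
    out[[i]] <- rec
    truth[[i]] <- tibble::tibble(sln = sln, rln_left = rl, rln_right = rr,
                                 recording_id = id, phonates = TRUE,
                                 has_event = has_event,
                                 transition_time = if (has_event) res$trans else NA_real_,
                                 onset_frame = round(onset_time * fr))
  }
  grid <- structure(out, class = "gaw_grid")
  attr(grid, "truth") <- dplyr::bind_rows(truth)
  grid
}

#' Construct an acoustic record
#'
#' @param samples pressure-like numeric series.
#' @param sample_rate Hz (default 50000).
#' @param recording_id character label.
#' @return an object of class `acoustic_record`.
#' @export
acoustic_record <- function(samples, sample_rate = 50000,
                            recording_id = "recording") {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 recording_id = recording_id),
            class = "acoustic_record")
}

#' Derive a synthetic acoustic signal from a GAW
#'
#' Produces a pressure-like stand-in for the subglottal microphone
#' channel: the GAW is linearly resampled to the acoustic rate, its time
#' derivative is taken (the radiated sound of a pulsating glottal area is
#' dominated by the flow derivative), normalised to unit standard
#' deviation, and white measurement noise is added. A flat GAW yields
#' pure noise.
#'
#' @param gaw a [gaw_record()].
#' @param sample_rate output rate in Hz (default 50000).
#' @param noise_sd additive noise level relative to the unit-variance
#'   signal (default 0.01).
#' @param seed optional integer seed for the noise.
#' @return an [acoustic_record()] of the same duration as the GAW.
#' @export
generate_acoustic <- function(gaw, sample_rate = 50000, noise_sd = 0.01,
                              seed = NULL) {
  stopifnot(inherits(gaw, "gaw_record"))
  n <- length(gaw$total)
  t_frames <- (0:(n - 1)) / gaw$frame_rate
  ns <- as.integer(round(n / gaw$frame_rate * sample_rate))
  ts <- (0:(ns - 1)) / sample_rate
  x <- stats::approx(t_frames, gaw$total, xout = ts, rule = 2)$y
  dx <- c(0, diff(x)) * sample_rate
  s <- stats::sd(dx)
  sig <- if (s > 0) dx / s else numeric(ns)
  with_seed(seed, {
    if (noise_sd > 0) sig <- sig + stats::rnorm(ns, 0, noise_sd)
    acoustic_record(sig, sample_rate, gaw$recording_id)
  })
}
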