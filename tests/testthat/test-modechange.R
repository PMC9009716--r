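test_that("smoothing preserves constants and drops the edges", {
  sm <- smooth_lf0(rep(400, 50))
  expect_length(sm, 40)
  expect_true(all(sm == 400))
  expect_equal(attr(sm, "offset"), 5L)
  expect_error(smooth_lf0(rep(400, 19)), "too short")
})

test_that("smoothing matches the literal moving mean and spreads a step", {
  lf0 <- c(rep(400, 60), rep(200, 60))
  sm <- smooth_lf0(lf0)
  ref <- oracle_movmean(lf0, 10)[6:115]
  expect_equal(as.numeric(sm), ref)
  # the transition is monotone and complete within 10 smoothed points
  expect_true(all(diff(sm) <= 1e-9))
  mid <- which(sm < 400 - 1e-9 & sm > 200 + 1e-9)
  expect_lte(length(mid), 10)
})

test_that("a linear LF0 ramp stays linear in the smoothed interior", {
  lf0 <- seq(300, 420, length.out = 80)
  sm <- as.numeric(smooth_lf0(lf0))
  interior <- sm[6:(length(sm) - 5)]
  expect_true(all(abs(diff(diff(interior))) < 1e-9))
  expect_equal(unique(round(diff(interior), 9)),
               round(diff(lf0)[1], 9))
})

test_that("median smoothing is available behind the config", {
  lf0 <- c(rep(400, 30), 900, rep(400, 30))  # one wild cycle
  sm_med <- smooth_lf0(lf0, detector_config(method = "median"))
  expect_true(all(sm_med == 400))
  sm_mean <- smooth_lf0(lf0)
  expect_gt(max(sm_mean), 400)
})

test_that("the detector needs 50 Hz within ten cycles, sustained", {
  expect_equal(nrow(detect_mode_changes(rep(400, 120))), 0)
  step <- function(delta) c(rep(400, 60), rep(400 - delta, 60))
  ev45 <- detect_mode_changes(smooth_lf0(step(45)))
  ev50 <- detect_mode_changes(smooth_lf0(step(50)))
  expect_equal(nrow(ev45), 0)
  expect_equal(nrow(ev50), 1)
  expect_equal(ev50$direction, "down")
  ev_up <- detect_mode_changes(smooth_lf0(c(rep(200, 60), rep(400, 60))))
  expect_equal(ev_up$direction, "up")
})

test_that("a 400 to 200 Hz sustained step yields exactly one down event", {
  lf0 <- c(rep(400, 100), rep(200, 100))
  ev <- detect_mode_changes(smooth_lf0(lf0))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "down")
  expect_lt(abs(ev$seq_index - 101), 10)
})

test_that("the detector is sign-symmetric around the trace mean", {
  set.seed(30)
  base <- 300 + cumsum(rnorm(150, 0, 2))
  base[80:150] <- base[80:150] + 120
  flipped <- 2 * mean(base) - base
  ev1 <- detect_mode_changes(base)
  ev2 <- detect_mode_changes(flipped)
  expect_equal(ev1$smooth_index, ev2$smooth_index)
  expect_true(all(ev1$direction != ev2$direction))
  expect_gt(nrow(ev1), 0)
})

test_that("raising the threshold never increases the event count", {
  set.seed(31)
  tr <- c(rep(400, 60), rep(330, 40), rep(250, 60)) + rnorm(160, 0, 3)
  counts <- vapply(c(30, 50, 70, 90, 120), function(thr) {
    nrow(detect_mode_changes(tr, detector_config(delta_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("slow drifts below threshold-per-span are not events", {
  drift <- seq(250, 400, length.out = 200)  # < 8 Hz per 10 cycles
  expect_equal(nrow(detect_mode_changes(smooth_lf0(drift))), 0)
})

test_that("events too close to the trace ends are discarded", {
  lf0 <- c(rep(400, 18), rep(200, 18))
  # the step is genuine but sits within the boundary guard
  ev <- detect_mode_changes(smooth_lf0(lf0), detector_config())
  expect_equal(nrow(ev), 0)
  relaxed <- detect_mode_changes(smooth_lf0(lf0),
                                 detector_config(boundary_guard = 2L))
  expect_equal(nrow(relaxed), 1)
})

test_that("event characterization reports before/after medians and flow", {
  cfg <- synth_config(duration = 1.5,
                      f0_schedule = list(c(0, 400), c(0.75, 200)),
                      transition_times = 0.75, jitter_sd = 0.005,
                      shimmer_sd = 0.01, noise_sd = 2, seed = 40)
  rec <- generate_gaw(cfg)
  rec$onset_frame <- 300
  a <- analyze_recording(rec)
  expect_equal(nrow(a$events), 1)
  ev <- a$events
  # frame quantization: 400 Hz cycles are 7-8 frames (375-429 Hz)
  expect_lt(abs(ev$lf0_before - 400), 30)
  expect_lt(abs(ev$lf0_after - 200), 15)
  expect_gt(ev$dr_after, ev$dr_before)
  expect_equal(ev$direction, "down")
  # flow at the event follows the linear ramp from stimulation onset;
  # trimming advanced onset_frame by 30 frames
  t_stim <- 330 / 3000 + ev$event_time_s
  expect_equal(ev$flow_at_event, 300 + 1100 * min(t_stim / 1.5, 1))
})

test_that("the before-median uses all ten cycles when exactly ten exist", {
  lens <- rep(10L, 40)
  start <- cumsum(c(1L, lens))
  cycles <- tibble::tibble(cycle_index = 1:40,
                           start_frame = start[-41],
                           min_frame = start[-41] + 5L,
                           end_frame = start[-1],
                           length_frames = lens, valid = TRUE,
                           exclusion_reason = NA_character_)
  rec <- simple_record(500)
  params <- cycle_parameters(cycles, rec)
  params$lf0 <- c(rep(400, 10), rep(200, 30))
  ev <- characterize_event(11L, "down", cycles, params, rec)
  expect_equal(ev$lf0_before, 400)  # medians of exactly the first 10
  expect_equal(ev$lf0_after, 200)
  # at the very start there is nothing before the event
  ev2 <- characterize_event(1L, "down", cycles, params, rec)
  expect_true(is.na(ev2$lf0_before))
})

test_that("flow at a 1.5 s event with the standard ramp is 1400 mL/s", {
  lens <- rep(15L, 20)
  start <- cumsum(c(4201L, lens))
  cycles <- tibble::tibble(cycle_index = 1:20,
                           start_frame = start[-21],
                           min_frame = start[-21] + 7L,
                           end_frame = start[-1],
                           length_frames = lens, valid = TRUE,
                           exclusion_reason = NA_character_)
  total <- 100 + 50 * sin(2 * pi * (1:4600) / 15)
  rec <- gaw_record(total, 0.5 * total, 0.5 * total, onset_frame = 300)
  params <- cycle_parameters(cycles, rec)
  ev <- characterize_event(5L, "down", cycles, params, rec)
  # t_stim = 300/3000 + (start_frame - 1)/3000 >= 1.5 s -> ramp saturates
  expect_equal(ev$flow_at_event, 1400)
})

test_that("recordings failing preprocessing are excluded with a reason", {
  short <- simple_record(700)
  a <- analyze_recording(short)
  expect_false(a$included)
  expect_match(a$reason, "minimum continuous phonation")
  expect_equal(nrow(a$events), 0)
  tiny <- simple_record(50)
  a2 <- analyze_recording(tiny)
  expect_false(a2$included)
  expect_match(a2$reason, "too short")
})
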