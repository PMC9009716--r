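# a clean (noise/perturbation free) generator config for exact checks
clean_config <- function(f0 = 300, duration = 1, phase_lag = 0,
                         od_cd_ratio_pre = 1, amplitude_start = 1000,
                         amplitude_end = 3000, seed = 1, ...) {
  synth_config(duration = duration, f0_schedule = list(c(0, f0)),
               jitter_sd = 0, shimmer_sd = 0, noise_sd = 0,
               amplitude_start = amplitude_start,
               amplitude_end = amplitude_end,
               od_cd_ratio_pre = od_cd_ratio_pre,
               phase_lag = phase_lag, seed = seed, ...)
}

# a simple valid record of n frames for io/preprocessing tests
simple_record <- function(n, frame_rate = 3000, ...) {
  total <- 100 + 50 * sin(2 * pi * (1:n) / 10)
  gaw_record(total = total, left = 0.5 * total, right = 0.5 * total,
             frame_rate = frame_rate, ...)
}
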