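# gawmode

Cycle-based analysis of **glottal area waveforms** (GAWs) — the
per-frame area enclosed between the vocal folds, extracted from
high-speed videoendoscopy — with detection of spontaneous **vibratory
mode changes**: abrupt, sustained jumps or drops of the local
fundamental frequency that resemble the falsetto-to-chest register
transition of the singing voice.

It is written for voice scientists working with flow-ramp driven
phonation experiments in which laryngeal nerve activation is varied over
a grid of conditions (SLN level 0–4 setting vocal-fold tension,
left/right RLN levels 0–7 setting adduction), but the per-recording
pipeline applies to any GAW time series.

## What it computes

For each recording the pipeline

1. trims the first and last 10 ms of the phonation segment and requires
   at least 0.25 s of continuous phonation (`trim_onset_offset()`,
   `passes_inclusion()`);
2. detects maximum-based oscillation cycles — local maxima with
   topographic prominence ≥ 5% of the recording's maximum dynamic range
   and pairwise separation ≥ 3 frames — then excludes cycles overlapping
   damaged video frames and cycles whose length strays outside
   [0.5×, 2×] the local median of 11 cycles (`detect_cycles()`);
3. computes seven per-cycle parameters (`cycle_parameters()`):

   | | |
   |---|---|
   | LF0 | local fundamental frequency, `frame_rate / cycle_length` (Hz) |
   | DR | dynamic range, max − min area per cycle (pixel²) |
   | PHA | left-right phase asymmetry, normalised offset of the partial-area maxima (positive = left lead) |
   | AP, TP | amplitude / time periodicity, `min/max` ratio of neighbouring cycles' DR / duration (1 = periodic) |
   | OD, CD | open / closing duration, minimum→end and start→minimum (ms) |

4. smooths the LF0 sequence with a ten-point moving average (dropping
   five cycles at each edge) and flags a **mode change** wherever the
   smoothed LF0 moves by ≥ 50 Hz within ten cycles and stays shifted for
   at least five consecutive cycles, away from the trace ends
   (`detect_mode_changes()`); each event is characterized by medians of
   LF0/DR/OD/CD over up to 10 valid cycles per side and by the airflow
   at the event on the linear ramp (`characterize_event()`).

`generate_gaw()` / `generate_grid()` provide a phenomenological
synthetic phonation generator (pulse trains with programmable F0
schedule, flow-ramp amplitude rise, OD:CD register shape, jitter,
shimmer, pre-event perturbation boost, left-right phase lag, noise and
damaged frames) so the full pipeline — including a 320-cell condition
grid — runs and is tested without any video data. `summarize_grid()`,
`spectrogram()` and `render_outputs()` aggregate and render the results.

## Worked example

```r
library(gawmode)

cfg <- synth_config(
  duration = 1.4,
  f0_schedule = list(c(0, 400), c(0.8, 212)),  # falsetto-like -> chest-like
  transition_times = 0.8,
  seed = 2024)
rec <- generate_gaw(cfg)
rec$onset_frame <- 300            # phonation began 0.1 s into the ramp

analysis <- analyze_recording(rec)
analysis$events[, c("event_time_s", "direction", "lf0_before", "lf0_after",
                    "dr_before", "dr_after", "od_after", "cd_after",
                    "flow_at_event")]
#> # A tibble: 1 × 9
#>   event_time_s direction lf0_before lf0_after dr_before dr_after od_after
#>          <dbl> <chr>          <dbl>     <dbl>     <dbl>    <dbl>    <dbl>
#> 1        0.792 down            429.      214.     2616.    3441.     1.67
#>   cd_after flow_at_event
#>      <dbl>         <dbl>
#> 1        3          961.
```

The programmed transition at 0.8 s (0.79 s after trimming) is recovered
at 0.792 s as a *down* event: the median LF0 over the ten cycles before
the event is 429 Hz (the 400 Hz target quantised to 7-frame cycles) and
214 Hz after; the dynamic range rises from about 2600 to 3400 pixel²;
after the event the closing duration (3 ms) clearly exceeds the open
duration (1.67 ms), the chest-register signature. The airflow at the
event follows the 300→1400 mL/s ramp: 961 mL/s at
`0.1 s + 0.01 s + 0.792 s` into stimulation.

For a whole condition grid:

```r
grid     <- generate_grid(grid_config(seed = 1))
analyses <- analyze_grid(grid)
summ     <- summarize_grid(analyses)
summ$by_sln          # included conditions, signals with changes, flow at change
render_outputs(summ, analyses, "out/")   # tables, heatmaps, per-event plots
```

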