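---
title: "Methods: cycle-based GAW analysis and mode-change detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cycle-based GAW analysis and mode-change detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gawmode)
```

## The problem

High-speed videoendoscopy of the larynx yields, after segmentation, a
*glottal area waveform* (GAW): the area enclosed between the vocal folds,
one value per video frame (typically 3000 frames/s), optionally split
into left and right partial areas at the glottal midline. During
phonation driven by a rising airflow ramp, the vocal folds can
spontaneously switch vibratory mode — an abrupt, sustained jump or (far
more often) drop of the fundamental frequency, resembling the
falsetto-to-chest register transition of the singing voice. `gawmode`
implements the cycle-level analysis chain for such recordings: cycle
detection, data cleaning, seven per-cycle vibratory parameters, detection
and characterization of mode changes, and aggregation over a grid of
laryngeal-nerve stimulation conditions (SLN level 0–4 controlling
vocal-fold tension; left/right RLN levels 0–7 controlling adduction).

## Preprocessing

Phonation onset is taken as given metadata (`onset_frame`); the pipeline
does not locate onset itself. `trim_onset_offset()` removes
`round(0.010 * frame_rate)` frames from each end of the segment (30
frames per end at 3000 fps) so that onset and offset transients cannot
masquerade as vibratory events, and `passes_inclusion()` requires at
least `round(0.25 * frame_rate)` remaining frames (750 at 3000 fps) of
continuous phonation. Trimming is applied first and the inclusion filter
is evaluated on the trimmed length. Short runs of damaged video frames
(always under 20 frames in the data this models) do *not* break
continuity for the inclusion filter: recordings with damaged runs are
retained and only the cycles overlapping them are excluded.

Frame indices are 1-based inside R, matching the language's conventions;
the on-disk CSV format (`write_gaw()`) uses a 0-based `frame_index`
column. Cycle intervals are half-open `[start, end)`, so one frame
belongs to exactly one cycle and a shared boundary maximum opens the
following cycle.

## Cycle detection

Cycles are anchored at local maxima of the total GAW. A candidate peak
must clear two hurdles:

* **Prominence.** Its topographic prominence must reach 5% of the
  recording's *maximum dynamic range* — the largest distance between any
  local peak and the lowest sample within 12.5 ms of it (±38 frames at
  3000 fps, rounding half up). Using a single per-recording scalar rather
  than per-peak windows makes the criterion scale-free across recordings
  whose amplitudes differ by orders of magnitude, and insensitive to the
  amplitude rise along the flow ramp.
* **Distance.** No two retained peaks may be closer than 3 frames (1 ms).
  The filter is greedy: peaks are processed in decreasing height, earlier
  index first on exact ties, and a peak is dropped if it lies closer than
  3 frames to an already retained one. A separation of exactly 3 frames
  is kept. These tie-break rules are part of the tested contract because
  off-the-shelf peak finders differ exactly at these boundaries.

Each pair of consecutive retained maxima forms one cycle; the internal
minimum is the earliest argmin strictly between them. Cycles overlapping
a damaged frame are flagged `damaged`. Finally an outlier rule flags
cycles whose length is below 0.5× or above 2.0× the median length of the
11 cycles centred on them (window shrunk at the ends, all medians from
the original lengths in a single pass). The bounds are deliberately
asymmetric-proof: a genuine F0 halving (alternating 7–8 frame cycles
jumping to 15 frames, the typical 400 → 200 Hz event) sits exactly on
the 2.0 boundary and is kept, while double/half-period detection
glitches are flagged. The 11/0.5/2.0 values are package defaults,
exposed as arguments.

## The seven cycle parameters

For every valid cycle (frame rate $f_s$, cycle frames $[s, e)$ with
internal minimum $m$):

| parameter | definition | unit |
|---|---|---|
| LF0 | $f_s / (e - s)$ | Hz |
| DR  | $\max - \min$ of the total GAW over $[s, e]$ | pixel² |
| PHA | $(t^{R}_{max} - t^{L}_{max}) / (e - s)$, wrapped into $[-0.5, 0.5]$ | — |
| AP  | $\min(DR_i, DR_{i+1}) / \max(DR_i, DR_{i+1})$ | — |
| TP  | $\min(L_i, L_{i+1}) / \max(L_i, L_{i+1})$ | — |
| OD  | $(e - m) \cdot 1000 / f_s$ | ms |
| CD  | $(m - s) \cdot 1000 / f_s$ | ms |

AP and TP use the min/max-ratio convention (1 = perfectly periodic;
lower = more perturbed, i.e. shimmer/jitter analogues) and are assigned
to the earlier cycle of each pair. They are computed only across
*directly consecutive valid* cycles; pairs broken by an excluded cycle
yield `NA`, never an artificial 0. PHA is positive for a left-side phase
lead and normalised by the cycle length; since the partial-area maxima
are frame-quantised, PHA resolution is one frame per cycle (0.05 at a
20-frame cycle). OD and CD tile the cycle exactly: OD + CD equals the
cycle duration by construction. AP, TP and PHA are invariant under any
positive rescaling of the GAW; DR scales linearly and LF0 not at all —
these invariances are property-tested.

## Mode-change detection

The LF0 sequence of valid cycles is smoothed with a ten-point moving
average. The window follows the usual even-window convention (five
cycles before through four after the current one, shrunk at the ends) —
with an even window a perfectly centred mean does not exist, and this
asymmetric form is what makes a 50 Hz step fully resolvable within a
ten-cycle span. The first and last five smoothed values are discarded.
The smoothing statistic is configurable (`method = "median"`), mean
being the default.

On the smoothed trace, index $i$ becomes a candidate when some $j$ with
$0 < j - i \le 10$ satisfies $|s_j - s_i| \ge 50$ Hz *and* at least five
consecutive values from $j$ onward stay at least 50 Hz away from $s_i$
on the same side. Overlapping candidates merge into one event anchored
at the steepest change; events within ten cycles of either trace end are
discarded, because changes that early or late cannot be told apart from
onset/offset effects. The 50 Hz threshold is large enough to be clearly
audible yet small enough to keep genuine smaller events. The detector is
sign-symmetric, monotone in the threshold, and produces no events on
drifts slower than the threshold per span — all property-tested.

Because a ten-point moving average localises an abrupt step only to
within about half a window, `analyze_recording()` refines each anchor on
the raw LF0 sequence: the pre- and post-event levels are estimated as
medians of regions clear of the boundary, and the event snaps to the
first cycle that sits — and stays, for two further cycles — closer to
the post level. On synthetic grids this places the anchor within about
one cycle of the programmed transition, which matters because the event
characterization medians ("up to 10 valid cycles immediately before and
after") would otherwise mix regimes.

Each event is characterized by the medians of LF0, DR, OD and CD over
those context windows, plus the airflow at the event, obtained from the
linear ramp: $\mathrm{flow} = F_0 + (F_1 - F_0)\,\min(t_{stim}/T, 1)$
with the default ramp 300 → 1400 mL/s over $T = 1.5$ s and $t_{stim}$
measured from stimulation onset (the `onset_frame` offset plus the event
time within the segment; trimming advances `onset_frame` so epoch times
stay correct).

## The synthetic generator

No in vivo recordings are distributed, so `generate_gaw()` provides a
phenomenological forward model with the statistical structure the
analysis assumes — it makes no attempt at fluid–structure vocal-fold
physics. Each cycle is a skewed raised-cosine pulse running from one
maximum through the internal minimum to the next maximum. The OD:CD
ratio parameterises the skew directly, because register is characterised
by the OD/CD relation rather than a specific waveform: 1.0 (OD ≈ CD,
falsetto-like) before the first programmed transition, 0.5 (CD twice OD,
chest-like) after. Nominal cycle length follows a piecewise-constant F0
schedule realised at cycle boundaries only, so ground-truth event
placement is unambiguous; boundary positions accumulate a continuous
phase, so a 400 Hz target at 3000 fps correctly yields alternating 7/8
frame cycles. Peak-to-trough amplitude ramps linearly
(`amplitude_start` → `amplitude_end`), standing in for the rising flow;
no published mapping from flow (mL/s) to area dynamic range exists, so
linearity is the assumption consistent with amplitude rising throughout
every recording. After the first transition the amplitude gains a factor
`amplitude_jump` (default 1.4): the chest-like mode oscillates wider,
consistent with observed DR steps across real events.

Jitter (cycle length) and shimmer (amplitude) are multiplicative
Gaussian perturbations; within a configurable window before each
programmed transition (default 0.08 s) both are multiplied by a boost
factor (default 4), emulating the pre-event instability in which
perturbation rises before the actual frequency drop. The left and right
partials are phase-shifted copies of the pulse (±`phase_lag`/2 cycles,
positive = left lead) scaled by `left_right_split`, and the total is
their *sum*, so left + right equals the total identically — additive
noise is split between the partials to preserve this. Damaged runs
(≤ 20 frames) zero the affected frames and set the mask.

Default study conditions: 3000 fps, a 1.5 s stimulation epoch, flow ramp
300 → 1400 mL/s, F0 near 400 Hz before and near 200 Hz after an event,
amplitude ramp 800 → 3500 pixel², baseline 20 pixel², jitter 1%, shimmer
3%, noise 5 pixel². `generate_grid()` visits all 5 × 8 × 8 = 320
SLN/RLN cells: phonation onset requires combined RLN drive to exceed a
tension-dependent floor (`rln_left + rln_right >= 3 + 2*sln`), so fewer
low-RLN cells phonate at high SLN; events are programmed (only where
SLN ≥ 1) in strongly and nearly symmetrically adducted cells
(`min(rln) >= 4`, `|diff| <= 2`). Both rules are explicit predicates in
`grid_config()` — qualitative emulations, not claims about physiology.
Pre-event F0 rises with SLN (340 + 15·SLN Hz), post-event F0 is
200 + 12·SLN Hz; SLN 0 cells instead drift slowly upward in F0 with
rising flow, which the detector must ignore. Onset is delayed by
0.1 + 0.03·SLN s, shortening high-SLN segments. Phase lag is tied to the
RLN left-right difference (0.04 per level), so asymmetric stimulation
shows up as phase asymmetry.

The synthetic acoustic channel (`generate_acoustic()`) is the
band-limited time-derivative of the resampled GAW plus white noise at
50 kHz — enough for spectrogram plumbing (4096-sample Hanning window,
80% overlap), not a vocal-tract model.

What passing tests on this generator do show: the pipeline recovers
programmed constants, placements and directions under realistic levels
of jitter, shimmer, noise, damage and frame quantization. What they do
not show: robustness to segmentation artifacts, anterior-posterior phase
"blurring" of PHA, chaotic vibratory regimes, or onset detection errors
— none of which the generator emulates.

## Numerical choices and degenerate inputs

* Frame-count constants round half away from zero (`round(0.010*fs)`,
  ±38-frame dynamic-range window at 3000 fps).
* Peak plateaus: the earliest sample of a flat-topped peak is the peak;
  argmin/argmax ties resolve to the earliest index throughout.
* A flat or monotone series has no maximum dynamic range (error), but
  `detect_peaks()` simply returns an empty set and downstream stages
  yield empty tables rather than failing a whole grid run.
* `compute_ap()` defines 1 for two zero-DR cycles (a constant is
  perfectly periodic).
* Recordings that are too short to trim, fail inclusion, or have too few
  valid cycles for smoothing are returned as non-included analyses with
  a machine-readable `reason`, never as errors.
* Prominence and threshold comparisons use a relative 1e-9 epsilon so
  that calibrated boundary cases (exactly 5%, exactly 50 Hz) are kept.

## Problem sizes used in the tests

The test suite regenerates everything programmatically: single
recordings of 1–1.5 s at 3000 fps, the full 320-cell grid once (about
200 phonating cells, ~50 programmed events; roughly a minute of CPU),
and 1000 random short series for the brute-force oracle equivalence
checks of peak detection, prominence, moving mean and outlier flagging.

## Known limitations

* The outlier rule's exact window and bounds are declared defaults, not
  reproductions of a published algorithm.
* PHA quantization is one frame per cycle; at 400 Hz (7–8 frames) that
  is ±0.13, so PHA is only meaningful averaged over many cycles.
* The detector reports all qualifying events; it does not label chaotic
  sections, where event counts are inherently less reliable.
* Flow at event depends on per-recording onset metadata; with synthetic
  data onset is known exactly, with real data its accuracy bounds the
  flow accuracy.
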