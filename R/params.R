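#' Local fundamental frequency of one cycle
#'
#' The inverse cycle duration: `frame_rate / length_frames`.
#'
#' @param length_frames cycle length in frames.
#' @param frame_rate frames per second.
#' @return LF0 in Hz.
#' @export
compute_lf0 <- function(length_frames, frame_rate) frame_rate / length_frames

#' Dynamic range of one cycle
#'
#' Maximum minus minimum of the total GAW over the closed interval
#' `[start_frame, end_frame]`.
#'
#' @param start_frame,end_frame cycle boundary frames (1-based).
#' @param gaw numeric area series.
#' @return dynamic range (pixel^2).
#' @export
compute_dr <- function(start_frame, end_frame, gaw) {
  seg <- gaw[start_frame:end_frame]
  max(seg) - min(seg)
}

# wrap a cycle fraction into [-0.5, 0.5]
wrap_half <- function(x) x - round(x)

#' Left-right phase asymmetry of one cycle
#'
#' Normalised timing offset between the maxima of the left and right
#' partial GAWs within the cycle: `(t_max_right - t_max_left) /
#' length_frames`, wrapped into `[-0.5, 0.5]`. The argmax is taken over
#' the half-open cycle interval, earliest index on ties. Positive values
#' mean a left-side phase lead.
#'
#' @param start_frame,end_frame cycle boundary frames (1-based).
#' @param left,right partial area series.
#' @return phase asymmetry, dimensionless in `[-0.5, 0.5]`.
#' @export
compute_pha <- function(start_frame, end_frame, left, right) {
  idx <- start_frame:(end_frame - 1L)
  t_left <- idx[which.max(left[idx])]
  t_right <- idx[which.max(right[idx])]
  wrap_half((t_right - t_left) / (end_frame - start_frame))
}

#' Amplitude periodicity of a cycle pair
#'
#' Similarity of the dynamic ranges of two neighbouring cycles:
#' `min(dr1, dr2) / max(dr1, dr2)`, defined as 1 when both are zero.
#' A value of 1 means perfectly repeating amplitude; lower values mean
#' higher shimmer-like perturbation.
#'
#' @param dr1,dr2 dynamic ranges of consecutive valid cycles.
#' @return amplitude periodicity in (0, 1].
#' @export
compute_ap <- function(dr1, dr2) {
  if (dr1 == 0 && dr2 == 0) return(1)
  min(dr1, dr2) / max(dr1, dr2)
}

#' Time periodicity of a cycle pair
#'
#' Similarity of the durations of two neighbouring cycles:
#' `min(len1, len2) / max(len1, len2)`. A value of 1 means perfectly
#' repeating period; lower values mean higher jitter-like perturbation.
#'
#' @param len1,len2 lengths (frames) of consecutive valid cycles.
#' @return time periodicity in (0, 1].
#' @export
compute_tp <- function(len1, len2) min(len1, len2) / max(len1, len2)

#' Open and closing duration of one cycle
#'
#' For maximum-anchored cycles the closing duration (CD) runs from the
#' cycle beginning (a maximum) to the internal minimum, and the open
#' duration (OD) from the minimum to the cycle end. They tile the cycle:
#' `od + cd` equals the cycle duration exactly.
#'
#' @param start_frame,min_frame,end_frame cycle landmark frames.
#' @param frame_rate frames per second.
#' @return named numeric `c(od = , cd = )` in milliseconds.
#' @export
compute_od_cd <- function(start_frame, min_frame, end_frame, frame_rate) {
  c(od = (end_frame - min_frame) * 1000 / frame_rate,
    cd = (min_frame - start_frame) * 1000 / frame_rate)
}

#' Per-cycle parameter table
#'
#' Computes the seven cycle-based parameters for every valid cycle of a
#' recording: LF0 (Hz), DR (pixel^2), PHA, AP, TP (dimensionless), OD and
#' CD (ms). AP and TP compare a cycle with its successor and are assigned
#' to the earlier cycle of the pair; they are only defined across
#' directly consecutive valid cycles (pairs broken by excluded cycles
#' yield `NA`, not zero). Invalid cycles keep their row with `NA`
#' parameters so the table tiles the peak sequence.
#'
#' @param cycles cycle tibble from [detect_cycles()].
#' @param record the [gaw_record()] the cycles came from.
#' @return a tibble with one row per cycle: `cycle_index`, `start_frame`,
#'   `time_s` (cycle start relative to segment start), `valid`,
#'   `exclusion_reason`, `lf0`, `dr`, `pha`, `ap`, `tp`, `od`, `cd`.
#' @export
cycle_parameters <- function(cycles, record) {
  stopifnot(inherits(record, "gaw_record"))
  n <- nrow(cycles)
  fr <- record$frame_rate
  lf0 <- dr <- pha <- ap <- tp <- od <- cd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!cycles$valid[i]) next
    s <- cycles$start_frame[i]; e <- cycles$end_frame[i]
    m <- cycles$min_frame[i]
    lf0[i] <- compute_lf0(cycles$length_frames[i], fr)
    dr[i] <- compute_dr(s, e, record$total)
    pha[i] <- compute_pha(s, e, record$left, record$right)
    oc <- compute_od_cd(s, m, e, fr)
    od[i] <- oc[["od"]]; cd[i] <- oc[["cd"]]
  }
  for (i in seq_len(max(0L, n - 1L))) {
    consecutive <- cycles$valid[i] && cycles$valid[i + 1L] &&
      cycles$end_frame[i] == cycles$start_frame[i + 1L]
    if (consecutive) {
      ap[i] <- compute_ap(dr[i], dr[i + 1L])
      tp[i] <- compute_tp(cycles$length_frames[i],
                          cycles$length_frames[i + 1L])
    }
  }
  tibble::tibble(cycle_index = cycles$cycle_index,
                 start_frame = cycles$start_frame,
                 time_s = (cycles$start_frame - 1L) / fr,
                 valid = cycles$valid,
                 exclusion_reason = cycles$exclusion_reason,
                 lf0 = lf0, dr = dr, pha = pha, ap = ap, tp = tp,
                 od = od, cd = cd)
}
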