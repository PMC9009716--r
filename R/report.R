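#' Analyse every recording of a condition grid
#'
#' Maps [analyze_recording()] over a list of grid cells (as returned by
#' [generate_grid()], or any list mixing [gaw_record()]s and
#' `gaw_no_phonation` markers). Non-phonating cells become non-included
#' analyses with reason `"no phonation"`.
#'
#' @param grid list of cells.
#' @param peak_cfg a [peak_config()].
#' @param det_cfg a [detector_config()].
#' @param trim apply onset/offset trimming per recording.
#' @return list of `gaw_analysis` objects.
#' @export
analyze_grid <- function(grid, peak_cfg = peak_config(),
                         det_cfg = detector_config(), trim = TRUE) {
  lapply(grid, function(cell) {
    if (inherits(cell, "gaw_no_phonation")) {
      out <- list(recording_id = cell$recording_id, condition = cell$condition,
                  included = FALSE, reason = "no phonation", cycles = NULL,
                  params = NULL, lf0_smooth = NULL, events = empty_events())
      class(out) <- "gaw_analysis"
      out
    } else {
      analyze_recording(cell, peak_cfg, det_cfg, trim = trim)
    }
  })
}

dr_slope_of <- function(params) {
  ok <- params$valid & !is.na(params$dr)
  if (sum(ok) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(params$dr[ok] ~ params$time_s[ok]))[2])
}

#' Summarize analyses over the condition grid
#'
#' Produces the per-cell summary (inclusion, event count, the
#' least-squares slope of per-cycle dynamic range against time as an
#' "amplitude rise" measure, mean phase asymmetry, mean flow at events)
#' and the per-SLN overview: number of included conditions, number of
#' signals with at least one mode change, maximum events per signal, and
#' mean flow at the detected events.
#'
#' @param analyses list of `gaw_analysis` from [analyze_grid()].
#' @return list with tibbles `cells`, `by_sln`, and `events` (all events
#'   with their condition columns).
#' @export
summarize_grid <- function(analyses) {
  cells <- dplyr::bind_rows(lapply(analyses, function(a) {
    ev <- a$events
    tibble::tibble(
      recording_id = a$recording_id,
      sln = a$condition$sln,
      rln_left = a$condition$rln_left,
      rln_right = a$condition$rln_right,
      included = a$included,
      reason = a$reason,
      n_events = nrow(ev),
      dr_slope = if (a$included) dr_slope_of(a$params) else NA_real_,
      mean_pha = if (a$included) mean(a$params$pha, na.rm = TRUE) else NA_real_,
      mean_flow_events = if (nrow(ev)) mean(ev$flow_at_event) else NA_real_)
  }))
  events <- dplyr::bind_rows(lapply(analyses, function(a) {
    if (!nrow(a$events)) return(NULL)
    dplyr::mutate(a$events, recording_id = a$recording_id,
                  sln = a$condition$sln, rln_left = a$condition$rln_left,
                  rln_right = a$condition$rln_right, .before = 1)
  }))
  if (!nrow(events)) {
    events <- dplyr::mutate(empty_events(), recording_id = character(0),
                            sln = integer(0), rln_left = integer(0),
                            rln_right = integer(0), .before = 1)
  }
  by_sln <- cells |>
    dplyr::group_by(.data$sln) |>
    dplyr::summarise(
      included_conditions = sum(.data$included),
      signals_with_changes = sum(.data$n_events > 0),
      max_changes_per_signal = if (any(.data$n_events > 0)) max(.data$n_events) else NA_integer_,
      mean_flow_at_change = if (any(.data$n_events > 0)) {
        mean(.data$mean_flow_events[.data$n_events > 0])
      } else NA_real_,
      .groups = "drop")
  list(cells = cells, by_sln = by_sln, events = events)
}

#' Short-time spectrogram of an acoustic record
#'
#' Short-time Fourier magnitude with a 4096-sample Hanning window and 80%
#' overlap (hop of `round(window * (1 - overlap))` samples); the
#' frequency axis runs from 0 to half the sample rate. Column count is
#' `floor((N - window) / hop) + 1`.
#'
#' @param acoustic an [acoustic_record()].
#' @param window window length in samples (default 4096).
#' @param overlap overlap fraction (default 0.80).
#' @return list of class `gaw_spectrogram` with `magnitude`
#'   (freq x time), `freq` (Hz) and `time` (s).
#' @export
spectrogram <- function(acoustic, window = 4096L, overlap = 0.80) {
  stopifnot(inherits(acoustic, "acoustic_record"))
  if (length(acoustic$samples) <= window) {
    stop("acoustic record shorter than one spectrogram window")
  }
  sp <- signal::specgram(acoustic$samples, n = window,
                         Fs = acoustic$sample_rate, window = window,
                         overlap = round(window * overlap))
  structure(list(magnitude = abs(sp$S), freq = as.numeric(sp$f),
                 time = as.numeric(sp$t)),
            class = "gaw_spectrogram")
}

#' Write grid-analysis artifacts to disk
#'
#' Writes, with deterministic names under `out_dir`: `summary_by_sln.csv`
#' and `cells.csv` (condition-grid tables), `events.csv`, `parameters.csv`
#' (per-cycle parameters of every included recording), `cells.json`, the
#' per-SLN grid heatmaps (`heatmap_events`, `heatmap_dr_slope`,
#' `heatmap_pha`; event counts in reds, phase lead sign diverging
#' red/green), and per-recording LF0 traces with event markers plus AP/TP
#' traces for recordings listed in `plot_recordings`.
#'
#' @param summaries output of [summarize_grid()].
#' @param analyses list of `gaw_analysis` (for the per-recording plots
#'   and the parameter table).
#' @param out_dir output directory, created if needed.
#' @param plot_recordings recording ids to plot individually (default:
#'   all recordings with at least one event).
#' @param format `"png"` or `"pdf"`.
#' @return invisibly, the vector of files written.
#' @export
render_outputs <- function(summaries, analyses, out_dir,
                           plot_recordings = NULL,
                           format = c("png", "pdf")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit_csv(summaries$by_sln, "summary_by_sln.csv")
  emit_csv(summaries$cells, "cells.csv")
  emit_csv(if (is.null(summaries$events)) empty_events() else summaries$events,
           "events.csv")
  params <- dplyr::bind_rows(lapply(analyses, function(a) {
    if (is.null(a$params)) return(NULL)
    dplyr::mutate(a$params, recording_id = a$recording_id, .before = 1)
  }))
  emit_csv(params, "parameters.csv")
  json_path <- file.path(out_dir, "cells.json")
  jsonlite::write_json(summaries$cells, json_path, digits = NA, na = "null")
  files <- c(files, json_path)

  save_plot <- function(p, name) {
    path <- file.path(out_dir, paste0(name, ".", format))
    ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 120)
    files <<- c(files, path)
  }
  cells <- summaries$cells
  if (nrow(cells)) {
    heat <- function(fill, palette_low, palette_high, title) {
      ggplot2::ggplot(cells, ggplot2::aes(x = .data$rln_right,
                                          y = .data$rln_left,
                                          fill = .data[[fill]])) +
        ggplot2::geom_tile() +
        ggplot2::facet_wrap(~sln, labeller = ggplot2::label_both) +
        ggplot2::scale_fill_gradient2(low = palette_low, mid = "white",
                                      high = palette_high, midpoint = 0,
                                      na.value = "grey90") +
        ggplot2::labs(title = title, x = "RLN right level",
                      y = "RLN left level") +
        ggplot2::theme_minimal()
    }
    save_plot(heat("n_events", "white", "red3",
                   "Detected mode changes per condition"), "heatmap_events")
    save_plot(heat("dr_slope", "steelblue", "red3",
                   "Dynamic-range increase over time"), "heatmap_dr_slope")
    save_plot(heat("mean_pha", "green4", "red3",
                   "Mean phase asymmetry (red = left lead)"), "heatmap_pha")
  }
  if (is.null(plot_recordings)) {
    plot_recordings <- cells$recording_id[cells$n_events > 0]
  }
  for (a in analyses) {
    if (!a$included || !(a$recording_id %in% plot_recordings)) next
    pv <- a$params[a$params$valid, ]
    markers <- a$events$event_time_s
    p1 <- ggplot2::ggplot(pv, ggplot2::aes(x = .data$time_s, y = .data$lf0)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.6) +
      ggplot2::geom_vline(xintercept = markers, colour = "red",
                          linetype = "dashed") +
      ggplot2::labs(title = paste("LF0 trace:", a$recording_id),
                    x = "time (s)", y = "LF0 (Hz)") +
      ggplot2::theme_minimal()
    save_plot(p1, paste0("lf0_", a$recording_id))
    long <- tibble::tibble(
      time_s = rep(pv$time_s, 2),
      value = c(pv$ap, pv$tp),
      parameter = rep(c("AP", "TP"), each = nrow(pv)))
    p2 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s,
                                             y = .data$value,
                                             colour = .data$parameter)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::geom_vline(xintercept = markers, colour = "red",
                          linetype = "dashed") +
      ggplot2::labs(title = paste("Amplitude/time periodicity:",
                                  a$recording_id),
                    x = "time (s)", y = "periodicity") +
      ggplot2::theme_minimal()
    save_plot(p2, paste0("perturbation_", a$recording_id))
  }
  invisible(files)
}
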