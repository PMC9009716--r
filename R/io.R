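#' Construct a GAW recording
#'
#' A `gaw_record` bundles the total glottal area series, the left/right
#' partial area series (split at the glottal midline), a damaged-frame
#' mask and the metadata of one phonation recording: camera frame rate,
#' the nerve-stimulation condition (SLN level 0-4, left/right RLN levels
#' 0-7), the airflow ramp schedule and the onset frame of the phonation
#' segment within the stimulation epoch.
#'
#' Frame indices in R are 1-based; on disk (see [write_gaw()]) the
#' `frame_index` column is 0-based.
#'
#' @param total numeric vector, total glottal area per frame (pixel^2).
#' @param left,right numeric vectors, partial areas left/right of the
#'   glottal midline. Must satisfy `left + right == total` up to noise.
#' @param frame_rate frames per second (default 3000).
#' @param damaged_mask logical vector flagging corrupted video frames.
#' @param condition list with `sln` (0-4), `rln_left`, `rln_right` (0-7);
#'   `NA` allowed when unknown.
#' @param flow_ramp list with `flow_start`, `flow_end` (mL/s) and
#'   `ramp_duration` (s) describing the linear airflow ramp applied over
#'   the stimulation epoch.
#' @param onset_frame frame offset of the segment start within the
#'   stimulation epoch (frames since stimulation onset).
#' @param recording_id character label.
#' @return an object of class `gaw_record`.
#' @export
gaw_record <- function(total, left, right, frame_rate = 3000,
                       damaged_mask = rep(FALSE, length(total)),
                       condition = list(sln = NA_integer_,
                                        rln_left = NA_integer_,
                                        rln_right = NA_integer_),
                       flow_ramp = list(flow_start = 300, flow_end = 1400,
                                        ramp_duration = 1.5),
                       onset_frame = 0,
                       recording_id = "recording") {
  n <- length(total)
  if (length(left) != n || length(right) != n || length(damaged_mask) != n) {
    stop("total, left, right and damaged_mask must all have length ", n)
  }
  if (!is.logical(damaged_mask)) stop("damaged_mask must be logical")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  ok <- !damaged_mask
  if (any(total[ok] < 0, na.rm = TRUE) || any(left[ok] < 0, na.rm = TRUE) ||
      any(right[ok] < 0, na.rm = TRUE)) {
    stop("area values must be >= 0 at non-damaged frames")
  }
  if (flow_ramp$flow_end < flow_ramp$flow_start) {
    stop("flow_end must be >= flow_start")
  }
  structure(
    list(total = as.numeric(total), left = as.numeric(left),
         right = as.numeric(right), frame_rate = frame_rate,
         damaged_mask = damaged_mask, condition = condition,
         flow_ramp = flow_ramp, onset_frame = onset_frame,
         recording_id = recording_id),
    class = "gaw_record")
}

#' @export
print.gaw_record <- function(x, ...) {
  cat("<gaw_record>", x$recording_id, "\n")
  cat(sprintf("  %d frames at %g fps (%.3f s), %d damaged\n",
              length(x$total), x$frame_rate,
              length(x$total) / x$frame_rate, sum(x$damaged_mask)))
  cond <- x$condition
  cat(sprintf("  condition: SLN %s, RLN L %s / R %s\n",
              cond$sln, cond$rln_left, cond$rln_right))
  invisible(x)
}

#' @export
length.gaw_record <- function(x) length(x$total)

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write / read a GAW recording
#'
#' One recording is stored as a CSV file (columns `frame_index` 0-based,
#' `total_area`, `left_area`, `right_area`, `damaged` 0/1) plus a JSON
#' sidecar of the same basename holding frame rate, condition, flow ramp,
#' onset frame and recording id. Values are written with 17 significant
#' digits so that a write/read round trip is lossless.
#'
#' @param record a [gaw_record()].
#' @param path CSV file path (sidecar is written next to it).
#' @return `write_gaw()` returns `path` invisibly; `read_gaw()` returns a
#'   [gaw_record()].
#' @export
write_gaw <- function(record, path) {
  stopifnot(inherits(record, "gaw_record"))
  n <- length(record$total)
  df <- data.frame(
    frame_index = 0:(n - 1L),
    total_area = sprintf("%.17g", record$total),
    left_area = sprintf("%.17g", record$left),
    right_area = sprintf("%.17g", record$right),
    damaged = as.integer(record$damaged_mask))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(frame_rate = record$frame_rate,
               condition = record$condition,
               flow_ramp = record$flow_ramp,
               onset_frame = record$onset_frame,
               recording_id = record$recording_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_gaw
#' @export
read_gaw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  required <- c("frame_index", "total_area", "left_area", "right_area",
                "damaged")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malformed GAW CSV: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("malformed GAW CSV: column '", col, "' is not numeric")
    }
    if (anyNA(v)) {
      stop("malformed GAW CSV: column '", col, "' has missing values (row ",
           which(is.na(v))[1], ")")
    }
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  # JSON null round-trips as NULL in lists; restore NA for condition fields
  cond <- lapply(meta$condition, function(v) if (is.null(v)) NA else v)
  gaw_record(total = df$total_area, left = df$left_area,
             right = df$right_area, frame_rate = meta$frame_rate,
             damaged_mask = df$damaged != 0,
             condition = cond, flow_ramp = as.list(meta$flow_ramp),
             onset_frame = meta$onset_frame,
             recording_id = meta$recording_id)
}

#' Trim phonation onset and offset
#'
#' Discards the first and last 10 ms of the phonation segment (30 frames
#' per end at 3000 fps) to exclude very early onset and potential early
#' offset from analysis. The trim length is `round(0.010 * frame_rate)`
#' frames per end; `onset_frame` is advanced accordingly so that times
#' relative to the stimulation epoch stay correct.
#'
#' @param record a [gaw_record()].
#' @param trim_s seconds removed per end (default 0.010).
#' @return the trimmed [gaw_record()].
#' @export
trim_onset_offset <- function(record, trim_s = 0.010) {
  stopifnot(inherits(record, "gaw_record"))
  k <- as.integer(round_half_up(trim_s * record$frame_rate))
  n <- length(record$total)
  if (n <= 2L * k) {
    stop("record too short to trim: ", n, " frames, need more than ", 2L * k)
  }
  keep <- (k + 1L):(n - k)
  record$total <- record$total[keep]
  record$left <- record$left[keep]
  record$right <- record$right[keep]
  record$damaged_mask <- record$damaged_mask[keep]
  record$onset_frame <- record$onset_frame + k
  record
}

#' Minimum-duration inclusion filter
#'
#' A recording is analysed only if it contains at least 0.25 s of
#' continuous phonation following onset (750 frames at 3000 fps). The
#' trimmed segment length is taken as the continuous phonation length;
#' damaged frames do not break continuity (only the affected cycles are
#' excluded later).
#'
#' @param record a [gaw_record()] (normally after [trim_onset_offset()]).
#' @param min_s required duration in seconds (default 0.25).
#' @return `TRUE` if the record passes the filter.
#' @export
passes_inclusion <- function(record, min_s = 0.25) {
  stopifnot(inherits(record, "gaw_record"))
  length(record$total) >= round_half_up(min_s * record$frame_rate)
}
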