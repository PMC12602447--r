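#' Multichannel physiological recording
#'
#' A recording is a tibble with a `time_s` column and one numeric column per
#' channel, uniformly sampled. Sampling rate, session start time and units
#' travel as attributes so the object pipes through dplyr verbs that do not
#' drop columns. EEG recordings are in microvolts; PPG is unit-free.
#'
#' @param data numeric matrix (samples x channels) or data frame of channel
#'   columns (a `time_s` column, if present, is used to cross-check `fs`).
#' @param channel_labels character vector of unique channel names; taken from
#'   column names when `data` is a data frame.
#' @param fs sampling rate in Hz (positive).
#' @param start_time session-clock time of the first sample, seconds.
#'   Sample i covers the half-open interval
#'   `[start_time + (i-1)/fs, start_time + i/fs)`.
#' @param units signal units, `"uV"` for EEG (the +/-200 uV artifact rule
#'   depends on it) or `"au"` for PPG.
#' @return A tibble of class `fl_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(0, 125, 3), c("Pz", "P3", "P4"), fs = 125)
#' rec_duration(rec)
recording <- function(data, channel_labels = NULL, fs,
                      start_time = 0, units = c("uV", "au")) {
  units <- match.arg(units)
  stopifnot_scalar_number(fs, "fs")
  if (fs <= 0) abort("`fs` must be positive.")
  if (is.data.frame(data)) {
    data <- data[, setdiff(names(data), "time_s"), drop = FALSE]
    if (is.null(channel_labels)) channel_labels <- names(data)
    data <- as.matrix(data)
  }
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(data) %||% paste0("ch", seq_len(ncol(data)))
  }
  if (length(channel_labels) != ncol(data)) {
    abort("`channel_labels` length must match the number of data columns.")
  }
  if (anyDuplicated(channel_labels)) {
    abort(paste0("Duplicate channel labels: ",
                 paste(unique(channel_labels[duplicated(channel_labels)]),
                       collapse = ", ")))
  }
  n <- nrow(data)
  out <- tibble::as_tibble(as.data.frame(data))
  names(out) <- channel_labels
  out <- tibble::add_column(out,
    time_s = start_time + (seq_len(n) - 1) / fs, .before = 1L)
  structure(out,
    fs = fs, start_time = start_time, units = units,
    class = c("fl_recording", class(out)))
}

#' @rdname recording
#' @param rec an `fl_recording`.
#' @export
rec_fs <- function(rec) attr(rec, "fs")

#' @rdname recording
#' @export
rec_start <- function(rec) attr(rec, "start_time") %||% 0

#' @rdname recording
#' @export
rec_channels <- function(rec) setdiff(names(rec), "time_s")

#' @rdname recording
#' @export
rec_duration <- function(rec) nrow(rec) / rec_fs(rec)

#' @rdname recording
#' @export
rec_matrix <- function(rec) {
  as.matrix(rec[, rec_channels(rec), drop = FALSE])
}

# Rebuild a recording with the same metadata but new sample values.
rec_update <- function(rec, mat) {
  recording(mat, rec_channels(rec), fs = rec_fs(rec),
            start_time = rec_start(rec), units = attr(rec, "units") %||% "uV")
}

#' Crop a recording to a half-open time window
#'
#' @param rec an `fl_recording`.
#' @param t_start,t_end window bounds in session seconds, `[t_start, t_end)`.
#' @return An `fl_recording` covering the window.
#' @export
rec_crop <- function(rec, t_start, t_end) {
  keep <- in_window(rec$time_s, t_start, t_end)
  if (!any(keep)) abort("Crop window contains no samples.")
  mat <- rec_matrix(rec)[keep, , drop = FALSE]
  recording(mat, rec_channels(rec), fs = rec_fs(rec),
            start_time = min(rec$time_s[keep]),
            units = attr(rec, "units") %||% "uV")
}

PARIETAL <- c("Pz", "P3", "P4")
EEG_CHANNELS <- c("AFz", "AF3", "AF4", "AF7", "AF8", "Pz", "P3", "P4")

# EEG recordings are usable downstream only with the parietal set and AFz.
check_eeg_channels <- function(rec, need = c(PARIETAL, "AFz")) {
  missing <- setdiff(need, rec_channels(rec))
  if (length(missing)) {
    abort(paste0("EEG recording is missing required channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(rec)
}

#' @export
print.fl_recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %.6g Hz, %.6g s, units %s\n",
              length(rec_channels(x)), rec_fs(x), rec_duration(x),
              attr(x, "units") %||% "?"))
  NextMethod()
}
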