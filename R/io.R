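#' Read and write multichannel recordings
#'
#' Two formats are supported. CSV is the canonical lossless format: one
#' header row of channel labels, an optional `time_s` column, comma
#' separated, UTF-8; the sampling rate is inferred from `time_s` (time
#' jitter above 1% of the sampling period is a format error) or must be
#' supplied. EDF (European Data Format) is supported for interoperability
#' with clinical/BCI tooling; data are stored as 16-bit integers, so a
#' round-trip preserves values only to the per-channel quantization step.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; inferred from the file extension when
#'   omitted.
#' @param fs sampling rate in Hz; required for CSV files without a `time_s`
#'   column, ignored otherwise.
#' @param units assumed units for CSV (`"uV"` for EEG, `"au"` for PPG);
#'   EDF carries its own physical-dimension field.
#' @return `read_recording()` returns an [recording()] object;
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, format = NULL, fs = NULL, units = "uV") {
  format <- format %||% guess_format(path)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  switch(format,
    csv = read_recording_csv(path, fs = fs, units = units),
    edf = read_recording_edf(path),
    abort(paste0("Unknown recording format: ", format))
  )
}

#' @rdname read_recording
#' @param rec an [recording()] object.
#' @export
write_recording <- function(rec, path, format = NULL) {
  format <- format %||% guess_format(path)
  ok <- tryCatch({
    switch(format,
      csv = write_recording_csv(rec, path),
      edf = write_recording_edf(rec, path),
      abort(paste0("Unknown recording format: ", format))
    )
    TRUE
  }, error = function(e) {
    abort(paste0("Failed to write recording to '", path, "': ",
                 conditionMessage(e)))
  })
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "edf")) ext else abort(
    paste0("Cannot infer format from extension '.", ext,
           "'; pass `format = \"csv\"` or `\"edf\"`."))
}

read_recording_csv <- function(path, fs = NULL, units = "uV") {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header)) {
    abort(paste0("Duplicate channel label(s) in CSV header: ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  start_time <- 0
  if ("time_s" %in% names(df)) {
    tt <- df$time_s
    if (length(tt) < 2) abort("CSV needs at least 2 samples to infer fs.")
    period <- median(diff(tt))
    if (period <= 0 || any(abs(diff(tt) - period) > 0.01 * period)) {
      abort("Non-uniform sampling in CSV `time_s` (jitter > 1% of period).")
    }
    fs <- 1 / period
    start_time <- tt[1]
  } else if (is.null(fs)) {
    abort("CSV has no `time_s` column; supply `fs`.")
  }
  recording(df, fs = fs, start_time = start_time, units = units)
}

write_recording_csv <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec), path, progress = FALSE)
  path
}

# ---- Minimal EDF (continuous, one data-record per second) ------------------
# The pre-installed R stack has no EDF package, so a small reader/writer for
# the plain continuous EDF layout is implemented here: 256-byte fixed header,
# 256 bytes per signal, then data records of little-endian int16 samples with
# linear physical scaling.

pad_ascii <- function(x, width) {
  x <- substr(format(x, scientific = FALSE, trim = TRUE), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  fs <- rec_fs(rec)
  if (abs(fs - round(fs)) > 1e-9) {
    abort("EDF writer requires an integer sampling rate; use CSV instead.")
  }
  fs <- as.integer(round(fs))
  mat <- rec_matrix(rec)
  labels <- rec_channels(rec)
  ns <- length(labels)
  n <- nrow(mat)
  n_rec <- n %/% fs
  if (n_rec < 1L) abort("Recording shorter than one EDF data record (1 s).")
  if (n %% fs != 0L) {
    warn("Recording truncated to a whole number of 1-s EDF records.")
    mat <- mat[seq_len(n_rec * fs), , drop = FALSE]
  }
  pmax_ <- pmax(apply(abs(mat), 2L, max), .Machine$double.eps)
  dig <- round(sweep(mat, 2L, pmax_ / 32767, "/"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii("X", 80), pad_ascii("X", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (1 + ns), 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(ns, 4),
    paste(pad_ascii(labels, 16), collapse = ""),
    paste(pad_ascii(rep("", ns), 80), collapse = ""),
    paste(pad_ascii(rep(attr(rec, "units") %||% "uV", ns), 8), collapse = ""),
    paste(pad_ascii(sprintf("%.6g", -pmax_), 8), collapse = ""),
    paste(pad_ascii(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(pad_ascii(rep(-32767L, ns), 8), collapse = ""),
    paste(pad_ascii(rep(32767L, ns), 8), collapse = ""),
    paste(pad_ascii(rep("", ns), 80), collapse = ""),
    paste(pad_ascii(rep(fs, ns), 8), collapse = ""),
    paste(pad_ascii(rep("", ns), 32), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[idx, s]), con, size = 2L, endian = "little")
    }
  }
  path
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nsamp)) != 1L) {
    abort("EDF reader supports a single shared sampling rate only.")
  }
  fs <- nsamp[1] / rec_dur
  mat <- matrix(NA_real_, n_rec * nsamp[1], ns)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[s], size = 2L,
                     endian = "little")
      phys <- (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) /
        (dmax_[s] - dmin_[s]) + pmin_[s]
      mat[((r - 1L) * nsamp[s] + 1L):(r * nsamp[s]), s] <- phys
    }
  }
  units <- if (any(dims == "uV")) "uV" else "au"
  recording(mat, labels, fs = fs, units = units)
}
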