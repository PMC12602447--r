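#' Run the full fatigue-labeling pipeline on one session
#'
#' Orchestrates, for a session bundle (task EEG, eyes-closed rest, PPG,
#' straight-segment schedule): EEG preprocessing (50 Hz notch, 2-40 Hz
#' band-pass), blink detection on raw AFz, 1-s epoching with +/-200 uV
#' rejection and blink flagging, IAF estimation from rest, strict-alpha
#' parietal GFP, the MDrow series, low/high fatigue labeling by the chosen
#' approach, ocular and cardiac feature extraction on the labeled windows,
#' and baseline normalization against the first 2 min of the task (MDrow
#' excepted). Deterministic given its inputs; any stage error is propagated
#' with the stage name.
#'
#' @param bundle an `fl_session` (see [simulate_session()]) or a list with
#'   elements `eeg`, `ppg`, `rest_ec`, `schedule`, `meta`.
#' @param approach `"EEG"` (individual MDrow extremes) or `"ToT"`
#'   (first/last repetitions).
#' @param k repetitions per condition; defaults to 1 for EEG and 2 for ToT
#'   (the asymmetry is recorded in the result).
#' @param baseline_len baseline length, s.
#' @return A list of class `fl_result`: `subject`, `approach`, `k`, `iaf`,
#'   `labels`, `mdrow`, `features` (tibble: feature, condition, value,
#'   raw_value, baseline), `meta`.
#' @export
run_pipeline <- function(bundle, approach = c("EEG", "ToT"), k = NULL,
                         baseline_len = 120) {
  approach <- match.arg(approach)
  k <- k %||% if (approach == "EEG") 1L else 2L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  schedule <- bundle$schedule
  span <- task_span(schedule)

  eeg_f <- stage("eeg_preprocess", bandpass_2_40(notch_50(bundle$eeg)))
  rest_f <- stage("eeg_preprocess", bandpass_2_40(notch_50(bundle$rest_ec)))
  blinks <- stage("blink_detection", detect_blinks(bundle$eeg))
  grid <- stage("epoching", flag_blink_epochs(epoch_reject(eeg_f), blinks))
  rest_grid <- stage("epoching", epoch_reject(rest_f))
  spec <- stage("iaf", estimate_iaf(rest_f))
  task_gfp <- stage("gfp", alpha_gfp(eeg_f, grid, spec))
  rest_gfp <- stage("gfp", alpha_gfp(rest_f, rest_grid, spec))
  mdrow <- stage("mdrow", compute_mdrow(task_gfp, rest_gfp))
  labels <- stage("labeling", switch(approach,
    EEG = eeg_labels(mdrow, schedule, k = k),
    ToT = tot_labels(schedule, k = k)))

  ppg_f <- stage("ppg_preprocess", preprocess_ppg(bundle$ppg))
  beats <- stage("beat_detection", detect_beats(ppg_f))
  ibi <- stage("ibi_correction", correct_ibi(ibi_series(beats)))

  features <- stage("features", assemble_features(
    labels, blinks, ibi, mdrow, span, baseline_len))

  structure(list(
    subject = bundle$meta$subject %||% NA_character_,
    approach = approach, k = k,
    iaf = spec$iaf, iaf_no_distinct_peak = spec$no_distinct_peak,
    labels = labels, mdrow = mdrow, features = features,
    meta = bundle$meta
  ), class = "fl_result")
}

# Per-condition physiological features, baseline-normalized except MDrow.
assemble_features <- function(labels, blinks, ibi, mdrow, span, baseline_len) {
  base_win <- tibble::tibble(t_start_s = span[["start"]],
                             t_end_s = span[["start"]] + baseline_len)
  baselines <- window_features(base_win, blinks, ibi, mdrow)
  rows <- purrr::map_dfr(c("Low", "High"), function(cond) {
    w <- labels[labels$condition == cond, c("t_start_s", "t_end_s")]
    vals <- window_features(w, blinks, ibi, mdrow)
    vals$condition <- cond
    vals
  })
  rows <- dplyr::left_join(rows,
    dplyr::rename(baselines, baseline = "value")[, c("feature", "baseline")],
    by = "feature")
  rows$raw_value <- rows$value
  norm <- rows$feature != "MDrow"
  rows$value[norm] <- rows$raw_value[norm] - rows$baseline[norm]
  rows$baseline[!norm] <- NA_real_
  rows[, c("feature", "condition", "value", "raw_value", "baseline")]
}

# Feature values pooled over a set of (possibly multiple) windows.
window_features <- function(windows, blinks, ibi, mdrow) {
  minutes <- sum(windows$t_end_s - windows$t_start_s) / 60
  in_any <- function(t) {
    Reduce(`|`, purrr::pmap(windows, function(t_start_s, t_end_s) {
      in_window(t, t_start_s, t_end_s)
    }))
  }
  bsel <- in_any(blinks$peak_time_s)
  nb <- sum(bsel)
  isel <- in_any(ibi$t_s)
  hrv <- hrv_spectral(ibi, windows = windows)
  win <- attr(mdrow, "window") %||% 60
  msel <- in_any(mdrow$window_start_s + win / 2) & !is.na(mdrow$mdrow)
  tibble::tibble(
    feature = c("EBR", "EBD", "EBA", "HR", "LF", "HF", "HRV", "MDrow"),
    value = c(
      nb / minutes,
      if (nb) mean(blinks$duration_ms[bsel]) else NA_real_,
      if (nb) mean(blinks$amplitude_uv[bsel]) else NA_real_,
      if (sum(isel) >= 3L) {
        v <- if ("ibi_smooth_ms" %in% names(ibi)) ibi$ibi_smooth_ms else ibi$ibi_ms
        60000 / mean(v[isel])
      } else NA_real_,
      mean(hrv$lf, na.rm = TRUE),
      mean(hrv$hf, na.rm = TRUE),
      mean(hrv$hrv, na.rm = TRUE),
      if (any(msel)) mean(mdrow$mdrow[msel]) else NA_real_
    )
  )
}

#' Tidy feature panel across subjects
#'
#' Row-binds the per-condition features of several pipeline results into the
#' tidy panel [compare_conditions()] expects.
#'
#' @param results list of `fl_result` objects.
#' @return A tibble `subject`, `approach`, `feature`, `condition`, `value`.
#' @export
result_panel <- function(results) {
  purrr::map_dfr(results, function(r) {
    tibble::tibble(subject = r$subject, approach = r$approach,
                   feature = r$features$feature,
                   condition = r$features$condition,
                   value = r$features$value)
  })
}

#' Write / read a pipeline result record (JSON)
#'
#' Serializes the subject id, approach, IAF, labels, MDrow series and the
#' feature panel to JSON, losslessly (full double precision).
#'
#' @param result an `fl_result`.
#' @param path JSON file path.
#' @return `read_result()` returns the record as a list of tibbles.
#' @export
write_result <- function(result, path) {
  rec <- list(
    subject = result$subject,
    approach = result$approach,
    k = result$k,
    iaf = result$iaf,
    labels = as.data.frame(result$labels),
    mdrow = as.data.frame(result$mdrow),
    features = as.data.frame(result$features),
    meta = result$meta[setdiff(names(result$meta), "seed")]
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  rec <- jsonlite::fromJSON(path)
  rec$labels <- tibble::as_tibble(rec$labels)
  rec$mdrow <- tibble::as_tibble(rec$mdrow)
  rec$features <- tibble::as_tibble(rec$features)
  rec
}
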