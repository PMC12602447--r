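#' Time-on-Task fatigue labels
#'
#' The conventional labeling: low fatigue is the first `k` straight-road
#' repetitions, high fatigue the last `k`, identical for every subject.
#'
#' @param schedule an [lap_schedule()].
#' @param k repetitions per condition.
#' @return A tibble of class `fl_labels` with columns `condition`
#'   (`"Low"`/`"High"`), `segment`, `t_start_s`, `t_end_s`; attribute
#'   `approach = "ToT"`.
#' @export
tot_labels <- function(schedule, k = 2) {
  n <- nrow(schedule)
  if (n < 2 * k) {
    abort(sprintf("Need at least %d segments for k = %d per condition.", 2 * k, k))
  }
  low <- schedule[seq_len(k), ]
  high <- schedule[(n - k + 1):n, ]
  make_labels(low, high, "ToT")
}

make_labels <- function(low, high, approach) {
  out <- dplyr::bind_rows(
    dplyr::mutate(low[, c("segment", "t_start_s", "t_end_s")], condition = "Low"),
    dplyr::mutate(high[, c("segment", "t_start_s", "t_end_s")], condition = "High")
  )
  out <- out[, c("condition", "segment", "t_start_s", "t_end_s")]
  structure(out, approach = approach, class = c("fl_labels", class(out)))
}

#' EEG-driven fatigue labels from the MDrow series
#'
#' Each straight-road repetition is scored by the mean of the MDrow windows
#' whose centre falls inside it; the top-`k` segments by score are labeled
#' high fatigue and the bottom-`k` low fatigue, individually per subject.
#' Ties are broken toward the earlier segment for Low and the later segment
#' for High. Segments with no usable MDrow window are excluded from the
#' ranking with a warning.
#'
#' @param mdrow `fl_mdrow` from [compute_mdrow()].
#' @param schedule an [lap_schedule()].
#' @param k repetitions per condition (default 1: the single extreme
#'   one-minute segment in each direction).
#' @return An `fl_labels` with `approach = "EEG"` and attribute
#'   `segment_scores` (tibble of per-segment MDrow scores).
#' @export
eeg_labels <- function(mdrow, schedule, k = 1) {
  win <- attr(mdrow, "window")
  centre <- mdrow$window_start_s + win / 2
  scores <- purrr::pmap_dfr(
    schedule[, c("segment", "t_start_s", "t_end_s")],
    function(segment, t_start_s, t_end_s) {
      v <- mdrow$mdrow[in_window(centre, t_start_s, t_end_s)]
      v <- v[!is.na(v)]
      tibble::tibble(segment = segment,
                     score = if (length(v)) mean(v) else NA_real_,
                     n_windows = length(v))
    })
  if (any(is.na(scores$score))) {
    warn(paste0("Segment(s) without usable MDrow windows excluded: ",
                paste(scores$segment[is.na(scores$score)], collapse = ", ")))
  }
  usable <- scores[!is.na(scores$score), ]
  if (nrow(usable) < 2 * k) {
    abort("Too few usable segments to label both conditions.")
  }
  high_seg <- usable$segment[order(-usable$score, -usable$segment)][seq_len(k)]
  rest <- usable[!usable$segment %in% high_seg, ]
  low_seg <- rest$segment[order(rest$score, rest$segment)][seq_len(k)]
  low <- schedule[match(sort(low_seg), schedule$segment), ]
  high <- schedule[match(sort(high_seg), schedule$segment), ]
  out <- make_labels(low, high, "EEG")
  attr(out, "segment_scores") <- scores
  out
}

#' Baseline normalization of a feature series
#'
#' The first 2 min of the task serve as baseline: the baseline value is the
#' mean of the feature over `[task_start, task_start + baseline_len)` and is
#' subtracted from every value. The MDrow index is directly comparable
#' between participants and must not be baseline-normalized; passing an
#' `fl_mdrow` (or `feature = "MDrow"`) is an error.
#'
#' @param df tibble with a time column and a value column.
#' @param value,time column names (strings) of the feature value and its
#'   window/sample start time.
#' @param task_start task start, s.
#' @param baseline_len baseline length, s.
#' @param feature optional feature name (for the MDrow guard and messages).
#' @return `df` with `value` baseline-subtracted and attribute `baseline`.
#' @export
baseline_normalize <- function(df, value = "value", time = "t_start_s",
                               task_start = 0, baseline_len = 120,
                               feature = NULL) {
  if (inherits(df, "fl_mdrow") || identical(toupper(feature %||% ""), "MDROW")) {
    abort(paste0("MDrow is never baseline-normalized: the index is a ",
                 "rest-referenced ratio, directly comparable across subjects."))
  }
  v <- df[[value]]
  tt <- df[[time]]
  sel <- in_window(tt, task_start, task_start + baseline_len) & !is.na(v)
  if (!any(sel)) {
    abort("Feature is not defined on the baseline period.")
  }
  base <- mean(v[sel])
  df[[value]] <- v - base
  attr(df, "baseline") <- base
  df
}
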