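#' Straight-segment lap schedule
#'
#' The ~1-min traversals of the longest straight road are the unit on which
#' fatigue conditions are labeled. A schedule is a tibble of non-overlapping,
#' strictly increasing segments inside `[task_start, task_end)`.
#'
#' @param segments data frame with columns `segment` (integer >= 1),
#'   `t_start_s`, `t_end_s` (session seconds).
#' @param task_start,task_end task bounds in session seconds; defaults span
#'   the segments.
#' @param target_len expected segment duration in seconds.
#' @param tol tolerated deviation of a segment duration from `target_len`.
#' @return A tibble of class `fl_schedule` with attributes `task_start`,
#'   `task_end`.
#' @export
lap_schedule <- function(segments, task_start = NULL, task_end = NULL,
                         target_len = 60, tol = 15) {
  seg <- tibble::as_tibble(segments)
  need <- c("segment", "t_start_s", "t_end_s")
  if (!all(need %in% names(seg))) {
    abort(paste0("`segments` must have columns: ", paste(need, collapse = ", ")))
  }
  seg <- dplyr::arrange(seg[, need], .data$t_start_s)
  dur <- seg$t_end_s - seg$t_start_s
  bad <- which(dur <= 0)
  if (length(bad)) {
    abort(paste0("Non-positive segment duration for segment(s): ",
                 paste(seg$segment[bad], collapse = ", ")))
  }
  off <- abs(dur - target_len) > tol
  if (any(off)) {
    abort(paste0("Segment duration outside ", target_len, " +/- ", tol,
                 " s for segment(s): ", paste(seg$segment[off], collapse = ", ")))
  }
  if (nrow(seg) > 1) {
    ovl <- which(seg$t_start_s[-1] < seg$t_end_s[-nrow(seg)])
    if (length(ovl)) {
      abort(paste0("Overlapping segments: ",
                   paste(sprintf("%d,%d", seg$segment[ovl], seg$segment[ovl + 1]),
                         collapse = "; ")))
    }
  }
  task_start <- task_start %||% min(seg$t_start_s)
  task_end <- task_end %||% max(seg$t_end_s)
  if (min(seg$t_start_s) < task_start || max(seg$t_end_s) > task_end) {
    abort("Segments must lie within [task_start, task_end].")
  }
  structure(seg, task_start = task_start, task_end = task_end,
            class = c("fl_schedule", class(seg)))
}

#' @rdname lap_schedule
#' @param x an `fl_schedule`.
#' @export
task_span <- function(x) {
  c(start = attr(x, "task_start"), end = attr(x, "task_end"))
}

#' Read / write straight-segment schedules (TSV)
#'
#' The file format is tab-separated with one header row and columns
#' `segment` (or `index`), `t_start_s`, `t_end_s`. Rows out of order are
#' sorted; overlaps or non-positive durations are validation errors naming
#' the offending segments.
#'
#' @param path file path.
#' @inheritParams lap_schedule
#' @return `read_events()` returns an `fl_schedule`.
#' @export
read_events <- function(path, task_start = NULL, task_end = NULL,
                        target_len = 60, tol = 15) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("index" %in% names(df) && !"segment" %in% names(df)) {
    names(df)[names(df) == "index"] <- "segment"
  }
  lap_schedule(df, task_start = task_start, task_end = task_end,
               target_len = target_len, tol = tol)
}

#' @rdname read_events
#' @param schedule an `fl_schedule`.
#' @export
write_events <- function(schedule, path) {
  readr::write_tsv(schedule[, c("segment", "t_start_s", "t_end_s")], path,
                   progress = FALSE)
  invisible(path)
}
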