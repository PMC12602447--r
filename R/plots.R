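#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rect
#'   geom_col geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot an MDrow series
#'
#' @param object an `fl_mdrow` from [compute_mdrow()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fl_mdrow <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$window_start_s, y = .data$mdrow)) +
    geom_line(na.rm = TRUE) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    labs(x = "Window start (s)", y = "MDrow",
         title = "Mental drowsiness index",
         subtitle = "Task alpha GFP / max eyes-closed rest alpha GFP") +
    theme_minimal()
}

#' Plot detected blink events over the task
#'
#' @param object an `fl_blinks` from [detect_blinks()].
#' @param ... unused.
#' @return A ggplot of blink amplitude against time.
#' @export
autoplot.fl_blinks <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$peak_time_s, y = .data$amplitude_uv)) +
    geom_point(alpha = 0.6) +
    labs(x = "Time (s)", y = "Blink amplitude (uV)",
         title = "Detected eyeblinks") +
    theme_minimal()
}

#' Plot paired effect sizes of the low-vs-high comparison
#'
#' @param object an `fl_comparison` from [compare_conditions()].
#' @param ... unused.
#' @return A ggplot of Cohen's d per feature.
#' @export
autoplot.fl_comparison <- function(object, ...) {
  tab <- object$table[is.finite(object$table$cohens_d), ]
  ggplot(tab, aes(x = .data$feature, y = .data$cohens_d)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    labs(x = NULL, y = "Cohen's d (paired, High - Low)",
         title = "Fatigue contrast per feature") +
    theme_minimal()
}

#' Plot fatigue labels over the MDrow series
#'
#' Shades the straight-road repetitions labeled low (green) and high (red)
#' fatigue on top of the MDrow trace.
#'
#' @param mdrow an `fl_mdrow`.
#' @param labels an `fl_labels`.
#' @return A ggplot.
#' @export
plot_labels <- function(mdrow, labels) {
  ymax <- max(mdrow$mdrow, na.rm = TRUE)
  autoplot(mdrow) +
    geom_rect(data = tibble::as_tibble(labels),
              aes(xmin = .data$t_start_s, xmax = .data$t_end_s,
                  ymin = 0, ymax = ymax, fill = .data$condition),
              alpha = 0.3, inherit.aes = FALSE) +
    ggplot2::scale_fill_manual(values = c(Low = "seagreen", High = "firebrick")) +
    labs(fill = "Fatigue",
         subtitle = paste0(attr(labels, "approach"), "-driven labeling"))
}
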