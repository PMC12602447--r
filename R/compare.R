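#' Paired low-vs-high comparison across subjects
#'
#' For every feature with at least 3 paired observations, the High - Low
#' difference across subjects is tested: a Shapiro-Wilk check on the paired
#' differences selects a paired t-test (normal) or a Wilcoxon signed-rank
#' test, the paired effect size is Cohen's d = mean(diff) / SD(diff), and
#' p-values are adjusted for the feature family with Holm-Bonferroni.
#'
#' @param panel tidy tibble with columns `subject`, `feature`, `condition`
#'   (`"Low"`/`"High"`), `value` — e.g. row-bound from
#'   [run_pipeline()] results via [result_panel()].
#' @param alpha normality-gate level for the Shapiro-Wilk test.
#' @return An object of class `fl_comparison`; its `table` element (also
#'   returned by [generics::tidy()]) holds one row per feature: `n`,
#'   `mean_diff`, `test`, `statistic`, `p_raw`, `p_adj`, `cohens_d`, `note`.
#' @export
compare_conditions <- function(panel, alpha = 0.05) {
  need <- c("subject", "feature", "condition", "value")
  if (!all(need %in% names(panel))) {
    abort(paste0("`panel` must have columns: ", paste(need, collapse = ", ")))
  }
  dup <- duplicated(panel[, c("subject", "feature", "condition")])
  if (any(dup)) {
    abort(paste0("Duplicate subject/feature/condition rows in `panel` ",
                 "(subjects must be unique): e.g. subject '",
                 panel$subject[dup][1], "', feature '",
                 panel$feature[dup][1], "'."))
  }
  wide <- tidyr::pivot_wider(panel[, need], names_from = "condition",
                             values_from = "value")
  rows <- dplyr::group_split(dplyr::group_by(wide, .data$feature))
  res <- purrr::map_dfr(rows, function(g) {
    feature <- g$feature[1]
    ok <- stats::complete.cases(g$Low, g$High)
    d <- g$High[ok] - g$Low[ok]
    n <- length(d)
    if (n < 3L) {
      return(tibble::tibble(feature = feature, n = n, mean_diff = NA_real_,
                            test = NA_character_, statistic = NA_real_,
                            p_raw = NA_real_, cohens_d = NA_real_,
                            note = "insufficient_n"))
    }
    sdd <- sd(d)
    if (sdd == 0) {
      if (all(d == 0)) {
        return(tibble::tibble(feature = feature, n = n, mean_diff = 0,
                              test = "degenerate", statistic = 0, p_raw = 1,
                              cohens_d = 0, note = "all_diffs_zero"))
      }
      return(tibble::tibble(feature = feature, n = n, mean_diff = mean(d),
                            test = "degenerate", statistic = NA_real_,
                            p_raw = NA_real_,
                            cohens_d = sign(mean(d)) * Inf,
                            note = "zero_variance_nonzero_diff"))
    }
    normal <- tryCatch(shapiro.test(d)$p.value >= alpha,
                       error = function(e) TRUE)
    if (normal) {
      ht <- t.test(d)
      test <- "paired t"
    } else {
      ht <- suppressWarnings(wilcox.test(d, exact = FALSE))
      test <- "wilcoxon signed-rank"
    }
    tibble::tibble(feature = feature, n = n, mean_diff = mean(d), test = test,
                   statistic = unname(ht$statistic), p_raw = ht$p.value,
                   cohens_d = mean(d) / sdd, note = NA_character_)
  })
  res$p_adj <- NA_real_
  testable <- !is.na(res$p_raw) & res$test != "degenerate"
  res$p_adj[testable] <- p.adjust(res$p_raw[testable], method = "holm")
  res$p_adj[!testable & !is.na(res$p_raw)] <- res$p_raw[!testable & !is.na(res$p_raw)]
  structure(list(table = res, alpha = alpha), class = "fl_comparison")
}

#' @export
print.fl_comparison <- function(x, ...) {
  cat("<low-vs-high paired comparison>\n")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_conditions
#' @param x an `fl_comparison`.
#' @param ... unused.
#' @export
tidy.fl_comparison <- function(x, ...) x$table

#' @rdname compare_conditions
#' @export
glance.fl_comparison <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$table),
    n_tested = sum(!is.na(x$table$p_adj)),
    n_significant = sum(x$table$p_adj < x$alpha, na.rm = TRUE),
    alpha = x$alpha
  )
}
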