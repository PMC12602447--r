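make_mdrow <- function(values, starts = NULL, window = 60, step = 15) {
  starts <- starts %||% seq(0, by = step, length.out = length(values))
  structure(
    tibble::tibble(window_start_s = starts,
                   n_epochs = 60L, mdrow = values),
    rest_denominator = 1, window = window, step = step,
    class = c("fl_mdrow", class(tibble::tibble())))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

eight_segments <- function() {
  lap_schedule(data.frame(segment = 1:8, t_start_s = (0:7) * 330 + 60,
                          t_end_s = (0:7) * 330 + 120),
               task_start = 0, task_end = 2700)
}

test_that("time-on-task labels take the first and last repetitions", {
  sch <- eight_segments()
  lab <- tot_labels(sch, k = 2)
  expect_equal(lab$segment[lab$condition == "Low"], c(1, 2))
  expect_equal(lab$segment[lab$condition == "High"], c(7, 8))
  expect_equal(attr(lab, "approach"), "ToT")

  sch4 <- lap_schedule(data.frame(segment = 1:4, t_start_s = (0:3) * 120,
                                  t_end_s = (0:3) * 120 + 60))
  lab4 <- tot_labels(sch4, k = 2)
  expect_equal(lab4$segment[lab4$condition == "Low"], c(1, 2))
  expect_equal(lab4$segment[lab4$condition == "High"], c(3, 4))

  sch3 <- lap_schedule(data.frame(segment = 1:3, t_start_s = (0:2) * 120,
                                  t_end_s = (0:2) * 120 + 60))
  expect_error(tot_labels(sch3, k = 2), "at least 4")
})

test_that("EEG labels pick the MDrow extremes with deterministic ties", {
  sch <- eight_segments()
  md_inc <- make_mdrow(seq(0.1, 0.9, length.out = 177))
  lab <- eeg_labels(md_inc, sch, k = 1)
  expect_equal(lab$segment[lab$condition == "Low"], 1)
  expect_equal(lab$segment[lab$condition == "High"], 8)

  md_const <- make_mdrow(rep(0.5, 177))
  lab2 <- eeg_labels(md_const, sch, k = 1)
  expect_equal(lab2$segment[lab2$condition == "Low"], 1)
  expect_equal(lab2$segment[lab2$condition == "High"], 8)

  # a bump at segment 4 wins High regardless of task position
  vals <- rep(0.2, 177)
  centre <- make_mdrow(vals)$window_start_s + 30
  vals[centre >= sch$t_start_s[4] & centre < sch$t_end_s[4]] <- 0.9
  lab3 <- eeg_labels(make_mdrow(vals), sch, k = 1)
  expect_equal(lab3$segment[lab3$condition == "High"], 4)
})

test_that("segments without usable MDrow windows are excluded with warning", {
  sch <- eight_segments()
  vals <- seq(0.1, 0.9, length.out = 177)
  centre <- seq(0, by = 15, length.out = 177) + 30
  vals[centre >= sch$t_start_s[3] & centre < sch$t_end_s[3]] <- NA
  expect_warning(lab <- eeg_labels(make_mdrow(vals), sch), "excluded: 3")
  expect_false(3 %in% lab$segment)
})

test_that("baseline normalization subtracts the first-2-min mean", {
  df <- tibble::tibble(t_start_s = seq(0, 540, by = 60),
                       value = rep(5, 10))
  out <- baseline_normalize(df)
  expect_true(all(out$value == 0))
  expect_equal(attr(out, "baseline"), 5)

  df2 <- tibble::tibble(t_start_s = seq(0, 540, by = 60),
                        value = c(rep(60, 5), rep(63, 5)))
  out2 <- baseline_normalize(df2)
  expect_equal(unique(out2$value), c(0, 3))

  md <- make_mdrow(rep(0.5, 20))
  expect_error(baseline_normalize(md, value = "mdrow",
                                  time = "window_start_s"),
               "never baseline-normalized")
  expect_error(baseline_normalize(df, feature = "MDrow"),
               "never baseline-normalized")
})

test_that("paired comparison handles degenerate inputs safely", {
  panel <- tidyr::expand_grid(subject = sprintf("S%02d", 1:6),
                              feature = "HR",
                              condition = c("Low", "High"))
  panel$value <- 70
  cmp <- compare_conditions(panel)
  tab <- tidy(cmp)
  expect_equal(tab$cohens_d, 0)
  expect_equal(tab$p_raw, 1)

  # constant non-zero differences: infinite-effect sentinel with a note
  panel2 <- panel
  panel2$value[panel2$condition == "High"] <- 71
  tab2 <- tidy(compare_conditions(panel2))
  expect_true(is.infinite(tab2$cohens_d))
  expect_equal(tab2$note, "zero_variance_nonzero_diff")

  # fewer than 3 pairs is reported, not tested
  panel3 <- panel[panel$subject %in% c("S01", "S02"), ]
  tab3 <- tidy(compare_conditions(panel3))
  expect_equal(tab3$note, "insufficient_n")
})

test_that("Holm adjustment is monotone and never below the raw p", {
  set.seed(51)
  panel <- tidyr::expand_grid(subject = sprintf("S%02d", 1:10),
                              feature = c("EBR", "EBD", "HR", "HRV"),
                              condition = c("Low", "High"))
  panel$value <- rnorm(nrow(panel))
  panel$value[panel$condition == "High" & panel$feature == "HR"] <-
    panel$value[panel$condition == "High" & panel$feature == "HR"] + 2
  tab <- tidy(compare_conditions(panel))
  expect_true(all(tab$p_adj >= tab$p_raw))
  ord <- order(tab$p_raw)
  expect_true(all(diff(tab$p_adj[ord]) >= -1e-12))
  expect_equal(tab$p_adj, p.adjust(tab$p_raw, method = "holm"))
})

test_that("family-wise error under the null stays controlled (property)", {
  set.seed(52)
  m <- 7
  n <- 12
  hits <- 0L
  reps <- 1000L
  for (r in seq_len(reps)) {
    p <- vapply(seq_len(m), function(j) stats::t.test(rnorm(n))$p.value,
                numeric(1))
    if (any(p.adjust(p, "holm") < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits / reps, 0.06)
})

test_that("glance summarizes the comparison", {
  set.seed(53)
  panel <- tidyr::expand_grid(subject = sprintf("S%02d", 1:8),
                              feature = c("HR", "EBR"),
                              condition = c("Low", "High"))
  panel$value <- rnorm(nrow(panel))
  g <- glance(compare_conditions(panel))
  expect_equal(g$n_features, 2)
  expect_equal(g$alpha, 0.05)
})
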