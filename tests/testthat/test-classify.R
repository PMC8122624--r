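test_that("metric identities hold exactly", {
  m <- compute_metrics(9, 1, 7, 3)
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))
  expect_equal(round(m$f1, 4), 0.8182)

  # harmonic mean of equal precision and sensitivity is the common value
  m2 <- compute_metrics(8, 2, 90, 2)
  expect_equal(m2$precision, m2$sensitivity)
  expect_equal(m2$f1, m2$precision)

  # degenerate specificity
  m3 <- compute_metrics(5, 0, 0, 2)
  expect_true(is.na(m3$specificity))
  expect_true(is.na(m3$balanced_accuracy))

  # identities on arbitrary counts
  set.seed(1)
  for (i in 1:50) {
    cnt <- rpois(4, 20)
    if (sum(cnt) == 0) next
    m <- compute_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    if (!is.na(m$balanced_accuracy)) {
      expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    }
    if (!is.na(m$sensitivity) && m$precision + m$sensitivity > 0) {
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity))
    }
    expect_true(all(stats::na.omit(unlist(
      m[, c("precision", "sensitivity", "specificity", "accuracy",
            "balanced_accuracy", "f1")])) >= 0))
  }
  expect_error(compute_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("the all-positive baseline reproduces the trial-count arithmetic", {
  expect_equal(all_positive_baseline(518, 202), 1036 / 1238)
  expect_equal(round(100 * all_positive_baseline(518, 202)), 84)
  expect_equal(all_positive_baseline(270, 254), 540 / 794)
  expect_equal(all_positive_baseline(5, 0), 1)
  expect_error(all_positive_baseline(0, 10), "at least one")
})

test_that("wrapper selection finds a separating feature first and is deterministic", {
  ft <- fake_features(n = 80, seed = 2, separator = "wavelet_entropy.CZ")
  reg <- attr(ft, "registry")
  x <- as.matrix(ft[, reg$column])
  y <- as.integer(ft$outcome == "incorrect")
  cfg <- model_config(seed = 5, k_max = 4, screen_top = 30)
  ws <- wrapper_select(x, y, cfg)
  expect_equal(reg$column[ws$selected[1]], "wavelet_entropy.CZ")
  expect_equal(length(ws$selected), which.max(ws$curve$f1))
  expect_true(all(cummax(ws$curve$f1) == sort(cummax(ws$curve$f1))))
  ws2 <- wrapper_select(x, y, cfg)
  expect_identical(ws, ws2)
  expect_error(wrapper_select(x, y, cfg, k_max = 0), ">= 1")
})

test_that("single-tree predictions equal the exhaustive stump oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 60
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(x))
    cfg <- model_config(n_trees = 1, max_depth = 1, seed = rep)
    p <- vigimark:::xgb_prob(
      vigimark:::xgb_fit(matrix(x, ncol = 1), y, cfg), matrix(x, ncol = 1))
    expect_equal(p, stump_oracle(x, y), tolerance = 1e-6)
  }
})

test_that("nested evaluation is deterministic, leak-free and duplicate-invariant", {
  ft <- fake_features(n = 60, seed = 3, separator = "pac.FZ")
  cfg <- model_config(seed = 9, k_max = 3, screen_top = 10)
  e1 <- nested_cv_evaluate(ft, cfg)
  e2 <- nested_cv_evaluate(ft, cfg)
  td <- withr::local_tempdir()
  write_eval_report(e1, file.path(td, "a.json"))
  write_eval_report(e2, file.path(td, "b.json"))
  expect_identical(readLines(file.path(td, "a.json")),
                   readLines(file.path(td, "b.json")))

  # fold audit: every outer fold's test rows are disjoint from its training
  # rows and the folds partition the data
  all_test <- sort(unlist(purrr::map(e1$fold_audit, "test")))
  expect_equal(all_test, seq_len(nrow(ft)))
  for (a in e1$fold_audit) {
    expect_length(intersect(a$train, a$test), 0)
  }

  # duplicating every candidate column leaves the metrics unchanged
  # (deterministic tie-break to the lower column index)
  reg <- attr(ft, "registry")
  cols <- reg$column[1:20]
  cfg2 <- model_config(seed = 9, k_max = 3, screen_top = Inf)
  base <- nested_cv_evaluate(ft, cfg2, columns = cols)
  ft_dup <- ft
  for (cl in cols) ft_dup[[paste0(cl, ".copy")]] <- ft[[cl]]
  reg2 <- dplyr::bind_rows(reg, dplyr::mutate(
    reg[reg$column %in% cols, ], column = paste0(.data$column, ".copy")))
  attr(ft_dup, "registry") <- reg2
  dup <- nested_cv_evaluate(ft_dup, cfg2,
                            columns = c(cols, paste0(cols, ".copy")))
  expect_equal(as.data.frame(base$pooled), as.data.frame(dup$pooled))
})

test_that("imputation inside the folds uses training statistics only", {
  ft <- fake_features(n = 60, seed = 4, separator = "gc.delta")
  ft$hjorth_mobility.LO[c(3, 17, 41)] <- NA
  cfg <- model_config(seed = 2, k_max = 2, screen_top = 8)
  expect_s3_class(nested_cv_evaluate(ft, cfg), "vigi_eval")
})

test_that("evaluation guards its preconditions", {
  ft <- fake_features(n = 20, seed = 5)
  expect_error(nested_cv_evaluate(ft, model_config()), "more trials")
  ft2 <- fake_features(n = 60, seed = 6, p_incorrect = 0.04)
  expect_error(nested_cv_evaluate(ft2, model_config()))
  ft3 <- fake_features(n = 60, seed = 7)
  expect_error(nested_cv_evaluate(ft3, model_config(), condition = "nope"),
               "unknown feature-set condition")
})

test_that("feature-set conditions partition the registry", {
  reg <- feature_registry()
  sp <- vigimark:::resolve_condition_columns(reg, "spectral")
  ho <- vigimark:::resolve_condition_columns(reg, "HOST")
  co <- vigimark:::resolve_condition_columns(reg, "combined")
  expect_length(sp, 80)
  expect_length(ho, 708 - 80)
  expect_setequal(c(sp, ho), co)
})

test_that("a channel with constant features falls back to the baseline", {
  ft <- fake_features(n = 70, seed = 8, p_incorrect = 0.6,
                      constant_channel = "RT")
  reg <- attr(ft, "registry")
  cols <- reg$column[reg$single_channel & !is.na(reg$channel) &
                       reg$channel == "RT"]
  ev <- nested_cv_evaluate(ft, model_config(seed = 3, k_max = 2,
                                            screen_top = 5),
                           columns = cols)
  expect_lt(abs(ev$pooled$f1 - ev$baseline_f1), 0.05)
})

test_that("tidiers and plots expose the report", {
  ft <- fake_features(n = 60, seed = 10, separator = "pli.LO-RO.delta")
  ev <- nested_cv_evaluate(ft, model_config(seed = 4, k_max = 2,
                                            screen_top = 6))
  td <- tidy(ev)
  expect_equal(nrow(td), 5)
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$f1, ev$pooled$f1)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_feature_separation(ft), "ggplot")
})
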