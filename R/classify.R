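# Gradient-boosted classification with wrapper forward feature selection
# under nested (5 x 5) stratified cross-validation.

#' Classifier configuration
#'
#' The ensemble is fixed at 30 trees of maximum depth 4 (learning rate 0.3,
#' no subsampling); the inner loop tunes only the selected feature subset
#' and the decision threshold.
#'
#' @param n_trees Boosting rounds (default 30).
#' @param max_depth Maximum tree depth (default 4).
#' @param learning_rate Shrinkage (default 0.3).
#' @param k_max Maximum number of wrapper-selected features (default 15;
#'   training performance typically saturates at 5-10).
#' @param improve_tol,patience Early stop for the greedy search: stop after
#'   `patience` consecutive steps that fail to improve the best
#'   cross-validated F1 by at least `improve_tol`.
#' @param screen_top Candidate pool size: only the `screen_top` columns with
#'   the highest training-fold point-biserial R^2 enter the greedy search
#'   (ties to the lower column index). `Inf` disables screening.
#' @param inner_folds,outer_folds Stratified fold counts (default 5 and 5).
#' @param threshold_grid Candidate decision thresholds tuned on inner
#'   out-of-fold probabilities; 0 means predict everything positive.
#' @param seed Seed controlling folds and the booster.
#' @return A `model_config` list.
#' @export
model_config <- function(n_trees = 30, max_depth = 4, learning_rate = 0.3,
                         k_max = 15, improve_tol = 1e-3, patience = 2,
                         screen_top = 40, inner_folds = 5, outer_folds = 5,
                         threshold_grid = c(0, seq(0.05, 0.95, by = 0.05)),
                         seed = 1) {
  if (n_trees < 1 || max_depth < 1) {
    abort("n_trees and max_depth must be >= 1")
  }
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 learning_rate = learning_rate, k_max = k_max,
                 improve_tol = improve_tol, patience = patience,
                 screen_top = screen_top, inner_folds = inner_folds,
                 outer_folds = outer_folds, threshold_grid = threshold_grid,
                 seed = seed),
            class = "model_config")
}

xgb_params <- function(cfg) {
  list(objective = "binary:logistic", max_depth = cfg$max_depth,
       eta = cfg$learning_rate, base_score = 0.5, nthread = 1,
       verbosity = 0, seed = cfg$seed)
}

xgb_fit <- function(x, y, cfg) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = xgb_params(cfg), data = dm,
                     nrounds = cfg$n_trees)
}

xgb_prob <- function(fit, x) {
  as.numeric(predict(fit, x, validate_features = FALSE))
}

# stratified k-fold assignment; deterministic under seed
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k) {
    abort(sprintf(
      "minority class has %d examples, fewer than the %d folds; collect more trials",
      min(table(y)), k))
  }
  with_local_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

f1_from_pred <- function(y, pred) {
  tp <- sum(pred & y == 1)
  prec <- if (sum(pred) > 0) tp / sum(pred) else 0
  sens <- if (sum(y == 1) > 0) tp / sum(y == 1) else NA_real_
  if (is.na(sens) || prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
}

# out-of-fold probabilities for a fixed feature subset
oof_probs <- function(x, y, cols, folds, cfg) {
  p <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- xgb_fit(x[tr, cols, drop = FALSE], y[tr], cfg)
    p[!tr] <- xgb_prob(fit, x[!tr, cols, drop = FALSE])
  }
  p
}

# point-biserial R^2 per column against a 0/1 label
column_r2 <- function(x, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    xc <- v - mean(v)
    sx <- sqrt(sum(xc^2))
    if (sx == 0 || sy == 0) 0 else (sum(xc * yc) / (sx * sy))^2
  }, numeric(1))
}

#' Wrapper forward feature selection
#'
#' Greedy search scored by stratified inner cross-validated F1 of the
#' boosted ensemble: starting from the single best feature, each step adds
#' the candidate whose addition maximizes the out-of-fold F1 (at the 0.5
#' probability threshold), stopping at `k_max` features or after `patience`
#' consecutive steps without an `improve_tol` improvement. The candidate
#' pool is pre-screened to the `screen_top` highest point-biserial R^2
#' columns. Ties break to the lower column index, making the search
#' deterministic under a fixed seed. The returned subset is the prefix of
#' the search path achieving the best cross-validated F1, and the decision
#' threshold is then tuned on out-of-fold probabilities of that subset
#' (grid includes 0 = all-positive).
#'
#' @param x Numeric feature matrix (no missing values).
#' @param y Binary labels (1 = incorrect, the positive class).
#' @param cfg A [model_config()].
#' @param k_max Maximum subset size (defaults to `cfg$k_max`).
#' @return List: `selected` (column indices, in selection order), `curve`
#'   (tibble `step`, `column`, `f1`), `threshold`, `oof_f1`.
#' @export
wrapper_select <- function(x, y, cfg = model_config(), k_max = cfg$k_max) {
  if (k_max < 1) abort("k_max must be >= 1")
  if (ncol(x) < 2) abort("need at least 2 candidate features")
  folds <- stratified_folds(y, cfg$inner_folds, cfg$seed)
  r2 <- column_r2(x, y)
  pool_n <- min(ncol(x), cfg$screen_top)
  pool <- order(-r2, seq_along(r2))[seq_len(pool_n)]

  sel <- integer(0)
  curve_col <- integer(0)
  curve_f1 <- numeric(0)
  best_so_far <- -Inf
  no_improve <- 0
  while (length(sel) < min(k_max, pool_n)) {
    cand <- setdiff(pool, sel)
    if (length(cand) == 0) break
    scores <- vapply(cand, function(cc) {
      p <- oof_probs(x, y, c(sel, cc), folds, cfg)
      f1_from_pred(y, p >= 0.5)
    }, numeric(1))
    best_i <- which(scores == max(scores))
    best_i <- best_i[which.min(cand[best_i])]
    sel <- c(sel, cand[best_i])
    curve_col <- c(curve_col, cand[best_i])
    curve_f1 <- c(curve_f1, scores[best_i])
    if (scores[best_i] >= best_so_far + cfg$improve_tol) {
      no_improve <- 0
    } else {
      no_improve <- no_improve + 1
    }
    best_so_far <- max(best_so_far, scores[best_i])
    if (no_improve >= cfg$patience) break
  }
  k_opt <- which.max(curve_f1)
  selected <- sel[seq_len(k_opt)]

  # threshold tuning on a fresh inner split: reusing the selection folds
  # would inherit the winner's-curse bias of the greedy search, and under a
  # null that bias pulls the tuned rule away from the F1-optimal
  # all-positive detector (threshold 0)
  folds_t <- stratified_folds(y, cfg$inner_folds, cfg$seed + 104729L)
  p_sel <- oof_probs(x, y, selected, folds_t, cfg)
  thr_f1 <- vapply(cfg$threshold_grid, function(th)
    f1_from_pred(y, p_sel >= th), numeric(1))
  best_t <- which.max(thr_f1) # ties to the lower threshold
  list(selected = selected,
       curve = tibble::tibble(step = seq_along(curve_f1),
                              column = curve_col, f1 = curve_f1),
       threshold = cfg$threshold_grid[best_t],
       oof_f1 = thr_f1[best_t])
}

resolve_condition_columns <- function(registry, condition) {
  switch(condition,
    spectral = registry$column[registry$family %in% POWER_BANDS],
    HOST = registry$column[!registry$family %in% POWER_BANDS],
    combined = registry$column,
    abort(paste0("unknown feature-set condition '", condition, "'"))
  )
}

#' Nested cross-validated evaluation
#'
#' Outer stratified 5-fold split; in each outer fold, missing-value
#' imputation statistics, wrapper feature selection and threshold tuning
#' are computed on the training folds only, the ensemble is refitted on the
#' selected features, and the held-out fold is scored. Metrics are reported
#' per fold and pooled from the summed confusion counts. The feature-set
#' condition restricts the candidate columns: `"spectral"` is the eight
#' band-power families, `"HOST"` everything else (the higher-order
#' spectrotemporal and connectivity families), `"combined"` all columns.
#'
#' @param features Feature table from [extract_features()] (needs >= 25
#'   trials and >= `outer_folds` examples of the minority class).
#' @param cfg A [model_config()].
#' @param condition `"combined"` (default), `"spectral"` or `"HOST"`.
#' @param columns Optional explicit column subset (overrides `condition`).
#' @return A `vigi_eval` object; see [tidy.vigi_eval()] and
#'   [glance.vigi_eval()].
#' @export
nested_cv_evaluate <- function(features, cfg = model_config(),
                               condition = "combined", columns = NULL) {
  reg <- attr(features, "registry")
  if (is.null(reg)) abort("features must come from extract_features()")
  y <- as.integer(features$outcome == "incorrect")
  if (length(y) < 25 || min(table(y)) < cfg$outer_folds) {
    abort("need >= 25 trials and >= 5 examples of each class for nested 5x5 folds; collect more trials")
  }
  cols <- columns %||% resolve_condition_columns(reg, condition)
  x <- as.matrix(features[, cols, drop = FALSE])
  folds <- stratified_folds(y, cfg$outer_folds, cfg$seed * 7919L)

  fold_rows <- list()
  selected <- list()
  curves <- list()
  audit <- list()
  counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (f in seq_len(cfg$outer_folds)) {
    tr <- folds != f
    imp <- impute_stats(x[tr, , drop = FALSE])
    xtr <- impute_apply(x[tr, , drop = FALSE], imp)
    xte <- impute_apply(x[!tr, , drop = FALSE], imp)
    ws <- wrapper_select(xtr, y[tr], cfg)
    fit <- xgb_fit(xtr[, ws$selected, drop = FALSE], y[tr], cfg)
    p <- xgb_prob(fit, xte[, ws$selected, drop = FALSE])
    pred <- p >= ws$threshold
    yt <- y[!tr]
    m <- compute_metrics(sum(pred & yt == 1), sum(pred & yt == 0),
                         sum(!pred & yt == 0), sum(!pred & yt == 1))
    counts <- counts + c(m$tp, m$fp, m$tn, m$fn)
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), m,
                                       tibble::tibble(threshold = ws$threshold,
                                                      n_selected = length(ws$selected)))
    selected[[f]] <- cols[ws$selected]
    curves[[f]] <- dplyr::mutate(ws$curve, fold = f,
                                 column = cols[.data$column])
    audit[[f]] <- list(train = which(tr), test = which(!tr))
  }
  pooled <- compute_metrics(counts["tp"], counts["fp"], counts["tn"],
                            counts["fn"])
  structure(list(
    condition = if (is.null(columns)) condition else "custom",
    period = attr(features, "period"),
    window_s = attr(features, "window_s"),
    session_id = attr(features, "session_id"),
    n_incorrect = sum(y == 1), n_correct = sum(y == 0),
    baseline_f1 = all_positive_baseline(sum(y == 1), sum(y == 0)),
    per_fold = dplyr::bind_rows(fold_rows),
    pooled = pooled,
    selected = selected,
    curves = dplyr::bind_rows(curves),
    fold_audit = audit,
    config = cfg
  ), class = "vigi_eval")
}

#' @export
print.vigi_eval <- function(x, ...) {
  cat(sprintf("<vigi_eval> %s | period %s (%.1f s) | %d+/%d- trials\n",
              x$condition, x$period %||% "?", x$window_s %||% NA,
              x$n_incorrect, x$n_correct))
  cat(sprintf("  pooled F1 %.3f (all-positive baseline %.3f), balanced accuracy %.3f\n",
              x$pooled$f1, x$baseline_f1, x$pooled$balanced_accuracy))
  invisible(x)
}

#' Per-channel classification performance
#'
#' Restricts the evaluation to the single-channel feature families of each
#' channel in turn (band powers, wavelet entropy, Hjorth, coupling index,
#' instantaneous amplitude/frequency; connectivity columns excluded) and
#' reports the pooled nested-CV F1 per channel.
#'
#' @param features Feature table from [extract_features()].
#' @param cfg A [model_config()]; `k_max` defaults to 5 here since each
#'   channel contributes only 16 columns.
#' @return Tibble `channel`, `f1`, `balanced_accuracy`, `n_selected`, with
#'   the all-positive baseline attached as attribute `"baseline_f1"`.
#' @export
single_channel_evaluation <- function(features,
                                      cfg = model_config(k_max = 5)) {
  reg <- attr(features, "registry")
  chans <- attr(features, "registry")$channel |> unique() |> stats::na.omit()
  out <- purrr::map_dfr(as.character(chans), function(cn) {
    cols <- reg$column[reg$single_channel & !is.na(reg$channel) &
                         reg$channel == cn]
    ev <- nested_cv_evaluate(features, cfg, columns = cols)
    tibble::tibble(channel = cn, f1 = ev$pooled$f1,
                   balanced_accuracy = ev$pooled$balanced_accuracy,
                   n_selected = mean(ev$per_fold$n_selected))
  })
  y <- features$outcome == "incorrect"
  attr(out, "baseline_f1") <- all_positive_baseline(sum(y), sum(!y))
  out
}

#' Compare evaluation periods and window lengths
#'
#' Runs the epoch-extraction, feature-extraction and nested-CV stages for
#' each period/window combination over one or more sessions and reports the
#' pooled F1 (confusion counts summed over sessions) next to the
#' all-positive baseline.
#'
#' @param sessions A single `list(session =, events =)` pair (e.g. from
#'   [generate_session()]) or a list of such pairs.
#' @param periods Periods to evaluate.
#' @param windows Window lengths (s) to evaluate (target period always
#'   uses 1 s).
#' @param cfg A [model_config()].
#' @param fcfg A [feature_config()].
#' @return Tibble `period`, `window_s`, `f1`, `balanced_accuracy`,
#'   `baseline_f1`, `n_trials`.
#' @export
period_comparison <- function(sessions,
                              periods = c("pre_target", "target", "delay"),
                              windows = 1.0,
                              cfg = model_config(),
                              fcfg = feature_config()) {
  if (!is.null(sessions$session)) sessions <- list(sessions)
  grid <- expand.grid(period = periods, window_s = windows,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$period == "target" & grid$window_s != 1.0) |
                 !any(grid$period == "target" & grid$window_s == 1.0), ]
  grid <- unique(grid)
  purrr::pmap_dfr(grid, function(period, window_s) {
    counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    npos <- 0; nneg <- 0
    for (s in sessions) {
      ep <- extract_epochs(s$session, s$events, period, window_s)
      ft <- extract_features(ep, fcfg)
      ev <- nested_cv_evaluate(ft, cfg)
      counts <- counts + c(ev$pooled$tp, ev$pooled$fp, ev$pooled$tn,
                           ev$pooled$fn)
      npos <- npos + ev$n_incorrect
      nneg <- nneg + ev$n_correct
    }
    m <- compute_metrics(counts["tp"], counts["fp"], counts["tn"],
                         counts["fn"])
    tibble::tibble(period = period, window_s = window_s, f1 = m$f1,
                   balanced_accuracy = m$balanced_accuracy,
                   baseline_f1 = all_positive_baseline(npos, nneg),
                   n_trials = npos + nneg)
  })
}

#' Serialize an evaluation report to JSON
#'
#' Deterministic (fixed seeds give byte-identical files).
#'
#' @param eval A `vigi_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  out <- list(
    condition = eval$condition, period = eval$period,
    window_s = eval$window_s, session_id = eval$session_id,
    n_incorrect = eval$n_incorrect, n_correct = eval$n_correct,
    baseline_f1 = eval$baseline_f1,
    pooled = as.list(eval$pooled),
    per_fold = as.data.frame(eval$per_fold),
    selected = eval$selected,
    selection_curve = as.data.frame(eval$curves),
    config = unclass(eval$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       null = "null")
  invisible(path)
}
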