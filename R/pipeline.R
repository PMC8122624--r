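# End-to-end orchestration: simulate (optional) -> ICA cleaning -> epochs ->
# features -> nested-CV evaluation per condition, with a manifest and
# figure-style summary tables.

#' Pipeline configuration
#'
#' Collects every stage's settings. Either `simulate` is given (synthetic
#' cohort) or `inputs` lists `signal`/`events` file pairs.
#'
#' @param out_dir Run directory (created).
#' @param simulate `NULL`, or a list with `n_sessions`, `regime`, and any
#'   [generator_config()] overrides.
#' @param inputs `NULL`, or a list of lists with `signal` and `events`
#'   paths.
#' @param ica_threshold Correlation threshold for eye-component removal;
#'   `NA` disables the ICA stage.
#' @param ica_criterion `"both"` or `"either"` (see
#'   [remove_eye_components()]).
#' @param period,window_s Epoch definition for the evaluation.
#' @param conditions Feature-set conditions to evaluate.
#' @param features A [feature_config()].
#' @param model A [model_config()].
#' @param seed Master seed (propagates to simulation and model).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            simulate = list(n_sessions = 2,
                                            regime = "balanced"),
                            inputs = NULL,
                            ica_threshold = 0.1,
                            ica_criterion = "both",
                            period = "delay", window_s = 1.0,
                            conditions = c("combined"),
                            features = feature_config(),
                            model = model_config(),
                            seed = 1) {
  structure(list(out_dir = out_dir, simulate = simulate, inputs = inputs,
                 ica_threshold = ica_threshold,
                 ica_criterion = ica_criterion,
                 period = period, window_s = window_s,
                 conditions = conditions, features = features,
                 model = model, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the
#'   [pipeline_config()] arguments (`features` and `model` as nested maps).
#' @param out_dir Optional override of the run directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  fcfg <- do.call(feature_config, y$features %||% list())
  mcfg <- do.call(model_config, y$model %||% list())
  pipeline_config(
    out_dir = out_dir %||% y$out_dir %||% abort("config needs out_dir"),
    simulate = y$simulate, inputs = y$inputs,
    ica_threshold = y$ica_threshold %||% 0.1,
    ica_criterion = y$ica_criterion %||% "both",
    period = y$period %||% "delay", window_s = y$window_s %||% 1.0,
    conditions = y$conditions %||% "combined",
    features = fcfg, model = mcfg, seed = y$seed %||% 1
  )
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> eye-component removal -> epoch
#' extraction -> feature extraction -> nested-CV evaluation for every
#' session and condition, writing per-session JSON reports, a top-features
#' table, a stage log, and a manifest (config hash, package version,
#' seeds) into the run directory.
#'
#' @param config A [pipeline_config()].
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  sessions <- load_or_simulate(config, say)

  results <- list()
  for (s in sessions) {
    sid <- s$session$session_id
    session <- s$session
    if (!is.na(config$ica_threshold)) {
      cl <- tryCatch(
        remove_eye_components(session, config$ica_threshold,
                              config$ica_criterion),
        error = function(e) abort(paste0("ICA stage failed for session ",
                                         sid, ": ", conditionMessage(e))))
      say("[%s] ICA removed %d component(s)", sid, sum(cl$report$removed))
      session <- cl$session
      readr::write_csv(cl$report, file.path(config$out_dir,
                                            paste0("ica_", sid, ".csv")),
                       progress = FALSE)
    }
    ep <- withCallingHandlers(
      extract_epochs(session, s$events, config$period, config$window_s),
      message = function(m) {
        log_lines <<- c(log_lines, paste0("[", sid, "] ", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    ft <- extract_features(ep, config$features)
    say("[%s] %d epochs x %d features (%s, %.1f s)", sid, nrow(ft),
        nrow(attr(ft, "registry")), config$period, config$window_s)
    readr::write_csv(utils::head(feature_r2(ft), 25),
                     file.path(config$out_dir, paste0("r2_", sid, ".csv")),
                     progress = FALSE)
    for (cond in config$conditions) {
      ev <- nested_cv_evaluate(ft, config$model, condition = cond)
      path <- file.path(config$out_dir,
                        paste0("report_", sid, "_", cond, ".json"))
      write_eval_report(ev, path)
      say("[%s] %s: pooled F1 %.3f (baseline %.3f)", sid, cond,
          ev$pooled$f1, ev$baseline_f1)
      results[[paste(sid, cond)]] <- ev
    }
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  manifest <- list(
    package = "vigimark",
    version = as.character(utils::packageVersion("vigimark")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    sessions = vapply(sessions, function(s) s$session$session_id,
                      character(1)),
    conditions = config$conditions,
    reports = list.files(config$out_dir, pattern = "^report_.*json$")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(config$out_dir)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$features <- unclass(out$features)
  out$model <- unclass(out$model)
  out$out_dir <- NULL # the hash identifies the analysis, not its location
  out
}

load_or_simulate <- function(config, say) {
  if (!is.null(config$inputs)) {
    return(purrr::map(config$inputs, function(inp) {
      if (!file.exists(inp$events %||% "")) {
        abort(paste0("events file not found: ", inp$events %||% "<missing>"))
      }
      say("loading %s", inp$signal)
      read_session(inp$signal, inp$events)
    }))
  }
  sim <- config$simulate %||% abort("config has neither inputs nor simulate")
  gen_args <- sim[setdiff(names(sim), c("n_sessions", "regime"))]
  gen_args$seed <- gen_args$seed %||% config$seed
  gcfg <- do.call(generator_config, gen_args)
  say("simulating %d %s session(s), ~%d trials each",
      sim$n_sessions %||% 2, sim$regime %||% "balanced", gcfg$n_trials)
  generate_cohort(gcfg, sim$n_sessions %||% 2, sim$regime %||% "balanced")
}

#' Summarize a completed run
#'
#' Builds the figure-style summary tables from the per-session reports in a
#' run directory: the feature-family selection frequency (a family selected
#' several times within one session counts once), the per-session pooled
#' metrics per condition, and the top discriminative features by R^2.
#' Tables are written as CSV next to the reports and returned.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return List of tibbles: `selection_frequency`, `session_metrics`,
#'   `r2_top_features`.
#' @export
summarize_run <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) {
    abort(paste0("no manifest.json in ", run_dir, "; run is incomplete"))
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  reports <- manifest$reports
  if (length(reports) == 0) {
    warn("run contains no reports; summaries are empty")
  }
  reg <- feature_registry()
  fam_of <- setNames(reg$family, reg$column)

  rows <- list()
  sel_rows <- list()
  for (rp in reports) {
    r <- jsonlite::read_json(file.path(run_dir, rp), simplifyVector = TRUE)
    rows[[rp]] <- tibble::tibble(
      session_id = r$session_id, condition = r$condition,
      f1 = r$pooled$f1, accuracy = r$pooled$accuracy,
      sensitivity = r$pooled$sensitivity, specificity = r$pooled$specificity,
      balanced_accuracy = r$pooled$balanced_accuracy,
      baseline_f1 = r$baseline_f1,
      n_incorrect = r$n_incorrect, n_correct = r$n_correct
    )
    sel_cols <- unique(unlist(r$selected))
    if (length(sel_cols) > 0) {
      sel_rows[[rp]] <- tibble::tibble(
        session_id = r$session_id, condition = r$condition,
        family = unique(unname(fam_of[sel_cols]))
      )
    }
  }
  session_metrics <- dplyr::bind_rows(rows)
  sel <- dplyr::bind_rows(sel_rows)
  n_sessions <- if (nrow(session_metrics) > 0) {
    length(unique(session_metrics$session_id))
  } else 0L
  selection_frequency <- if (nrow(sel) > 0) {
    sel |>
      dplyr::distinct(.data$session_id, .data$condition, .data$family) |>
      dplyr::count(.data$condition, .data$family, name = "n_sessions_selected") |>
      dplyr::mutate(pct_sessions = 100 * .data$n_sessions_selected /
                      max(1, n_sessions))
  } else {
    tibble::tibble(condition = character(), family = character(),
                   n_sessions_selected = integer(), pct_sessions = numeric())
  }
  r2_files <- list.files(run_dir, pattern = "^r2_.*csv$", full.names = TRUE)
  r2_top <- purrr::map_dfr(r2_files, function(f) {
    dplyr::mutate(readr::read_csv(f, show_col_types = FALSE, progress = FALSE),
                  session_id = sub("^r2_(.*)\\.csv$", "\\1", basename(f)))
  })
  out <- list(selection_frequency = selection_frequency,
              session_metrics = session_metrics,
              r2_top_features = r2_top)
  readr::write_csv(selection_frequency,
                   file.path(run_dir, "summary_selection_frequency.csv"),
                   progress = FALSE)
  readr::write_csv(session_metrics,
                   file.path(run_dir, "summary_session_metrics.csv"),
                   progress = FALSE)
  if (nrow(r2_top) > 0) {
    readr::write_csv(r2_top, file.path(run_dir, "summary_r2_top_features.csv"),
                     progress = FALSE)
  }
  out
}
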