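#' Run the calibration stage end to end
#'
#' The workhorse workflow: read (or take) a device inventory and session
#' table, summarize each device's replicates with Grubbs screening, score
#' the training devices under one model, and fit the exponential
#' calibration. Optionally writes a report: the per-device summary table,
#' the fit parameters, and a provenance block sufficient to reproduce the
#' run.
#'
#' @param devices An `atomizer_fleet` or path to a devices CSV.
#' @param sessions A session `data.frame` or path to a sessions CSV.
#' @param model A [score_model()] (default the model-1 score).
#' @param train_ids Device ids used for fitting; default all devices with
#'   summaries.
#' @param alpha Grubbs significance level.
#' @param method Fit method, see [fit_exponential()].
#' @param aggregation Multi-coil aggregation convention.
#' @param out_dir Optional directory; when given, writes `summary.csv`,
#'   `calibration.json` and `provenance.json`.
#' @return A list of class `calibration_run` with `fit` (`carbonyl_fit`),
#'   `summaries`, `scores` (per training device), `model`, `alpha`.
#' @export
calibrate_run <- function(devices, sessions,
                          model = builtin_models()$model1,
                          train_ids = NULL, alpha = 0.05,
                          method = c("loglinear", "nls"),
                          aggregation = c("sum_wires", "per_coil"),
                          out_dir = NULL) {
  method <- match.arg(method)
  aggregation <- match.arg(aggregation)
  if (is.character(devices)) devices <- read_devices(devices)
  if (is.character(sessions)) sessions <- read_sessions(sessions)
  stopifnot(inherits(devices, "atomizer_fleet"))

  summaries <- summarize_emissions(sessions, alpha)
  if (is.null(train_ids)) train_ids <- summaries$device_id
  absent <- setdiff(train_ids, names(devices))
  if (length(absent))
    stop("train id(s) not in devices: ", paste(absent, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(train_ids, summaries$device_id)
  if (length(absent))
    stop("train id(s) without sessions: ", paste(absent, collapse = ", "),
         call. = FALSE)

  scores <- vapply(train_ids, function(id)
    evaluate_score_model(model, devices[[id]], aggregation), numeric(1))
  y <- summaries$mean_emission[match(train_ids, summaries$device_id)]
  fit <- fit_exponential(scores, y, method = method)

  run <- structure(
    list(fit = fit,
         summaries = summaries,
         scores = data.frame(device_id = train_ids, score = scores,
                             stringsAsFactors = FALSE, row.names = NULL),
         model = model, alpha = alpha, method = method,
         aggregation = aggregation, train_ids = train_ids),
    class = "calibration_run"
  )
  if (!is.null(out_dir)) write_run_report(run, out_dir)
  run
}

#' @export
print.calibration_run <- function(x, digits = 4, ...) {
  cat(sprintf("Calibration run: model '%s', %d training device(s), alpha = %g\n",
              x$model$name, length(x$train_ids), x$alpha))
  cat(sprintf("  outliers removed: %d\n", sum(x$summaries$n_outliers_removed)))
  print(x$fit, digits = digits)
  invisible(x)
}

#' Run the evaluation stage end to end
#'
#' Extends [calibrate_run()] with out-of-sample evaluation: fits each
#' candidate model on the training devices and measures identity-line
#' predictive R2 on the evaluation devices via [rank_models()].
#'
#' @inheritParams calibrate_run
#' @param models Named list of `score_model` objects (default
#'   [builtin_models()]).
#' @param eval_ids Device ids evaluated (>= 2); default all devices with
#'   summaries. May overlap `train_ids`.
#' @return A list of class `evaluation_run` with `ranking` (the
#'   [rank_models()] table), `evaluations` (per-model
#'   `calibration_evaluation` for models that succeeded), `summaries`.
#' @export
evaluate_run <- function(devices, sessions, models = builtin_models(),
                         train_ids = NULL, eval_ids = NULL, alpha = 0.05,
                         method = c("loglinear", "nls"),
                         aggregation = c("sum_wires", "per_coil"),
                         out_dir = NULL) {
  method <- match.arg(method)
  aggregation <- match.arg(aggregation)
  if (is.character(devices)) devices <- read_devices(devices)
  if (is.character(sessions)) sessions <- read_sessions(sessions)
  if (is.character(models)) models <- read_models(models)
  stopifnot(inherits(devices, "atomizer_fleet"))

  summaries <- summarize_emissions(sessions, alpha)
  if (is.null(train_ids)) train_ids <- summaries$device_id
  if (is.null(eval_ids)) eval_ids <- summaries$device_id
  if (length(eval_ids) < 2L)
    stop("need at least 2 evaluation devices", call. = FALSE)

  ranking <- rank_models(models, devices, summaries, train_ids, eval_ids,
                         method, aggregation)
  evaluations <- list()
  for (m in models) {
    res <- tryCatch(
      train_predict_evaluate(m, devices, summaries, train_ids, eval_ids,
                             method, aggregation),
      error = function(e) NULL)
    if (!is.null(res)) evaluations[[m$name]] <- res
  }
  run <- structure(
    list(ranking = ranking, evaluations = evaluations,
         summaries = summaries, alpha = alpha, method = method,
         aggregation = aggregation,
         train_ids = train_ids, eval_ids = eval_ids),
    class = "evaluation_run"
  )
  if (!is.null(out_dir)) write_run_report(run, out_dir)
  run
}

#' @export
print.evaluation_run <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation run: %d model(s), train %d / eval %d device(s)\n",
              nrow(x$ranking), length(x$train_ids), length(x$eval_ids)))
  df <- x$ranking
  df$a <- signif(df$a, digits); df$b <- signif(df$b, digits)
  df$fit_r2 <- signif(df$fit_r2, digits)
  df$predictive_r2 <- signif(df$predictive_r2, digits)
  print(df[, c("model", "a", "b", "fit_r2", "predictive_r2", "status")],
        row.names = FALSE)
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Writes the per-device summary table (`summary.csv`), the fit or
#' ranking results (`calibration.json` / `ranking.csv` +
#' `evaluation.json`), and a provenance block (`provenance.json`: config
#' echo and package version) sufficient to reproduce the run on the same
#' inputs.
#'
#' @param run A `calibration_run` or `evaluation_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create report directory: ", dir, call. = FALSE)
  utils::write.csv(run$summaries, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  prov <- list(
    package = "coiltox",
    version = as.character(utils::packageVersion("coiltox")),
    alpha = run$alpha, method = run$method,
    aggregation = run$aggregation,
    train_ids = run$train_ids
  )
  if (inherits(run, "calibration_run")) {
    jsonlite::write_json(
      list(model = run$model$name, expression = run$model$expression,
           a = run$fit$a, b = run$fit$b, method = run$fit$method,
           fit_r2 = run$fit$fit_r2, fit_r2_log = run$fit$fit_r2_log,
           n_train = run$fit$n,
           n_outliers_removed = sum(run$summaries$n_outliers_removed)),
      file.path(dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(run$ranking, file.path(dir, "ranking.csv"),
                     row.names = FALSE)
    ev <- lapply(run$evaluations, function(e)
      list(model = e$model, a = e$fit$a, b = e$fit$b,
           method = e$fit$method, fit_r2 = e$fit$fit_r2,
           predictive_r2 = e$predictive_r2,
           n_train = length(e$train_ids), n_eval = length(e$eval_ids),
           pairs = e$pairs))
    jsonlite::write_json(ev, file.path(dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    prov$eval_ids <- run$eval_ids
  }
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
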