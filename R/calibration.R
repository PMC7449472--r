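#' Fit an exponential emission-score calibration
#'
#' Fits \eqn{y = a e^{bx}} relating per-device emission factors (total
#' carbonyls per gram of e-liquid) to a geometric device score. The
#' exponential form follows from the roughly exponential temperature
#' dependence of solvent degradation (Clausius-Clapeyron behaviour of the
#' enthalpy of vaporization).
#'
#' Two estimators are available. `"loglinear"` (the default, matching the
#' ubiquitous spreadsheet "exponential trendline") runs ordinary least
#' squares of \eqn{\ln y} on \eqn{x}, with \eqn{a = e^{intercept}} and
#' \eqn{b = slope}; it requires all y > 0. `"nls"` minimizes
#' \eqn{\sum (y_i - a e^{b x_i})^2} directly, initialized from the
#' log-linear solution. Both report `fit_r2` as \eqn{1 - SS_{res}/SS_{tot}}
#' computed on the ORIGINAL scale, so the methods are comparable; the
#' log-scale OLS \eqn{R^2} is reported alongside as `fit_r2_log` for the
#' log-linear method, since trendline software prints that value.
#'
#' @param x Numeric device scores (length >= 3, not all equal).
#' @param y Positive emission factors, same length.
#' @param weights Optional non-negative case weights (default unweighted;
#'   inverse-variance weights may be supplied for heteroscedastic data).
#' @param method `"loglinear"` or `"nls"`.
#' @return An object of class `carbonyl_fit` with components `a`, `b`,
#'   `method`, `fit_r2`, `fit_r2_log` (log-linear only, else `NA`),
#'   `sigma_log` (residual SD of the log-linear regression), `residuals`
#'   (observed - fitted, original scale), `data`, `n`.
#' @examples
#' x <- c(0, 1, 2, 3)
#' fit <- fit_exponential(x, 2 * exp(0.5 * x))
#' coef(fit)         # a = 2, b = 0.5
#' predict(fit, 4)   # 2 * exp(2)
#' @export
fit_exponential <- function(x, y, weights = NULL,
                            method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points to fit", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate design: all scores identical", call. = FALSE)
  if (any(y <= 0))
    stop("all emissions must be positive (log-linear initialization ",
         "requires log y)", call. = FALSE)
  if (!is.null(weights) &&
      (length(weights) != length(y) || any(weights < 0)))
    stop("weights must be non-negative and match the data length",
         call. = FALSE)

  ll <- if (is.null(weights)) stats::lm(log(y) ~ x)
        else stats::lm(log(y) ~ x, weights = weights)
  cf <- stats::coef(ll)
  if (anyNA(cf)) stop("degenerate design: slope not estimable", call. = FALSE)
  a <- unname(exp(cf[1]))
  b <- unname(cf[2])
  # summary.lm warns on noiseless (zero-residual) data; the values are fine
  sll <- suppressWarnings(summary(ll))
  fit_r2_log <- sll$r.squared
  sigma_log <- sll$sigma
  log_ci <- tryCatch(suppressWarnings(stats::confint(ll, level = 0.95)),
                     error = function(e) NULL)

  if (method == "nls") {
    nfit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x),
                        start = list(a = a, b = b),
                        data = data.frame(x = x, y = y),
                        weights = if (is.null(weights))
                          rep(1, length(y)) else weights,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(nfit, "error")) {
      cond <- simpleError(paste0(
        "nonlinear least squares did not converge: ",
        conditionMessage(nfit),
        " (log-linear fallback attached as attr 'fallback')"))
      attr(cond, "fallback") <- fit_exponential(x, y, weights, "loglinear")
      stop(cond)
    }
    cf <- stats::coef(nfit)
    a <- unname(cf["a"])
    b <- unname(cf["b"])
    fit_r2_log <- NA_real_
    log_ci <- NULL
  }

  fitted <- a * exp(b * x)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  ss_res <- sum(w * (y - fitted)^2)
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  # constant data fitted exactly (b = 0): define R2 = 1; otherwise the
  # ratio form stands, even when it goes negative for a flat fit on
  # varying data
  fit_r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot
            else if (ss_res <= .Machine$double.eps * sum(y^2)) 1
            else NA_real_

  structure(
    list(a = a, b = b, method = method,
         fit_r2 = fit_r2, fit_r2_log = fit_r2_log,
         sigma_log = sigma_log, log_ci = log_ci,
         residuals = y - fitted,
         data = data.frame(x = x, y = y),
         weights = weights, n = length(y),
         call = match.call()),
    class = "carbonyl_fit"
  )
}

#' @export
print.carbonyl_fit <- function(x, digits = 4, ...) {
  cat("Exponential emission calibration  y = a * exp(b * x)\n")
  cat(sprintf("  method: %s, n = %d\n",
              switch(x$method, loglinear = "log-linear OLS",
                     nls = "nonlinear least squares"), x$n))
  cat(sprintf("  a = %s (amplitude, emission units)\n",
              format(x$a, digits = digits)))
  cat(sprintf("  b = %s (rate, per score unit)\n",
              format(x$b, digits = digits)))
  cat(sprintf("  R2 (original scale) = %s\n",
              format(x$fit_r2, digits = digits)))
  if (!is.na(x$fit_r2_log))
    cat(sprintf("  R2 (log scale)      = %s\n",
                format(x$fit_r2_log, digits = digits)))
  invisible(x)
}

#' @export
summary.carbonyl_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.carbonyl_fit")
}

#' @export
print.summary.carbonyl_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  f <- x$fit
  if (!is.null(f$log_ci)) {
    cat("  95% CI (log-scale OLS):\n")
    cat(sprintf("    ln a: [%s, %s]  =>  a: [%s, %s]\n",
                format(f$log_ci[1, 1], digits = digits),
                format(f$log_ci[1, 2], digits = digits),
                format(exp(f$log_ci[1, 1]), digits = digits),
                format(exp(f$log_ci[1, 2]), digits = digits)))
    cat(sprintf("    b:    [%s, %s]\n",
                format(f$log_ci[2, 1], digits = digits),
                format(f$log_ci[2, 2], digits = digits)))
  }
  cat(sprintf("  residual range: [%s, %s]\n",
              format(min(f$residuals), digits = digits),
              format(max(f$residuals), digits = digits)))
  invisible(x)
}

#' @export
coef.carbonyl_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' Predict emission factors from a calibration
#'
#' @param object A `carbonyl_fit`.
#' @param newdata Numeric vector of scores (or a data.frame with a column
#'   `x` or `score`). Defaults to the training scores.
#' @param ... Unused.
#' @return Predicted emission factors, \eqn{\hat y = a e^{bx}} (positive).
#' @export
predict.carbonyl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) {
         col <- intersect(c("x", "score"), names(newdata))[1]
         if (is.na(col)) stop("newdata needs a column `x` or `score`",
                              call. = FALSE)
         newdata[[col]]
       } else as.numeric(newdata)
  object$a * exp(object$b * x)
}

#' @export
fitted.carbonyl_fit <- function(object, ...) {
  object$a * exp(object$b * object$data$x)
}

#' @export
residuals.carbonyl_fit <- function(object, ...) {
  object$residuals
}

#' Simulate emission factors from a fitted calibration
#'
#' Draws new responses at the training scores under the fitted curve with
#' multiplicative lognormal noise whose log-scale SD is the residual SD of
#' the log-linear regression — the noise structure the calibration assumes
#' (absolute spread grows with the mean).
#'
#' @param object A `carbonyl_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns, one simulated response per
#'   column, rows aligned with the training scores.
#' @export
simulate.carbonyl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, mu * exp(
    stats::rnorm(length(mu), 0, object$sigma_log)), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a calibration fit
#'
#' Scatter of emission factor against score with the fitted exponential
#' curve overlaid (dashed).
#'
#' @param x A `carbonyl_fit`.
#' @param ... Passed to [plot.default()].
#' @export
plot.carbonyl_fit <- function(x, ...) {
  d <- x$data
  plot(d$x, d$y, xlab = "device score", ylab = "emission factor",
       main = sprintf("y = %.3g exp(%.3g x),  R2 = %.3f",
                      x$a, x$b, x$fit_r2), ...)
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  graphics::lines(xs, x$a * exp(x$b * xs), lty = 2)
  invisible(x)
}

#' Identity-line coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2} with
#' the predictions taken as-is (the identity line), NOT the squared
#' correlation of a refitted regression. It equals 1 only for perfect
#' prediction, 0 for the mean predictor, and is negative when the
#' predictions are worse than predicting the mean — a diagnostic a squared
#' correlation cannot give.
#'
#' @param observed Observed emission factors (length >= 2, not all equal).
#' @param predicted Predicted emission factors, same length.
#' @return The coefficient of determination (may be negative).
#' @examples
#' predictive_r2(c(1, 2, 3), c(3, 2, 1))  # -3
#' @export
predictive_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ", call. = FALSE)
  if (length(observed) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed values are all identical: R2 undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Train a calibration and evaluate its predictions
#'
#' Runs the calibrate-then-predict workflow for one score model: scores
#' every device, fits the exponential calibration on the training devices'
#' mean emission factors, predicts the evaluation devices from their
#' scores, and measures accuracy with the identity-line [predictive_r2()].
#' The evaluation set may overlap the training set (the study design
#' evaluates all devices with a subset in training); both id sets are
#' recorded so strict held-out evaluation is equally expressible.
#'
#' @param model A [score_model()].
#' @param fleet An `atomizer_fleet`.
#' @param summaries Per-device emission summaries from
#'   [summarize_emissions()].
#' @param train_ids Device ids used for fitting (>= 3).
#' @param eval_ids Device ids used for evaluation (>= 2); defaults to all
#'   devices in `summaries`.
#' @param method Fit method, see [fit_exponential()].
#' @param aggregation Multi-coil aggregation convention.
#' @param weights Optional training weights, see [fit_exponential()].
#' @return A list of class `calibration_evaluation` with components `fit`
#'   (the `carbonyl_fit`), `predictive_r2`, `pairs` (per-device score,
#'   observed, predicted), `train_ids`, `eval_ids`, `model`.
#' @export
train_predict_evaluate <- function(model, fleet, summaries,
                                   train_ids, eval_ids = NULL,
                                   method = c("loglinear", "nls"),
                                   aggregation = c("sum_wires", "per_coil"),
                                   weights = NULL) {
  stopifnot(inherits(model, "score_model"), inherits(fleet, "atomizer_fleet"))
  method <- match.arg(method)
  aggregation <- match.arg(aggregation)
  if (is.null(eval_ids)) eval_ids <- summaries$device_id
  absent <- setdiff(c(train_ids, eval_ids), names(fleet))
  if (length(absent))
    stop("device id(s) not in fleet: ", paste(absent, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(c(train_ids, eval_ids), summaries$device_id)
  if (length(absent))
    stop("device id(s) without emission summaries: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (length(train_ids) < 3L)
    stop("need at least 3 training devices", call. = FALSE)
  if (length(eval_ids) < 2L)
    stop("need at least 2 evaluation devices (predictive R2 undefined ",
         "for a single device)", call. = FALSE)

  score_of <- function(ids) vapply(
    ids, function(id) evaluate_score_model(model, fleet[[id]], aggregation),
    numeric(1))
  mean_of <- function(ids)
    summaries$mean_emission[match(ids, summaries$device_id)]

  fit <- fit_exponential(score_of(train_ids), mean_of(train_ids),
                         weights = weights, method = method)
  eval_scores <- score_of(eval_ids)
  observed <- mean_of(eval_ids)
  predicted <- predict(fit, eval_scores)
  structure(
    list(fit = fit,
         predictive_r2 = predictive_r2(observed, predicted),
         pairs = data.frame(device_id = eval_ids, score = eval_scores,
                            observed = observed, predicted = predicted,
                            stringsAsFactors = FALSE, row.names = NULL),
         train_ids = train_ids, eval_ids = eval_ids, model = model$name),
    class = "calibration_evaluation"
  )
}

#' @export
print.calibration_evaluation <- function(x, digits = 4, ...) {
  cat(sprintf("Calibration evaluation for score model '%s'\n", x$model))
  cat(sprintf("  train: %d device(s); eval: %d device(s)\n",
              length(x$train_ids), length(x$eval_ids)))
  cat(sprintf("  a = %s, b = %s, fit R2 = %s\n",
              format(x$fit$a, digits = digits),
              format(x$fit$b, digits = digits),
              format(x$fit$fit_r2, digits = digits)))
  cat(sprintf("  predictive R2 (identity line) = %s\n",
              format(x$predictive_r2, digits = digits)))
  invisible(x)
}

#' Rank candidate score models by predictive accuracy
#'
#' Runs [train_predict_evaluate()] for every candidate model and sorts the
#' successful ones by descending predictive R2 (ties broken by model name
#' for reproducibility). Models that fail on any device — e.g. a power
#' model on a fleet without power settings — are reported as failed rows,
#' never silently dropped.
#'
#' @inheritParams train_predict_evaluate
#' @param models Named list of `score_model` objects.
#' @return A `data.frame` with columns `model, a, b, fit_r2,
#'   predictive_r2, status, message`, ranked rows first.
#' @export
rank_models <- function(models, fleet, summaries, train_ids,
                        eval_ids = NULL,
                        method = c("loglinear", "nls"),
                        aggregation = c("sum_wires", "per_coil")) {
  method <- match.arg(method)
  aggregation <- match.arg(aggregation)
  rows <- lapply(models, function(m) {
    res <- tryCatch(
      train_predict_evaluate(m, fleet, summaries, train_ids, eval_ids,
                             method, aggregation),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(model = m$name, a = NA_real_, b = NA_real_,
                 fit_r2 = NA_real_, predictive_r2 = NA_real_,
                 status = "failed", message = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(model = m$name, a = res$fit$a, b = res$fit$b,
                 fit_r2 = res$fit$fit_r2, predictive_r2 = res$predictive_r2,
                 status = "ok", message = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  ranked <- out[ok, , drop = FALSE]
  ranked <- ranked[order(-ranked$predictive_r2, ranked$model), , drop = FALSE]
  failed <- out[!ok, , drop = FALSE]
  failed <- failed[order(failed$model), , drop = FALSE]
  res <- rbind(ranked, failed)
  rownames(res) <- NULL
  res
}
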