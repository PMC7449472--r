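#' Model-1 device score
#'
#' The geometric predictor of relative carbonyl toxin levels:
#' \deqn{score = L / (SA \times n)}
#' with L the total coil length (mm), SA the total wick outer surface area
#' (mm^2) and n the number of wraps per coil. A long coil concentrates
#' thermal energy, a large wick spreads it into more e-liquid, and more
#' wraps distribute the contact more evenly; the ratio rises with expected
#' solvent degradation.
#'
#' @param L Total coil length in mm (> 0).
#' @param SA Total wick outer surface area in mm^2 (> 0).
#' @param n Wraps per coil (>= 1).
#' @return The score in 1/mm (vectorized).
#' @examples
#' model1_score(100, 50, 10)  # 0.2
#' @export
model1_score <- function(L, SA, n) {
  if (any(!is.finite(L) | L <= 0) || any(!is.finite(SA) | SA <= 0) ||
      any(!is.finite(n) | n < 1))
    stop("model1_score needs L > 0, SA > 0, n >= 1", call. = FALSE)
  L / (SA * n)
}

# variables a score expression may reference
.score_vars <- c("L", "SA", "n", "W")

# walk an expression AST, allowing only monomial syntax:
# products, quotients, powers and parentheses over {L, SA, n, W} and numbers
.check_score_expr <- function(e) {
  if (is.numeric(e)) {
    if (!is.finite(e) || e <= 0)
      stop("numeric constants in score expressions must be positive",
           call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.symbol(e)) {
    if (!as.character(e) %in% .score_vars)
      stop("unknown variable in score expression: ", as.character(e),
           " (allowed: ", paste(.score_vars, collapse = ", "), ")",
           call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.check_score_expr(e[[2]]))
    if (!op %in% c("*", "/", "^"))
      stop("score expressions are restricted to products, quotients and ",
           "powers; operator not allowed: ", op, call. = FALSE)
    .check_score_expr(e[[2]])
    .check_score_expr(e[[3]])
    return(invisible(TRUE))
  }
  stop("invalid score expression", call. = FALSE)
}

#' Define a candidate score model
#'
#' A named formula over the device variables `L` (total coil length, mm),
#' `SA` (total wick outer surface area, mm^2), `n` (wraps per coil) and `W`
#' (power, watts). Expressions are restricted to products, quotients and
#' powers of these variables and positive constants (monomial form), which
#' covers every published candidate and keeps evaluation safe and
#' unit-checkable.
#'
#' @param name Unique model name.
#' @param expression The formula as a string, e.g. `"L / (SA * n)"`.
#' @param description Optional free-text description.
#' @return An object of class `score_model`.
#' @examples
#' score_model("W_over_SA", "W / SA")
#' @export
score_model <- function(name, expression, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  e <- str2lang(expression)
  .check_score_expr(e)
  structure(
    list(name = name, expression = expression, expr = e,
         variables = intersect(.score_vars, all.vars(e)),
         description = description),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %s: %s%s\n", x$name, x$expression,
              if (nzchar(x$description)) paste0("  (", x$description, ")")
              else ""))
  invisible(x)
}

#' Built-in score models
#'
#' The candidate models with printed formulas: `model1` = L/(SA*n) (the
#' geometric predictor), `power_model_1a` = (W*L)/(SA*n) and
#' `power_model_2a` = W/(L*SA) (power-containing alternatives). Further
#' candidates are user-definable via [score_model()] or a models file.
#'
#' @return Named list of `score_model` objects.
#' @export
builtin_models <- function() {
  score_model_list(list(
    score_model("model1", "L / (SA * n)",
                "coil length over wick area times wraps"),
    score_model("power_model_1a", "(W * L) / (SA * n)",
                "watts times coil length over wick area times wraps"),
    score_model("power_model_2a", "W / (L * SA)",
                "watts over coil length times wick area")
  ))
}

#' Assemble a list of score models with unique names
#'
#' @param models List of `score_model` objects.
#' @return The list, named by model name.
#' @export
score_model_list <- function(models) {
  stopifnot(all(vapply(models, inherits, logical(1), "score_model")))
  nm <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate score model name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  stats::setNames(models, nm)
}

#' Read score models from a JSON config file
#'
#' The file maps model names to expression strings, e.g.
#' `{"model1": "L / (SA * n)", "W_over_SA": "W / SA"}`.
#'
#' @param path Path to a JSON file.
#' @return Named list of `score_model` objects.
#' @export
read_models <- function(path) {
  if (!file.exists(path)) stop("models file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_model_list(mapply(score_model, names(raw), unlist(raw),
                          SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

#' Write score models to a JSON config file
#'
#' Inverse of [read_models()]; round-trips names and expressions.
#'
#' @param models Named list of `score_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  x <- stats::setNames(
    lapply(models, `[[`, "expression"),
    vapply(models, `[[`, character(1), "name")
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Evaluate a score model on a device
#'
#' Evaluates the model's expression on the device's effective geometry
#' (see [effective_geometry()]) and power setting. Power is required only
#' when the expression references `W`; a device without a power setting
#' fails with an error naming the missing variable.
#'
#' @param model A [score_model()].
#' @param device An [atomizer_device()].
#' @param aggregation Multi-coil aggregation convention, passed to
#'   [effective_geometry()].
#' @return The scalar score.
#' @examples
#' d <- atomizer_device("EC1",
#'   coil_spec("single", "horizontal", wire_length = 100, wraps = 10),
#'   wick_spec("measured", area = 50), power = 50)
#' evaluate_score_model(builtin_models()$model1, d)  # 0.2
#' @export
evaluate_score_model <- function(model, device,
                                 aggregation = c("sum_wires", "per_coil")) {
  stopifnot(inherits(model, "score_model"))
  geom <- effective_geometry(device, aggregation)
  vars <- list(L = geom$L, SA = geom$SA, n = geom$n, W = device$power)
  for (v in model$variables) {
    if (is.null(vars[[v]]) || is.na(vars[[v]]))
      stop("device ", device$device_id, " lacks variable ", v,
           " required by model ", model$name, call. = FALSE)
  }
  val <- eval(model$expr, vars)
  if (!is.finite(val) || val <= 0)
    stop("model ", model$name, " evaluated to a non-positive or non-finite ",
         "score on device ", device$device_id, call. = FALSE)
  val
}

#' Score every device under every model
#'
#' Builds the device-by-model score matrix as a long-format table. A
#' device that fails under a model (e.g. a power model with no power
#' setting) gets `status = "failed"` and the error message instead of
#' aborting the whole run.
#'
#' @param fleet An `atomizer_fleet` or a path to a devices CSV.
#' @param models Named list of `score_model` objects (or a path to a
#'   models JSON); defaults to [builtin_models()].
#' @param aggregation Multi-coil aggregation convention.
#' @return A `data.frame` with columns `device_id, model, score, status,
#'   message`.
#' @export
score_table <- function(fleet, models = builtin_models(),
                        aggregation = c("sum_wires", "per_coil")) {
  if (is.character(fleet)) fleet <- read_devices(fleet)
  if (is.character(models)) models <- read_models(models)
  stopifnot(inherits(fleet, "atomizer_fleet"))
  aggregation <- match.arg(aggregation)
  if (length(fleet) == 0L) {
    warning("empty fleet: score table has no rows")
    return(data.frame(device_id = character(0), model = character(0),
                      score = numeric(0), status = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (d in fleet) {
    for (m in models) {
      res <- tryCatch(
        list(score = evaluate_score_model(m, d, aggregation),
             status = "ok", message = ""),
        error = function(e) list(score = NA_real_, status = "failed",
                                 message = conditionMessage(e))
      )
      rows[[length(rows) + 1L]] <- data.frame(
        device_id = d$device_id, model = m$name, score = res$score,
        status = res$status, message = res$message, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
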