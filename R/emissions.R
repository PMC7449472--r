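#' The six-carbonyl panel
#'
#' Analyte names of the carbonyl panel quantified per collection session:
#' the major thermal degradation products of propylene glycol and glycerol.
#'
#' @return Character vector of the six analyte names.
#' @export
carbonyl_panel <- function() {
  c("formaldehyde", "acetaldehyde", "acetone",
    "propanal", "butyraldehyde", "benzaldehyde")
}

# molar masses (g/mol) for nmol -> ug conversion
.carbonyl_mw <- c(
  formaldehyde = 30.026,
  acetaldehyde = 44.053,
  acetone = 58.080,
  propanal = 58.080,
  butyraldehyde = 72.107,
  benzaldehyde = 106.124
)

#' Read a session table from CSV
#'
#' Expected columns: `device_id, replicate_id`, the six analytes of
#' [carbonyl_panel()], `unit` (`"ug"` or `"nmol"`), `eliquid_g`. Amounts
#' are collection totals over one session; `eliquid_g` is the tank mass
#' lost during the session. `nmol` amounts are converted to micrograms via
#' a fixed molar-mass table so downstream totals are in a single unit
#' system. Blank or negative cells fail loudly with the row number: a
#' missing analyte is an error, never silently zero.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of sessions with analyte amounts in ug.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("sessions file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("device_id", "replicate_id", carbonyl_panel(), "eliquid_g")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sessions file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"unit" %in% names(df)) df$unit <- "ug"
  bad_unit <- !df$unit %in% c("ug", "nmol")
  if (any(bad_unit))
    stop("sessions file row ", which(bad_unit)[1], ": unknown unit '",
         df$unit[bad_unit][1], "' (use 'ug' or 'nmol')", call. = FALSE)
  for (an in carbonyl_panel()) {
    v <- df[[an]]
    if (!is.numeric(v) || anyNA(v))
      stop("sessions file: analyte '", an, "' has a missing or non-numeric ",
           "value at row ", which(!is.finite(as.numeric(v)))[1], call. = FALSE)
    if (any(v < 0))
      stop("sessions file: analyte '", an, "' negative at row ",
           which(v < 0)[1], call. = FALSE)
    nm <- df$unit == "nmol"
    if (any(nm)) df[[an]][nm] <- v[nm] * .carbonyl_mw[[an]] / 1000
  }
  df$unit <- "ug"
  if (anyNA(df$eliquid_g) || any(df$eliquid_g <= 0))
    stop("sessions file: eliquid_g must be positive at row ",
         which(!is.finite(df$eliquid_g) | df$eliquid_g <= 0)[1], call. = FALSE)
  df
}

#' Total carbonyls per session
#'
#' Sums the six panel analytes for each session row. All six must be
#' present and non-missing; a missing analyte is an error naming it.
#'
#' @param sessions A session `data.frame` (see [read_sessions()]).
#' @return Numeric vector of per-session totals (same unit as the input).
#' @export
total_carbonyls <- function(sessions) {
  for (an in carbonyl_panel()) {
    if (!an %in% names(sessions) || anyNA(sessions[[an]]))
      stop("missing analyte: ", an, call. = FALSE)
    if (any(sessions[[an]] < 0))
      stop("negative amount for analyte: ", an, call. = FALSE)
  }
  rowSums(as.matrix(sessions[, carbonyl_panel(), drop = FALSE]))
}

#' Normalize session totals by e-liquid consumed
#'
#' Total carbonyls divided by the mass of e-liquid consumed during the
#' session (tank mass before minus after), giving an emission factor in
#' amount per gram. Normalizing by consumption inherently accounts for the
#' power dependence of aerosol production.
#'
#' @param sessions A session `data.frame` with an `eliquid_g` column.
#' @return Numeric vector of normalized totals (amount per g).
#' @export
normalize_per_eliquid <- function(sessions) {
  if (!"eliquid_g" %in% names(sessions))
    stop("sessions need an `eliquid_g` column", call. = FALSE)
  el <- sessions$eliquid_g
  if (anyNA(el) || any(el <= 0))
    stop("eliquid_g must be positive for every session", call. = FALSE)
  total_carbonyls(sessions) / el
}

#' Grubbs statistic
#'
#' Maximum studentized deviation G = max_i |y_i - mean(y)| / s, with s the
#' sample standard deviation (n - 1 denominator). For zero-variance data G
#' is defined as 0 (no outlier). Ties in the extreme deviation resolve to
#' the larger value: the failure modes behind replicate outliers (burnt
#' coils, dry wicks) inflate emissions.
#'
#' @param values Numeric vector, length >= 3.
#' @return List with `G` (the statistic) and `index` (position of the most
#'   extreme value).
#' @export
grubbs_statistic <- function(values) {
  n <- length(values)
  if (n < 3L) stop("Grubbs test undefined for n < 3", call. = FALSE)
  s <- stats::sd(values)
  # zero variance up to floating-point jitter: no outlier by convention
  if (s <= max(abs(values), 1e-300) * 1e-10)
    return(list(G = 0, index = NA_integer_))
  dev <- abs(values - mean(values))
  cand <- which(dev == max(dev))
  index <- if (length(cand) > 1L) cand[which.max(values[cand])] else cand
  list(G = max(dev) / s, index = index)
}

#' Grubbs critical value
#'
#' Two-sided critical value for the Grubbs test at level `alpha`:
#' \deqn{G_{crit} = \frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n-2+t^2}}}
#' where t is the upper alpha/(2n) quantile of the t distribution with
#' n - 2 degrees of freedom.
#'
#' @param n Number of replicates (>= 3).
#' @param alpha Significance level in (0, 1).
#' @return The critical value.
#' @examples
#' grubbs_critical_value(10, 0.05)  # ~2.290
#' @export
grubbs_critical_value <- function(n, alpha = 0.05) {
  if (n < 3L) stop("Grubbs test undefined for n < 3", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Summarize one device's replicates with Grubbs screening
#'
#' Applies the Grubbs test iteratively to the per-session normalized total
#' carbonyls of one device: while the statistic exceeds the critical value
#' at level `alpha`, the single most extreme value is removed, stopping
#' before the replicate count would fall below 2. Returns the mean, the
#' standard error of the mean, and the screening counts.
#'
#' @param values Per-session normalized totals for one device (>= 3).
#' @param alpha Grubbs significance level (two-sided), default 0.05.
#' @return List with `mean`, `se`, `n_used`, `n_outliers_removed`,
#'   `removed_values`, `removed_indices` (positions in the input vector)
#'   and `screening_stopped` (TRUE when screening hit the floor of 2
#'   retained values and could not continue).
#' @export
screen_replicates <- function(values, alpha = 0.05) {
  if (length(values) < 3L)
    stop("need at least 3 replicate sessions per device", call. = FALSE)
  kept <- values
  pos <- seq_along(values)
  removed_idx <- integer(0)
  stopped <- FALSE
  repeat {
    if (length(kept) < 3L) {
      # test undefined below 3; screening cannot continue at the floor
      stopped <- TRUE
      break
    }
    g <- grubbs_statistic(kept)
    if (g$G <= grubbs_critical_value(length(kept), alpha)) break
    removed_idx <- c(removed_idx, pos[g$index])
    kept <- kept[-g$index]
    pos <- pos[-g$index]
  }
  n <- length(kept)
  list(
    mean = mean(kept),
    se = if (n > 1) stats::sd(kept) / sqrt(n) else 0,
    n_used = n,
    n_outliers_removed = length(removed_idx),
    removed_values = values[removed_idx],
    removed_indices = removed_idx,
    screening_stopped = stopped
  )
}

#' Per-device emission summaries
#'
#' Groups a session table by device, normalizes each session's total
#' carbonyls by e-liquid consumed, screens replicates with the iterative
#' Grubbs procedure and returns one row per device with the mean emission
#' factor, its standard error, and screening counts.
#'
#' @param sessions A session `data.frame` (see [read_sessions()]).
#' @param alpha Grubbs significance level, default 0.05.
#' @return A `data.frame` with columns `device_id, mean_emission,
#'   standard_error, n_used, n_outliers_removed, screening_stopped`,
#'   ordered by first appearance of each device.
#' @export
summarize_emissions <- function(sessions, alpha = 0.05) {
  y <- normalize_per_eliquid(sessions)
  ids <- unique(sessions$device_id)
  rows <- lapply(ids, function(id) {
    v <- y[sessions$device_id == id]
    s <- tryCatch(screen_replicates(v, alpha), error = function(e)
      stop("device ", id, ": ", conditionMessage(e), call. = FALSE))
    data.frame(device_id = id, mean_emission = s$mean,
               standard_error = s$se, n_used = s$n_used,
               n_outliers_removed = s$n_outliers_removed,
               screening_stopped = s$screening_stopped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
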