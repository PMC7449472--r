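# fixed six-analyte split of the session total (fractions sum to 1);
# formaldehyde/acetaldehyde dominance as in carbonyl emission surveys.
# the split never affects totals-based analysis.
.analyte_split <- c(
  formaldehyde = 0.30,
  acetaldehyde = 0.40,
  acetone = 0.10,
  propanal = 0.08,
  butyraldehyde = 0.07,
  benzaldehyde = 0.05
)

#' Configuration for a synthetic device fleet
#'
#' Defines the study conditions a synthetic benchmark emulates: a fleet of
#' a dozen atomizers spanning all three coil styles and both orientations,
#' each measured in at least triplicate, with true emission factors
#' following \eqn{y = a e^{b \cdot score}} of the model-1 score and
#' multiplicative lognormal session noise (absolute spread grows with the
#' mean, as observed for high-emitting devices). Occasional gross
#' outliers — burnt coils, improper resistance readings — are high-side
#' multiplicative shocks.
#'
#' Defaults: 12 devices, 4 replicates, `a_true = 5` (ug/g), `b_true = 8`
#' (per score unit), `noise_sigma = 0.2` (log scale), no outliers.
#' Geometry ranges give model-1 scores roughly 0.02-0.5 per mm, typical of
#' commercial builds.
#'
#' @param n_devices Number of devices.
#' @param replicates_per_device Sessions per device (>= 3).
#' @param a_true,b_true True calibration parameters.
#' @param noise_sigma Log-scale SD of multiplicative session noise (>= 0).
#' @param outlier_rate Per-session probability of a gross outlier.
#' @param outlier_multiplier High-side outlier multiplier (> 1).
#' @param wire_length_range,wraps_range,wick_diameter_range,
#'   wick_length_range,power_range Geometry sampling ranges
#'   (mm / turns / mm / mm / W).
#' @param eliquid_range Range of e-liquid consumed per session (g).
#' @param style_mix Named proportions over the six style-orientation
#'   combinations `single_horizontal, single_vertical, parallel_horizontal,
#'   parallel_vertical, dual_horizontal, dual_vertical`; must sum to 1.
#' @param seed RNG seed (integer).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_devices = 12L,
                             replicates_per_device = 4L,
                             a_true = 5, b_true = 8,
                             noise_sigma = 0.2,
                             outlier_rate = 0,
                             outlier_multiplier = 20,
                             wire_length_range = c(50, 120),
                             wraps_range = c(5L, 12L),
                             wick_diameter_range = c(2, 4),
                             wick_length_range = c(8, 15),
                             power_range = c(10, 80),
                             eliquid_range = c(0.3, 1.5),
                             style_mix = c(single_horizontal = 0.25,
                                           single_vertical = 0.25,
                                           parallel_horizontal = 0.125,
                                           parallel_vertical = 0.125,
                                           dual_horizontal = 0.125,
                                           dual_vertical = 0.125),
                             seed = 1L) {
  ranges <- list(wire_length_range = wire_length_range,
                 wraps_range = wraps_range,
                 wick_diameter_range = wick_diameter_range,
                 wick_length_range = wick_length_range,
                 power_range = power_range,
                 eliquid_range = eliquid_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
      stop(nm, " must be a positive c(min, max) with min <= max",
           call. = FALSE)
  }
  combos <- c("single_horizontal", "single_vertical", "parallel_horizontal",
              "parallel_vertical", "dual_horizontal", "dual_vertical")
  if (is.null(names(style_mix)) || !all(names(style_mix) %in% combos))
    stop("style_mix must be named by style_orientation combinations",
         call. = FALSE)
  if (any(style_mix < 0) || abs(sum(style_mix) - 1) > 1e-8)
    stop("style_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (n_devices < 0) stop("n_devices must be >= 0", call. = FALSE)
  if (n_devices > 0 && replicates_per_device < 3L)
    stop("replicates_per_device must be >= 3", call. = FALSE)
  if (a_true <= 0) stop("a_true must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must be in [0, 1]", call. = FALSE)
  if (outlier_multiplier <= 1)
    stop("outlier_multiplier must be > 1", call. = FALSE)
  structure(
    c(list(n_devices = as.integer(n_devices),
           replicates_per_device = as.integer(replicates_per_device),
           a_true = a_true, b_true = b_true, noise_sigma = noise_sigma,
           outlier_rate = outlier_rate,
           outlier_multiplier = outlier_multiplier),
      ranges,
      list(style_mix = style_mix[combos][!is.na(style_mix[combos])],
           seed = as.integer(seed))),
    class = "synthetic_config"
  )
}

#' Generate a synthetic atomizer fleet
#'
#' Samples `n_devices` devices uniformly within the configured geometry
#' ranges, with style-orientation combinations drawn from `style_mix`.
#' Dual builds get two wicks (one per coil); parallel builds share one
#' wick between two wires. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return An `atomizer_fleet` of `n_devices` devices `SD01, SD02, ...`.
#' @export
generate_fleet <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  if (config$n_devices == 0L) return(atomizer_fleet(list()))
  combos <- sample(names(config$style_mix), config$n_devices,
                   replace = TRUE, prob = config$style_mix)
  devices <- lapply(seq_len(config$n_devices), function(i) {
    parts <- strsplit(combos[i], "_", fixed = TRUE)[[1]]
    style <- parts[1]; orientation <- parts[2]
    wire_length <- stats::runif(1, config$wire_length_range[1],
                                config$wire_length_range[2])
    wraps <- sample(seq(config$wraps_range[1], config$wraps_range[2]), 1)
    wd <- stats::runif(1, config$wick_diameter_range[1],
                       config$wick_diameter_range[2])
    wl <- stats::runif(1, config$wick_length_range[1],
                       config$wick_length_range[2])
    power <- stats::runif(1, config$power_range[1], config$power_range[2])
    wick_count <- if (style == "dual") 2L else 1L
    atomizer_device(
      sprintf("SD%02d", i),
      coil_spec(style, orientation, wire_length = wire_length,
                wraps = wraps),
      wick_spec("cylinder", diameter = wd, length = wl, count = wick_count),
      power = power
    )
  })
  atomizer_fleet(devices)
}

#' Generate synthetic emission sessions for a fleet
#'
#' For each device and replicate, the true emission factor is
#' \eqn{a_{true} e^{b_{true} \cdot score}} (ug per g) with the model-1
#' score from [effective_geometry()]; the session's factor multiplies in
#' lognormal noise \eqn{e^\varepsilon}, \eqn{\varepsilon \sim N(0,
#' \sigma^2)}, and — with probability `outlier_rate` — a high-side gross
#' outlier shock. The factor times the sampled e-liquid mass gives the
#' session total, split across the six analytes by fixed proportions.
#' Noise and outlier draws are consumed for every session regardless of
#' `noise_sigma` and `outlier_rate`, so runs at the same seed differ only
#' where those parameters act.
#'
#' @param fleet An `atomizer_fleet` (typically from [generate_fleet()]).
#' @param config A [synthetic_config()].
#' @return A session `data.frame` (the [read_sessions()] schema, amounts
#'   in ug) with attribute `"truth"`: a `data.frame` of per-session
#'   `device_id, replicate_id, score_true, emission_true, is_outlier`.
#' @export
generate_sessions <- function(fleet, config) {
  stopifnot(inherits(fleet, "atomizer_fleet"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  rows <- list(); truth <- list()
  for (d in fleet) {
    geom <- effective_geometry(d)
    score <- model1_score(geom$L, geom$SA, geom$n)
    mu <- config$a_true * exp(config$b_true * score)
    for (r in seq_len(config$replicates_per_device)) {
      z <- stats::rnorm(1)
      u <- stats::runif(1)
      el <- stats::runif(1, config$eliquid_range[1], config$eliquid_range[2])
      is_out <- u < config$outlier_rate
      factor_ug_per_g <- mu * exp(config$noise_sigma * z) *
        if (is_out) config$outlier_multiplier else 1
      total_ug <- factor_ug_per_g * el
      amounts <- as.list(total_ug * .analyte_split)
      rep_id <- sprintf("R%d", r)
      rows[[length(rows) + 1L]] <- data.frame(
        device_id = d$device_id, replicate_id = rep_id,
        amounts, unit = "ug", eliquid_g = el,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        device_id = d$device_id, replicate_id = rep_id,
        score_true = score, emission_true = mu, is_outlier = is_out,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    sessions <- data.frame(device_id = character(0),
                           replicate_id = character(0))
    attr(sessions, "truth") <- data.frame()
    return(sessions)
  }
  sessions <- do.call(rbind, rows)
  attr(sessions, "truth") <- do.call(rbind, truth)
  sessions
}

#' Write a complete synthetic benchmark to disk
#'
#' Generates a fleet and its sessions and writes three delimited files:
#' `devices.csv` and `sessions.csv` in the standard input schemas, and
#' `truth.csv` recording the generating parameters per session (true
#' score, true emission factor, injected-outlier flag) plus `a_true` /
#' `b_true` columns, for test assertions.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `devices`, `sessions`, `truth` (the
#'   in-memory objects) and `paths`.
#' @export
make_benchmark <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create benchmark directory: ", dir, call. = FALSE)
  fleet <- generate_fleet(config)
  sessions <- generate_sessions(fleet, config)
  truth <- attr(sessions, "truth")
  truth$a_true <- config$a_true
  truth$b_true <- config$b_true
  paths <- list(devices = file.path(dir, "devices.csv"),
                sessions = file.path(dir, "sessions.csv"),
                truth = file.path(dir, "truth.csv"))
  write_devices(fleet, paths$devices)
  out_sessions <- sessions
  attr(out_sessions, "truth") <- NULL
  utils::write.csv(out_sessions, paths$sessions, row.names = FALSE)
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  invisible(list(devices = fleet, sessions = sessions, truth = truth,
                 paths = paths))
}
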