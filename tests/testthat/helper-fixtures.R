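# shared fixtures and independent oracles for the test suite

# a small hand-built fleet: one of each style
fixture_fleet <- function() {
  atomizer_fleet(list(
    atomizer_device("ECA",
                    coil_spec("single", "horizontal", wire_length = 100,
                              wraps = 10),
                    wick_spec("measured", area = 50), power = 40),
    atomizer_device("ECB",
                    coil_spec("parallel", "vertical", wire_length = 60,
                              wraps = 6),
                    wick_spec("measured", area = 40), power = 55),
    atomizer_device("ECC",
                    coil_spec("dual", "horizontal", wire_length = 98.04,
                              wraps = 8),
                    wick_spec("cylinder", diameter = 3, length = 10,
                              count = 2), power = 65)
  ))
}

# one session row with the six analytes in ug
fixture_session <- function(device_id = "ECA", replicate_id = "R1",
                            amounts = c(1, 2, 3, 4, 5, 6),
                            eliquid_g = 1) {
  stopifnot(length(amounts) == 6)
  df <- data.frame(device_id = device_id, replicate_id = replicate_id,
                   stringsAsFactors = FALSE)
  for (i in seq_along(carbonyl_panel())) df[[carbonyl_panel()[i]]] <- amounts[i]
  df$unit <- "ug"
  df$eliquid_g <- eliquid_g
  df
}

# sessions table with given per-session normalized totals for one device,
# each session consuming 1 g and split evenly over analytes
fixture_sessions_with_totals <- function(totals, device_id = "ECA") {
  do.call(rbind, lapply(seq_along(totals), function(i)
    fixture_session(device_id, sprintf("R%d", i),
                    amounts = rep(totals[i] / 6, 6), eliquid_g = 1)))
}

# independent Grubbs critical value: coded separately from the package
# (same published formula, written from the t-quantile definition)
oracle_grubbs_crit <- function(n, alpha) {
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
}

# independent grid-search minimizer over (a, b), used as the oracle for
# fit_exponential. loss = "original" minimizes sum((y - a*exp(b*x))^2)
# (the nls objective); loss = "log" minimizes
# sum((log y - log a - b*x)^2) (the log-linear OLS objective). Returns
# the best grid point and the grid resolution around it.
oracle_grid_fit <- function(x, y, a_range, b_range, n_grid = 201,
                            loss = c("original", "log")) {
  loss <- match.arg(loss)
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  b_grid <- seq(b_range[1], b_range[2], length.out = n_grid)
  best <- c(NA, NA); best_ss <- Inf
  ly <- log(y)
  for (a in a_grid) {
    # vectorize over b for speed
    ss <- if (loss == "original") {
      pred <- outer(b_grid, x, function(b, x) a * exp(b * x))
      rowSums(sweep(pred, 2, y)^2)
    } else {
      pred <- outer(b_grid, x, function(b, x) log(a) + b * x)
      rowSums(sweep(pred, 2, ly)^2)
    }
    i <- which.min(ss)
    if (ss[i] < best_ss) { best_ss <- ss[i]; best <- c(a, b_grid[i]) }
  }
  list(a = best[1], b = best[2], ss = best_ss,
       res_a = diff(a_range) / (n_grid - 1),
       res_b = diff(b_range) / (n_grid - 1))
}
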