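test_that("noiseless exponential data is recovered exactly by both methods", {
  x <- c(0, 1, 2, 3)
  y <- 2 * exp(0.5 * x)
  for (m in c("loglinear", "nls")) {
    fit <- fit_exponential(x, y, method = m)
    expect_equal(coef(fit), c(a = 2, b = 0.5), tolerance = 1e-8)
    expect_equal(fit$fit_r2, 1, tolerance = 1e-10)
    expect_equal(predict(fit, 4), 2 * exp(2), tolerance = 1e-8)
    expect_equal(residuals(fit), rep(0, 4), tolerance = 1e-8)
  }
})

test_that("degenerate inputs follow the documented conventions", {
  # constant y at distinct x: flat curve a = 3, b = 0, perfect fit
  fit <- fit_exponential(0:3, rep(3, 4))
  expect_equal(coef(fit), c(a = 3, b = 0), tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1)
  expect_equal(predict(fit, 100), 3)
  # constant x: degenerate design
  expect_error(fit_exponential(rep(1, 4), c(1, 2, 3, 4)), "degenerate")
  # non-positive y rejected
  expect_error(fit_exponential(0:3, c(1, 2, 0, 4)), "positive")
  # too few points
  expect_error(fit_exponential(c(0, 1), c(1, 2)), "3 points")
})

test_that("fitting agrees with an independent grid-search minimizer", {
  set.seed(41)
  for (i in 1:6) {
    a0 <- runif(1, 2, 8); b0 <- runif(1, 2, 6)
    x <- sort(runif(9, 0, 0.6))
    y <- a0 * exp(b0 * x) * exp(rnorm(9, 0, 0.2))
    fit <- fit_exponential(x, y, method = "nls")
    g <- oracle_grid_fit(x, y, a_range = c(fit$a * 0.8, fit$a * 1.2),
                         b_range = c(fit$b - 1, fit$b + 1))
    # the nls optimum must beat or match the best grid point, and the
    # grid's best point must lie within one grid cell of the nls solution
    ss_fit <- sum((y - fit$a * exp(fit$b * x))^2)
    expect_lte(ss_fit, g$ss + 1e-9)
    expect_lt(abs(fit$a - g$a), 2 * g$res_a)
    expect_lt(abs(fit$b - g$b), 2 * g$res_b)
  }
})

test_that("log-linear and nls estimates agree on well-behaved data", {
  set.seed(42)
  x <- sort(runif(12, 0, 0.6))
  y <- 5 * exp(8 * x) * exp(rnorm(12, 0, 0.05))
  f1 <- fit_exponential(x, y, method = "loglinear")
  f2 <- fit_exponential(x, y, method = "nls")
  expect_equal(f1$b, f2$b, tolerance = 0.1)
  # amplitude is an extrapolation to x = 0; the estimators agree on the
  # fitted curve over the observed score range
  expect_equal(predict(f1, x), predict(f2, x), tolerance = 0.1)
  # both report an original-scale R2; log-linear also reports the
  # log-scale (trendline) value
  expect_false(is.na(f1$fit_r2_log))
  expect_true(is.na(f2$fit_r2_log))
})

test_that("identity-line predictive R2 matches the hand formula", {
  y <- c(1, 2, 3)
  expect_equal(predictive_r2(y, y), 1)
  expect_equal(predictive_r2(y, rep(mean(y), 3)), 0)
  # reversal: 1 - 8/2 = -3
  expect_equal(predictive_r2(c(1, 2, 3), c(3, 2, 1)), -3)
  # random pairs against the explicit formula
  set.seed(43)
  for (i in 1:20) {
    obs <- rnorm(sample(2:15, 1), 10, 3)
    if (sd(obs) == 0) next
    pred <- obs + rnorm(length(obs))
    expect_equal(predictive_r2(obs, pred),
                 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  }
  expect_error(predictive_r2(c(1, 1), c(1, 2)), "identical")
  expect_error(predictive_r2(1, 1), "at least 2")
})

test_that("train/predict/evaluate closes the loop and matches a two-step oracle", {
  cfg <- synthetic_config(noise_sigma = 0, seed = 5)
  fl <- generate_fleet(cfg)
  summaries <- summarize_emissions(generate_sessions(fl, cfg))
  m1 <- builtin_models()$model1
  # eval = train on noiseless data: perfect prediction
  res <- train_predict_evaluate(m1, fl, summaries,
                                train_ids = names(fl)[1:9],
                                eval_ids = names(fl)[1:9])
  expect_equal(res$predictive_r2, 1, tolerance = 1e-10)
  # noisy fleet: reproduce the pipeline with an independent two-step
  # computation (oracle fit on train, plug scores in, hand R2 on eval)
  cfg2 <- synthetic_config(seed = 6)
  fl2 <- generate_fleet(cfg2)
  sm2 <- summarize_emissions(generate_sessions(fl2, cfg2))
  res2 <- train_predict_evaluate(m1, fl2, sm2,
                                 train_ids = names(fl2)[1:9])
  scores <- vapply(names(fl2), function(id) {
    g <- effective_geometry(fl2[[id]]); g$L / (g$SA * g$n)
  }, numeric(1))
  cf <- coef(lm(log(sm2$mean_emission[1:9]) ~ scores[1:9]))
  pred <- exp(cf[1]) * exp(cf[2] * scores)
  obs <- sm2$mean_emission
  expect_equal(res2$predictive_r2,
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-10)
  expect_identical(res2$train_ids, names(fl2)[1:9])
  expect_identical(res2$eval_ids, sm2$device_id)
  # degenerate and undersized inputs propagate errors
  expect_error(train_predict_evaluate(m1, fl2, sm2,
                                      train_ids = names(fl2)[1:2]),
               "3 training")
  expect_error(train_predict_evaluate(m1, fl2, sm2,
                                      train_ids = names(fl2)[1:9],
                                      eval_ids = names(fl2)[1]),
               "2 evaluation")
  expect_error(train_predict_evaluate(m1, fl2, sm2,
                                      train_ids = c(names(fl2)[1:8], "ZZ")),
               "ZZ")
})

test_that("adding independent noise to predictions degrades expected predictive R2", {
  set.seed(44)
  deltas <- replicate(100, {
    obs <- rlnorm(10, 2, 0.5)
    pred <- obs * exp(rnorm(10, 0, 0.1))
    noisy <- pred * exp(rnorm(10, 0, 0.3))
    predictive_r2(obs, noisy) - predictive_r2(obs, pred)
  })
  expect_lt(mean(deltas), 0)
})

test_that("model ranking sorts by predictive R2 and keeps failures visible", {
  m <- builtin_models()
  cfg <- synthetic_config(seed = 8)
  fl <- generate_fleet(cfg)
  sm <- summarize_emissions(generate_sessions(fl, cfg))
  rk <- rank_models(m, fl, sm, train_ids = names(fl)[1:9])
  expect_identical(rk$model[1], "model1")  # generator uses the model-1 score
  expect_true(all(diff(rk$predictive_r2[rk$status == "ok"]) <= 0))
  # single model: ranked first trivially
  rk1 <- rank_models(m["model1"], fl, sm, train_ids = names(fl)[1:9])
  expect_identical(nrow(rk1), 1L)
  # devices without power: power models appear as failed rows
  fl_np <- atomizer_fleet(lapply(unclass(fl), function(d) {
    d$power <- NA_real_; d
  }))
  rk2 <- rank_models(m, fl_np, sm, train_ids = names(fl)[1:9])
  expect_setequal(rk2$status[rk2$model != "model1"], "failed")
  expect_identical(rk2$status[rk2$model == "model1"], "ok")
  # ties break lexicographically by model name
  dup <- score_model_list(list(score_model("b_copy", "L / (SA * n)"),
                               score_model("a_copy", "L / (SA * n)")))
  rk3 <- rank_models(dup, fl, sm, train_ids = names(fl)[1:9])
  expect_identical(rk3$model, c("a_copy", "b_copy"))
})

test_that("carbonyl_fit methods behave as a classed model object", {
  x <- c(0, 0.2, 0.4, 0.6)
  fit <- fit_exponential(x, c(5, 9, 18, 42))
  expect_s3_class(fit, "carbonyl_fit")
  expect_named(coef(fit), c("a", "b"))
  expect_output(print(fit), "Exponential emission calibration")
  expect_output(print(summary(fit)), "95% CI")
  expect_equal(fitted(fit) + residuals(fit), c(5, 9, 18, 42))
  # predict accepts vectors and data frames
  expect_equal(predict(fit, data.frame(score = x)), predict(fit, x))
  # simulate reproduces the lognormal noise law around the fitted curve
  sims <- simulate(fit, nsim = 200, seed = 9)
  expect_identical(dim(sims), c(4L, 200L))
  expect_true(all(sims > 0))
  med <- apply(sims, 1, median)
  expect_equal(unname(med), unname(fitted(fit)), tolerance = 0.2)
  # plot draws without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
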