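make_frame <- function(d, intervention_cost = 0, horizon = 6) {
  fr <- build_analysis_frame(zero_fill_items(d), horizon = horizon)
  finalize_outcomes(fr, horizon = horizon,
                    intervention_cost = intervention_cost)
}

test_that("Gaussian QALY model recovers a known additive treatment effect", {
  cfg <- complete_config(n = 2000, seed = 51,
                         true_utility_effect = c(0, 0.04, 0.06, 0))
  d <- simulate_trial(cfg)
  fr <- make_frame(d)
  fit <- fit_outcome_model(fr, "qaly", cea_model_spec())
  est <- coef(fit)[["armintervention"]]
  se <- sqrt(diag(vcov(fit)))[["armintervention"]]
  target <- attr(d, "truth")$delta_qaly[["h6"]]
  expect_lt(abs(est - target), 3 * se)
})

test_that("Gamma log-link model recovers a known multiplicative cost effect", {
  # direct generation: costs ~ Gamma with a known arm multiplier
  set.seed(52)
  n <- 4000
  arm <- factor(rep(c("control", "intervention"), each = n / 2),
                levels = c("control", "intervention"))
  age <- rnorm(n, 72, 7)
  beta_true <- 0.3
  mu <- exp(7 + 0.01 * (age - 72) + beta_true * (arm == "intervention"))
  y <- rgamma(n, shape = 2, rate = 2 / mu)
  fit <- glm(y ~ arm + age, family = Gamma(link = "log"))
  est <- coef(fit)[["armintervention"]]
  se <- sqrt(diag(vcov(fit)))[["armintervention"]]
  expect_lt(abs(est - beta_true), 3 * se)
})

test_that("step-halving Gamma fitter agrees with stats::glm on well-behaved data", {
  d <- small_trial(n = 60, seed = 59)
  fr <- make_frame(d, intervention_cost = 650)
  f <- total_cost ~ arm + u_0 + age + gender
  # strictly converged oracle: the Gamma deviance is flat near its optimum,
  # so glm's default stopping rule leaves ~1e-4 slack in the coefficients
  oracle <- glm(f, Gamma(link = "log"), fr,
                control = list(epsilon = 1e-12, maxit = 500))
  expect_true(oracle$converged)
  fit <- fit_outcome_model(fr, "cost", cea_model_spec(
    covariates = c("u_0", "age", "gender")))
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-4)
  expect_equal(predict(fit, fr), unname(predict(oracle, fr,
                                                type = "response")),
               tolerance = 1e-4, ignore_attr = TRUE)
  rp1 <- recycled_predictions(fit, fr)
  rp2 <- recycled_predictions(oracle, fr)
  expect_equal(rp1$delta, rp2$delta, tolerance = 1e-4)
})

test_that("constant outcome yields a zero treatment effect", {
  d <- small_trial(n = 30, seed = 53)
  fr <- make_frame(d)
  fr$qaly <- 0.5
  fit <- fit_outcome_model(fr, "qaly", tiny_spec())
  expect_equal(unname(coef(fit)[["armintervention"]]), 0, tolerance = 1e-10)
})

test_that("zero total costs are bumped for the Gamma family and logged", {
  d <- small_trial(n = 30, seed = 54)
  fr <- make_frame(d)
  fr$total_cost[1:3] <- 0
  fit <- fit_outcome_model(fr, "cost", tiny_spec())
  expect_identical(attr(fit, "n_zero_adjusted"), 3L)
  expect_true(fit$converged)
})

test_that("recycled predictions equal the treatment coefficient under identity link", {
  d <- small_trial(n = 60, seed = 55)
  fr <- make_frame(d)
  fit <- fit_outcome_model(fr, "qaly", cea_model_spec())
  rp <- recycled_predictions(fit, fr)
  expect_equal(rp$delta, unname(coef(fit)[["armintervention"]]),
               tolerance = 1e-10)
})

test_that("recycled predictions on a log-link model match brute-force averaging", {
  # 6-row toy dataset, hand-evaluated standardization
  toy <- data.frame(
    arm = factor(c("control", "control", "control",
                   "intervention", "intervention", "intervention"),
                 levels = c("control", "intervention")),
    age = c(60, 70, 80, 65, 75, 85),
    total_cost = c(100, 220, 150, 240, 400, 310)
  )
  fit <- glm(total_cost ~ arm + age, family = Gamma(link = "log"),
             data = toy)
  b <- coef(fit)
  # oracle: mean over all six participants of exp(lp) under each arm
  lp0 <- b[1] + b["age"] * toy$age
  lp1 <- b[1] + b["armintervention"] + b["age"] * toy$age
  oracle <- mean(exp(lp1)) - mean(exp(lp0))
  rp <- recycled_predictions(fit, toy)
  expect_equal(rp$delta, unname(oracle), tolerance = 1e-9)
  # balance property: both arm means standardise over the same rows, so a
  # covariate-shifted frame changes both but their construction is shared
  expect_equal(rp$mean_control, mean(exp(lp0)), tolerance = 1e-9)
  expect_equal(rp$mean_intervention, mean(exp(lp1)), tolerance = 1e-9)
})

test_that("zero treatment coefficient gives exactly zero increments", {
  d <- small_trial(n = 40, seed = 56)
  fr <- make_frame(d)
  fit <- fit_outcome_model(fr, "qaly", tiny_spec())
  fit$coefficients[["armintervention"]] <- 0
  rp <- recycled_predictions(fit, fr)
  expect_equal(rp$delta, 0, tolerance = 1e-12)
})

test_that("covariate schema mismatches are caught", {
  d <- small_trial(n = 30, seed = 57)
  fr <- make_frame(d)
  fit <- fit_outcome_model(fr, "qaly", cea_model_spec())
  expect_error(recycled_predictions(fit, fr[, c("id", "arm", "age")]),
               "schema")
})

test_that("pooling over imputations averages per-imputation estimates", {
  cfg <- mar_config(n = 70, seed = 58)
  d <- apply_missingness(simulate_trial(cfg), cfg)
  fr <- build_analysis_frame(zero_fill_items(d))
  st <- impute_trial(fr, m = 4, seed = 5)
  am <- pool_over_imputations(st, cea_model_spec(), horizon = 6,
                              intervention_cost = 650)
  expect_equal(am$delta_qaly, mean(am$per_imputation[, "delta_qaly"]))
  expect_equal(am$delta_cost, mean(am$per_imputation[, "delta_cost"]))
  expect_gt(am$between_var[["delta_qaly"]], 0)
  # the per-patient intervention cost flows into the incremental cost
  # (approximately 650, up to Gamma-model curvature)
  am0 <- pool_over_imputations(st, cea_model_spec(), horizon = 6,
                               intervention_cost = 0)
  expect_gt(am$delta_cost - am0$delta_cost, 400)
  expect_lt(abs((am$delta_cost - am0$delta_cost) - 650), 250)
})
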