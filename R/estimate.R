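#' Adjustment model specification
#'
#' Fixes the GLM families and covariate set for the two outcomes: total
#' cost is modelled with a Gamma family (log link by default — the robust
#' choice for right-skewed costs) and QALYs with a Gaussian family and
#' identity link. The treatment indicator is always included and the
#' covariate set is identical for both outcomes.
#'
#' @param covariates baseline covariate columns (default [cea_covariates()]).
#' @param gamma_link link for the cost model (default `"log"`).
#' @return object of class `cea_model_spec`.
#' @export
cea_model_spec <- function(covariates = cea_covariates(),
                           gamma_link = "log") {
  structure(list(covariates = covariates, gamma_link = gamma_link),
            class = "cea_model_spec")
}

#' Derive analysis outcomes on a completed frame
#'
#' Adds `qaly` (trapezoidal AUC over the horizon, death rule respected) and
#' `total_cost` (sum of category costs over the horizon's periods, plus the
#' per-patient intervention cost for intervention-arm participants) to a
#' completed analysis frame.
#'
#' @param frame completed `analysis_frame` (no `NA` in analysis variables).
#' @param horizon months.
#' @param intervention_cost per-patient intervention cost (GBP).
#' @return the frame with `qaly` and `total_cost` columns.
#' @export
finalize_outcomes <- function(frame, horizon = attr(frame, "horizon") %||% 6,
                              intervention_cost = 0) {
  tp <- c(0, 3, 6, 12)
  frame$qaly <- compute_qalys(frame, horizon = horizon,
                              timepoints = tp[tp <= horizon])
  cost_cols <- attr(frame, "cost_cols") %||%
    grep("^cost_", names(frame), value = TRUE)
  frame$total_cost <- rowSums(frame[, cost_cols, drop = FALSE]) +
    ifelse(frame$arm == "intervention", intervention_cost, 0)
  frame
}

# Gamma deviance (unit shape); saturated model has mu = y.
gamma_deviance <- function(y, mu) 2 * sum((y - mu) / mu - log(y / mu))

# IRLS for the Gamma/log model with deviance step-halving. Plain glm.fit
# can oscillate indefinitely on heavy-tailed cost resamples because it
# never damps a diverging step; for the log link the IRLS weights are
# identically 1, so each step is a least-squares solve of the working
# response, and halving back towards the previous iterate restores
# monotone deviance descent.
fit_gamma_log <- function(f, data, maxit = 200, tol = 1e-12) {
  mf <- model.frame(f, data)
  y <- model.response(mf)
  if (any(y <= 0)) stopf("estimation error: Gamma outcome must be positive")
  X <- model.matrix(attr(mf, "terms"), mf)
  ls_beta <- function(z) {
    b <- lm.fit(X, z)$coefficients
    replace(b, is.na(b), 0)
  }
  beta <- ls_beta(log(y))
  eta <- drop(X %*% beta)
  dev <- gamma_deviance(y, exp(eta))
  converged <- FALSE
  iter <- 0
  while (iter < maxit) {
    iter <- iter + 1
    z <- eta + y / exp(eta) - 1          # working response, unit weights
    beta_new <- ls_beta(z)
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      dev_try <- gamma_deviance(y, exp(eta_try))
      if (is.finite(dev_try) && dev_try <= dev * (1 + 1e-12)) break
      step <- step / 2
      if (step < 1e-10) { dev_try <- dev; eta_try <- eta; beta_try <- beta; break }
    }
    done <- abs(dev - dev_try) / (0.1 + abs(dev_try)) < tol
    beta <- beta_try; eta <- eta_try; dev <- dev_try
    if (done) { converged <- TRUE; break }
  }
  structure(list(coefficients = beta, deviance = dev, iter = iter,
                 converged = converged, formula = f,
                 terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 fitted.values = exp(eta),
                 family = Gamma(link = "log")),
            class = "gamma_glm")
}

#' @export
predict.gamma_glm <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- log(object$fitted.values)
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- model.frame(tt, newdata, xlev = object$xlevels)
    X <- model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") exp(eta) else eta
}

#' @export
formula.gamma_glm <- function(x, ...) x$formula

#' Fit a covariate-adjusted outcome model
#'
#' GLM of an outcome on the treatment indicator plus the specified baseline
#' covariates: Gaussian/identity for QALYs, Gamma (log link by default) for
#' costs. Gamma requires strictly positive outcomes, so non-positive total
#' costs (possible in the control arm) are raised to the smallest positive
#' observed cost times 1e-3; the number of adjusted rows is recorded in
#' attribute `"n_zero_adjusted"`.
#'
#' @param frame completed frame with the outcome column present.
#' @param outcome `"qaly"` or `"cost"`.
#' @param spec a [cea_model_spec()].
#' @return fitted `glm` object.
#' @export
fit_outcome_model <- function(frame, outcome = c("qaly", "cost"),
                              spec = cea_model_spec()) {
  outcome <- match.arg(outcome)
  ycol <- switch(outcome, qaly = "qaly", cost = "total_cost")
  if (!ycol %in% names(frame))
    stopf("frame lacks outcome column '%s'; run finalize_outcomes() first",
          ycol)
  if (anyNA(frame[[ycol]]))
    stopf("outcome '%s' contains missing values; impute first", ycol)
  covs <- intersect(spec$covariates, names(frame))
  n_zero <- 0L
  dat <- frame
  fam <- if (outcome == "qaly") gaussian() else Gamma(link = spec$gamma_link)
  if (outcome == "cost") {
    y <- dat[[ycol]]
    nonpos <- y <= 0
    if (any(nonpos)) {
      if (all(nonpos)) stopf("estimation error: all total costs are zero")
      bump <- min(y[y > 0]) * 1e-3
      dat[[ycol]][nonpos] <- bump
      n_zero <- sum(nonpos)
    }
  }
  if (var(dat[[ycol]]) == 0 && outcome == "qaly") {
    # constant outcome: lm still fits (zero effects); keep going
  }
  f <- as.formula(paste(ycol, "~ arm",
                        if (length(covs)) paste("+", paste(covs, collapse = " + "))
                        else ""))
  if (outcome == "cost" && spec$gamma_link == "log") {
    fit <- tryCatch(fit_gamma_log(f, dat),
                    error = function(e)
                      stopf("estimation error fitting cost model: %s",
                            conditionMessage(e)))
    if (!fit$converged)
      stopf("estimation error: cost model did not converge")
    attr(fit, "n_zero_adjusted") <- n_zero
    return(fit)
  }
  fit <- tryCatch(suppressWarnings(glm(f, family = fam, data = dat,
                                       control = list(maxit = 200))),
                  error = function(e)
                    stopf("estimation error fitting %s model: %s", outcome,
                          conditionMessage(e)))
  if (!fit$converged)
    stopf("estimation error: %s model did not converge", outcome)
  attr(fit, "n_zero_adjusted") <- n_zero
  fit
}

#' Recycled predictions (marginal standardization)
#'
#' Predicts every participant's expected outcome with the treatment
#' indicator forced to each arm in turn, on the response scale, and averages
#' over the full pooled covariate distribution. Both arm means therefore use
#' the identical covariate distribution, so covariate imbalance contributes
#' nothing to the incremental estimate; with an identity link the increment
#' equals the raw treatment coefficient.
#'
#' @param fit fitted outcome model from [fit_outcome_model()].
#' @param frame the completed frame the model was fitted on (or any frame
#'   with the same covariate schema to standardise over).
#' @param subset optional logical/integer row selector: average predictions
#'   over this subset only (used by subgroup scenarios).
#' @return named list: `mean_control`, `mean_intervention`, `delta`.
#' @export
recycled_predictions <- function(fit, frame, subset = NULL) {
  need <- setdiff(all.vars(formula(fit)[[3]]), "arm")
  missing_cols <- setdiff(need, names(frame))
  if (length(missing_cols))
    stopf("covariate schema mismatch: frame lacks %s",
          paste(missing_cols, collapse = ", "))
  if (is.null(subset)) subset <- rep(TRUE, nrow(frame))
  d0 <- d1 <- frame
  d0$arm <- factor("control", levels = levels(frame$arm))
  d1$arm <- factor("intervention", levels = levels(frame$arm))
  p0 <- mean(predict(fit, newdata = d0[subset, , drop = FALSE],
                     type = "response"))
  p1 <- mean(predict(fit, newdata = d1[subset, , drop = FALSE],
                     type = "response"))
  list(mean_control = p0, mean_intervention = p1, delta = p1 - p0)
}

# Fit both outcome models on one completed frame and standardise.
estimate_arm_means <- function(frame, spec = cea_model_spec(),
                               subset = NULL) {
  fit_c <- fit_outcome_model(frame, "cost", spec)
  fit_q <- fit_outcome_model(frame, "qaly", spec)
  rc <- recycled_predictions(fit_c, frame, subset)
  rq <- recycled_predictions(fit_q, frame, subset)
  list(cost_control = rc$mean_control,
       cost_intervention = rc$mean_intervention,
       qaly_control = rq$mean_control,
       qaly_intervention = rq$mean_intervention,
       delta_cost = rc$delta, delta_qaly = rq$delta)
}

#' Pool recycled-prediction estimates over an imputed stack
#'
#' Runs both outcome models and recycled predictions on each completed
#' dataset and combines with Rubin's rule for point estimates (the mean over
#' imputations); the between-imputation variance of each quantity is
#' recorded. When nothing was missing, all copies are identical and the
#' pooled estimate equals the single-dataset estimate with zero
#' between-imputation variance.
#'
#' @param stack an `imputed_stack` from [impute_trial()].
#' @param spec a [cea_model_spec()].
#' @param horizon months.
#' @param intervention_cost per-patient intervention cost (GBP).
#' @return object of class `arm_means`: pooled per-arm means, `delta_cost`,
#'   `delta_qaly`, per-imputation estimates and between-imputation variances.
#' @export
pool_over_imputations <- function(stack, spec = cea_model_spec(),
                                  horizon = 6, intervention_cost = 0) {
  stopifnot(inherits(stack, "imputed_stack"))
  per <- lapply(stack$imputations, function(fr) {
    fr <- finalize_outcomes(fr, horizon = horizon,
                            intervention_cost = intervention_cost)
    unlist(estimate_arm_means(fr, spec))
  })
  mat <- do.call(rbind, per)
  pooled <- colMeans(mat)
  between <- apply(mat, 2, var)
  if (nrow(mat) == 1) between[] <- 0
  structure(c(as.list(pooled),
              list(per_imputation = mat, between_var = between,
                   m = stack$m, horizon = horizon,
                   intervention_cost = intervention_cost)),
            class = "arm_means")
}

#' @export
print.arm_means <- function(x, ...) {
  cat(sprintf("Adjusted arm means over %d months (pooled over m = %d)\n",
              x$horizon, x$m))
  cat(sprintf("  cost:  control %0.2f, intervention %0.2f, delta %0.2f\n",
              x$cost_control, x$cost_intervention, x$delta_cost))
  cat(sprintf("  QALYs: control %0.4f, intervention %0.4f, delta %0.4f\n",
              x$qaly_control, x$qaly_intervention, x$delta_qaly))
  invisible(x)
}
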