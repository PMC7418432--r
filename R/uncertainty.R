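quadrant_of <- function(delta_cost, delta_qaly) {
  # boundary convention: delta_cost >= 0 -> north, delta_qaly >= 0 -> east
  paste0(ifelse(delta_cost >= 0, "N", "S"), ifelse(delta_qaly >= 0, "E", "W"))
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' `ICER = delta_cost / delta_qaly`. A bare ratio is meaningless off the
#' north-east quadrant, so the result always carries a quadrant label and a
#' dominance classification: `dominant` (cheaper and more effective, SE),
#' `dominated` (dearer and less effective, NW), or a quadrant-labelled
#' ratio. A zero QALY difference yields a tagged undefined result, not an
#' error.
#'
#' @param delta_cost incremental cost (GBP), or an `arm_means` object.
#' @param delta_qaly incremental QALYs (ignored if `delta_cost` is an
#'   `arm_means`).
#' @return object of class `icer`: list with `ratio` (`NA` when undefined),
#'   `quadrant`, `classification`, `delta_cost`, `delta_qaly`.
#' @examples
#' icer(1000, 0.1)   # 10000 GBP/QALY, NE
#' icer(-1, 0.01)    # dominant
#' @export
icer <- function(delta_cost, delta_qaly = NULL) {
  if (inherits(delta_cost, "arm_means")) {
    delta_qaly <- delta_cost$delta_qaly
    delta_cost <- delta_cost$delta_cost
  }
  if (is.null(delta_qaly)) stopf("delta_qaly required")
  if (delta_qaly == 0) {
    return(structure(list(ratio = NA_real_, quadrant = quadrant_of(delta_cost, 0),
                          classification = "undefined (zero QALY difference)",
                          delta_cost = delta_cost, delta_qaly = delta_qaly),
                     class = "icer"))
  }
  q <- quadrant_of(delta_cost, delta_qaly)
  classification <- switch(q,
    NE = "NE: more costly, more effective",
    SW = "SW: less costly, less effective",
    SE = "dominant (less costly, more effective)",
    NW = "dominated (more costly, less effective)")
  structure(list(ratio = delta_cost / delta_qaly, quadrant = q,
                 classification = classification,
                 delta_cost = delta_cost, delta_qaly = delta_qaly),
            class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (is.na(x$ratio)) cat("ICER undefined:", x$classification, "\n")
  else cat(sprintf("ICER: %0.0f GBP/QALY [%s]\n", x$ratio, x$classification))
  invisible(x)
}

#' Bootstrap the full estimation pipeline
#'
#' Non-parametric bootstrap of the incremental cost and QALY estimates:
#' each iteration resamples participants with replacement, stratified by
#' randomised arm (preserving arm sizes), from the original possibly
#' incomplete data; re-runs zero-fill, a single fresh imputation, outcome
#' construction, both GLMs and recycled predictions; and records one
#' `(delta_cost, delta_qaly)` pair. The point estimate comes from the full
#' `m`-imputation stack on the original data. Iterations whose pipeline
#' fails (e.g. a degenerate resample) are retried with a new draw; more
#' than 5% failures aborts the run.
#'
#' @param data trial dataset (post-missingness; complete data work too and
#'   make the imputation step a no-op).
#' @param units a `unit_cost_table`.
#' @param intervention_cost per-patient intervention cost (GBP).
#' @param spec a [cea_model_spec()].
#' @param horizon months.
#' @param B bootstrap iterations (default 1000).
#' @param m imputations for the point estimate (default 50).
#' @param m_boot imputations per bootstrap iteration (default 1: resample
#'   then impute afresh, propagating imputation uncertainty without an
#'   m x B blow-up).
#' @param k,cycles PMM donor pool and chained-equation cycles.
#' @param seed integer seed; iteration i uses a sub-seed derived from it.
#' @param exclude_items resource items excluded from costing.
#' @param covariates covariate set (default from `spec`).
#' @return object of class `cea_estimate`: point `delta_cost`/`delta_qaly`,
#'   `icer`, the pooled `arm_means`, a `B x 2` matrix `pairs` of bootstrap
#'   increments with quadrant labels, percentile 95% CIs, and the failure
#'   count.
#' @export
bootstrap_pipeline <- function(data, units = default_unit_costs(),
                               intervention_cost = 0,
                               spec = cea_model_spec(), horizon = 6,
                               B = 1000, m = 50, m_boot = 1,
                               k = 5, cycles = 10, seed = 1,
                               exclude_items = NULL,
                               covariates = spec$covariates) {
  if (B < 1) stopf("bootstrap error: B must be >= 1")
  run_once <- function(d, n_imp, sub_seed) {
    d <- zero_fill_items(d, units)
    fr <- build_analysis_frame(d, units, horizon = horizon,
                               covariates = intersect(covariates, names(d)),
                               exclude_items = exclude_items)
    st <- impute_trial(fr, m = n_imp, k = k, cycles = cycles,
                       covariates = covariates, seed = sub_seed)
    pool_over_imputations(st, spec, horizon = horizon,
                          intervention_cost = intervention_cost)
  }
  point <- run_once(data, m, derive_seed(seed, "impute"))

  idx_int <- which(data$arm == "intervention")
  idx_ctl <- which(data$arm == "control")
  set.seed(derive_seed(seed, "bootstrap"))
  pairs <- matrix(NA_real_, B, 2,
                  dimnames = list(NULL, c("delta_cost", "delta_qaly")))
  failures <- 0L
  max_failures <- max(1L, ceiling(0.05 * B))
  b <- 1L
  while (b <= B) {
    rows <- c(sample(idx_int, length(idx_int), replace = TRUE),
              sample(idx_ctl, length(idx_ctl), replace = TRUE))
    d_b <- data[rows, , drop = FALSE]
    d_b$id <- sprintf("B%05d", seq_len(nrow(d_b)))
    sub_seed <- sample.int(2147480000L, 1)
    res <- tryCatch(run_once(d_b, m_boot, sub_seed), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > max_failures)
        stopf("bootstrap run error: %d resamples failed (last: %s)",
              failures, conditionMessage(res))
      next
    }
    pairs[b, ] <- c(res$delta_cost, res$delta_qaly)
    b <- b + 1L
  }
  ci <- apply(pairs, 2, quantile, probs = c(0.025, 0.975))
  structure(list(delta_cost = point$delta_cost,
                 delta_qaly = point$delta_qaly,
                 icer = icer(point$delta_cost, point$delta_qaly),
                 arm_means = point, pairs = pairs,
                 quadrant = quadrant_of(pairs[, 1], pairs[, 2]),
                 ci_delta_cost = ci[, "delta_cost"],
                 ci_delta_qaly = ci[, "delta_qaly"],
                 B = B, failures = failures, seed = seed,
                 horizon = horizon,
                 intervention_cost = intervention_cost),
            class = "cea_estimate")
}

#' @export
print.cea_estimate <- function(x, ...) {
  cat(sprintf("Cost-utility estimate over %d months (B = %d bootstrap pairs)\n",
              x$horizon, x$B))
  cat(sprintf("  delta cost : %0.2f GBP (95%% CI %0.2f to %0.2f)\n",
              x$delta_cost, x$ci_delta_cost[1], x$ci_delta_cost[2]))
  cat(sprintf("  delta QALY : %0.4f (95%% CI %0.4f to %0.4f)\n",
              x$delta_qaly, x$ci_delta_qaly[1], x$ci_delta_qaly[2]))
  print(x$icer)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability the intervention is
#' cost-effective is the fraction of bootstrap pairs with positive
#' incremental net monetary benefit, `lambda * delta_qaly - delta_cost > 0`
#' (strict inequality: exact zeros count as not cost-effective). Every
#' threshold is evaluated against the same pair set.
#'
#' @param est a `cea_estimate` (or a 2-column matrix of
#'   delta-cost/delta-QALY pairs).
#' @param thresholds GBP/QALY grid (default 0 to 200,000 in steps of 500).
#' @return data.frame of class `ceac_curve`: `threshold`,
#'   `prob_cost_effective`.
#' @export
ceac <- function(est, thresholds = seq(0, 200000, by = 500)) {
  pairs <- if (inherits(est, "cea_estimate")) est$pairs else as.matrix(est)
  if (!nrow(pairs)) stopf("empty bootstrap pair set")
  if (any(thresholds < 0)) stopf("thresholds must be >= 0")
  prob <- vapply(thresholds, function(l)
    mean(l * pairs[, 2] - pairs[, 1] > 0), numeric(1))
  structure(data.frame(threshold = thresholds,
                       prob_cost_effective = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Cost-effectiveness plane quadrant summary
#'
#' Counts bootstrap pairs per quadrant of the cost-effectiveness plane.
#' Boundary pairs follow the convention `delta_cost >= 0` is north and
#' `delta_qaly >= 0` is east (so the origin is NE).
#'
#' @param est a `cea_estimate` or 2-column pair matrix.
#' @return data.frame: `quadrant` (NE/NW/SE/SW), `count`, `fraction`.
#' @export
ce_plane_quadrants <- function(est) {
  pairs <- if (inherits(est, "cea_estimate")) est$pairs else as.matrix(est)
  q <- factor(quadrant_of(pairs[, 1], pairs[, 2]),
              levels = c("NE", "NW", "SE", "SW"))
  tab <- table(q)
  data.frame(quadrant = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / nrow(pairs))
}
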