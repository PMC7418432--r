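#' Deterministic item-level zero-fill
#'
#' Within each cost category (imputation group) and period, a missing
#' resource item is set to zero if and only if at least one *other* item in
#' the same category at the same period was completed — the respondent
#' evidently answered that section, so a blank item means no use. If every
#' item in the category is missing, the category stays missing and is left
#' to multiple imputation. Groups with a single item (hospitalisation) can
#' never be zero-filled. Pure and deterministic.
#'
#' @param data trial dataset with `<item>_<month>` count columns.
#' @param units a `unit_cost_table` defining the item -> group mapping.
#' @param periods assessment months to process (default all of 3/6/12 that
#'   are present).
#' @return the dataset with zero-filled items; attribute `"zero_fill_log"`
#'   counts filled cells per group-period.
#' @export
zero_fill_items <- function(data, units = default_unit_costs(),
                            periods = NULL) {
  stopifnot(inherits(units, "unit_cost_table"))
  if (is.null(periods)) {
    candidates <- c(3, 6, 12)
    periods <- candidates[vapply(candidates, function(p)
      any(item_count_col(units$item, p) %in% names(data)), logical(1))]
  }
  log <- list()
  for (g in unique(units$mi_group)) {
    items <- units$item[units$mi_group == g]
    for (p in periods) {
      cols <- intersect(item_count_col(items, p), names(data))
      if (length(cols) < 2) next  # no "other item" exists to license a zero
      m <- as.matrix(data[cols])
      n_obs <- rowSums(!is.na(m))
      fill <- is.na(m) & n_obs > 0
      m[fill] <- 0L
      data[cols] <- m
      log[[paste0(g, "_", p)]] <- sum(fill)
    }
  }
  attr(data, "zero_fill_log") <- unlist(log)
  data
}

#' Covariates of the default adjustment / imputation model
#'
#' Baseline utility and cost plus the demographic and medical-history
#' covariates adjusted for in the outcome models; the imputation models use
#' the same list (congeniality).
#'
#' @return character vector of column names.
#' @export
cea_covariates <- function() {
  c("u_0", "baseline_cost", "age", "gender", "hy_stage", "moca", "mmse",
    "diabetes", "mi_history", "ihd_history", "dbs_history", "carer")
}

#' Build the participant-level analysis frame
#'
#' Collapses item counts into category-level costs per period (`NA` where a
#' whole category is missing after zero-filling), and assembles the columns
#' the imputation and estimation stages work on: id, arm, covariates,
#' per-timepoint utilities and per-period category costs.
#'
#' @param data trial dataset (run [zero_fill_items()] first).
#' @param units a `unit_cost_table`.
#' @param horizon analysis horizon in months (6 or 12).
#' @param covariates baseline covariate columns to carry.
#' @param exclude_items resource items excluded from costing (scenario use).
#' @return data.frame of class `analysis_frame`; attribute `"cost_cols"`
#'   names the category-cost columns and `"u_cols"` the utility columns.
#' @export
build_analysis_frame <- function(data, units = default_unit_costs(),
                                 horizon = 6,
                                 covariates = cea_covariates(),
                                 exclude_items = NULL) {
  tp <- c(0, 3, 6, 12)
  tp <- tp[tp <= horizon]
  periods <- tp[tp > 0]
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stopf("dataset lacks covariate column(s): %s",
          paste(missing_cov, collapse = ", "))
  cc <- resource_category_costs(data, units, periods,
                                exclude_items = exclude_items)
  u_cols <- paste0("u_", tp)
  out <- cbind(
    data[c("id", "arm", covariates, "death_month",
           intersect("followed_12m", names(data)))],
    data[u_cols],
    cc[setdiff(names(cc), "id")]
  )
  out$arm <- factor(out$arm, levels = c("control", "intervention"))
  if ("gender" %in% names(out))
    out$gender <- factor(out$gender, levels = c("female", "male"))
  structure(out, cost_cols = setdiff(names(cc), "id"), u_cols = u_cols,
            horizon = horizon, class = c("analysis_frame", "data.frame"))
}

# ---- chained-equations PMM engine ------------------------------------------

# One PMM draw for a single variable: Bayesian linear regression on the
# observed rows, predicted means for observed rows under the posterior mean
# and for missing rows under a posterior draw, then type-1 matching to the k
# nearest donors.
pmm_draw <- function(y, X, mis, k) {
  obs <- !mis
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  n_obs <- length(yo)
  if (n_obs <= ncol(Xo) + 1) {
    # too few donors to fit the full model: fall back to intercept-only
    Xo <- Xo[, 1, drop = FALSE]
    X <- X[, 1, drop = FALSE]
  }
  qrx <- qr(Xo)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[mis, keep, drop = FALSE]
  fit <- .lm.fit(Xo, yo)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(n_obs - length(beta), 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  xtx_inv <- chol2inv(qr.R(qr(Xo)))
  cov_chol <- tryCatch(chol(sigma2 * xtx_inv), error = function(e) NULL)
  beta_star <- if (is.null(cov_chol)) beta else
    beta + as.numeric(t(cov_chol) %*% rnorm(length(beta)))
  pred_obs <- as.numeric(Xo %*% beta)
  pred_mis <- as.numeric(Xm %*% beta_star)
  kk <- min(k, n_obs)
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    donors <- order(d, runif(n_obs))[seq_len(kk)]  # random tie-break
    yo[donors[sample.int(kk, 1)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Imputes missing utilities and category-level costs separately within each
#' trial arm. Each of the `m` imputations initialises missing cells from
#' random observed draws, then cycles through the variables in temporal
#' order (utilities before costs, earlier periods first), regressing each on
#' the baseline covariates plus the current values of the other imputation
#' variables, and replacing missing values with the observed value of one of
#' the `k` donors whose predicted means are nearest (predictive mean
#' matching with a Bayesian parameter draw). Imputed values are therefore
#' always observed donor values: utilities stay within the value-set range
#' and costs stay non-negative by construction.
#'
#' @param frame an `analysis_frame` from [build_analysis_frame()].
#' @param m number of imputed datasets (default 50).
#' @param k donor pool size (default 5).
#' @param cycles chained-equation cycles per imputation (default 10).
#' @param covariates predictor columns (default [cea_covariates()]).
#' @param seed integer seed.
#' @return object of class `imputed_stack`: list with `imputations` (list of
#'   `m` completed frames), `mask` (logical missingness matrix), `vars`,
#'   and the imputation settings.
#' @export
impute_trial <- function(frame, m = 50, k = 5, cycles = 10,
                         covariates = cea_covariates(), seed = 1) {
  if (m < 1) stopf("imputation error: m must be >= 1")
  if (k < 1) stopf("imputation error: donor pool k must be >= 1")
  vars <- c(setdiff(attr(frame, "u_cols") %||%
                      grep("^u_", names(frame), value = TRUE), "u_0"),
            attr(frame, "cost_cols") %||%
              grep("^cost_", names(frame), value = TRUE))
  vars <- vars[vapply(vars, function(v) anyNA(frame[[v]]), logical(1))]
  mask <- as.matrix(is.na(frame[, vars, drop = FALSE]))
  rownames(mask) <- frame$id

  all_vars <- c(setdiff(attr(frame, "u_cols") %||% character(0), "u_0"),
                attr(frame, "cost_cols") %||% character(0))
  for (a in levels(frame$arm)) {
    rows <- frame$arm == a
    for (v in vars) {
      n_donor <- sum(!is.na(frame[[v]][rows]))
      if (n_donor < k)
        stopf("imputation error: variable '%s' has %d observed donors in the %s arm (need >= k = %d)",
              v, n_donor, a, k)
    }
  }
  if (!length(vars)) {
    return(structure(list(imputations = rep(list(frame), m), mask = mask,
                          vars = character(0), m = m, k = k,
                          cycles = cycles, seed = seed),
                     class = "imputed_stack"))
  }

  set.seed(derive_seed(seed, "impute"))
  pred_base <- intersect(covariates, names(frame))
  arm_rows <- lapply(levels(frame$arm), function(a) which(frame$arm == a))
  names(arm_rows) <- levels(frame$arm)
  # baseline covariates are complete, so their design block never changes
  base_mm <- lapply(arm_rows, function(rows)
    model.matrix(~ ., data = frame[rows, pred_base, drop = FALSE]))
  mis_by <- lapply(arm_rows, function(rows)
    lapply(setNames(vars, vars), function(v) is.na(frame[[v]][rows])))

  imputations <- vector("list", m)
  for (im in seq_len(m)) {
    comp <- frame
    # initial fill: random observed draw within arm
    for (a in levels(frame$arm)) {
      rows <- arm_rows[[a]]
      for (v in vars) {
        misr <- rows[mis_by[[a]][[v]]]
        if (length(misr))
          comp[[v]][misr] <- sample(frame[[v]][rows[!mis_by[[a]][[v]]]],
                                    length(misr), replace = TRUE)
      }
    }
    for (cyc in seq_len(cycles)) {
      for (v in vars) {
        others <- setdiff(all_vars, v)
        for (a in levels(frame$arm)) {
          rows <- arm_rows[[a]]
          mis <- mis_by[[a]][[v]]
          if (!any(mis)) next
          X <- cbind(base_mm[[a]],
                     as.matrix(comp[rows, others, drop = FALSE]))
          comp[[v]][rows][mis] <- pmm_draw(comp[[v]][rows], X, mis, k)
        }
      }
    }
    imputations[[im]] <- comp
  }
  structure(list(imputations = imputations, mask = mask, vars = vars,
                 m = m, k = k, cycles = cycles, seed = seed),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack: m =", x$m, "completed datasets\n")
  cat("  variables imputed:", if (length(x$vars))
    paste(x$vars, collapse = ", ") else "(none - data complete)", "\n")
  cat("  PMM donors k =", x$k, ", cycles =", x$cycles, "\n")
  invisible(x)
}
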