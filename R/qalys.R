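#' QALYs by the trapezoidal area-under-the-curve method
#'
#' Integrates a participant's utility trajectory over time, assuming linear
#' change between consecutive assessments; each trapezoid contributes
#' `(u_a + u_b)/2 * (months_b - months_a)/12` QALYs. Participants who died
#' have utility zero from the first scheduled assessment after the death
#' month (the trajectory supplied should already contain those zeros; they
#' are also enforced here from `death_month`).
#'
#' @param utilities numeric vector of utilities at `months`; no `NA` allowed
#'   within the horizon (impute first).
#' @param months assessment months, strictly increasing, starting at 0.
#' @param horizon analysis horizon in months; must be one of `months`.
#' @param death_month month of death, or `NA` if alive.
#' @return QALYs accrued over the horizon (years of full health).
#' @examples
#' auc_qalys(c(0.8, 0.8, 0.8), c(0, 3, 6), horizon = 6)   # 0.40
#' auc_qalys(c(1, 0.5, 0), c(0, 3, 6), horizon = 6)       # 0.25
#' @export
auc_qalys <- function(utilities, months, horizon = max(months),
                      death_month = NA) {
  if (length(utilities) != length(months))
    stopf("utilities and months differ in length")
  if (is.unsorted(months, strictly = TRUE) || months[1] != 0)
    stopf("months must be strictly increasing and start at 0")
  if (!horizon %in% months)
    stopf("horizon (%s months) must coincide with an assessment month",
          horizon)
  keep <- months <= horizon
  u <- utilities[keep]
  mo <- months[keep]
  if (!is.na(death_month)) u[mo > death_month] <- 0
  if (anyNA(u))
    stopf("missing utility within horizon at month(s) %s; impute first",
          paste(mo[is.na(u)], collapse = ", "))
  sum((head(u, -1) + u[-1]) / 2 * diff(mo) / 12)
}

#' Per-participant QALYs for a trial dataset
#'
#' Vectorised [auc_qalys()] over the rows of a wide-format trial dataset
#' (utility columns `u_<month>`, plus `death_month`).
#'
#' @param data a trial dataset or analysis frame.
#' @param horizon months (6 or 12 for the standard schedule 0/3/6/12).
#' @param timepoints assessment months present as `u_*` columns.
#' @return numeric vector of QALYs, one per row.
#' @export
compute_qalys <- function(data, horizon = 6, timepoints = c(0, 3, 6, 12)) {
  tp <- timepoints[timepoints <= horizon]
  cols <- paste0("u_", tp)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stopf("dataset lacks utility column(s): %s", paste(miss, collapse = ", "))
  um <- as.matrix(data[cols])
  dm <- if ("death_month" %in% names(data)) data$death_month else
    rep(NA_real_, nrow(data))
  vapply(seq_len(nrow(um)), function(i)
    auc_qalys(um[i, ], tp, horizon = horizon, death_month = dm[i]),
    numeric(1))
}
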