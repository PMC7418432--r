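#' Annual equivalent cost of a capital purchase
#'
#' Spreads a purchase cost `K` over an `n`-year lifespan as an equivalent
#' annual cost using the annuity factor `(1 - (1 + r)^-n) / r`; at `r = 0`
#' the factor is its limit `n`, so the annual cost is simply `K / n`.
#'
#' @param K purchase cost (GBP).
#' @param r annual discount rate as a fraction (default 0.035).
#' @param n lifespan in years (>= 1).
#' @return annual equivalent cost, full precision (round at reporting).
#' @examples
#' annuitize(11.99, 0.035, 2) # 6.3115... -> 6.31 at 2 d.p.
#' @export
annuitize <- function(K, r = 0.035, n) {
  if (any(K < 0)) stopf("annuitization: purchase cost K must be >= 0")
  if (any(r < 0)) stopf("annuitization: discount rate r must be >= 0")
  if (any(n < 1)) stopf("annuitization: lifespan n must be >= 1 year")
  factor <- ifelse(r == 0, n, (1 - (1 + r)^-n) / r)
  K / factor
}

#' Read an intervention costing ledger
#'
#' A ledger is a YAML file of line items grouped into sections (e.g.
#' therapist training, therapy sessions, patient equipment). Each item has a
#' unit cost and either a literal `quantity` or a `quantity_rule` expression
#' evaluated against `n_participants` and `n_sessions`; items may carry an
#' `annuitize` spec (`r`, `n`) converting a purchase cost to an annual
#' equivalent, and a `per_visit` flag marking quantities that scale with the
#' session count (used by [recost_sessions()]).
#'
#' @param path YAML ledger file.
#' @return an object of class `cost_ledger`.
#' @export
read_cost_ledger <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$n_participants) || raw$n_participants < 1)
    stopf("ledger must give n_participants >= 1")
  items <- list()
  for (section in names(raw$sections)) {
    for (it in raw$sections[[section]]) {
      if (is.null(it$label) || is.null(it$unit_cost))
        stopf("ledger item in section '%s' lacks label or unit_cost", section)
      if (it$unit_cost < 0)
        stopf("ledger error: item '%s' has negative unit cost", it$label)
      items[[length(items) + 1L]] <- list(
        section = section, label = it$label, unit_cost = it$unit_cost,
        quantity = it[["quantity"]] %||% NA_real_,
        quantity_rule = it[["quantity_rule"]] %||% NA_character_,
        per_visit = isTRUE(it$per_visit),
        annuitize_r = if (is.null(it[["annuitize"]])) NA_real_ else
          it[["annuitize"]][["rate"]] %||% 0.035,
        annuitize_n = if (is.null(it[["annuitize"]])) NA_real_ else
          it[["annuitize"]][["lifespan"]] %||%
            stopf("ledger error: annuitize spec for '%s' needs a lifespan",
                  it$label)
      )
    }
  }
  structure(list(currency = raw$currency %||% "GBP",
                 base_year = raw$base_year %||% NA,
                 n_participants = raw$n_participants,
                 n_sessions = raw$n_sessions %||% 12,
                 items = items),
            class = "cost_ledger")
}

#' Default intervention costing ledger
#'
#' The shipped ledger for a 12-session home-based physiotherapy programme
#' delivered to 238 participants (2016 GBP), covering therapist training,
#' per-visit session costs and shared patient equipment with annuitization.
#'
#' @return a `cost_ledger`.
#' @export
default_ledger <- function() {
  read_cost_ledger(system.file("extdata", "intervention_ledger.yaml",
                               package = "trialcea"))
}

# Evaluate a quantity rule in a minimal environment exposing only the ledger
# denominators and base arithmetic.
resolve_quantity <- function(item, ledger) {
  if (!is.na(item$quantity)) return(item$quantity)
  if (is.na(item$quantity_rule))
    stopf("ledger error: item '%s' has neither quantity nor quantity_rule",
          item$label)
  env <- list2env(list(n_participants = ledger$n_participants,
                       n_sessions = ledger$n_sessions),
                  parent = baseenv())
  q <- tryCatch(eval(parse(text = item$quantity_rule), env),
                error = function(e)
                  stopf("ledger error: cannot resolve quantity for item '%s': %s",
                        item$label, conditionMessage(e)))
  if (!is.numeric(q) || length(q) != 1 || !is.finite(q) || q < 0)
    stopf("ledger error: quantity rule for item '%s' did not yield a single non-negative number",
          item$label)
  q
}

#' Resolve a ledger into an audit table of item sums
#'
#' For each line item: the effective unit cost (annuitized where specified)
#' and the resolved quantity are reported at 2 d.p. — costing-table
#' convention, so printed unit cost x printed quantity reproduces each sum —
#' and multiplied to give the item sum.
#'
#' @param ledger a `cost_ledger`.
#' @return data.frame with columns `section`, `label`, `unit_cost`
#'   (effective, 2 d.p.), `quantity` (resolved, 2 d.p.), `sum` and
#'   `sum_2dp`.
#' @export
ledger_item_sums <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  rows <- lapply(ledger$items, function(it) {
    uc <- it$unit_cost
    if (!is.na(it$annuitize_n)) uc <- annuitize(uc, it$annuitize_r,
                                                it$annuitize_n)
    uc <- round2(uc)
    q <- round2(resolve_quantity(it, ledger))
    data.frame(section = it$section, label = it$label,
               unit_cost = uc, quantity = q, sum = uc * q,
               per_visit = it$per_visit)
  })
  out <- do.call(rbind, rows)
  out$sum_2dp <- round2(out$sum)
  out
}

#' Intervention cost per patient
#'
#' Total of all resolved ledger item sums divided by the number of
#' participants costed.
#'
#' @param ledger a `cost_ledger`.
#' @param audit if `TRUE`, attach the [ledger_item_sums()] table as
#'   attribute `"audit"`.
#' @return per-patient cost (full precision; report with [round2()]).
#' @export
intervention_cost_per_patient <- function(ledger, audit = FALSE) {
  if (ledger$n_participants <= 0)
    stopf("ledger error: n_participants must be positive")
  tab <- ledger_item_sums(ledger)
  out <- sum(tab$sum) / ledger$n_participants
  if (audit) attr(out, "audit") <- tab
  out
}

#' Re-cost the intervention for a different session count
#'
#' Scales per-visit items (therapist time, consumables, travel) to the new
#' number of sessions; fixed items (training, equipment) are unchanged.
#' Used for cost-reduction sensitivity scenarios; the QALY side of any
#' analysis is untouched.
#'
#' @param ledger a `cost_ledger`.
#' @param sessions new session count, between 1 and the ledger's count.
#' @return a `cost_ledger` with `n_sessions` replaced.
#' @export
recost_sessions <- function(ledger, sessions) {
  stopifnot(inherits(ledger, "cost_ledger"))
  if (!is.numeric(sessions) || length(sessions) != 1 ||
      sessions < 1 || sessions > ledger$n_sessions)
    stopf("config error: sessions must be a single count in 1..%d",
          ledger$n_sessions)
  ledger$n_sessions <- sessions
  ledger
}

#' Read a unit-cost table
#'
#' Maps each resource-use item to a unit cost, a costing category
#' (primary_care, secondary_care, social_care, medication) and an imputation
#' group (`nhs_ex_hosp`, `hospitalisation`, `social_care`) used for
#' category-level missing-data handling. Items flagged `excluded`
#' (medication) are costed for audit but left out of analysis totals.
#'
#' @param path YAML unit-cost file.
#' @return data.frame of class `unit_cost_table` with columns `item`,
#'   `unit_cost`, `category`, `mi_group`, `excluded`, `routine_physio`.
#' @export
read_unit_costs <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$items) || !length(raw$items))
    stopf("unit-cost file has no items")
  rows <- lapply(names(raw$items), function(nm) {
    it <- raw$items[[nm]]
    if (is.null(it$unit_cost) || it$unit_cost < 0)
      stopf("unit-cost error: item '%s' needs a non-negative unit_cost", nm)
    data.frame(item = nm, unit_cost = it$unit_cost,
               category = it$category %||% "primary_care",
               mi_group = it$mi_group %||% "nhs_ex_hosp",
               excluded = isTRUE(it$excluded),
               routine_physio = isTRUE(it$routine_physio))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("unit_cost_table", "data.frame")
  attr(out, "base_year") <- raw$base_year %||% NA
  attr(out, "currency") <- raw$currency %||% "GBP"
  out
}

#' Default (synthetic) unit-cost table
#'
#' Illustrative 2016-GBP unit costs for the standard resource items; real
#' analyses should supply a table sourced from national unit-cost schedules.
#'
#' @return a `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  read_unit_costs(system.file("extdata", "unit_costs_synthetic.yaml",
                              package = "trialcea"))
}

item_count_col <- function(item, period) paste0(item, "_", period)

#' Cost routine resource use by category
#'
#' Per participant: category cost = sum over that category's items of
#' count x unit cost, within the requested periods. Medication is costed
#' but excluded from `total`; the total is primary + secondary + social
#' care, plus the per-patient intervention cost for intervention-arm rows
#' when supplied.
#'
#' @param data trial dataset with `<item>_<month>` count columns.
#' @param units a `unit_cost_table`.
#' @param periods assessment months covering the horizon (default `c(3, 6)`).
#' @param intervention_cost per-patient intervention cost added to
#'   intervention-arm totals (default 0 = not added).
#' @param exclude_items item names to drop (e.g. `"physio_visit"` for the
#'   routine-physiotherapy exclusion scenario).
#' @return data.frame: `id`, one column per costing category, `total`.
#'   `NA` counts propagate to their category (cost unknown until imputed).
#' @export
cost_resource_use <- function(data, units, periods = c(3, 6),
                              intervention_cost = 0, exclude_items = NULL) {
  stopifnot(inherits(units, "unit_cost_table"))
  units <- units[!units$item %in% exclude_items, ]
  needed <- as.vector(outer(units$item, periods, item_count_col))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stopf("mapping error: dataset lacks resource columns: %s",
          paste(missing_cols, collapse = ", "))
  out <- data.frame(id = data$id)
  for (cat in unique(units$category)) {
    items <- units$item[units$category == cat]
    cols <- as.vector(outer(items, periods, item_count_col))
    ucost <- rep(units$unit_cost[match(items, units$item)], length(periods))
    m <- as.matrix(data[cols])
    out[[cat]] <- as.numeric(m %*% ucost)
  }
  incl <- setdiff(unique(units$category[!units$excluded]), character(0))
  out$total <- rowSums(out[, incl, drop = FALSE])
  if (intervention_cost != 0)
    out$total <- out$total +
      ifelse(data$arm == "intervention", intervention_cost, 0)
  out
}

#' Per-period imputation-group costs
#'
#' Builds the category-level cost variables used for missing-data handling:
#' for each imputation group (NHS excluding hospitalisation, hospitalisation,
#' social care) and period, the sum of count x unit cost. If any item in the
#' group is still missing for a participant-period (after zero-filling), the
#' group cost is `NA` and is left to multiple imputation. Excluded
#' (medication) items are not part of any analysis group.
#'
#' @inheritParams cost_resource_use
#' @return data.frame with `id` and `cost_<mi_group>_<period>` columns.
#' @export
resource_category_costs <- function(data, units, periods = c(3, 6),
                                    exclude_items = NULL) {
  stopifnot(inherits(units, "unit_cost_table"))
  units <- units[!units$excluded & !units$item %in% exclude_items, ]
  out <- data.frame(id = data$id)
  for (g in unique(units$mi_group)) {
    items <- units$item[units$mi_group == g]
    ucost <- units$unit_cost[units$mi_group == g]
    for (p in periods) {
      cols <- item_count_col(items, p)
      missing_cols <- setdiff(cols, names(data))
      if (length(missing_cols))
        stopf("mapping error: dataset lacks resource columns: %s",
              paste(missing_cols, collapse = ", "))
      m <- as.matrix(data[cols])
      out[[paste0("cost_", g, "_", p)]] <- as.numeric(m %*% ucost)
    }
  }
  out
}
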