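#' Default service-use profile for the synthetic generator
#'
#' Per-item 3-monthly count intensities (conditional on the category being
#' used at all) and category use probabilities, calibrated so a control-arm
#' participant accrues routine NHS + social-care costs of about 3,000 GBP
#' over 6 months under the default unit costs, with a heavy right tail
#' driven by hospitalisation.
#'
#' @return list with elements `items` (data.frame: `item`, `block`, `rate`)
#'   and `use_prob` (named vector of per-period category use probabilities).
#' @export
default_service_profile <- function() {
  list(
    items = data.frame(
      item = c("gp_visit", "nurse_visit", "physio_visit", "ambulance",
               "outpatient_visit", "hospital_day", "home_care_visit",
               "meals_on_wheels", "medication"),
      block = c("primary", "primary", "primary", "secondary", "secondary",
                "hospital", "social", "social", "medication"),
      rate = c(3.3, 2.2, 1.7, 0.3, 2.4, 11, 30, 20, 3)
    ),
    use_prob = c(primary = 0.90, secondary = 0.50, hospital = 0.12,
                 social = 0.45, medication = 0.80)
  )
}

#' Configuration for the synthetic two-arm trial generator
#'
#' Defines the study conditions the generator emulates: a two-arm trial with
#' assessments at 0/3/6/12 months, small per-timepoint utility differences,
#' skewed zero-inflated service-use costs, occasional deaths, MAR
#' missingness that is heavier in the intervention arm at 6 months, and
#' ~50% attrition at 12 months.
#'
#' @param n_intervention,n_control arm sizes (defaults 238 / 236).
#' @param timepoints assessment months, strictly increasing from 0.
#' @param true_utility_effect per-timepoint utility difference attributable
#'   to the intervention (same length as `timepoints`, first entry 0).
#' @param utility_baseline_mean,utility_baseline_sd baseline utility
#'   distribution (normal, censored to the value-set range).
#' @param utility_drift per-timepoint mean change from baseline shared by
#'   both arms (gradual decline by default).
#' @param utility_noise_sd assessment-level noise around the participant's
#'   latent baseline.
#' @param utility_floor,utility_ceiling value-set bounds for censoring.
#' @param cost_shape shape of the mean-1 gamma frailty multiplying count
#'   intensities; values < 1 give the long right tail typical of service-use
#'   costs.
#' @param service_profile see [default_service_profile()].
#' @param true_cost_effect extra expected routine NHS cost (GBP) in the
#'   intervention arm over the 6-month horizon, spread evenly over follow-up
#'   periods (sustained at the same per-period rate beyond 6 months).
#' @param death_hazard per-follow-up-period death probability.
#' @param missing_prob list with matrices `utility` and `costs`
#'   (rows intervention/control, columns follow-up timepoints): baseline MAR
#'   missingness probabilities, shifted per participant by age and baseline
#'   utility.
#' @param item_skip probability an individual resource item is skipped even
#'   when the rest of its questionnaire section was completed (exercises the
#'   item-level zero-fill rule).
#' @param attrition_12m fraction of surviving participants with no 12-month
#'   follow-up at all.
#' @param mar_beta_age,mar_beta_u0 log-odds shifts per SD of age / baseline
#'   utility in the MAR mechanism.
#' @param unit_costs unit-cost table used to cost the baseline period and to
#'   calibrate `true_cost_effect`.
#' @param generate_states if `TRUE`, also draw 5-digit EQ-5D-3L states and
#'   derive utilities by scoring them (for testing the scoring module);
#'   utility effects/drift are ignored in this mode.
#' @param seed integer seed; all generator randomness derives from it.
#' @return validated `sim_config` object.
#' @export
sim_config <- function(n_intervention = 238, n_control = 236,
                       timepoints = c(0, 3, 6, 12),
                       true_utility_effect = c(0, 0.020, 0.031, 0.017),
                       utility_baseline_mean = 0.69,
                       utility_baseline_sd = 0.21,
                       utility_drift = c(0, -0.02, -0.04, -0.06),
                       utility_noise_sd = 0.15,
                       utility_floor = -0.594, utility_ceiling = 1,
                       cost_shape = 0.8,
                       service_profile = default_service_profile(),
                       true_cost_effect = 0,
                       death_hazard = 0.01,
                       missing_prob = NULL,
                       item_skip = 0.03,
                       attrition_12m = 0.5,
                       mar_beta_age = 0.25, mar_beta_u0 = -0.4,
                       unit_costs = default_unit_costs(),
                       generate_states = FALSE,
                       seed = 1) {
  if (n_intervention < 2 || n_control < 2)
    stopf("configuration error: n_intervention and n_control must be >= 2")
  if (length(timepoints) < 2 || timepoints[1] != 0 ||
      is.unsorted(timepoints, strictly = TRUE))
    stopf("configuration error: timepoints must be strictly increasing and start at 0")
  nt <- length(timepoints)
  if (length(true_utility_effect) != nt || true_utility_effect[1] != 0)
    stopf("configuration error: true_utility_effect must match timepoints with first entry 0")
  if (length(utility_drift) != nt || utility_drift[1] != 0)
    stopf("configuration error: utility_drift must match timepoints with first entry 0")
  assert_prob(death_hazard, "death_hazard")
  assert_prob(item_skip, "item_skip")
  assert_prob(attrition_12m, "attrition_12m")
  if (utility_baseline_sd <= 0 || utility_noise_sd < 0 || cost_shape <= 0)
    stopf("configuration error: utility_baseline_sd, cost_shape must be > 0 and utility_noise_sd >= 0")
  if (is.null(missing_prob)) {
    fu <- nt - 1L
    u <- matrix(0, 2, fu, dimnames = list(c("intervention", "control"),
                                          timepoints[-1]))
    defaults_int <- c(0.10, 0.21, 0.15)
    defaults_ctl <- c(0.08, 0.10, 0.15)
    u["intervention", ] <- defaults_int[seq_len(fu)]
    u["control", ] <- defaults_ctl[seq_len(fu)]
    missing_prob <- list(utility = u, costs = u)
  }
  for (nm in c("utility", "costs")) {
    m <- missing_prob[[nm]]
    if (!is.matrix(m) || nrow(m) != 2 || ncol(m) != nt - 1)
      stopf("configuration error: missing_prob$%s must be a 2 x %d matrix", nm, nt - 1)
    assert_prob(m, paste0("missing_prob$", nm))
  }
  structure(
    list(n_intervention = n_intervention, n_control = n_control,
         timepoints = timepoints, true_utility_effect = true_utility_effect,
         utility_baseline_mean = utility_baseline_mean,
         utility_baseline_sd = utility_baseline_sd,
         utility_drift = utility_drift, utility_noise_sd = utility_noise_sd,
         utility_floor = utility_floor, utility_ceiling = utility_ceiling,
         cost_shape = cost_shape, service_profile = service_profile,
         true_cost_effect = true_cost_effect, death_hazard = death_hazard,
         missing_prob = missing_prob, item_skip = item_skip,
         attrition_12m = attrition_12m,
         mar_beta_age = mar_beta_age, mar_beta_u0 = mar_beta_u0,
         unit_costs = unit_costs, generate_states = generate_states,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Expected per-period cost by service block for a control-arm participant:
# use_prob * sum(rate * unit_cost); gamma frailty has mean 1.
expected_block_cost <- function(config, exclude_medication = TRUE) {
  sp <- config$service_profile
  uc <- config$unit_costs
  blocks <- unique(sp$items$block)
  if (exclude_medication) blocks <- setdiff(blocks, "medication")
  out <- vapply(blocks, function(b) {
    it <- sp$items[sp$items$block == b, ]
    u <- uc$unit_cost[match(it$item, uc$item)]
    if (anyNA(u)) stopf("unit-cost table lacks item(s): %s",
                        paste(it$item[is.na(u)], collapse = ", "))
    sp$use_prob[[b]] * sum(it$rate * u)
  }, numeric(1))
  setNames(out, blocks)
}

# NHS blocks carry the intervention's routine-cost effect.
NHS_BLOCKS <- c("primary", "secondary", "hospital")

# Per-period rate multiplier for the intervention arm implementing
# true_cost_effect (additive GBP per 6 months => /2 per 3-month period).
cost_effect_multiplier <- function(config) {
  if (config$true_cost_effect == 0) return(1)
  e_nhs <- sum(expected_block_cost(config)[NHS_BLOCKS])
  1 + (config$true_cost_effect / 2) / e_nhs
}

draw_period_counts <- function(n, config, multiplier = 1) {
  sp <- config$service_profile
  out <- matrix(0L, n, nrow(sp$items),
                dimnames = list(NULL, sp$items$item))
  for (b in unique(sp$items$block)) {
    it <- sp$items[sp$items$block == b, ]
    used <- rbinom(n, 1, sp$use_prob[[b]])
    g <- rgamma(n, shape = config$cost_shape, rate = config$cost_shape)
    f <- if (b %in% NHS_BLOCKS) multiplier else 1
    for (j in seq_len(nrow(it)))
      out[, it$item[j]] <- used * rpois(n, it$rate[j] * f * g)
  }
  out
}

# Fixed marginal level probabilities per dimension for the optional
# state-generation mode (scoring-module testing only).
STATE_LEVEL_PROBS <- matrix(
  c(0.45, 0.50, 0.05,
    0.70, 0.25, 0.05,
    0.50, 0.42, 0.08,
    0.35, 0.55, 0.10,
    0.55, 0.38, 0.07),
  nrow = 5, byrow = TRUE,
  dimnames = list(c("mobility", "self_care", "usual_activities",
                    "pain_discomfort", "anxiety_depression"), 1:3))

draw_states <- function(n) {
  m <- vapply(rownames(STATE_LEVEL_PROBS), function(d)
    sample.int(3, n, replace = TRUE, prob = STATE_LEVEL_PROBS[d, ]),
    integer(n))
  apply(m, 1, paste0, collapse = "")
}

#' Simulate a complete synthetic two-arm trial
#'
#' Generates a complete (pre-missingness) participant-level dataset in the
#' wide format the pipeline consumes, with the true incremental utility and
#' cost effects recorded as metadata. Deterministic given the config seed.
#'
#' The `"truth"` attribute records the *analytic* per-timepoint arm utility
#' means (closed-form mean of a normal censored to the value-set range), the
#' implied incremental QALYs over 6 and 12 months by the trapezoid rule, the
#' routine-cost increments, and the expected control-arm per-period cost by
#' category. With a nonzero death hazard the analytic utility/cost truths
#' are conditional on survival.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `trial_data`; attribute `"truth"` carries the
#'   generator metadata.
#' @export
simulate_trial <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(derive_seed(config$seed, "simulate"))
  n_int <- config$n_intervention
  n_ctl <- config$n_control
  n <- n_int + n_ctl
  arm <- rep(c("intervention", "control"), c(n_int, n_ctl))
  tp <- config$timepoints
  fu <- tp[-1]

  dat <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    arm = arm,
    age = round(rnorm(n, 72, 7.7), 1),
    gender = sample(c("female", "male"), n, replace = TRUE,
                    prob = c(0.35, 0.65)),
    hy_stage = sample(2:4, n, replace = TRUE, prob = c(0.3, 0.5, 0.2)),
    moca = pmin(pmax(round(rnorm(n, 23, 3)), 10), 30),
    mmse = pmin(pmax(round(rnorm(n, 27, 1.8)), 24), 30),
    diabetes = rbinom(n, 1, 0.10),
    mi_history = rbinom(n, 1, 0.08),
    ihd_history = rbinom(n, 1, 0.12),
    dbs_history = rbinom(n, 1, 0.05),
    carer = rbinom(n, 1, 0.60),
    updrs = pmin(pmax(round(rnorm(n, 32, 16)), 5), 80),
    fog = rbinom(n, 1, ifelse(arm == "intervention", 0.64, 0.59)),
    falls_12m = rnbinom(n, size = 1.5, mu = 4),
    stringsAsFactors = FALSE
  )

  # deaths: per-period hazard, death month uniform within the period
  death_month <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  for (k in seq_along(fu)) {
    dies <- alive & rbinom(n, 1, config$death_hazard) == 1
    lo <- if (k == 1) 0 else fu[k - 1]
    death_month[dies] <- round(runif(sum(dies), lo, fu[k]), 1)
    alive <- alive & !dies
  }
  dat$death_month <- death_month

  # utilities: latent baseline + drift + arm effect, censored to value range
  is_int <- arm == "intervention"
  if (config$generate_states) {
    set.seed(derive_seed(config$seed, "states"))
    for (j in seq_along(tp)) {
      st <- draw_states(n)
      dat[[paste0("eq5d_", tp[j])]] <- st
      dat[[paste0("u_", tp[j])]] <- score_eq5d(st)
    }
  } else {
    b <- rnorm(n, config$utility_baseline_mean, config$utility_baseline_sd)
    dat$u_0 <- clip(b, config$utility_floor, config$utility_ceiling)
    for (j in seq_along(fu)) {
      mu <- b + config$utility_drift[j + 1] +
        config$true_utility_effect[j + 1] * is_int
      dat[[paste0("u_", fu[j])]] <-
        clip(rnorm(n, mu, config$utility_noise_sd),
             config$utility_floor, config$utility_ceiling)
    }
  }

  # baseline (pre-randomisation) service use, costed into one covariate
  mult <- cost_effect_multiplier(config)
  uc <- config$unit_costs
  base_counts <- draw_period_counts(n, config, multiplier = 1)
  keep <- uc$item[!uc$excluded]
  bu <- uc$unit_cost[match(keep, uc$item)]
  dat$baseline_cost <- as.numeric(base_counts[, keep, drop = FALSE] %*% bu)

  # follow-up resource use
  for (p in fu) {
    cnt <- draw_period_counts(n, config,
                              multiplier = ifelse(is_int, mult, 1))
    for (item in colnames(cnt))
      dat[[item_count_col(item, p)]] <- cnt[, item]
  }

  # death rule: zeros from the first assessment after the death month
  for (p in fu) {
    gone <- !is.na(death_month) & death_month < p
    dat[[paste0("u_", p)]][gone] <- 0
    if (config$generate_states)
      dat[[paste0("eq5d_", p)]][gone] <- NA_character_
    for (item in config$service_profile$items$item)
      dat[[item_count_col(item, p)]][gone] <- 0L
  }

  # 12-month follow-up flag (deaths have known outcomes, so count as followed)
  if (max(tp) >= 12) {
    dat$followed_12m <- as.integer(
      rbinom(n, 1, 1 - config$attrition_12m) == 1 | !is.na(death_month))
  } else dat$followed_12m <- 1L

  truth <- generator_truth(config)
  truth$n <- n
  structure(dat, truth = truth, sim_config = config,
            class = c("trial_data", "data.frame"))
}

# Analytic truth metadata (exact when death_hazard = 0 and states mode off).
generator_truth <- function(config) {
  tp <- config$timepoints
  s_fu <- sqrt(config$utility_baseline_sd^2 + config$utility_noise_sd^2)
  mean_at <- function(j, eff) {
    if (j == 1)
      cens_norm_mean(config$utility_baseline_mean, config$utility_baseline_sd,
                     config$utility_floor, config$utility_ceiling)
    else
      cens_norm_mean(config$utility_baseline_mean + config$utility_drift[j] +
                       eff * config$true_utility_effect[j],
                     s_fu, config$utility_floor, config$utility_ceiling)
  }
  m_int <- vapply(seq_along(tp), mean_at, numeric(1), eff = 1)
  m_ctl <- vapply(seq_along(tp), mean_at, numeric(1), eff = 0)
  trap <- function(diffs, months, horizon) {
    keep <- months <= horizon
    d <- diffs[keep]; mo <- months[keep]
    sum((head(d, -1) + d[-1]) / 2 * diff(mo) / 12)
  }
  horizons <- tp[tp > 0]
  delta_qaly <- setNames(
    vapply(horizons, function(h) trap(m_int - m_ctl, tp, h), numeric(1)),
    paste0("h", horizons))
  per_period_cost_effect <- config$true_cost_effect / 2
  n_periods <- setNames(vapply(horizons, function(h) sum(tp > 0 & tp <= h),
                               numeric(1)), paste0("h", horizons))
  list(
    utility_means = rbind(intervention = m_int, control = m_ctl),
    timepoints = tp,
    delta_qaly = delta_qaly,
    delta_cost_routine = per_period_cost_effect * n_periods,
    expected_period_cost_control = expected_block_cost(config),
    true_utility_effect = config$true_utility_effect,
    true_cost_effect = config$true_cost_effect
  )
}

#' Delete values under a MAR mechanism
#'
#' Sets follow-up utilities and resource-use items to missing with
#' probabilities that depend only on arm, timepoint and observed baseline
#' data (age and baseline utility), i.e. missing at random. Questionnaire
#' non-response removes a whole period's items at once; an independent
#' item-skip mechanism additionally blanks single items (feeding the
#' zero-fill rule). Participants not followed to 12 months lose all
#' 12-month values. Death-implied zeros are never deleted, and baseline is
#' always complete. The complete input is retained as attribute
#' `"complete"` for recovery tests.
#'
#' @param data a complete `trial_data` from [simulate_trial()].
#' @param config the same [sim_config()].
#' @return `trial_data` with `NA`s; attributes `"complete"` (the input) and
#'   `"truth"` carried over.
#' @export
apply_missingness <- function(data, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "missing"))
  fu <- config$timepoints[-1]
  n <- nrow(data)
  z_age <- as.numeric(scale(data$age))
  z_u0 <- as.numeric(scale(data$u_0))
  items <- config$service_profile$items$item
  out <- data

  for (k in seq_along(fu)) {
    p <- fu[k]
    protected <- !is.na(data$death_month) & data$death_month < p
    not_followed <- p >= 12 & data$followed_12m == 0L

    for (layer in c("utility", "costs")) {
      base <- config$missing_prob[[layer]][, k]
      shift <- config$mar_beta_age * z_age + config$mar_beta_u0 * z_u0
      # calibrate the intercept per arm so the marginal missingness rate
      # equals the configured probability despite the covariate shifts
      pr <- numeric(n)
      for (a in c("intervention", "control")) {
        rows <- data$arm == a
        if (base[[a]] <= 0) { pr[rows] <- 0; next }
        if (base[[a]] >= 1) { pr[rows] <- 1; next }
        ic <- uniroot(function(cc) mean(plogis(cc + shift[rows])) - base[[a]],
                      interval = c(-30, 30))$root
        pr[rows] <- plogis(ic + shift[rows])
      }
      mis <- rbinom(n, 1, pr) == 1 | not_followed
      mis[protected] <- FALSE
      if (layer == "utility") {
        out[[paste0("u_", p)]][mis] <- NA_real_
        if (config$generate_states && paste0("eq5d_", p) %in% names(out))
          out[[paste0("eq5d_", p)]][mis] <- NA_character_
      } else {
        skip <- matrix(rbinom(n * length(items), 1, config$item_skip) == 1,
                       n, length(items))
        for (j in seq_along(items)) {
          col <- item_count_col(items[j], p)
          gone <- (mis | skip[, j]) & !protected
          out[[col]][gone] <- NA_integer_
        }
      }
    }
  }
  structure(out, complete = data, truth = attr(data, "truth"),
            sim_config = config, class = class(data))
}
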