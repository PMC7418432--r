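# Shared fixtures: all built in code at test time.

# Data-frame comparison that ignores generator metadata attributes.
bare <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}

# A unit-cost table whose single category has exactly three items.
three_item_units <- function() {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    "items:",
    "  svc_a: {unit_cost: 10, category: primary_care, mi_group: gx}",
    "  svc_b: {unit_cost: 20, category: primary_care, mi_group: gx}",
    "  svc_c: {unit_cost: 30, category: primary_care, mi_group: gx}"), tmp)
  read_unit_costs(tmp)
}

# Zero-probability missingness matrix for a given number of follow-ups.
no_missing <- function(n_fu = 3) {
  m <- matrix(0, 2, n_fu,
              dimnames = list(c("intervention", "control"), NULL))
  list(utility = m, costs = m)
}

# Small, fast, death-free, fully observed trial.
complete_config <- function(n = 40, seed = 1, ...) {
  sim_config(n_intervention = n, n_control = n, death_hazard = 0,
             missing_prob = no_missing(), item_skip = 0, attrition_12m = 0,
             seed = seed, ...)
}

# Small trial with the default missingness pattern.
mar_config <- function(n = 60, seed = 1, ...) {
  sim_config(n_intervention = n, n_control = n, death_hazard = 0,
             seed = seed, ...)
}

small_trial <- function(n = 40, seed = 1, ...) {
  simulate_trial(complete_config(n = n, seed = seed, ...))
}

# Reduced covariate set so GLMs fit on tiny fixtures.
tiny_spec <- function() cea_model_spec(covariates = c("age", "u_0"))

# Hand-built 10-participant dataset (5 per arm), complete, no deaths.
toy_trial <- function() {
  set.seed(99)
  n <- 10
  d <- data.frame(
    id = sprintf("T%02d", 1:n),
    arm = rep(c("intervention", "control"), each = 5),
    age = c(70, 65, 80, 72, 68, 74, 71, 77, 69, 75),
    gender = rep(c("female", "male"), 5),
    hy_stage = rep(3, n), moca = rep(24, n), mmse = rep(27, n),
    diabetes = 0, mi_history = 0, ihd_history = 0, dbs_history = 0,
    carer = 1, updrs = seq(20, 47, by = 3), fog = rep(c(0, 1), 5),
    falls_12m = rep(2, n),
    baseline_cost = c(100, 0, 250, 80, 120, 90, 60, 300, 40, 150),
    death_month = NA_real_, followed_12m = 1L,
    u_0 = c(.8, .7, .6, .9, .75, .85, .65, .7, .8, .72),
    u_3 = c(.82, .68, .63, .88, .77, .8, .6, .71, .78, .7),
    u_6 = c(.8, .66, .6, .85, .74, .78, .62, .7, .75, .69),
    stringsAsFactors = FALSE
  )
  for (item in default_unit_costs()$item) {
    for (p in c(3, 6)) {
      d[[paste0(item, "_", p)]] <- rpois(n, 1)
    }
  }
  class(d) <- c("trial_data", "data.frame")
  d
}
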