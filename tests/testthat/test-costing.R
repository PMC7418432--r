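test_that("annuitization follows the annuity-factor formula with its r -> 0 limit", {
  # closed form: K / [(1 - (1+r)^-n) / r]
  expect_equal(annuitize(11.99, 0.035, 2),
               11.99 / ((1 - 1.035^-2) / 0.035), tolerance = 1e-12)
  expect_equal(round2(annuitize(11.99, 0.035, 2)), 6.31)
  expect_equal(annuitize(10, 0, 1), 10)
  expect_equal(annuitize(100, 0.035, 1), 103.5)
  # per-year cost tends to K/n as r -> 0
  expect_equal(annuitize(50, 1e-10, 4), 50 / 4, tolerance = 1e-6)
  expect_error(annuitize(-1, 0.035, 2), "K must be")
  expect_error(annuitize(1, -0.1, 2), "r must be")
  expect_error(annuitize(1, 0.035, 0.5), "n must be")
})

test_that("default ledger reproduces every printed line-item sum", {
  tab <- ledger_item_sums(default_ledger())
  sums <- setNames(tab$sum_2dp, tab$label)
  expect_equal(sums[["trainer_time"]], 288.75)
  expect_equal(sums[["room_hire"]], 300)
  expect_equal(sums[["training_materials"]], 49)
  expect_equal(sums[["therapist_time"]], 124578.72)
  expect_equal(sums[["consumables"]], 3427.20)
  expect_equal(sums[["travel"]], 22848)
  expect_equal(sums[["printed_materials"]], 476)
  expect_equal(sums[["dvds"]], 19.04)
  expect_equal(sums[["weighted_vests"]], 1289.01)
  expect_equal(sums[["balance_pads"]], 1154.90)
  expect_equal(sums[["step_counts"]], 100.14)
  # annuitized effective unit cost and apportioned quantities as printed
  expect_equal(tab$unit_cost[tab$label == "step_counts"], 6.31)
  expect_equal(tab$quantity[tab$label == "weighted_vests"], 23.8)
  expect_equal(tab$quantity[tab$label == "balance_pads"], 59.5)
  expect_equal(tab$quantity[tab$label == "step_counts"], 15.87)
})

test_that("per-patient intervention cost matches an independent spreadsheet-style sum", {
  # oracle: item sums recomputed by hand from the printed table
  oracle <- sum(288.75, 300, 49, 43.62 * 238 * 12, 1.20 * 238 * 12,
                8 * 238 * 12, 2 * 238, 0.08 * 238, 54.16 * 23.8,
                19.41 * 59.5, 6.31 * 15.87) / 238
  got <- intervention_cost_per_patient(default_ledger())
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(round2(got), 649.29)
})

test_that("ledger arithmetic is linear and handles degenerate items", {
  led <- default_ledger()
  # single per-participant two-pound item
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 10", "sections:", "  s:",
               "    - label: thing", "      unit_cost: 2.00",
               "      quantity_rule: n_participants"), tmp)
  single <- read_cost_ledger(tmp)
  expect_equal(intervention_cost_per_patient(single), 2)
  # zero quantity gives a zero sum
  writeLines(c("n_participants: 10", "sections:", "  s:",
               "    - label: unused", "      unit_cost: 99",
               "      quantity: 0"), tmp)
  expect_equal(ledger_item_sums(read_cost_ledger(tmp))$sum, 0)
  # homogeneity: doubling all unit costs doubles the per-patient cost
  led2 <- led
  led2$items <- lapply(led$items, function(it) {
    it$unit_cost <- it$unit_cost * 2
    it
  })
  expect_equal(intervention_cost_per_patient(led2),
               2 * intervention_cost_per_patient(led), tolerance = 1e-9)
  # unresolvable quantity rule names the item
  writeLines(c("n_participants: 10", "sections:", "  s:",
               "    - label: broken", "      unit_cost: 1",
               "      quantity_rule: nonsense_variable"), tmp)
  expect_error(ledger_item_sums(read_cost_ledger(tmp)), "broken")
})

test_that("session recosting scales per-visit items only", {
  led <- default_ledger()
  expect_equal(ledger_item_sums(recost_sessions(led, 12)),
               ledger_item_sums(led))
  t12 <- ledger_item_sums(led)
  t8 <- ledger_item_sums(recost_sessions(led, 8))
  pv <- t12$per_visit
  expect_equal(t8$sum[pv], t12$sum[pv] * 8 / 12, tolerance = 1e-12)
  expect_equal(t8$sum[!pv], t12$sum[!pv])
  # per-patient cost at 8 sessions drops by 4 visits of (43.62 + 1.20 + 8)
  expect_equal(intervention_cost_per_patient(recost_sessions(led, 8)),
               intervention_cost_per_patient(led) - 4 * (43.62 + 1.20 + 8),
               tolerance = 1e-9)
  expect_error(recost_sessions(led, 0), "sessions")
  expect_error(recost_sessions(led, 13), "sessions")
})

test_that("resource-use costing sums counts times unit costs by category", {
  d <- toy_trial()
  units <- default_unit_costs()
  # all-zero counts cost zero in every category
  d0 <- d
  for (col in grep("_(3|6)$", names(d0), value = TRUE)) d0[[col]] <- 0L
  cc0 <- cost_resource_use(d0, units)
  expect_true(all(cc0[setdiff(names(cc0), "id")] == 0))
  # two GP visits and nothing else: primary care = 2u, total = 2u
  d1 <- d0
  d1$gp_visit_3 <- c(2, rep(0, 9))
  u_gp <- units$unit_cost[units$item == "gp_visit"]
  cc1 <- cost_resource_use(d1, units)
  expect_equal(cc1$primary_care[1], 2 * u_gp)
  expect_equal(cc1$total[1], 2 * u_gp)
  # medication is costed but excluded from the total
  d2 <- d0
  d2$medication_3 <- 4
  cc2 <- cost_resource_use(d2, units)
  expect_true(all(cc2$medication > 0))
  expect_true(all(cc2$total == 0))
  # additivity: total = included category sum, every participant
  cc <- cost_resource_use(d, units)
  expect_equal(cc$total,
               cc$primary_care + cc$secondary_care + cc$social_care)
  # intervention cost lands only on intervention-arm participants
  cci <- cost_resource_use(d, units, intervention_cost = 100)
  expect_equal(cci$total - cc$total,
               ifelse(d$arm == "intervention", 100, 0))
  # homogeneity in unit costs
  units2 <- units
  units2$unit_cost <- units2$unit_cost * 3
  expect_equal(cost_resource_use(d, units2)$total, cc$total * 3)
  # unmapped item errors with its name
  d3 <- d
  d3$gp_visit_3 <- NULL
  expect_error(cost_resource_use(d3, units), "gp_visit_3")
})

test_that("category costs against the generator's analytic expectation", {
  cfg <- complete_config(n = 3000, seed = 21)
  d <- simulate_trial(cfg)
  truth <- attr(d, "truth")$expected_period_cost_control
  units <- default_unit_costs()
  ctl <- d[d$arm == "control", ]
  cc <- cost_resource_use(ctl, units, periods = 3)
  # expected primary-care cost per 3-month period, from the profile
  exp_primary <- truth[["primary"]]
  se <- sd(cc$primary_care) / sqrt(nrow(ctl))
  expect_lt(abs(mean(cc$primary_care) - exp_primary), 3 * se)
  exp_total <- sum(truth)
  se_t <- sd(cc$total) / sqrt(nrow(ctl))
  expect_lt(abs(mean(cc$total) - exp_total), 3 * se_t)
})
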