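# Discounting, effective utilities, and QALY / cost accrual.

test_that("discount factors follow 1/(1+r)^t", {
  expect_identical(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(10, 0.035), 1.035^-10)
  expect_equal(discount_factor(10, 0.035), 0.708919, tolerance = 1e-6)
  expect_identical(discount_factor(0:50, 0), rep(1, 51))
  expect_error(discount_factor(-1, 0.035), "non-negative")
})

test_that("effective utilities mix base, functional-impairment and non-use", {
  u <- base_params$utilities
  pw <- base_params$pathway
  expect_equal(effective_utility("normal", u, pw), 0.82 * 0.95 + 0.18 * 0.79)
  expect_equal(effective_utility("normal", u, pw), 0.9212)
  expect_equal(effective_utility("mild_unaided", u, pw), 0.78 * 0.80 + 0.22 * 0.74)
  expect_equal(effective_utility("mild_unaided", u, pw), 0.7868)
  expect_identical(effective_utility("profound_ci", u, pw), 0.61)
  expect_error(effective_utility("dead", u, pw), "dead")

  # no functional impairment and no non-use: the base utility unchanged
  pw0 <- pw
  pw0$p_functional_impairment[] <- 0
  expect_identical(effective_utility("moderate_unaided", u, pw0), 0.73)
  expect_identical(effective_utility("moderate_ha", u, pw0, nonuse_weight = 0), 0.90)

  # every effective utility lies between the FI and base utilities
  us <- state_utilities(u, pw)
  expect_true(all(us >= 0 & us <= 1))
  expect_equal(unname(us[["dead"]]), 0)
})

test_that("QALY accrual discounts occupancy-weighted utilities", {
  u <- base_params$utilities
  pw <- base_params$pathway
  tr <- manual_trace(single_state_occupancy("normal", 2))
  expect_equal(accrue_qalys(tr, u, pw, 0.035), 0.9212 * (1 + 1 / 1.035),
               tolerance = 1e-9)
  expect_equal(accrue_qalys(tr, u, pw, 0.035), 1.81130, tolerance = 1e-4)

  expect_identical(accrue_qalys(manual_trace(single_state_occupancy("dead", 5)),
                                u, pw, 0.035), 0)
  one <- manual_trace(single_state_occupancy("severe_unaided", 1))
  expect_equal(accrue_qalys(one, u, pw, 0),
               effective_utility("severe_unaided", u, pw))
})

test_that("QALYs with unit utilities and no mortality equal the annuity", {
  u1 <- base_params$utilities
  u1$base[] <- 1
  u1$functional[] <- 1
  u1$aided[] <- 1
  u1$aided_functional[] <- 1
  u1$ci <- 1
  h <- 40
  tr <- manual_trace(single_state_occupancy("normal", h + 1))
  expect_equal(accrue_qalys(tr, u1, base_params$pathway, 0.035),
               sum(1.035^-(0:h)), tolerance = 1e-10)
  expect_equal(accrue_qalys(tr, u1, base_params$pathway, 0.035, from_cycle = 1),
               sum(1.035^-(1:h)), tolerance = 1e-10)
})

test_that("cost accrual prices events and recurring occupancy", {
  co <- base_params$costs

  # a cohort that stays in normal hearing incurs nothing
  tr <- manual_trace(single_state_occupancy("normal", 61))
  expect_identical(accrue_costs(tr, co, 0.035), 0)

  # one hearing-aid fitting at cycle 0, nothing else, undiscounted
  occ <- single_state_occupancy("dead", 1)
  tr1 <- manual_trace(occ)
  tr1$flows[1, "ha_fittings"] <- 1
  expect_equal(accrue_costs(tr1, co, 0), 54 + 0.58 * 380 + 0.42 * 275)
  expect_equal(accrue_costs(tr1, co, 0), 389.90)

  # one implantation at cycle 0 with its expected complications
  tr2 <- manual_trace(occ)
  tr2$flows[1, "ci_implants"] <- 1
  tr2$flows[1, "complications"] <- base_params$pathway$p_major_complication_y1
  expect_equal(accrue_costs(tr2, co, 0), 5308 + 22919 + 6617 + 0.04 * 10292)
  expect_equal(accrue_costs(tr2, co, 0), 35255.68)

  # implant-year occupants accrue no maintenance; later years do
  occ3 <- single_state_occupancy("profound_ci", 3)
  tr3 <- manual_trace(occ3)
  tr3$flows[1, "ci_implants"] <- 1
  expect_equal(accrue_costs(tr3, co, 0),
               5308 + 22919 + 6617 + 2 * 945)
})

test_that("discounted totals decrease with the discount rate", {
  tr <- run_cohort(base_params)
  u <- base_params$utilities
  pw <- base_params$pathway
  q <- vapply(c(0, 0.035, 0.06), function(r) accrue_qalys(tr, u, pw, r),
              numeric(1))
  cost <- vapply(c(0, 0.035, 0.06),
                 function(r) accrue_costs(tr, base_params$costs, r), numeric(1))
  expect_true(all(diff(q) < 0))
  expect_true(all(diff(cost) < 0))
})

test_that("costs respond linearly to a unit cost", {
  # no implants: monaural hearing-aid price enters linearly
  p <- base_params
  p$pathway$p_need_ci <- 0
  tr <- run_cohort(p)
  cost_at <- function(x) {
    co <- p$costs
    co$ha_monaural <- x
    accrue_costs(tr, co, 0.035)
  }
  expect_equal(cost_at(550) - cost_at(275), cost_at(275) - cost_at(0),
               tolerance = 1e-9)
})

test_that("strategy QALYs respect the life-year bound", {
  r <- evaluate_strategy(base_params)
  tr <- run_cohort(base_params)
  disc_ly <- sum(discount_factor(tr$cycles[-1], 0.035) *
                   (1 - tr$occupancy[-1, "dead"]))
  expect_gte(r$draws$qaly, 0)
  expect_lte(r$draws$qaly, disc_ly * max(state_utilities(
    base_params$utilities, base_params$pathway)))
})
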