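# Parameter fixture, severity-table repair, validation, config round-trip.

test_that("severity-table repair fixes the exponent typos and renormalizes", {
  tab <- repair_severity_table()

  # normal row (ages 50-59): plain renormalization by the printed row sum
  printed_sum <- 9.57e-01 + 4.11e-02 + 1.37e-03 + 2 * 1.99e-07
  expect_equal(tab$bands[["50-59"]]["normal", "normal"], 0.957 / printed_sum,
               tolerance = 1e-12)
  expect_equal(tab$bands[["50-59"]]["normal", "normal"], 0.957507,
               tolerance = 1e-6)

  # mild rows print stay probabilities two orders of magnitude too small:
  # diagonal x10, then renormalize
  fixed_sum <- 9.31e-01 + 6.93e-02 + 2 * 2.00e-05
  expect_equal(tab$bands[["50-59"]]["mild", "mild"], 0.931 / fixed_sum,
               tolerance = 1e-12)
  expect_equal(tab$bands[["50-59"]]["mild", "mild"], 0.930684, tolerance = 1e-6)
  expect_equal(tab$bands[["50-59"]]["mild", "moderate"], 0.069276,
               tolerance = 1e-5)
  expect_true(any(tab$log$action == "diagonal x10 (exponent fix)" &
                    tab$log$row == "mild"))

  # every repaired row sums to one, profound is absorbing
  for (b in names(tab$bands)) {
    expect_equal(unname(rowSums(tab$bands[[b]])), rep(1, 5), tolerance = 1e-12)
    expect_identical(unname(tab$bands[[b]]["profound", ]), c(0, 0, 0, 0, 1))
  }
})

test_that("rows already summing to one pass through unchanged, bad rows error", {
  clean <- list(test = matrix(c(0.9, 0.1, 0, 0, 0,
                                0, 0.95, 0.05, 0, 0,
                                0, 0, 1, 0, 0,
                                0, 0, 0, 1, 0),
                              4, 5, byrow = TRUE,
                              dimnames = list(severity_levels()[1:4],
                                              severity_levels())))
  out <- repair_severity_table(clean)
  expect_identical(out$bands$test["normal", "normal"], 0.9)
  expect_identical(nrow(out$log), 0L)

  broken <- clean
  broken$test["normal", ] <- c(0.6, 0.1, 0, 0, 0)  # sums to 0.7: unrepairable
  expect_error(repair_severity_table(broken), "sums to 0.7")
})

test_that("the bundled fixture reproduces the printed pathway, utility and cost values", {
  p <- base_params

  expect_identical(unname(p$pathway$p_functional_impairment),
                   c(0.18, 0.22, 0.26, 0.26, 0.26))
  expect_identical(unname(p$pathway$p_receive_ha), c(0.30, 0.52, 0.71, 0.71, 0.58))
  expect_identical(p$pathway$p_need_ci, 0.60)
  expect_identical(unname(p$pathway$p_ha_nonuse), c(0.13, 0.30, 0.30, 0.30, 0.03))
  expect_identical(p$pathway$p_ci_failure, 0.03)
  expect_identical(p$pathway$p_major_complication_y1, 0.04)

  expect_identical(unname(p$utilities$base), c(0.95, 0.80, 0.73, 0.73, 0.46))
  expect_identical(unname(p$utilities$functional), c(0.79, 0.74, 0.67, 0.67, 0.26))
  expect_identical(unname(p$utilities$aided), c(0.89, 0.90, 0.90, 0.64))
  expect_identical(unname(p$utilities$aided_functional), c(0.83, 0.84, 0.84, 0.43))
  expect_identical(p$utilities$ci, 0.61)
  expect_identical(p$utilities$base[["profound"]], 0.46)

  expect_identical(p$costs$ha_monaural, 275)
  expect_identical(p$costs$ha_binaural, 380)
  expect_identical(p$costs$p_binaural, 0.58)
  expect_identical(p$costs$ha_aftercare, 26)
  expect_identical(p$costs$hearing_evaluation, 54)
  expect_identical(unname(p$costs$p_assess_no_ha), c(0.30, 0.05))
  expect_identical(p$costs$ci_device, 22919)
  expect_identical(p$costs$ci_candidacy, 5308)
  expect_identical(p$costs$p_assess_no_ci, 0.40)
  expect_identical(p$costs$ci_maintenance_y1, 6617)
  expect_identical(p$costs$ci_maintenance, 945)
  expect_identical(p$costs$ci_upgrade, 5445)
  expect_identical(p$costs$major_complication, 10292)

  expect_identical(p$settings$discount_rate, 0.035)
  expect_identical(p$settings$wtp, 20000)
  expect_identical(p$settings$entry_age, 50)
  expect_identical(p$settings$cohort_size, 1000)
})

test_that("validation names the offending field", {
  expect_error(validate_parameters(params_with(utilities = modifyList(
    base_params$utilities, list(ci = 1.2)))), "utilities\\$ci")
  bad <- base_params
  bad$utilities$functional[["mild"]] <- 0.85  # above the base utility 0.80
  expect_error(validate_parameters(bad), "utilities\\$functional")
  bad <- base_params
  bad$settings$discount_rate <- 0.10
  expect_error(validate_parameters(bad), "discount_rate")
  bad <- base_params
  bad$settings$init_severity[["mild"]] <- 0.5
  expect_error(validate_parameters(bad), "init_severity")
  bad <- base_params
  bad$costs$ci_device <- -1
  expect_error(validate_parameters(bad), "costs\\$ci_device")
})

test_that("config loading falls back to defaults and round-trips", {
  expect_equal(load_config(""), base_params, ignore_attr = TRUE)

  p <- load_config("settings:\n  discount_rate: 0.0\n")
  expect_identical(p$settings$discount_rate, 0)
  expect_identical(p$costs$ci_device, base_params$costs$ci_device)

  expect_error(load_config("utilities:\n  base:\n    mild: 1.2\n"),
               "utilities\\$base")

  # write(load(x)) == load(write(x)) for the bundled fixture
  loaded <- load_config(fixture_path())
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_config(loaded, tmp)
  reloaded <- load_config(tmp)
  for (part in c("severity", "pathway", "utilities", "costs", "settings")) {
    expect_equal(loaded[[part]], reloaded[[part]], tolerance = 1e-12)
  }
  expect_equal(loaded$mortality$q, reloaded$mortality$q, tolerance = 1e-12)
})

test_that("a therapy block in the config becomes a scenario", {
  p <- load_config(
    "therapy:\n  eligibility: [severe, profound]\n  recovery: back_1\n  efficacy: 0.4\n  price: 1500\n")
  th <- attr(p, "therapy")
  expect_s3_class(th, "therapy_scenario")
  expect_identical(th$eligibility, c("severe", "profound"))
  expect_identical(th$efficacy, 0.4)
  expect_equal(th$price, 1500)
})
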