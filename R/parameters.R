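# Model inputs: severity transition tables, pathway probabilities, utilities,
# unit costs, economic settings and the mortality schedule.

.age_bands <- c("50-59", "60-69", "70+")

# Annual severity transition probabilities as printed in the source tables,
# by age band. Rows: current severity; columns: severity next cycle,
# conditional on survival. The mild rows carry exponent typos (stay
# probabilities printed two orders of magnitude too small); see
# repair_severity_table().
.raw_severity_rows <- function() {
  mk <- function(...) {
    m <- rbind(...)
    dimnames(m) <- list(.severity_names[1:4], .severity_names)
    m
  }
  list(
    "50-59" = mk(
      normal   = c(9.57e-01, 4.11e-02, 1.37e-03, 1.99e-07, 1.99e-07),
      mild     = c(0,        9.31e-02, 6.93e-02, 2.00e-05, 2.00e-05),
      moderate = c(0,        0,        9.99e-01, 4.30e-04, 4.30e-04),
      severe   = c(0,        0,        0,        1.00e+00, 4.30e-04)
    ),
    "60-69" = mk(
      normal   = c(9.67e-01, 3.24e-02, 3.30e-04, 6.28e-06, 6.28e-06),
      mild     = c(0,        9.79e-02, 1.98e-02, 5.70e-04, 5.70e-04),
      moderate = c(0,        0,        8.90e-01, 5.48e-02, 5.48e-02),
      severe   = c(0,        0,        0,        9.45e-01, 5.48e-02)
    ),
    "70+" = mk(
      normal   = c(9.64e-01, 3.55e-02, 5.60e-04, 4.15e-06, 4.15e-06),
      mild     = c(0,        9.70e-02, 2.91e-02, 3.30e-04, 3.30e-04),
      moderate = c(0,        0,        9.56e-01, 2.20e-02, 2.20e-02),
      severe   = c(0,        0,        0,        9.78e-01, 2.20e-02)
    )
  )
}

#' Repair and normalize a severity transition table
#'
#' The published annual transition probabilities contain rows that cannot sum
#' to one: the mild-hearing-loss rows print stay probabilities near 0.09
#' where every other row stays near 1, an apparent exponent typo. This
#' routine applies a conservative two-step repair: (i) any row whose total
#' mass is below 0.5 has its diagonal (stay) entry multiplied by 10;
#' (ii) every row is divided by its sum. A profound row (absorbing among
#' severities, conditional on survival) is appended when absent, since the
#' severity of hearing loss never improves under standard care.
#'
#' @param raw Named list of age-band matrices (rows: current severity,
#'   columns: next-cycle severity), as printed. Rows for `profound` may be
#'   omitted.
#' @param tol Maximum tolerated deviation of a row sum from 1 *after* the
#'   exponent fix; rows further out are treated as data errors.
#' @return List with elements `bands` (repaired matrices, each row summing
#'   to 1 within 1e-12, with an absorbing profound row) and `log`
#'   (data.frame of repairs applied: band, row, action).
#' @export
#' @examples
#' tab <- repair_severity_table()
#' tab$bands[["50-59"]]["normal", "normal"]  # 0.957507 after normalization
repair_severity_table <- function(raw = .raw_severity_rows(), tol = 0.01) {
  log <- data.frame(band = character(), row = character(), action = character(),
                    stringsAsFactors = FALSE)
  bands <- lapply(names(raw), function(bn) {
    m <- raw[[bn]]
    if (any(m < 0)) stop("negative transition probability in band ", bn, call. = FALSE)
    if (!"profound" %in% rownames(m)) {
      m <- rbind(m, profound = c(0, 0, 0, 0, 1))
    }
    for (rn in rownames(m)) {
      s <- sum(m[rn, ])
      if (s < 0.5) {
        m[rn, rn] <- m[rn, rn] * 10
        log[nrow(log) + 1L, ] <<- c(bn, rn, "diagonal x10 (exponent fix)")
        s <- sum(m[rn, ])
      }
      if (abs(s - 1) > tol) {
        stop(sprintf("severity row '%s' (band %s) sums to %.4f after repair; not a probability row",
                     rn, bn, s), call. = FALSE)
      }
      if (s != 1) {
        m[rn, ] <- m[rn, ] / s
        if (abs(s - 1) > 1e-9) {
          log[nrow(log) + 1L, ] <<- c(bn, rn, sprintf("renormalized (sum %.7f)", s))
        }
      }
    }
    m
  })
  names(bands) <- names(raw)
  list(bands = bands, log = log)
}

# Gompertz-Makeham default fitted to UK 2016-18 national life tables (sexes
# combined): remaining life expectancy at age 50 of 33.0 years.
.default_gm <- list(makeham = 2.0e-4, slope = 2.252e-3, rate = 0.1)

#' The bundled model parameter set
#'
#' Returns the complete deterministic input set for the hearing-care pathway
#' model: annual severity transition probabilities by age band (repaired, see
#' [repair_severity_table()]), care-pathway probabilities, HUI-3 utilities
#' with functional-impairment variants, 2018 GBP unit costs, economic
#' settings (3.5% discounting, GBP 20,000/QALY threshold, entry at age 50,
#' lifetime horizon) and a parametric all-cause mortality schedule.
#'
#' @return An object of class `arhl_parameters`: a validated nested list with
#'   components `severity`, `pathway`, `utilities`, `costs`, `settings`,
#'   `mortality` and a `repair_log` attribute.
#' @export
#' @examples
#' p <- default_parameters()
#' p$utilities$base[["profound"]]  # 0.46
#' p$costs$ci_device               # 22919
default_parameters <- function() {
  rep <- repair_severity_table()

  pathway <- list(
    p_functional_impairment = c(normal = 0.18, mild = 0.22, moderate = 0.26,
                                severe = 0.26, profound = 0.26),
    p_receive_ha = c(mild = 0.30, moderate = 0.52, severe = 0.71,
                     profound = 0.71, profound_ci = 0.58),
    p_need_ci = 0.60,
    p_ha_nonuse = c(mild = 0.13, moderate = 0.30, severe = 0.30,
                    profound = 0.30, profound_ci = 0.03),
    p_ci_failure = 0.03,
    p_major_complication_y1 = 0.04
  )

  utilities <- list(
    base = c(normal = 0.95, mild = 0.80, moderate = 0.73, severe = 0.73,
             profound = 0.46),
    functional = c(normal = 0.79, mild = 0.74, moderate = 0.67, severe = 0.67,
                   profound = 0.26),
    aided = c(mild = 0.89, moderate = 0.90, severe = 0.90, profound = 0.64),
    aided_functional = c(mild = 0.83, moderate = 0.84, severe = 0.84,
                         profound = 0.43),
    ci = 0.61,
    se_base = c(normal = 0.08, mild = 0.03, moderate = 0.03, severe = 0.03,
                profound = 0.21),
    se_ci = 0.19
  )

  costs <- list(
    ha_monaural = 275,
    ha_binaural = 380,
    p_binaural = 0.58,
    ha_aftercare = 26,
    hearing_evaluation = 54,
    p_assess_no_ha = c(mild = 0.30, moderate_plus = 0.05),
    ci_device = 22919,
    ci_candidacy = 5308,
    p_assess_no_ci = 0.40,
    ci_maintenance_y1 = 6617,
    ci_maintenance = 945,
    ci_upgrade = 5445,
    ci_upgrade_interval = 5,
    major_complication = 10292,
    therapy_price = 0,
    # device replacement cadence for hearing aids (years of continuous use);
    # 0 disables replacement
    ha_refit_interval = 5,
    charge_evaluation_on_therapy = TRUE
  )

  settings <- list(
    discount_rate = 0.035,
    wtp = 20000,
    cycle_length = 1,
    entry_age = 50,
    max_age = 110,
    cohort_size = 1000,
    init_severity = c(normal = 1, mild = 0, moderate = 0, severe = 0,
                      profound = 0),
    half_cycle_correction = FALSE,
    aftercare_for_nonusers = TRUE,
    # pathway mechanics: device uptake re-evaluated every cycle for unaided
    # occupants ("annual") or only on incident entry into a severity
    # ("incident"); hearing-aid non-use as an annual state transition back
    # to unaided ("transition") or a within-state utility mixture ("mixture")
    uptake_timing = "annual",
    ha_nonuse = "transition"
  )

  mortality <- build_mortality_schedule(
    makeham = .default_gm$makeham, slope = .default_gm$slope,
    rate = .default_gm$rate,
    entry_age = settings$entry_age, max_age = settings$max_age
  )

  params <- structure(
    list(severity = rep$bands, pathway = pathway, utilities = utilities,
         costs = costs, settings = settings, mortality = mortality),
    class = "arhl_parameters", repair_log = rep$log
  )
  validate_parameters(params)
  params
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the inputs: repaired severity rows
#' sum to 1 and never place mass on improvement; pathway probabilities and
#' utilities lie in \[0, 1\] with functional-impairment utilities below the
#' corresponding base utility and aided utilities at least the unaided ones;
#' costs are non-negative; the initial severity distribution sums to 1; the
#' discount rate lies in the supported 0-6% range; and the mortality
#' schedule covers all model ages with death certain at the terminal age.
#'
#' @param params An `arhl_parameters` object (or a plain list with the same
#'   structure).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field and constraint.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, what) {
    stop(sprintf("invalid parameters: %s %s", field, what), call. = FALSE)
  }
  # severity tables
  for (bn in names(params$severity)) {
    m <- params$severity[[bn]]
    if (any(m < 0)) fail(paste0("severity$", bn), "has negative entries")
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      fail(paste0("severity$", bn), "has rows not summing to 1")
    }
    if (any(m[lower.tri(m)] != 0)) {
      fail(paste0("severity$", bn), "places mass on severity improvement")
    }
    if (m["profound", "profound"] != 1) {
      fail(paste0("severity$", bn), "profound row must be absorbing")
    }
  }
  pr01 <- function(x, field) {
    if (any(x < 0 | x > 1)) fail(field, "must lie in [0, 1]")
  }
  pw <- params$pathway
  pr01(pw$p_functional_impairment, "pathway$p_functional_impairment")
  pr01(pw$p_receive_ha, "pathway$p_receive_ha")
  pr01(pw$p_need_ci, "pathway$p_need_ci")
  pr01(pw$p_ha_nonuse, "pathway$p_ha_nonuse")
  pr01(pw$p_ci_failure, "pathway$p_ci_failure")
  pr01(pw$p_major_complication_y1, "pathway$p_major_complication_y1")

  u <- params$utilities
  pr01(u$base, "utilities$base")
  pr01(u$functional, "utilities$functional")
  pr01(u$aided, "utilities$aided")
  pr01(u$aided_functional, "utilities$aided_functional")
  pr01(u$ci, "utilities$ci")
  if (any(u$functional > u$base + 1e-12)) {
    fail("utilities$functional", "must not exceed the base utility")
  }
  if (any(u$aided_functional > u$aided + 1e-12)) {
    fail("utilities$aided_functional", "must not exceed the aided utility")
  }
  if (any(u$aided < u$base[names(u$aided)] - 1e-12)) {
    fail("utilities$aided", "must be at least the unaided utility of the same severity")
  }

  co <- params$costs
  money <- c("ha_monaural", "ha_binaural", "ha_aftercare", "hearing_evaluation",
             "ci_device", "ci_candidacy", "ci_maintenance_y1", "ci_maintenance",
             "ci_upgrade", "major_complication", "therapy_price")
  for (f in money) {
    if (co[[f]] < 0) fail(paste0("costs$", f), "must be non-negative")
  }
  pr01(co$p_binaural, "costs$p_binaural")
  pr01(co$p_assess_no_ha, "costs$p_assess_no_ha")
  pr01(co$p_assess_no_ci, "costs$p_assess_no_ci")
  if (co$p_assess_no_ci >= 1) fail("costs$p_assess_no_ci", "must be below 1")

  st <- params$settings
  if (abs(sum(st$init_severity) - 1) > 1e-9) {
    fail("settings$init_severity", "must sum to 1")
  }
  if (any(st$init_severity < 0)) fail("settings$init_severity", "must be non-negative")
  if (st$discount_rate < 0 || st$discount_rate > 0.06) {
    fail("settings$discount_rate", "must lie in [0, 0.06]")
  }
  if (st$entry_age >= st$max_age) fail("settings$entry_age", "must be below max_age")
  if (st$wtp < 0) fail("settings$wtp", "must be non-negative")
  if (!st$uptake_timing %in% c("annual", "incident")) {
    fail("settings$uptake_timing", "must be 'annual' or 'incident'")
  }
  if (!st$ha_nonuse %in% c("transition", "mixture")) {
    fail("settings$ha_nonuse", "must be 'transition' or 'mixture'")
  }

  mo <- params$mortality
  ages <- st$entry_age:st$max_age
  if (!all(ages %in% mo$age)) fail("mortality", "must cover every model age")
  pr01(mo$q, "mortality$q")
  if (mo$q[mo$age == st$max_age] != 1) {
    fail("mortality", "death must be certain at max_age")
  }
  invisible(params)
}

#' @export
print.arhl_parameters <- function(x, ...) {
  st <- x$settings
  cat("Hearing-loss pathway model parameters\n")
  cat(sprintf("  entry age %d, horizon to age %d, discount %.1f%%, WTP GBP %s/QALY\n",
              st$entry_age, st$max_age, 100 * st$discount_rate,
              format(st$wtp, big.mark = ",")))
  cat(sprintf("  mortality: e(%d) = %.1f years\n", st$entry_age,
              life_expectancy(x$mortality)))
  lg <- attr(x, "repair_log")
  if (!is.null(lg) && nrow(lg)) {
    cat(sprintf("  severity table repairs applied: %d\n", nrow(lg)))
  }
  invisible(x)
}
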