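# End-to-end analyses: strategy evaluation over PSA draws, incremental
# comparison (iNMB), headroom and scenario tables, and the value-based
# ceiling-price search.

# discounted lifetime (cost, QALYs, administrations) for one parameter set
.run_one <- function(params, therapy) {
  st <- params$settings
  if (!is.null(therapy)) params$costs$therapy_price <- therapy$price
  trace <- run_cohort(params, therapy)
  aw <- NULL
  if (!isTRUE(st$aftercare_for_nonusers) &&
      identical(st$ha_nonuse, "mixture")) {
    nu <- params$pathway$p_ha_nonuse[c("mild", "moderate", "severe", "profound")]
    aw <- stats::setNames(1 - nu, .state_names[.ha_states])
  }
  # when non-use is an explicit state transition, HA-state occupants are
  # all users: no utility down-mixing
  pw_u <- params$pathway
  if (identical(st$ha_nonuse, "transition")) pw_u$p_ha_nonuse[] <- 0
  q <- accrue_qalys(trace, params$utilities, pw_u, st$discount_rate,
                    from_cycle = 1, half_cycle = st$half_cycle_correction)
  c0 <- accrue_costs(trace, params$costs, st$discount_rate,
                     aftercare_weights = aw,
                     half_cycle = st$half_cycle_correction)
  adm <- trace$flows[, "therapy_administrations"]
  c(cost = c0, qaly = q,
    admin = sum(adm),
    admin_disc = sum(discount_factor(trace$cycles, st$discount_rate) * adm),
    life_years = .life_years(trace))
}

#' Evaluate a treatment strategy
#'
#' Computes discounted mean lifetime cost and QALYs per patient for one
#' strategy (standard care, or standard care augmented by a
#' [therapy_scenario()]). With a [psa_spec()], the model is re-run for each
#' sampled parameter set; per-draw results are retained so strategies
#' evaluated with the same spec and seed share draws (common random
#' numbers). Without one, a single deterministic run at the parameter means
#' is returned.
#'
#' @param params An `arhl_parameters` object.
#' @param therapy Optional [therapy_scenario()].
#' @param psa Optional [psa_spec()].
#' @return Object of class `strategy_result`: `draws` (data.frame with one
#'   row per draw: cost, qaly, administrations, discounted administrations,
#'   life years) and `summary` (means with percentile intervals).
#' @export
evaluate_strategy <- function(params, therapy = NULL, psa = NULL) {
  if (is.null(psa)) {
    draws <- as.data.frame(t(.run_one(params, therapy)))
    level <- 0.95
  } else {
    rows <- vapply(seq_len(psa$iterations), function(d) {
      .run_one(sample_parameter_set(params, psa, d), therapy)
    }, numeric(5))
    draws <- as.data.frame(t(rows))
    level <- psa$level
  }
  summ <- lapply(draws, function(v) {
    ci <- if (nrow(draws) >= 2) percentile_interval(v, level) else c(low = v, high = v)
    c(mean = mean(v), ci)
  })
  structure(list(draws = draws, summary = summ, level = level,
                 therapy = therapy, n = nrow(draws)),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  lab <- if (is.null(x$therapy)) "standard care" else x$therapy$label
  cat(sprintf("Strategy: %s (%d draw%s)\n", lab, x$n, if (x$n > 1) "s" else ""))
  cat(sprintf("  cost  GBP %9.0f [%0.0f, %0.0f]\n", x$summary$cost["mean"],
              x$summary$cost["low"], x$summary$cost["high"]))
  cat(sprintf("  QALYs     %9.2f [%0.2f, %0.2f]\n", x$summary$qaly["mean"],
              x$summary$qaly["low"], x$summary$qaly["high"]))
  invisible(x)
}

#' Compare a novel strategy with current care
#'
#' Per-draw incremental cost, incremental QALYs and incremental net
#' monetary benefit,
#' \eqn{iNMB = (Q_n \lambda - C_n) - (Q_c \lambda - C_c)}, with percentile
#' intervals. Requires both strategies to have been evaluated with the same
#' number of draws (and, for meaningful intervals, the same seed: common
#' random numbers).
#'
#' @param novel,current `strategy_result` objects.
#' @param wtp Willingness-to-pay threshold \eqn{\lambda}, GBP per QALY.
#' @param level Interval level (defaults to the novel arm's).
#' @return Object of class `comparison_result` with per-draw vectors and a
#'   summary (means and percentile intervals of incremental cost, QALYs and
#'   iNMB; mean administrations per person).
#' @export
compare_strategies <- function(novel, current, wtp = 20000, level = NULL) {
  stopifnot(inherits(novel, "strategy_result"),
            inherits(current, "strategy_result"))
  if (novel$n != current$n) {
    stop("strategies were evaluated with different draw counts", call. = FALSE)
  }
  level <- level %||% novel$level
  inc_cost <- novel$draws$cost - current$draws$cost
  inc_qaly <- novel$draws$qaly - current$draws$qaly
  inmb <- inc_qaly * wtp - inc_cost
  ci <- function(v) {
    if (length(v) >= 2) percentile_interval(v, level) else c(low = v, high = v)
  }
  structure(
    list(draws = data.frame(inc_cost = inc_cost, inc_qaly = inc_qaly, inmb = inmb),
         summary = list(inc_cost = c(mean = mean(inc_cost), ci(inc_cost)),
                        inc_qaly = c(mean = mean(inc_qaly), ci(inc_qaly)),
                        inmb = c(mean = mean(inmb), ci(inmb))),
         mean_administrations = mean(novel$draws$admin),
         mean_administrations_disc = mean(novel$draws$admin_disc),
         wtp = wtp, level = level, n = novel$n,
         novel = novel, current = current),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Incremental result at GBP %s/QALY (%d draws)\n",
              format(x$wtp, big.mark = ","), x$n))
  cat(sprintf("  incremental cost  GBP %9.0f [%0.0f, %0.0f]\n",
              s$inc_cost["mean"], s$inc_cost["low"], s$inc_cost["high"]))
  cat(sprintf("  incremental QALYs     %9.3f [%0.3f, %0.3f]\n",
              s$inc_qaly["mean"], s$inc_qaly["low"], s$inc_qaly["high"]))
  cat(sprintf("  iNMB              GBP %9.0f [%0.0f, %0.0f]\n",
              s$inmb["mean"], s$inmb["low"], s$inmb["high"]))
  cat(sprintf("  mean administrations per person %.3f\n", x$mean_administrations))
  invisible(x)
}

#' Headroom analysis
#'
#' Values a perfect novel therapeutic — 100% effective for every
#' hearing-loss severity, full recovery to normal hearing, zero price —
#' against standard care, bounding the commercial opportunity.
#'
#' @param params An `arhl_parameters` object.
#' @param psa Optional [psa_spec()].
#' @param wtp Willingness-to-pay threshold (defaults to the settings).
#' @return A `comparison_result`.
#' @export
run_headroom <- function(params, psa = NULL, wtp = params$settings$wtp) {
  current <- evaluate_strategy(params, NULL, psa)
  novel <- evaluate_strategy(params, scenario_catalog()[[1]], psa)
  compare_strategies(novel, current, wtp)
}

#' The published scenario table
#'
#' Evaluates the six catalog scenarios (see [scenario_catalog()]) against a
#' shared standard-care arm and tabulates incremental costs, incremental
#' QALYs and iNMB with percentile intervals.
#'
#' @inheritParams run_headroom
#' @return Data frame with one row per scenario; the full
#'   `comparison_result` objects are attached as the `comparisons`
#'   attribute.
#' @export
run_scenarios <- function(params, psa = NULL, wtp = params$settings$wtp) {
  current <- evaluate_strategy(params, NULL, psa)
  catalog <- scenario_catalog()
  comps <- lapply(catalog, function(sc) {
    compare_strategies(evaluate_strategy(params, sc, psa), current, wtp)
  })
  tab <- data.frame(
    scenario = seq_along(catalog),
    recovery = vapply(catalog, `[[`, "", "recovery"),
    severity = vapply(catalog, function(s) paste(s$eligibility, collapse = "/"), ""),
    inc_cost = vapply(comps, function(cm) cm$summary$inc_cost[["mean"]], 0),
    inc_cost_low = vapply(comps, function(cm) cm$summary$inc_cost[["low"]], 0),
    inc_cost_high = vapply(comps, function(cm) cm$summary$inc_cost[["high"]], 0),
    inc_qaly = vapply(comps, function(cm) cm$summary$inc_qaly[["mean"]], 0),
    inc_qaly_low = vapply(comps, function(cm) cm$summary$inc_qaly[["low"]], 0),
    inc_qaly_high = vapply(comps, function(cm) cm$summary$inc_qaly[["high"]], 0),
    inmb = vapply(comps, function(cm) cm$summary$inmb[["mean"]], 0),
    inmb_low = vapply(comps, function(cm) cm$summary$inmb[["low"]], 0),
    inmb_high = vapply(comps, function(cm) cm$summary$inmb[["high"]], 0),
    administrations = vapply(comps, `[[`, 0, "mean_administrations")
  )
  attr(tab, "comparisons") <- comps
  tab
}

#' Ceiling-price search
#'
#' Finds the per-administration price at which the mean iNMB of a therapy
#' scenario crosses zero, by bisection with common random numbers across
#' price evaluations. Because the therapy price enters lifetime cost
#' linearly (price times discounted administrations, with the cohort
#' dynamics independent of price), each draw's iNMB at price `p` equals its
#' zero-price iNMB minus `p` times its discounted administrations; the
#' bisection operates on the mean of that exact per-draw relation.
#'
#' @param params An `arhl_parameters` object.
#' @param eligibility,recovery,efficacy Scenario shape, as in
#'   [therapy_scenario()].
#' @param psa Optional [psa_spec()].
#' @param tol Tolerance on the mean iNMB at the returned price, GBP
#'   (default 50).
#' @param wtp Willingness-to-pay threshold.
#' @param price_upper Initial upper bracket for the price (expanded as
#'   needed).
#' @return Object of class `threshold_result`: the ceiling price per
#'   administration, mean administrations per person (undiscounted and
#'   discounted), the per-person lifetime spend at the ceiling
#'   (price x mean administrations), and the zero-price comparison. If the
#'   scenario is not cost-effective even at zero price, the price is 0 with
#'   a warning.
#' @export
threshold_search <- function(params, eligibility, recovery, efficacy,
                             psa = NULL, tol = 50,
                             wtp = params$settings$wtp, price_upper = 50000) {
  stopifnot(tol > 0, efficacy > 0, efficacy <= 1)
  scenario <- therapy_scenario(eligibility, recovery, efficacy, price = 0)
  current <- evaluate_strategy(params, NULL, psa)
  novel <- evaluate_strategy(params, scenario, psa)
  comp <- compare_strategies(novel, current, wtp)
  inmb0 <- comp$draws$inmb
  adisc <- novel$draws$admin_disc
  g <- function(p) mean(inmb0 - p * adisc)

  out <- list(scenario = scenario, comparison = comp,
              mean_administrations = mean(novel$draws$admin),
              mean_administrations_disc = mean(adisc),
              wtp = wtp, tol = tol)
  if (g(0) < 0) {
    warning("mean iNMB is negative at zero price; no positive ceiling price")
    out$price <- 0
  } else if (mean(adisc) <= 0) {
    stop("scenario yields no therapy administrations; ceiling price undefined",
         call. = FALSE)
  } else {
    lo <- 0
    hi <- price_upper
    while (g(hi) > 0) {
      lo <- hi
      hi <- hi * 2
      if (hi > 1e12) stop("ceiling price search failed to bracket a root",
                          call. = FALSE)
    }
    while (abs(g((lo + hi) / 2)) > tol && (hi - lo) > 1e-9) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    out$price <- (lo + hi) / 2
  }
  out$inmb_at_price <- g(out$price)
  out$per_person <- out$price * out$mean_administrations
  class(out) <- "threshold_result"
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Ceiling price (%s, efficacy %.0f%%)\n", x$scenario$label,
              100 * x$scenario$efficacy))
  cat(sprintf("  per administration GBP %0.0f (mean iNMB there: %0.1f)\n",
              x$price, x$inmb_at_price))
  cat(sprintf("  administrations per person %.3f -> per-person spend GBP %0.0f\n",
              x$mean_administrations, x$per_person))
  invisible(x)
}
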