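# Rewards: convert a cohort trace into discounted lifetime QALYs and costs
# per patient.
#
# Timing convention: transitions and one-off events happen at cycle start;
# occupancy rewards (utilities, recurring costs) accrue on post-transition
# occupancy. The accrual functions weight whatever cycles they are given by
# 1/(1+r)^cycle; strategy evaluation passes cycles >= 1, so the entry-year
# distribution (cycle 0) accrues event costs only. No half-cycle correction
# by default (switchable in the settings).

#' Discount factor for an annual cycle
#'
#' @param cycle Integer cycle index (0 = entry year), scalar or vector.
#' @param rate Annual discount rate (fraction, >= 0).
#' @return `1 / (1 + rate)^cycle`.
#' @export
#' @examples
#' discount_factor(10, 0.035)  # 0.708919
discount_factor <- function(cycle, rate) {
  if (any(cycle < 0)) stop("cycle must be non-negative", call. = FALSE)
  if (rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  (1 + rate)^(-cycle)
}

#' Effective per-cycle utility of a health state
#'
#' Combines the state's base and functional-impairment (FI) utilities by
#' the severity-specific FI probability:
#' \eqn{(1 - p_{FI}) u_{base} + p_{FI} u_{FI}}. For hearing-aid states the
#' aided base/FI pair is first mixed with the unaided pair by the annual
#' non-use weight, so that non-users accrue unaided utility while remaining
#' in the device state. The cochlear-implant state uses its single utility
#' with no FI term.
#'
#' @param state A state name from [health_states()] (not `"dead"`).
#' @param utilities,pathway Components of an `arhl_parameters` object.
#' @param nonuse_weight Optional override of the hearing-aid non-use weight;
#'   defaults to the pathway's severity-specific value (0 for non-HA states).
#' @return Utility weight in \[0, 1\].
#' @export
#' @examples
#' p <- default_parameters()
#' effective_utility("normal", p$utilities, p$pathway)        # 0.9212
#' effective_utility("mild_unaided", p$utilities, p$pathway)  # 0.7868
effective_utility <- function(state, utilities, pathway, nonuse_weight = NULL) {
  i <- match(state, .state_names)
  if (is.na(i)) stop("unknown state: ", state, call. = FALSE)
  if (i == .dead_state) stop("no utility is defined for the dead state", call. = FALSE)
  if (i == .ci_state) return(utilities$ci)
  sev <- .severity_names[.state_severity[i]]
  p_fi <- pathway$p_functional_impairment[[sev]]
  if (i %in% .ha_states) {
    w <- nonuse_weight %||% pathway$p_ha_nonuse[[sev]]
    base <- (1 - w) * utilities$aided[[sev]] + w * utilities$base[[sev]]
    fi <- (1 - w) * utilities$aided_functional[[sev]] + w * utilities$functional[[sev]]
  } else {
    if (!is.null(nonuse_weight) && nonuse_weight != 0) {
      stop("nonuse_weight applies to hearing-aid states only", call. = FALSE)
    }
    base <- utilities$base[[sev]]
    fi <- utilities$functional[[sev]]
  }
  (1 - p_fi) * base + p_fi * fi
}

#' Per-state utility vector
#'
#' [effective_utility()] evaluated for every living state, with 0 for death.
#'
#' @inheritParams effective_utility
#' @return Named numeric vector over the 11 states.
#' @export
state_utilities <- function(utilities, pathway) {
  u <- vapply(.state_names[1:10], effective_utility, numeric(1),
              utilities = utilities, pathway = pathway)
  c(u, dead = 0)
}

#' Discounted QALYs accrued by a cohort trace
#'
#' Sums occupancy-weighted state utilities over the cycles present in the
#' trace, discounting each cycle `t` by `1/(1+rate)^t` (cycle length one
#' year, so the utility weight is the QALY accrued per cycle).
#'
#' @param trace An `arhl_trace` (or any object with an `occupancy` matrix
#'   and `cycles` vector).
#' @param utilities,pathway Components of an `arhl_parameters` object.
#' @param rate Annual discount rate.
#' @param from_cycle Drop cycles before this index (default `NULL`: use all
#'   rows of the trace).
#' @param half_cycle Apply a half-cycle correction: occupancy at each
#'   retained cycle `t >= 1` is replaced by the mean of cycles `t - 1` and
#'   `t` (default FALSE).
#' @return Discounted QALYs per initial cohort member.
#' @export
accrue_qalys <- function(trace, utilities, pathway, rate, from_cycle = NULL,
                         half_cycle = FALSE) {
  u <- state_utilities(utilities, pathway)
  occ <- .reward_occupancy(trace, half_cycle)
  keep <- if (is.null(from_cycle)) rep(TRUE, length(trace$cycles)) else trace$cycles >= from_cycle
  df <- discount_factor(trace$cycles[keep], rate)
  sum(df * (occ[keep, , drop = FALSE] %*% u))
}

# occupancy matrix used for per-cycle rewards, optionally half-cycle corrected
.reward_occupancy <- function(trace, half_cycle) {
  occ <- trace$occupancy
  if (isTRUE(half_cycle) && nrow(occ) > 1L) {
    occ[-1L, ] <- (occ[-1L, , drop = FALSE] + occ[-nrow(occ), , drop = FALSE]) / 2
  }
  occ
}

# expected device cost of one hearing-aid fitting (binaural mix) plus the
# hearing evaluation
.ha_fitting_cost <- function(costs) {
  costs$hearing_evaluation +
    costs$p_binaural * costs$ha_binaural +
    (1 - costs$p_binaural) * costs$ha_monaural
}

#' Discounted costs accrued by a cohort trace
#'
#' Prices the trace's event flows and recurring state occupancy:
#' hearing-aid fittings and replacements (evaluation plus the
#' binaural-mix device cost), assessments not leading to a hearing aid,
#' cochlear implantation (candidacy, device, first-year maintenance, with
#' expected major-complication costs flowing separately), candidacy
#' assessments without implantation, processor upgrades, therapy
#' administrations (per-administration price, plus the hearing evaluation
#' when so configured), hearing-aid aftercare per year in HA states, and
#' implant maintenance per year from the second year in the CI state.
#' Normal hearing accrues no cost. Event flows are discounted at their
#' cycle; recurring occupancy costs accrue from cycle 1 (post-transition
#' occupancy).
#'
#' @param trace An `arhl_trace`.
#' @param costs Cost component of an `arhl_parameters` object.
#' @param rate Annual discount rate.
#' @param aftercare_weights Optional named weights (per hearing-aid state)
#'   on aftercare accrual; used to withhold aftercare from the non-user
#'   share when so configured. Default 1 for all HA states.
#' @param half_cycle Half-cycle correction on recurring occupancy costs
#'   (events are unaffected; they occur at cycle start).
#' @return Discounted cost per initial cohort member, GBP.
#' @export
accrue_costs <- function(trace, costs, rate, aftercare_weights = NULL,
                         half_cycle = FALSE) {
  df <- discount_factor(trace$cycles, rate)
  fl <- trace$flows

  therapy_unit <- costs$therapy_price +
    if (isTRUE(costs$charge_evaluation_on_therapy)) costs$hearing_evaluation else 0
  unit <- c(
    ha_fittings = .ha_fitting_cost(costs),
    ha_refits = .ha_fitting_cost(costs),
    ha_assessments = costs$hearing_evaluation,
    ci_implants = costs$ci_device + costs$ci_candidacy + costs$ci_maintenance_y1,
    ci_assessments = costs$ci_candidacy,
    ci_upgrades = costs$ci_upgrade,
    complications = costs$major_complication,
    therapy_administrations = therapy_unit
  )
  event_cost <- sum(df * (fl[, names(unit), drop = FALSE] %*% unit))

  post <- trace$cycles >= 1
  occ <- .reward_occupancy(trace, half_cycle)[post, , drop = FALSE]
  dfp <- df[post]
  w <- rep(1, length(.ha_states))
  if (!is.null(aftercare_weights)) {
    w <- aftercare_weights[.state_names[.ha_states]]
    if (anyNA(w)) stop("aftercare_weights must name every hearing-aid state",
                       call. = FALSE)
  }
  ha_occ <- as.vector(occ[, .ha_states, drop = FALSE] %*% w)
  # maintenance from year 2 on: implant-year occupants are covered by the
  # first-year maintenance bundled with the implantation event
  ci_maint_occ <- pmax(0, occ[, .ci_state] - fl[post, "ci_implants"])
  recurring <- sum(dfp * (ha_occ * costs$ha_aftercare +
                            ci_maint_occ * costs$ci_maintenance))
  event_cost + recurring
}
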