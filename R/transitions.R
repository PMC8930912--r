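# Composition of the full 11-state annual transition matrix from the
# severity transition table, the care-pathway probabilities and the
# age-specific death probability.
#
# Convention: mortality acts first each cycle and competes with progression,
# so every living state sends q(age) to death and (1 - q(age)) times the
# severity/pathway composition elsewhere. Device uptake is evaluated on
# *entry* into a severity (incident transitions): an entrant without a
# device draws hearing-aid uptake at the new severity; an incident profound
# entrant first draws cochlear-implant need (CI takes precedence), and CI
# non-use/failure returns users to unaided profound hearing loss. Hearing-aid
# non-use is a within-state utility condition (see effective_utility), not a
# separate state.

.event_names <- c("therapy", "fit", "nonrecip_mild", "nonrecip_modplus", "implant")

# Compose the destination distribution (over the 11 states, conditional on
# survival) plus expected event counts for mass leaving severity `sev_i`
# with device status `device` ("none"/"ha"), given the severity row
# `sev_probs` (length 5). `entry = TRUE` treats every non-normal destination
# as an incident presentation (used for the initial cohort).
#
# `annual_uptake` re-evaluates device uptake every cycle for unaided
# occupants (not only on incident entry); `w_nonuse` is the annual
# probability that a hearing-aid user abandons the device, moving to the
# unaided state at the destination severity (0 when non-use is modeled as
# a within-state utility mixture instead).
.compose_row <- function(sev_probs, sev_i, device, pathway, therapy = NULL,
                         entry = FALSE, annual_uptake = FALSE, w_nonuse = 0) {
  p <- numeric(11)
  ev <- stats::setNames(numeric(length(.event_names)), .event_names)

  land <- function(m, s, dev) {
    idx <- if (s == 1L) 1L
    else if (dev == "ha") .ha_state[s]
    else if (dev == "ci") .ci_state
    else .unaided_state[s]
    p[idx] <<- p[idx] + m
  }

  # device-uptake logic for an unaided arrival into severity s:
  # CI need takes precedence for profound, then hearing-aid uptake; the
  # non-recipient share feeds the assessed-without-HA flow
  arrive_uptake <- function(m, s) {
    if (s == 1L) {
      land(m, 1L, "none")
      return(invisible())
    }
    if (s == 5L) {
      ci <- m * pathway$p_need_ci
      ev[["implant"]] <<- ev[["implant"]] + ci
      land(ci, 5L, "ci")
      m <- m - ci
    }
    pha <- pathway$p_receive_ha[[.severity_names[s]]]
    ev[["fit"]] <<- ev[["fit"]] + m * pha
    land(m * pha, s, "ha")
    land(m * (1 - pha), s, "none")
    nr <- if (s == 2L) "nonrecip_mild" else "nonrecip_modplus"
    ev[[nr]] <<- ev[[nr]] + m * (1 - pha)
  }

  branch <- function(wmass, dev) {
    for (s in 1:5) {
      m <- wmass * sev_probs[s]
      if (m <= 0) next
      incident <- if (entry) s != 1L else s != sev_i
      if (!is.null(therapy) && incident &&
          .severity_names[s] %in% therapy$eligibility) {
        ev[["therapy"]] <<- ev[["therapy"]] + m
        if (therapy$efficacy > 0) {
          s2 <- .recover_index(s, therapy$recovery)
          land(m * therapy$efficacy, s2,
               if (s2 == 1L || dev != "ha") "none" else "ha")
        }
        m <- m * (1 - therapy$efficacy)
        if (m <= 0) next
      }
      if (dev == "ha") {
        if (s == 5L && incident) {
          # existing hearing-aid users presenting with profound loss still
          # undergo implant candidacy first
          ci <- m * pathway$p_need_ci
          ev[["implant"]] <<- ev[["implant"]] + ci
          land(ci, 5L, "ci")
          m <- m - ci
        }
        land(m, s, "ha")
      } else if (dev == "abandoned") {
        # the device was given up this cycle: no uptake redraw until later
        land(m, s, "none")
      } else {
        if (incident || annual_uptake) arrive_uptake(m, s) else land(m, s, "none")
      }
    }
  }

  if (device == "ha" && w_nonuse > 0) {
    branch(1 - w_nonuse, "ha")
    branch(w_nonuse, "abandoned")
  } else {
    branch(1, device)
  }
  list(p = p, ev = ev)
}

# Per-age-band transition structure conditional on survival: an 11 x 11
# row-stochastic matrix B, an 11 x n_events matrix of expected event counts
# per surviving occupant, and the per-origin probability of remaining in the
# hearing-aid state set (used to age device vintages).
.build_band <- function(params, band, therapy = NULL) {
  sev <- params$severity[[band]]
  pw <- params$pathway
  st <- params$settings
  annual <- identical(st$uptake_timing, "annual")
  nonuse_flow <- identical(st$ha_nonuse, "transition")
  B <- matrix(0, 11, 11, dimnames = list(.state_names, .state_names))
  EV <- matrix(0, 11, length(.event_names),
               dimnames = list(.state_names, .event_names))
  for (i in 1:9) {
    is_ha <- i %in% .ha_states
    w <- if (is_ha && nonuse_flow) {
      pw$p_ha_nonuse[[.severity_names[.state_severity[i]]]]
    } else 0
    r <- .compose_row(sev[.state_severity[i], ], .state_severity[i],
                      if (is_ha) "ha" else "none", pw, therapy,
                      annual_uptake = annual, w_nonuse = w)
    B[i, ] <- r$p
    EV[i, ] <- r$ev
  }
  # CI users: annual non-use/device failure reverts to unaided profound
  B[.ci_state, .unaided_state[5L]] <- pw$p_ci_failure
  B[.ci_state, .ci_state] <- 1 - pw$p_ci_failure
  B[.dead_state, .dead_state] <- 1
  if (any(B < 0)) stop("internal error: negative composed transition probability")
  ha_keep <- rowSums(B[, .ha_states, drop = FALSE])
  list(B = B, EV = EV, ha_keep = ha_keep)
}

.band_of_age <- function(age) {
  ifelse(age < 60, "50-59", ifelse(age < 70, "60-69", "70+"))
}

#' Full 11-state annual transition matrix at a given age
#'
#' Composes the severity transition row set for the relevant age band with
#' the care-pathway device-uptake logic and the age-specific death
#' probability into the complete row-stochastic matrix over the eleven
#' model states. Mortality competes first: every living state moves to
#' death with probability `q` and follows the severity/pathway composition
#' with probability `1 - q`.
#'
#' @param params An `arhl_parameters` object.
#' @param age Age in years (selects the age band and, unless `q` is given,
#'   the death probability).
#' @param q Optional override of the annual death probability.
#' @param therapy Optional [therapy_scenario()] applied to incident
#'   severity inflow before device uptake.
#' @return An 11 x 11 row-stochastic matrix (rows sum to 1 within 1e-10;
#'   death is absorbing).
#' @export
#' @examples
#' M <- expand_transition_matrix(default_parameters(), age = 55)
#' rowSums(M)
expand_transition_matrix <- function(params, age, q = NULL, therapy = NULL) {
  if (is.null(q)) {
    q <- params$mortality$q[match(age, params$mortality$age)]
    if (is.na(q)) stop("age outside mortality schedule coverage", call. = FALSE)
  }
  stopifnot(q >= 0, q <= 1)
  band <- .band_of_age(age)
  B <- .build_band(params, band, therapy)$B
  M <- (1 - q) * B
  M[, .dead_state] <- M[, .dead_state] + q
  M[.dead_state, ] <- 0
  M[.dead_state, .dead_state] <- 1
  M
}
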