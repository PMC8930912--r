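# Novel-therapeutic scenarios: who is eligible, how far hearing recovers,
# how often the therapy works, and what one administration costs.

#' Define a novel-therapeutic scenario
#'
#' A scenario specifies which hearing-loss severities are eligible for the
#' regenerative therapy, the recovery rule applied to responders, the
#' per-administration response probability, and the per-administration
#' price. Therapy is administered to each cycle's *incident* entrants into
#' an eligible severity (uptake 100% under the headroom assumption);
#' responders move per the recovery rule, non-responders continue into
#' standard-care device uptake, and responders whose hearing loss later
#' re-progresses are treated again.
#'
#' @param eligibility Character vector, subset of
#'   `c("mild", "moderate", "severe", "profound")`.
#' @param recovery One of `"to_normal"`, `"back_1"`, `"back_2"`: full
#'   restoration of normal hearing, or improvement by one or two severity
#'   levels (floored at normal).
#' @param efficacy Probability of response per administration, in \[0, 1\].
#' @param price Price per administration, GBP (default 0, the headroom
#'   assumption).
#' @param retreatment Whether responders who re-progress may be treated
#'   again (default TRUE).
#' @param label Optional display label; composed from the rule and
#'   eligibility when omitted.
#' @return Object of class `therapy_scenario`.
#' @export
#' @examples
#' therapy_scenario("profound", "to_normal", efficacy = 1)
therapy_scenario <- function(eligibility = c("mild", "moderate", "severe", "profound"),
                             recovery = c("to_normal", "back_1", "back_2"),
                             efficacy = 1, price = 0, retreatment = TRUE,
                             label = NULL) {
  recovery <- match.arg(recovery)
  elig_idx <- .severity_index(eligibility)
  if (any(elig_idx == 1L)) {
    stop("normal hearing is not a treatable severity", call. = FALSE)
  }
  stopifnot(efficacy >= 0, efficacy <= 1, price >= 0)
  structure(
    list(eligibility = .severity_names[sort(unique(elig_idx))],
         recovery = recovery, efficacy = efficacy, price = price,
         retreatment = isTRUE(retreatment),
         label = label %||% sprintf("%s / %s", recovery,
                                    paste(eligibility, collapse = "+"))),
    class = "therapy_scenario"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Severity index a responder recovers to. Partial recovery moves a patient
# back exactly k severity bands (so a two-band recovery restores a moderate
# deficit to normal hearing). A mild deficit has no intermediate band: its
# only possible improvement is full restoration, which the scenario
# definitions reserve for the full-recovery rule, so mild responders keep
# their mild classification under the partial rules.
.recover_index <- function(sev_idx, recovery) {
  if (recovery == "to_normal") return(rep(1L, length(sev_idx)))
  k <- if (recovery == "back_1") 1L else 2L
  ifelse(sev_idx == 2L, 2L, pmax(1L, sev_idx - k))
}

#' Apply a therapy scenario to an inflow of incident hearing-loss cases
#'
#' Distributes the occupancy mass entering each severity this cycle across
#' the post-therapy severities: every eligible entrant is administered the
#' therapy, a fraction equal to the efficacy responds and moves per the
#' recovery rule, and the remainder (plus all ineligible inflow) stays put.
#' Administrations are counted regardless of response.
#'
#' @param inflow Named numeric vector of non-negative masses entering each
#'   severity (names from [severity_levels()], `normal` allowed and passed
#'   through).
#' @param scenario A [therapy_scenario()].
#' @return List with `distribution` (post-therapy mass per severity) and
#'   `administrations` (total doses given).
#' @export
#' @examples
#' sc <- therapy_scenario(recovery = "to_normal", efficacy = 1)
#' apply_therapy(c(mild = 0.04), sc)
apply_therapy <- function(inflow, scenario) {
  stopifnot(inherits(scenario, "therapy_scenario"))
  if (any(inflow < 0)) stop("inflow masses must be non-negative", call. = FALSE)
  idx <- .severity_index(names(inflow))
  out <- stats::setNames(numeric(5), .severity_names)
  administrations <- 0
  for (k in seq_along(inflow)) {
    s <- idx[k]
    m <- inflow[[k]]
    if (.severity_names[s] %in% scenario$eligibility) {
      administrations <- administrations + m
      s2 <- .recover_index(s, scenario$recovery)
      out[s2] <- out[s2] + m * scenario$efficacy
      out[s] <- out[s] + m * (1 - scenario$efficacy)
    } else {
      out[s] <- out[s] + m
    }
  }
  list(distribution = out, administrations = administrations)
}

#' The six published therapy scenarios
#'
#' Scenario 1 is the headroom case (full recovery, all severities); 2 and 3
#' weaken the recovery rule to one or two severity levels; 4-6 restrict
#' eligibility to progressively more severe hearing loss. All assume a
#' 100%-effective therapy at zero cost.
#'
#' @return List of six [therapy_scenario()] objects.
#' @export
#' @examples
#' sapply(scenario_catalog(), function(s) s$label)
scenario_catalog <- function() {
  all_sev <- c("mild", "moderate", "severe", "profound")
  list(
    therapy_scenario(all_sev, "to_normal", label = "1: to normal, all severities"),
    therapy_scenario(all_sev, "back_1", label = "2: back 1 state, all severities"),
    therapy_scenario(all_sev, "back_2", label = "3: back 2 states, all severities"),
    therapy_scenario(c("moderate", "severe", "profound"), "to_normal",
                     label = "4: to normal, moderate+"),
    therapy_scenario(c("severe", "profound"), "to_normal",
                     label = "5: to normal, severe+"),
    therapy_scenario("profound", "to_normal", label = "6: to normal, profound only")
  )
}

#' @export
print.therapy_scenario <- function(x, ...) {
  cat(sprintf("Therapy scenario: %s\n  efficacy %.0f%%, price GBP %s/administration\n",
              x$label, 100 * x$efficacy, format(x$price, big.mark = ",")))
  invisible(x)
}
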