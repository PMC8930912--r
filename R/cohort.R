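# Deterministic cohort engine: iterate state occupancy through the
# age-specific transition matrices, recording the costed event flows.

.flow_names <- c("ha_fittings", "ha_refits", "ha_assessments", "ci_implants",
                 "ci_assessments", "ci_upgrades", "complications",
                 "therapy_administrations")

#' Run the cohort simulation
#'
#' Propagates the state-occupancy distribution of a cohort entering at the
#' model entry age through the age-specific 11-state transition matrices,
#' one annual cycle at a time, until the terminal age (by which death is
#' certain). The engine is fully deterministic: it tracks expected
#' fractions of the cohort, not sampled individuals. Alongside occupancy it
#' records per-cycle expected event flows per initial cohort member:
#' hearing-aid fittings and replacements, assessments not leading to a
#' hearing aid, cochlear implantations, candidacy assessments without
#' implantation, processor upgrades (charged at implant anniversaries),
#' expected major complications, and therapy administrations.
#'
#' Cycle 0 holds the entry distribution after the entry presentation
#' (therapy and device uptake applied to any cohort members entering with
#' hearing loss); cycle t >= 1 holds post-transition occupancy after the
#' transition at age `entry_age + t - 1`.
#'
#' @param params An `arhl_parameters` object.
#' @param therapy Optional [therapy_scenario()]; `NULL` is standard care.
#' @param horizon Number of annual cycles; defaults to
#'   `max_age - entry_age + 1`, which fully absorbs the cohort.
#' @return Object of class `arhl_trace` with matrices `occupancy`
#'   (`horizon + 1` rows, 11 state columns, fractions of the initial
#'   cohort) and `flows` (expected events per initial cohort member), plus
#'   the cycle and age indices.
#' @export
#' @examples
#' tr <- run_cohort(default_parameters())
#' colSums(tr$flows)["ci_implants"]  # lifetime implants per person
run_cohort <- function(params, therapy = NULL, horizon = NULL) {
  st <- params$settings
  if (!is.null(therapy)) {
    stopifnot(inherits(therapy, "therapy_scenario"))
    if (!therapy$retreatment) {
      stop("the cohort engine models incident presentations as independent episodes; ",
           "retreatment = FALSE is not supported", call. = FALSE)
    }
  }
  if (is.null(horizon)) horizon <- st$max_age - st$entry_age + 1L
  if (horizon < 0) stop("horizon must be non-negative", call. = FALSE)
  ages <- st$entry_age + seq_len(horizon) - 1L
  qv <- params$mortality$q[match(ages, params$mortality$age)]
  if (anyNA(qv)) {
    stop("horizon exceeds mortality schedule coverage", call. = FALSE)
  }

  bands <- unique(.band_of_age(ages))
  bm <- lapply(stats::setNames(bands, bands), function(b) {
    .build_band(params, b, therapy)
  })

  occupancy <- matrix(0, horizon + 1L, 11L,
                      dimnames = list(0:horizon, .state_names))
  flows <- matrix(0, horizon + 1L, length(.flow_names),
                  dimnames = list(0:horizon, .flow_names))

  co <- params$costs
  pw <- params$pathway
  pa_mild <- co$p_assess_no_ha[["mild"]]
  pa_modp <- co$p_assess_no_ha[["moderate_plus"]]
  ci_assess_ratio <- co$p_assess_no_ci / (1 - co$p_assess_no_ci)

  # entry presentation: members entering with hearing loss are treated (if
  # eligible) and draw device uptake like incident cases
  init <- st$init_severity[.severity_names]
  ent <- .compose_row(init, sev_i = NA_integer_, device = "none",
                      pathway = pw, therapy = therapy, entry = TRUE,
                      annual_uptake = identical(st$uptake_timing, "annual"))
  x <- ent$p
  flows[1L, ] <- c(ent$ev[["fit"]], 0,
                   ent$ev[["nonrecip_mild"]] * pa_mild +
                     ent$ev[["nonrecip_modplus"]] * pa_modp,
                   ent$ev[["implant"]],
                   ent$ev[["implant"]] * ci_assess_ratio,
                   0,
                   ent$ev[["implant"]] * pw$p_major_complication_y1,
                   ent$ev[["therapy"]])
  occupancy[1L, ] <- x

  # device vintages: mass by completed years since fitting/implantation,
  # used to time hearing-aid replacements and processor upgrades
  refit_int <- co$ha_refit_interval
  upg_int <- co$ci_upgrade_interval
  ha_v <- if (refit_int > 0) ent$ev[["fit"]] else numeric(0)
  ci_v <- ent$ev[["implant"]]

  for (t in seq_len(horizon)) {
    qa <- qv[t]
    bnd <- bm[[.band_of_age(ages[t])]]
    living <- x[1:10]
    surv <- (1 - qa) * living

    evs <- as.vector(surv %*% bnd$EV[1:10, , drop = FALSE])
    names(evs) <- .event_names
    fit_t <- evs[["fit"]]
    implant_t <- evs[["implant"]]
    assess_t <- evs[["nonrecip_mild"]] * pa_mild +
      evs[["nonrecip_modplus"]] * pa_modp

    xl <- as.vector(surv %*% bnd$B[1:10, 1:10, drop = FALSE])
    x <- c(xl, x[11L] + qa * sum(living))

    # age hearing-aid vintages by the aggregate retention of the HA pool
    refit_t <- 0
    if (refit_int > 0) {
      ha_mass <- sum(living[.ha_states])
      keep <- if (ha_mass > 0) {
        sum(surv[.ha_states] * bnd$ha_keep[.ha_states]) / ha_mass
      } else 0
      ha_v <- c(0, ha_v * keep)
      if (length(ha_v) > refit_int) {
        refit_t <- sum(ha_v[(refit_int + 1L):length(ha_v)])
        ha_v <- ha_v[seq_len(refit_int)]
      }
      ha_v[1L] <- ha_v[1L] + fit_t + refit_t
    }

    # cochlear-implant vintages decay exactly (death and device failure)
    ci_v <- c(0, ci_v * (1 - qa) * (1 - pw$p_ci_failure))
    vage <- seq_along(ci_v) - 1L
    upgrade_t <- if (upg_int > 0) {
      sum(ci_v[vage > 0 & vage %% upg_int == 0])
    } else 0
    ci_v[1L] <- implant_t

    occupancy[t + 1L, ] <- x
    flows[t + 1L, ] <- c(fit_t, refit_t, assess_t, implant_t,
                         implant_t * ci_assess_ratio, upgrade_t,
                         implant_t * pw$p_major_complication_y1,
                         evs[["therapy"]])
  }

  structure(
    list(occupancy = occupancy, flows = flows, cycles = 0:horizon,
         ages = c(st$entry_age, ages), states = .state_names),
    class = "arhl_trace"
  )
}

#' Tidy export of a cohort trace
#'
#' @param x An `arhl_trace`.
#' @param what `"occupancy"` (one row per cycle and state) or `"flows"`
#'   (one row per cycle and event type).
#' @param ... Unused.
#' @return A data.frame in long format.
#' @export
as.data.frame.arhl_trace <- function(x, ..., what = c("occupancy", "flows")) {
  what <- match.arg(what)
  m <- x[[what]]
  data.frame(
    cycle = rep(x$cycles, times = ncol(m)),
    age = rep(x$ages, times = ncol(m)),
    name = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    row.names = NULL
  )
}

#' @export
print.arhl_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  cat(sprintf("Cohort trace: %d cycles, ages %d-%d\n", n - 1L,
              x$ages[1L], x$ages[n]))
  cat(sprintf("  dead by end: %.1f%%; lifetime therapy administrations %.3f per person\n",
              100 * x$occupancy[n, .dead_state],
              sum(x$flows[, "therapy_administrations"])))
  invisible(x)
}

# undiscounted expected life years lived in the model (post-transition
# person-years, i.e. completed years from entry)
.life_years <- function(trace) {
  sum(1 - trace$occupancy[-1L, .dead_state])
}
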