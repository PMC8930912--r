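# Probabilistic sensitivity analysis: distributional assumptions per
# parameter family (Dirichlet for transition rows and multi-category
# probabilities, Beta for utilities and single probabilities, Gamma for
# unit costs) and the per-draw sampler.

#' Settings for probabilistic sensitivity analysis
#'
#' @param iterations Number of PSA draws (default 10,000).
#' @param seed Root seed; per-draw substreams are keyed by draw index so
#'   that compared strategies share parameter draws (common random numbers).
#' @param ess Effective sample size behind each Dirichlet row and
#'   Beta-sampled pathway probability (default 100). `Inf` collapses these
#'   draws to their means.
#' @param cost_cv Coefficient of variation of the Gamma cost distributions
#'   (default 0.10, i.e. costs varied by 10%). `0` collapses cost draws.
#' @param level Interval level for percentile summaries (default 0.95).
#' @param fi_prob_se Assumed standard error for the functional-impairment
#'   probabilities, which are published without one (default 0.05).
#' @param derived_utility_se Assumed standard error for sampled utility
#'   decrements/increments (functional-impairment and aided utilities,
#'   published without standard errors; default 0.03, the standard error of
#'   the mild-to-severe base utilities).
#' @param se_scale Multiplier on every utility standard error (0 collapses
#'   utility draws; useful for degeneracy checks).
#' @return Object of class `psa_spec`.
#' @export
psa_spec <- function(iterations = 10000, seed = 1, ess = 100, cost_cv = 0.10,
                     level = 0.95, fi_prob_se = 0.05,
                     derived_utility_se = 0.03, se_scale = 1) {
  stopifnot(iterations >= 1, ess > 0, cost_cv >= 0, level > 0, level <= 1,
            se_scale >= 0)
  structure(list(iterations = as.integer(iterations), seed = seed, ess = ess,
                 cost_cv = cost_cv, level = level, fi_prob_se = fi_prob_se,
                 derived_utility_se = derived_utility_se, se_scale = se_scale),
            class = "psa_spec")
}

#' Beta shape parameters from a mean and standard error
#'
#' Method of moments: \eqn{\nu = m(1-m)/se^2 - 1}, \eqn{\alpha = m\nu},
#' \eqn{\beta = (1-m)\nu}.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @return Named vector `c(shape1, shape2)`.
#' @export
#' @examples
#' beta_from_mean_se(0.80, 0.03)  # ~ c(141.42, 35.36)
beta_from_mean_se <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)", call. = FALSE)
  if (se^2 >= mean * (1 - mean)) {
    stop("infeasible moments: se^2 must be below mean * (1 - mean)", call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Gamma shape and scale from a mean and coefficient of variation
#'
#' `shape = 1/cv^2`, `scale = mean * cv^2`, so the distribution has the
#' stated mean and standard deviation `cv * mean`.
#'
#' @param mean Mean cost, GBP (> 0; zero-cost items are fixed, not sampled).
#' @param cv Coefficient of variation.
#' @return Named vector `c(shape, scale)`.
#' @export
#' @examples
#' gamma_from_mean_cv(275, 0.10)  # shape 100, scale 2.75
gamma_from_mean_cv <- function(mean, cv) {
  if (mean <= 0) stop("mean must be positive (zero-cost items are fixed)",
                      call. = FALSE)
  c(shape = 1 / cv^2, scale = mean * cv^2)
}

#' Dirichlet concentration vector for a transition row
#'
#' Scales the row by the effective sample size; structural zeros keep a
#' zero concentration and are excluded from the draw (reinserted as exact
#' zeros), so impossible transitions stay impossible across all draws.
#'
#' @param probs Probability row summing to 1.
#' @param ess Effective sample size.
#' @return Concentration vector `probs * ess`.
#' @export
dirichlet_row <- function(probs, ess) {
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1", call. = FALSE)
  probs * ess
}

# one Dirichlet draw honoring structural zeros
.rdirichlet_row <- function(probs, ess) {
  if (!is.finite(ess)) return(probs)
  out <- numeric(length(probs))
  nz <- probs > 0
  if (sum(nz) <= 1L) return(probs)
  g <- stats::rgamma(sum(nz), shape = probs[nz] * ess, rate = 1)
  if (sum(g) == 0) return(probs)  # degenerate underflow guard
  out[nz] <- g / sum(g)
  out
}

# Beta draw by mean/se; collapses when se is 0
.rbeta_ms <- function(mean, se) {
  if (se <= 0) return(mean)
  if (mean <= 0 || mean >= 1) return(mean)
  sh <- beta_from_mean_se(mean, min(se, sqrt(mean * (1 - mean)) * 0.999))
  stats::rbeta(1, sh[1], sh[2])
}

# Beta draw parameterized as a two-category Dirichlet with ESS
.rbeta_ess <- function(mean, ess) {
  if (!is.finite(ess) || mean <= 0 || mean >= 1) return(mean)
  stats::rbeta(1, mean * ess, (1 - mean) * ess)
}

.rgamma_cv <- function(mean, cv) {
  if (cv <= 0 || mean <= 0) return(mean)
  p <- gamma_from_mean_cv(mean, cv)
  stats::rgamma(1, shape = p[["shape"]], scale = p[["scale"]])
}

# deterministic per-draw substream seed, below 2^31
.draw_seed <- function(seed, draw_index) {
  (abs(seed) %% 20011 + 1) * 100003 + draw_index
}

#' Sample one uncertain parameter set
#'
#' Draws a complete model parameter set from the per-family uncertainty
#' distributions: severity transition rows from Dirichlet distributions
#' (concentration `mean * ess`, structural zeros preserved); pathway and
#' proportion parameters from Beta distributions; utilities from Beta
#' distributions with the published standard errors, with the
#' functional-impairment and aided utilities sampled as decrements below /
#' increments above the base severity utility so that the orderings
#' (FI below base, aided above unaided) hold in every draw; and unit costs
#' from Gamma distributions with a fixed coefficient of variation. The
#' mortality schedule, discount rate and therapy price are not sampled.
#'
#' Reproducible: the random stream is keyed by `(spec$seed, draw_index)`,
#' so strategies compared draw-by-draw share parameter sets.
#'
#' @param base An `arhl_parameters` object (the deterministic means).
#' @param spec A [psa_spec()].
#' @param draw_index Positive integer identifying the draw.
#' @return An `arhl_parameters` object.
#' @export
sample_parameter_set <- function(base, spec, draw_index) {
  set.seed(.draw_seed(spec$seed, draw_index))
  p <- base
  ess <- spec$ess

  for (bn in names(p$severity)) {
    m <- p$severity[[bn]]
    for (r in 1:4) m[r, ] <- .rdirichlet_row(m[r, ], ess)
    p$severity[[bn]] <- m
  }

  pw <- p$pathway
  pw$p_functional_impairment[] <- vapply(
    pw$p_functional_impairment, .rbeta_ms, numeric(1),
    se = spec$fi_prob_se * spec$se_scale)
  pw$p_receive_ha[] <- vapply(pw$p_receive_ha, .rbeta_ess, numeric(1), ess = ess)
  pw$p_need_ci <- .rbeta_ess(pw$p_need_ci, ess)
  pw$p_ha_nonuse[] <- vapply(pw$p_ha_nonuse, .rbeta_ess, numeric(1), ess = ess)
  pw$p_ci_failure <- .rbeta_ess(pw$p_ci_failure, ess)
  pw$p_major_complication_y1 <- .rbeta_ess(pw$p_major_complication_y1, ess)
  p$pathway <- pw

  u <- p$utilities
  dse <- spec$derived_utility_se * spec$se_scale
  base_u <- u$base
  for (s in names(base_u)) {
    base_u[s] <- .rbeta_ms(u$base[[s]], u$se_base[[s]] * spec$se_scale)
  }
  fi <- base_u
  for (s in names(fi)) {
    dec <- .rbeta_ms(u$base[[s]] - u$functional[[s]], dse)
    fi[s] <- max(0, base_u[s] - dec)
  }
  aided <- u$aided
  aided_fi <- u$aided_functional
  for (s in names(aided)) {
    inc <- .rbeta_ms(u$aided[[s]] - u$base[[s]], dse)
    aided[s] <- min(1, base_u[s] + inc)
    dec <- .rbeta_ms(u$aided[[s]] - u$aided_functional[[s]], dse)
    aided_fi[s] <- max(0, aided[s] - dec)
  }
  u$base <- base_u
  u$functional <- fi
  u$aided <- aided
  u$aided_functional <- aided_fi
  u$ci <- .rbeta_ms(base$utilities$ci, base$utilities$se_ci * spec$se_scale)
  p$utilities <- u

  co <- p$costs
  cv <- spec$cost_cv
  for (f in c("ha_monaural", "ha_binaural", "ha_aftercare", "hearing_evaluation",
              "ci_device", "ci_candidacy", "ci_maintenance_y1", "ci_maintenance",
              "ci_upgrade", "major_complication")) {
    co[[f]] <- .rgamma_cv(base$costs[[f]], cv)
  }
  co$p_binaural <- .rbeta_ess(co$p_binaural, ess)
  co$p_assess_no_ha[] <- vapply(co$p_assess_no_ha, .rbeta_ess, numeric(1), ess = ess)
  co$p_assess_no_ci <- .rbeta_ess(co$p_assess_no_ci, ess)
  p$costs <- co

  p
}

#' Percentile interval of a sample
#'
#' Linear-interpolation (inclusive) percentiles at `(1 - level)/2` and
#' `1 - (1 - level)/2`, the convention of spreadsheet percentile functions.
#'
#' @param samples Numeric vector (at least two values).
#' @param level Interval level in (0, 1\]; `1` returns the range.
#' @return Named vector `c(low, high)`.
#' @export
#' @examples
#' percentile_interval(0:100, 0.95)  # c(2.5, 97.5)
percentile_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2L) {
    stop("at least two samples are required", call. = FALSE)
  }
  a <- (1 - level) / 2
  q <- stats::quantile(samples, c(a, 1 - a), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}
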