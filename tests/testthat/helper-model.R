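# Shared fixtures and the independent Monte-Carlo oracle.

base_params <- default_parameters()

# parameter set with selective overrides, revalidated
params_with <- function(p = base_params, ...) {
  mods <- list(...)
  for (nm in names(mods)) {
    parts <- strsplit(nm, "\\.")[[1]]
    if (length(parts) == 2) {
      p[[parts[1]]][[parts[2]]] <- mods[[nm]]
    } else {
      p[[nm]] <- mods[[nm]]
    }
  }
  p
}

# Independent individual-level microsimulation: samples n patient paths
# through the same age-specific transition matrices the cohort engine
# composes, and tabulates occupancy. Used as an oracle for the deterministic
# cohort trace.
simulate_microcohort <- function(params, therapy = NULL, n = 200000, seed = 42) {
  set.seed(seed)
  st <- params$settings
  horizon <- st$max_age - st$entry_age + 1L
  ages <- st$entry_age + seq_len(horizon) - 1L
  ent <- arhlce:::.compose_row(
    st$init_severity, NA_integer_, "none", params$pathway, therapy,
    entry = TRUE, annual_uptake = identical(st$uptake_timing, "annual"))
  state <- sample.int(11L, n, replace = TRUE, prob = ent$p)
  occ <- matrix(0, horizon + 1L, 11L)
  occ[1L, ] <- tabulate(state, 11L) / n
  for (t in seq_len(horizon)) {
    M <- expand_transition_matrix(params, ages[t], therapy = therapy)
    new_state <- state
    for (s in setdiff(unique(state), 11L)) {
      idx <- which(state == s)
      new_state[idx] <- sample.int(11L, length(idx), replace = TRUE,
                                   prob = M[s, ])
    }
    state <- new_state
    occ[t + 1L, ] <- tabulate(state, 11L) / n
  }
  occ
}

# standardized deviations between cohort occupancy and microsimulated
# occupancy (binomial standard errors, floored at two simulated patients)
microsim_z <- function(trace, micro, n) {
  se <- sqrt(pmax(trace$occupancy * (1 - trace$occupancy), 0) / n)
  abs(trace$occupancy - micro) / pmax(se, 2 / n)
}

fixture_path <- function() {
  system.file("extdata", "params_paper2018.yaml", package = "arhlce")
}

# build a minimal trace by hand (for accrual arithmetic tests)
manual_trace <- function(occupancy, flows = NULL, cycles = NULL) {
  states <- health_states()
  if (is.null(cycles)) cycles <- seq_len(nrow(occupancy)) - 1L
  if (is.null(flows)) {
    flows <- matrix(0, nrow(occupancy), length(arhlce:::.flow_names),
                    dimnames = list(cycles, arhlce:::.flow_names))
  }
  colnames(occupancy) <- states
  structure(list(occupancy = occupancy, flows = flows, cycles = cycles,
                 ages = cycles + 50, states = states),
            class = "arhl_trace")
}

# occupancy matrix with all mass in one state for every cycle
single_state_occupancy <- function(state, n_cycles) {
  occ <- matrix(0, n_cycles, 11)
  occ[, match(state, health_states())] <- 1
  occ
}
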