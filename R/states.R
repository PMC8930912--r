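# State space of the hearing-care pathway model.
#
# Severity of hearing loss (PTA-classified) crossed with device status gives
# ten living states plus death. Hearing-aid (HA) states persist once a device
# is fitted; the cochlear-implant (CI) state is reachable only from incident
# profound hearing loss.

.state_names <- c(
  "normal",
  "mild_unaided", "mild_ha",
  "moderate_unaided", "moderate_ha",
  "severe_unaided", "severe_ha",
  "profound_unaided", "profound_ha",
  "profound_ci",
  "dead"
)

.severity_names <- c("normal", "mild", "moderate", "severe", "profound")

# severity index (1..5) of each state; NA for death
.state_severity <- c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, NA_integer_)

# state index for the unaided / HA state of each severity (HA: NA for normal)
.unaided_state <- c(1L, 2L, 4L, 6L, 8L)
.ha_state <- c(NA_integer_, 3L, 5L, 7L, 9L)

.ha_states <- c(3L, 5L, 7L, 9L)
.ci_state <- 10L
.dead_state <- 11L

#' Health states of the hearing-loss pathway model
#'
#' The model distinguishes eleven mutually exclusive states: normal hearing;
#' mild, moderate, severe and profound hearing loss, each split into unaided
#' and hearing-aided; profound hearing loss with a cochlear implant; and
#' death.
#'
#' @return Character vector of the eleven state names, in model order
#'   (death last).
#' @export
#' @examples
#' health_states()
health_states <- function() .state_names

#' Severity labels used throughout the model
#'
#' @return Character vector: normal, mild, moderate, severe, profound.
#' @export
severity_levels <- function() .severity_names

# map a severity label (or vector) to its index, with validation
.severity_index <- function(x) {
  i <- match(x, .severity_names)
  if (anyNA(i)) {
    stop("unknown severity: ", paste(x[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}
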