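# Structured-text configuration: load and write the complete parameter set
# as YAML, with missing fields falling back to the bundled defaults. The
# bundled fixture (inst/extdata/params_paper2018.yaml) carries the full
# published parameter set.

#' Path to the bundled parameter fixture
#'
#' @return File path of the packaged YAML parameter set.
#' @export
default_config_path <- function() {
  system.file("extdata", "params_paper2018.yaml", package = "arhlce",
              mustWork = TRUE)
}

# recursively overlay non-NULL config values on defaults
.overlay <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- .overlay(base[[nm]], over[[nm]])
    } else if (is.numeric(base[[nm]]) && !is.null(names(base[[nm]])) &&
               is.list(over[[nm]])) {
      v <- unlist(over[[nm]])
      unknown <- setdiff(names(v), names(base[[nm]]))
      if (length(unknown)) {
        stop("unknown config field: ", nm, "$", unknown[1], call. = FALSE)
      }
      base[[nm]][names(v)] <- v
    } else {
      base[[nm]] <- if (is.list(over[[nm]])) unlist(over[[nm]]) else over[[nm]]
    }
  }
  base
}

#' Load model parameters from a configuration document
#'
#' Reads a YAML document whose keys mirror the parameter structure
#' (`severity_transitions`, `pathway`, `utilities`, `costs`, `settings`,
#' `mortality`, optionally `therapy`). Missing fields fall back to the
#' bundled defaults; severity transition rows are passed through
#' [repair_severity_table()]; every invariant is validated on load, with
#' violations reported by field name. A `therapy` block, when present, is
#' attached as the `"therapy"` attribute of the result.
#'
#' @param source Path to a YAML file, or a YAML string.
#' @return A validated `arhl_parameters` object.
#' @export
#' @examples
#' p <- load_config(default_config_path())
#' identical(p$costs$ci_device, default_parameters()$costs$ci_device)
load_config <- function(source) {
  doc <- if (is.character(source) && length(source) == 1L && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  doc <- doc %||% list()
  base <- default_parameters()

  if (!is.null(doc$severity_transitions)) {
    raw <- lapply(doc$severity_transitions, function(band) {
      m <- do.call(rbind, band)
      colnames(m) <- .severity_names
      m
    })
    rep <- repair_severity_table(raw)
    base$severity <- rep$bands
    attr(base, "repair_log") <- rep$log
  }
  for (sec in c("pathway", "utilities", "costs", "settings")) {
    if (!is.null(doc[[sec]])) base[[sec]] <- .overlay(base[[sec]], doc[[sec]])
  }
  if (!is.null(doc$mortality)) {
    mo <- doc$mortality
    base$mortality <- if (!is.null(mo$lifetable)) {
      build_mortality_schedule(lifetable = mo$lifetable,
                               entry_age = base$settings$entry_age,
                               max_age = base$settings$max_age)
    } else if (!is.null(mo$age)) {
      build_mortality_schedule(
        lifetable = data.frame(age = unlist(mo$age), q = unlist(mo$q)),
        entry_age = base$settings$entry_age, max_age = base$settings$max_age)
    } else {
      build_mortality_schedule(makeham = mo$makeham %||% .default_gm$makeham,
                               slope = mo$slope %||% .default_gm$slope,
                               rate = mo$rate %||% .default_gm$rate,
                               entry_age = base$settings$entry_age,
                               max_age = base$settings$max_age)
    }
  } else if (!is.null(doc$settings)) {
    # settings may change the age range; rebuild the default schedule over it
    gm <- attr(base$mortality, "parametric")
    base$mortality <- build_mortality_schedule(
      makeham = gm$makeham, slope = gm$slope, rate = gm$rate,
      entry_age = base$settings$entry_age, max_age = base$settings$max_age)
  }
  validate_parameters(base)
  if (!is.null(doc$therapy)) {
    th <- doc$therapy
    attr(base, "therapy") <- therapy_scenario(
      eligibility = unlist(th$eligibility),
      recovery = th$recovery %||% "to_normal",
      efficacy = th$efficacy %||% 1,
      price = th$price %||% 0,
      retreatment = th$retreatment %||% TRUE
    )
  }
  base
}

#' Write model parameters to a configuration file
#'
#' Serializes an `arhl_parameters` object as YAML that [load_config()]
#' reads back to an equal object. The severity table is written in its
#' repaired form; a parametric mortality schedule is written as its
#' Gompertz-Makeham parameters, a tabulated one as inline age/q columns.
#'
#' @param params An `arhl_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  sev <- lapply(params$severity, function(m) {
    lapply(stats::setNames(rownames(m), rownames(m)), function(r) unname(m[r, ]))
  })
  veclist <- function(v) as.list(v)
  gm <- attr(params$mortality, "parametric")
  mo <- if (!is.null(gm)) {
    gm
  } else {
    list(age = params$mortality$age, q = params$mortality$q)
  }
  doc <- list(
    severity_transitions = sev,
    pathway = lapply(params$pathway, function(x) if (length(x) > 1) veclist(x) else x),
    utilities = lapply(params$utilities, function(x) if (length(x) > 1) veclist(x) else x),
    costs = lapply(params$costs, function(x) if (length(x) > 1) veclist(x) else x),
    settings = lapply(params$settings, function(x) if (length(x) > 1) veclist(x) else x),
    mortality = mo
  )
  th <- attr(params, "therapy")
  if (!is.null(th)) {
    doc$therapy <- list(eligibility = th$eligibility, recovery = th$recovery,
                        efficacy = th$efficacy, price = th$price,
                        retreatment = th$retreatment)
  }
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
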