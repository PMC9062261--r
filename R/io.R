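# CSV/JSON writers and run-configuration loading.

.fmt12 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Write and read simulation time series as CSV
#'
#' One row per grid time; columns are species then (optionally) fluxes, in
#' the fixed registry order, with unit annotations in the header
#' (`ATP_c[mM]`, `dPsi[mV]`, `J_CK[mM/s]`).  Values are written with 12
#' significant digits; write -> read -> write is byte-identical.
#'
#' @param result A [SimulationResult-class].
#' @param path output file.
#' @param fluxes include flux columns.
#' @return the path, invisibly (`writeTimeseries`); a data.frame with the
#'   annotated column names (`readTimeseries`).
#' @export
writeTimeseries <- function(result, path, fluxes = TRUE) {
  spTab <- result@model@species
  units <- stats::setNames(spTab$unit, spTab$name)
  cols <- c("time[s]",
            sprintf("%s[%s]", colnames(result@states),
                    units[colnames(result@states)]))
  m <- cbind(result@times, result@states)
  if (fluxes) {
    fx <- colnames(result@fluxes)
    funit <- ifelse(fx %in% .thermoNames(),
                    ifelse(fx == "aF1", "unitless", "kJ/mol"), "mM/s")
    cols <- c(cols, sprintf("J_%s[%s]", fx, funit))
    m <- cbind(m, result@fluxes)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  body <- apply(m, 1, function(r) paste(.fmt12(r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeTimeseries
#' @export
readTimeseries <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a metrics or sensitivity report
#'
#' Metrics lists are written as JSON keyed by metric name; sensitivity
#' reports (data.frames) as CSV with columns enzyme, pathway, S, rank.
#'
#' @param x metrics list (from [irMetrics()]) or report data.frame (from
#'   [sensitivityReport()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReport <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Load and validate a run configuration
#'
#' A YAML document describing one run: optional model `overrides` (list of
#' `{path, value, multiplicative}`), a `protocol` block (`type`:
#' constant/standard/two-step plus fractions and times), optional `solver`
#' settings and an `outputs` block (`trajectory`, `fluxes`, `metrics`,
#' `sensitivity`).  All validation problems are reported together.
#'
#' @param path YAML file.
#' @return a validated `cardioRunConfig` list with elements `model`,
#'   `protocol`, `settings`, `outputs`.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  errs <- character()

  model <- defaultModel()
  for (ov in doc$overrides) {
    bad <- setdiff(names(ov), c("path", "value", "multiplicative"))
    if (length(bad) || is.null(ov$path) || is.null(ov$value)) {
      errs <- c(errs, paste0("malformed override: ",
                             paste(deparse(ov), collapse = "")))
      next
    }
    res <- tryCatch(
      applyOverrides(model, list(parameterOverride(
        ov$path, as.numeric(ov$value), isTRUE(ov$multiplicative)))),
      error = function(e) conditionMessage(e))
    if (is.character(res)) errs <- c(errs, res) else model <- res
  }

  prot <- doc$protocol
  type <- if (is.null(prot$type)) "standard" else prot$type
  protocol <- tryCatch(switch(
    type,
    constant = oxygenProtocol(data.frame(
      start = 0, end = prot$tEnd %||% 3000, fraction = prot$fraction %||% 1),
      label = "constant"),
    standard = standardProtocol(prot$ischemicFraction %||% 0.01,
                                prot$tIschStart %||% 1000,
                                prot$tRep %||% 2000, prot$tEnd %||% 3000),
    "two-step" = twoStepProtocol(prot$ischemicFraction %||% 0.005,
                                 prot$step1Fraction %||% 0.05,
                                 prot$tIsch %||% 1000, prot$tStep1 %||% 2000,
                                 prot$tStep2 %||% 3000, prot$tEnd %||% 4000),
    stop("unknown protocol type: ", type)),
    error = function(e) {
      errs <<- c(errs, conditionMessage(e)); NULL
    })

  sv <- doc$solver
  settings <- tryCatch(
    solverSettings(rtol = sv$rtol %||% 1e-8, atolConc = sv$atolConc %||% 1e-10,
                   atolPsi = sv$atolPsi %||% 1e-6,
                   gridDt = sv$gridDt %||% 1, method = sv$method %||% "lsoda"),
    error = function(e) {
      errs <<- c(errs, conditionMessage(e)); NULL
    })

  out <- doc$outputs
  outputs <- list(trajectory = out$trajectory %||% TRUE,
                  fluxes = out$fluxes %||% TRUE,
                  metrics = out$metrics %||% FALSE,
                  sensitivity = out$sensitivity %||% FALSE)

  known <- c("overrides", "protocol", "solver", "outputs")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config field(s): ",
                           paste(unknown, collapse = ", ")))
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(list(model = model, protocol = protocol, settings = settings,
                 outputs = outputs), class = "cardioRunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
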