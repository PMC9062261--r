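# SimulationResult accessors.

#' Simulation result accessors
#'
#' @param result A [SimulationResult-class].
#' @param species,flux column name(s).
#' @return `resultTimes`: the output time grid (s); `speciesTrace` /
#'   `fluxTrace`: named numeric trajectory of one column; `as.data.frame`:
#'   time, states and fluxes side by side.
#' @export
resultTimes <- function(result) result@times

#' @rdname resultTimes
#' @export
speciesTrace <- function(result, species) {
  if (!species %in% colnames(result@states))
    stop("unknown species: ", species)
  stats::setNames(result@states[, species], NULL)
}

#' @rdname resultTimes
#' @export
fluxTrace <- function(result, flux) {
  if (!flux %in% colnames(result@fluxes))
    stop("unknown flux: ", flux)
  stats::setNames(result@fluxes[, flux], NULL)
}

#' @rdname resultTimes
#' @param x A [SimulationResult-class].
#' @param row.names,optional,... passed on conventionally (unused).
#' @export
as.data.frame.SimulationResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(time = x@times, x@states,
             stats::setNames(as.data.frame(x@fluxes),
                             paste0("J_", colnames(x@fluxes))),
             check.names = FALSE)
}

# value of a column at (exactly) the given time; boundary rows keep the
# pre-switch value, so stateAt(result, onset) is the pre-ischemic state.
.traceAt <- function(result, column, time, flux = FALSE) {
  i <- which(abs(result@times - time) < 1e-9)
  if (!length(i)) {
    # fall back to linear interpolation
    tr <- if (flux) fluxTrace(result, column) else speciesTrace(result, column)
    return(stats::approx(result@times, tr, xout = time)$y)
  }
  unname(if (flux) result@fluxes[i[1], column] else result@states[i[1], column])
}
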