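# Scalar ischemia/reperfusion readouts extracted from a SimulationResult.

# first downward crossing of `thresh` at/after time t0 (linear interpolation);
# NA if never crossed
.crossDownTime <- function(times, x, thresh, t0) {
  sel <- times >= t0
  t <- times[sel]; v <- x[sel]
  below <- v < thresh
  if (!any(below)) return(NA_real_)
  i <- which(below)[1]
  if (i == 1) return(t[1])
  # interpolate between the last point at/above and the first below
  t[i - 1] + (thresh - v[i - 1]) * (t[i] - t[i - 1]) / (v[i] - v[i - 1])
}

#' Time to cytosolic ATP depletion
#'
#' Elapsed time from ischemia onset until cytosolic ATP first falls below
#' `thresholdFrac` of its pre-ischemic value (the state at the last instant
#' before the oxygen step-down), linearly interpolated between grid points.
#' The "depleted" threshold is not a printed quantity; the defaults are 5%
#' ("depleted") and 1% ("approaches zero") of the pre-ischemic level.
#'
#' @param result A [SimulationResult-class] of a protocol with an ischemic
#'   segment.
#' @param thresholdFrac depletion threshold as a fraction of pre-ischemic ATP.
#' @return elapsed seconds since ischemia onset, or NA if never depleted.
#' @export
atpDepletionTime <- function(result, thresholdFrac = 0.05) {
  onset <- .ischemiaOnset(result@protocol)
  pre <- .traceAt(result, "ATP_c", onset)
  tc <- .crossDownTime(result@times, speciesTrace(result, "ATP_c"),
                       thresholdFrac * pre, onset)
  if (is.na(tc)) NA_real_ else unname(tc - onset)
}

# generic settling time: first time >= t0 from which the trace stays within
# tolFrac of its final value
.settleTime <- function(times, x, t0, tolFrac) {
  sel <- times >= t0
  t <- times[sel]; v <- x[sel]
  final <- v[length(v)]
  tol <- tolFrac * max(abs(final), 1e-12)
  ok <- abs(v - final) <= tol
  # last index that violates the band; settle just after it
  bad <- which(!ok)
  if (!length(bad)) return(t[1])
  i <- bad[length(bad)]
  if (i == length(t)) return(NA_real_)
  # interpolate the band entry between t[i] and t[i+1]
  lo <- final - tol; hi <- final + tol
  b <- if (v[i] < lo) lo else hi
  t[i] + (b - v[i]) * (t[i + 1] - t[i]) / (v[i + 1] - v[i])
}

#' Post-reperfusion recovery time of a species
#'
#' First time after the final oxygen restoration at which the trace enters,
#' and remains within, `tolFrac` of its final value; reported as elapsed
#' seconds since the restoration.  `species` may also be `"ATP:ADP"` for the
#' cytosolic ATP-to-ADP concentration ratio.
#'
#' @param result A [SimulationResult-class] with a reperfusion segment.
#' @param species species name (or `"ATP:ADP"`).
#' @param tolFrac settling band as a fraction of the final value.
#' @return elapsed seconds, or NA (with a warning) if the trace has not
#'   settled by the end of the simulation.
#' @export
recoveryTime <- function(result, species = "ATP_c", tolFrac = 0.05) {
  t0 <- .finalRestoration(result@protocol)
  x <- if (identical(species, "ATP:ADP")) {
    speciesTrace(result, "ATP_c") / pmax(speciesTrace(result, "ADP_c"), 1e-9)
  } else speciesTrace(result, species)
  ts <- .settleTime(result@times, x, t0, tolFrac)
  if (is.na(ts)) {
    warning(species, " has not settled by the end of the simulation")
    return(NA_real_)
  }
  ts - t0
}

#' Membrane-potential readouts of an ischemia/reperfusion run
#'
#' @param result A [SimulationResult-class].
#' @param spikeBand spike-duration threshold as a multiple of the
#'   pre-ischemic potential.
#' @return list with `plateau` (dPsi at the end of the ischemic segment, mV),
#'   `spikeRatio` (max reperfusion dPsi over the pre-ischemic value) and
#'   `spikeDuration` (total time above `spikeBand` x pre-ischemic, s).
#' @export
dpsiMetrics <- function(result, spikeBand = 1.1) {
  onset <- .ischemiaOnset(result@protocol)
  rep0 <- .reperfusionOnset(result@protocol)
  pre <- .traceAt(result, "dPsi", onset)
  plateau <- .traceAt(result, "dPsi", rep0)
  sel <- result@times >= rep0
  t <- result@times[sel]; v <- speciesTrace(result, "dPsi")[sel]
  above <- v > spikeBand * pre
  dur <- if (any(above)) sum(diff(t)[above[-length(above)]]) else 0
  list(plateau = unname(plateau), spikeRatio = unname(max(v) / pre),
       spikeDuration = unname(dur))
}

#' Reverse-electron-transport interval at complex I
#'
#' The maximal contiguous interval after reperfusion onset during which the
#' complex-I rate is negative (electrons flowing from ubiquinol back to NAD+).
#'
#' @param result A [SimulationResult-class].
#' @return numeric `c(start, end)` in absolute seconds, or NULL if complex I
#'   never runs in reverse after reperfusion.
#' @export
retInterval <- function(result) {
  rep0 <- .reperfusionOnset(result@protocol)
  sel <- result@times >= rep0
  t <- result@times[sel]; v <- fluxTrace(result, "C1")[sel]
  neg <- v < 0
  if (!any(neg)) return(NULL)
  runs <- rle(neg)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  negruns <- which(runs$values)
  len <- t[ends[negruns]] - t[starts[negruns]]
  k <- negruns[which.max(len)]
  c(start = t[starts[k]], end = t[ends[k]])
}

#' Complex-III reperfusion spike ratio
#'
#' Maximum complex-III rate within `window` seconds after reperfusion onset,
#' relative to the pre-ischemic steady rate.
#'
#' @param result A [SimulationResult-class].
#' @param window search window after reperfusion onset (s).
#' @return fold change (dimensionless).
#' @export
c3SpikeRatio <- function(result, window = 60) {
  onset <- .ischemiaOnset(result@protocol)
  rep0 <- .reperfusionOnset(result@protocol)
  pre <- .traceAt(result, "C3", onset, flux = TRUE)
  if (pre <= 0) stop("pre-ischemic complex-III rate is not positive")
  sel <- result@times >= rep0 & result@times <= rep0 + window
  unname(max(fluxTrace(result, "C3")[sel]) / pre)
}

#' All ischemia/reperfusion injury-surrogate metrics
#'
#' @param result A [SimulationResult-class].
#' @param depletionFrac threshold for [atpDepletionTime()].
#' @param recoveryTol settling band for [recoveryTime()].
#' @return named list: `atp_depletion_time`, `atp_recovery_time`,
#'   `dpsi_ischemic_plateau`, `dpsi_spike_ratio`, `dpsi_spike_duration`,
#'   `ret_interval` (or NULL), `c3_spike_ratio`, `crp_recovery_time`,
#'   `atp_adp_settle_time`.
#' @export
irMetrics <- function(result, depletionFrac = 0.05, recoveryTol = 0.05) {
  dp <- dpsiMetrics(result)
  list(
    atp_depletion_time   = atpDepletionTime(result, depletionFrac),
    atp_recovery_time    = suppressWarnings(recoveryTime(result, "ATP_c", recoveryTol)),
    dpsi_ischemic_plateau = dp$plateau,
    dpsi_spike_ratio     = dp$spikeRatio,
    dpsi_spike_duration  = dp$spikeDuration,
    ret_interval         = retInterval(result),
    c3_spike_ratio       = c3SpikeRatio(result),
    crp_recovery_time    = suppressWarnings(recoveryTime(result, "CrP_c", recoveryTol)),
    atp_adp_settle_time  = suppressWarnings(recoveryTime(result, "ATP:ADP", recoveryTol))
  )
}
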