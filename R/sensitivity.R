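# Finite-difference metabolic sensitivity analysis.
#
# "Activity" of an enzyme/transporter is a multiplicative scaling of its
# maximal-rate constant(s); for reversible Michaelis-Menten forms the forward
# and reverse maxima are scaled jointly, preserving the equilibrium constant.

# lean trajectory evaluation: full states at the requested absolute times
.statesAt <- function(model, protocol, at, settings, initState = NULL) {
  seg <- protocol@segments
  physO2 <- model@species$initial[model@species$name == "O2_v"]
  state <- if (is.null(initState)) initialState(model) else initState
  state <- applyAssignments(state[.speciesOrder()], model)
  odesp <- .odeSpecies()
  out <- matrix(NA_real_, length(at), length(state),
                dimnames = list(NULL, names(state)))
  for (k in seq_len(nrow(seg))) {
    o2v <- seg$fraction[k] * physO2
    pvec <- .paramVector(model, fraction = seg$fraction[k])
    # a time exactly on a boundary is evaluated in the earlier segment
    # (pre-switch state; the state itself is continuous across the switch)
    inSeg <- which(at > seg$start[k] & at <= seg$end[k])
    times <- sort(unique(c(seg$start[k], seg$end[k], at[inSeg])))
    sol <- .integrateSegment(state[odesp], times, pvec, settings)
    m <- sol$out
    if (length(inSeg)) {
      rows <- match(at[inSeg], m[, "time"])
      for (r in seq_along(inSeg)) {
        st <- state
        st[odesp] <- m[rows[r], odesp]
        st["O2_v"] <- o2v
        out[inSeg[r], ] <- applyAssignments(st, model)
      }
    }
    state[odesp] <- m[nrow(m), odesp]
    state["O2_v"] <- o2v
    state <- applyAssignments(state, model)
  }
  out
}

#' Relative sensitivities of species to enzyme activities
#'
#' For each enzyme j, the protocol is re-simulated with the activity scaled by
#' (1 +/- delta) and the relative sensitivity of species i is the central
#' difference s_ij = (C+ - C-) / (2 delta C0), i.e. dC_i/dX_j * X_j/C_i --
#' the relative concentration change per relative activity change.
#' Constant-kind species are excluded; a species with zero unperturbed
#' concentration at a timepoint is reported NA and excluded from aggregation.
#'
#' One perturbed simulation traverses the whole protocol, so all timepoints
#' are read from the same pair of runs (2 stiff solves per enzyme).
#'
#' @param model A [CardioModel-class].
#' @param protocol An [OxygenProtocol-class].
#' @param timepoints named numeric vector of evaluation times (s); defaults
#'   to the end of the pre-ischemic phase, the end of ischemia and 1000 s
#'   after reperfusion under the standard protocol.
#' @param delta relative perturbation, in (0, 0.1].
#' @param settings A [SolverSettings-class].
#' @param enzymes reaction identifiers to perturb (default: all).
#' @param initState optional pre-equilibrated starting state.
#' @return A [SensitivityAnalysis-class].
#' @export
relativeSensitivities <- function(model, protocol,
                                  timepoints = c(physiol = 1000,
                                                 ischemia = 2000,
                                                 reperfusion = 3000),
                                  delta = 0.01,
                                  settings = solverSettings(),
                                  enzymes = names(.activityMap()),
                                  initState = NULL) {
  if (!is.numeric(delta) || delta <= 0 || delta > 0.1)
    stop("delta must lie in (0, 0.1]")
  tEnd <- max(protocol@segments$end)
  if (any(timepoints <= 0 | timepoints > tEnd))
    stop("timepoints must lie within the protocol span")
  spTab <- speciesTable(model)
  rows <- spTab$name[spTab$kind != "constant"]
  base <- .statesAt(model, protocol, timepoints, settings, initState)

  coef <- array(NA_real_, c(length(rows), length(enzymes), length(timepoints)),
                dimnames = list(rows, enzymes, names(timepoints)))
  for (j in seq_along(enzymes)) {
    up <- .statesAt(.scaleActivity(model, enzymes[j], 1 + delta),
                    protocol, timepoints, settings, initState)
    dn <- .statesAt(.scaleActivity(model, enzymes[j], 1 - delta),
                    protocol, timepoints, settings, initState)
    for (k in seq_along(timepoints)) {
      c0 <- base[k, rows]
      s <- (up[k, rows] - dn[k, rows]) / (2 * delta * c0)
      s[c0 == 0] <- NA_real_
      coef[, j, k] <- s
    }
  }
  new("SensitivityAnalysis", coefficients = coef,
      timepoints = timepoints, delta = delta, protocol = protocol)
}

#' Aggregate sensitivities to per-enzyme control scores
#'
#' The overall control exerted by enzyme j is the L1 norm over species of its
#' relative sensitivities, S_j = sum_i |s_ij|, ranked in descending order
#' (ties broken lexicographically by enzyme name).
#'
#' @param sens A [SensitivityAnalysis-class].
#' @return data.frame with columns `timepoint`, `enzyme`, `pathway`, `S`,
#'   `rank`.
#' @export
sensitivityReport <- function(sens) {
  amap <- .activityMap()
  out <- list()
  for (k in seq_len(dim(sens@coefficients)[3])) {
    m <- sens@coefficients[, , k, drop = FALSE][, , 1]
    S <- colSums(abs(m), na.rm = TRUE)
    ord <- order(-S, names(S))
    rk <- integer(length(S)); rk[ord] <- seq_along(S)
    out[[k]] <- data.frame(
      timepoint = dimnames(sens@coefficients)[[3]][k],
      enzyme = names(S),
      pathway = vapply(names(S), function(e) amap[[e]]$pathway, character(1)),
      S = unname(S), rank = rk, row.names = NULL)
  }
  res <- do.call(rbind, out)
  res[order(match(res$timepoint, dimnames(sens@coefficients)[[3]]), res$rank), ]
}
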