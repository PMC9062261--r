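# Oxygen protocols and time-course integration.

#' Solver settings constructor
#'
#' Defaults: vode (BDF) with rtol 1e-8, atol 1e-10 mM for concentrations and
#' 1e-6 mV for the membrane potential; 1 s output grid with an automatic
#' 0.05 s refinement window for 30 s after each oxygen step-up (resolving the
#' seconds-scale complex-III spike at reperfusion).
#'
#' @param rtol,atolConc,atolPsi integration tolerances.
#' @param maxStep maximum internal step size (s); the 1 s cap keeps the
#'   solver from over-stepping the violent post-switch transients.
#' @param gridDt,refineDt,refineWindow output grid control (s).
#' @param method deSolve stiff method identifier.
#' @return A [SolverSettings-class].
#' @export
solverSettings <- function(rtol = 1e-8, atolConc = 1e-10, atolPsi = 1e-6,
                           maxStep = 1, gridDt = 1, refineDt = 0.05,
                           refineWindow = 30, method = "vode") {
  new("SolverSettings", rtol = rtol, atolConc = atolConc, atolPsi = atolPsi,
      maxStep = maxStep, gridDt = gridDt, refineDt = refineDt,
      refineWindow = refineWindow, method = method)
}

#' Oxygen protocols
#'
#' `oxygenProtocol` builds a schedule from explicit segments.
#' `standardProtocol` is the canonical three-phase experiment: physiological
#' perfusion, ischemia at a reduced vessel-oxygen fraction, then full
#' reperfusion.  `twoStepProtocol` restores oxygen in two steps (a reduced
#' first reperfusion level before full restoration).
#'
#' @param segments data.frame with columns start, end (s) and fraction
#'   (vessel O2 as a fraction of the physiological 0.1326 mM, in (0, 1]).
#' @param label protocol label.
#' @return An [OxygenProtocol-class].
#' @examples
#' standardProtocol(0.01)
#' twoStepProtocol(0.005, 0.05)
#' @export
oxygenProtocol <- function(segments, label = "custom") {
  obj <- new("OxygenProtocol",
             segments = as.data.frame(segments)[, c("start", "end", "fraction")],
             label = label)
  validObject(obj)
  obj
}

#' @rdname oxygenProtocol
#' @param ischemicFraction vessel O2 during ischemia, fraction of physiological.
#' @param tIschStart,tRep,tEnd phase boundaries (s).
#' @export
standardProtocol <- function(ischemicFraction, tIschStart = 1000,
                             tRep = 2000, tEnd = 3000) {
  if (!is.numeric(ischemicFraction) || ischemicFraction <= 0 ||
      ischemicFraction > 1)
    stop("ischemicFraction must lie in (0, 1]")
  seg <- data.frame(start = c(0, tIschStart, tRep),
                    end = c(tIschStart, tRep, tEnd),
                    fraction = c(1, ischemicFraction, 1))
  oxygenProtocol(seg, label = sprintf("standard %g%%", 100 * ischemicFraction))
}

#' @rdname oxygenProtocol
#' @param step1Fraction vessel O2 during the first reperfusion step.
#' @param tIsch,tStep1,tStep2 phase boundaries of the two-step design (s).
#' @export
twoStepProtocol <- function(ischemicFraction, step1Fraction, tIsch = 1000,
                            tStep1 = 2000, tStep2 = 3000, tEnd = 4000) {
  if (any(c(ischemicFraction, step1Fraction) <= 0) ||
      any(c(ischemicFraction, step1Fraction) > 1))
    stop("oxygen fractions must lie in (0, 1]")
  seg <- data.frame(start = c(0, tIsch, tStep1, tStep2),
                    end = c(tIsch, tStep1, tStep2, tEnd),
                    fraction = c(1, ischemicFraction, step1Fraction, 1))
  oxygenProtocol(seg, label = sprintf("two-step %g%% / %g%%",
                                      100 * ischemicFraction,
                                      100 * step1Fraction))
}

#' Vessel-oxygen fraction at a time
#'
#' @param protocol An [OxygenProtocol-class].
#' @param time time (s); must be covered by the protocol.
#' @return oxygen fraction of physiological at `time`.
#' @export
oxygenAt <- function(protocol, time) {
  seg <- protocol@segments
  vapply(time, function(t) {
    i <- which(t >= seg$start & (t < seg$end | (t == seg$end & seg$end == max(seg$end))))
    if (!length(i)) stop("protocol undefined at time ", t)
    seg$fraction[i[1]]
  }, numeric(1))
}

# protocol landmarks used by the metrics module
.ischemiaOnset <- function(protocol) {
  seg <- protocol@segments
  i <- which(seg$fraction < 1)
  if (!length(i)) stop("protocol has no ischemic segment")
  seg$start[i[1]]
}
.reperfusionOnset <- function(protocol) {
  seg <- protocol@segments
  i <- which(seg$fraction < 1)
  if (!length(i)) stop("protocol has no ischemic segment")
  imin <- i[which.min(seg$fraction[i])]
  if (imin == nrow(seg)) stop("protocol has no reperfusion segment")
  seg$end[imin]
}
.finalRestoration <- function(protocol) {
  seg <- protocol@segments
  n <- nrow(seg)
  up <- which(diff(seg$fraction) > 0) + 1L
  if (!length(up)) stop("protocol has no oxygen step-up")
  seg$start[up[length(up)]]
}

.odeAtol <- function(settings) {
  odesp <- .odeSpecies()
  atol <- rep(settings@atolConc, length(odesp))
  atol[odesp == "dPsi"] <- settings@atolPsi
  atol
}

# integrate one constant-oxygen span on an explicit absolute time grid
.integrateSegment <- function(y0, times, pvec, settings) {
  out <- deSolve::ode(
    y = y0, times = times, func = "cardio_derivs", parms = pvec,
    dllname = "cardiomyosim", initfunc = "cardio_initmod",
    nout = length(.fluxNames()) + length(.thermoNames()),
    outnames = c(.fluxNames(), .thermoNames()),
    method = settings@method, rtol = settings@rtol, atol = .odeAtol(settings),
    hmax = if (is.finite(settings@maxStep)) settings@maxStep else NULL,
    maxsteps = 50000)
  di <- attributes(out)[c("istate", "rstate")]
  list(out = unclass(out), diagnostics = di)
}

.segmentGrid <- function(seg, k, settings) {
  times <- seq(seg$start[k], seg$end[k], by = settings@gridDt)
  if (times[length(times)] < seg$end[k]) times <- c(times, seg$end[k])
  if (k > 1 && seg$fraction[k] > seg$fraction[k - 1]) {
    refEnd <- min(seg$start[k] + settings@refineWindow, seg$end[k])
    times <- sort(unique(c(times, seq(seg$start[k], refEnd,
                                      by = settings@refineDt))))
  }
  times
}

#' Run a time-course simulation
#'
#' Integrates the full ODE system under a piecewise-constant oxygen protocol
#' with a stiff solver, restarting the integration at each protocol
#' discontinuity (the oxygen switches are instantaneous; no smoothing ramp).
#' States and all fluxes are recorded on the output grid.  The simulation is
#' deterministic for fixed settings.
#'
#' @param model A [CardioModel-class].
#' @param protocol An [OxygenProtocol-class].
#' @param settings A [SolverSettings-class].
#' @param initState optional named full state vector to start from (e.g. a
#'   pre-equilibrated steady state from [findSteadyState()]); defaults to the
#'   model's tabulated initial values.
#' @return A [SimulationResult-class].
#' @examples
#' \donttest{
#' sim <- runSimulation(defaultModel(), standardProtocol(0.01))
#' }
#' @export
runSimulation <- function(model, protocol, settings = solverSettings(),
                          initState = NULL) {
  stopifnot(is(model, "CardioModel"), is(protocol, "OxygenProtocol"),
            is(settings, "SolverSettings"))
  seg <- protocol@segments
  physO2 <- model@species$initial[model@species$name == "O2_v"]
  state <- if (is.null(initState)) initialState(model) else initState
  if (!all(.speciesOrder() %in% names(state)))
    stop("initState must cover the full species registry")
  state <- applyAssignments(state[.speciesOrder()], model)

  odesp <- .odeSpecies()
  rows <- list(); diag <- list()
  for (k in seq_len(nrow(seg))) {
    o2v <- seg$fraction[k] * physO2
    pvec <- .paramVector(model, fraction = seg$fraction[k])
    times <- .segmentGrid(seg, k, settings)
    y0 <- state[odesp]
    res <- .integrateSegment(y0, times, pvec, settings)
    m <- res$out
    if (k > 1) m <- m[-1, , drop = FALSE]  # boundary row kept from previous segment
    m <- cbind(m, O2_v = o2v)
    rows[[k]] <- m
    diag[[k]] <- res$diagnostics
    last <- res$out[nrow(res$out), ]
    state[odesp] <- last[odesp]
    state["O2_v"] <- o2v
    state <- applyAssignments(state, model)
  }
  raw <- do.call(rbind, rows)
  times <- raw[, "time"]

  # negative-concentration guard (the rate laws evaluate clamped-at-zero
  # concentrations, so small negative solver excursions are floored in the
  # output; substantive violations are an integration failure)
  conc <- setdiff(odesp, "dPsi")
  bad <- which(raw[, conc, drop = FALSE] < -0.1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative concentration: %s at t = %g s",
                 conc[bad[1, 2]], times[bad[1, 1]]))
  raw[, conc][raw[, conc] < 0] <- 0

  # reconstruct the full state matrix (constants + assignments + dPsi)
  init <- initialState(model)
  states <- matrix(0, nrow(raw), length(init),
                   dimnames = list(NULL, names(init)))
  states[, names(init)] <- rep(init, each = nrow(raw))
  states[, odesp] <- raw[, odesp]
  states[, "O2_v"] <- raw[, "O2_v"]
  p <- model@parameters
  states[, "mADP_c"] <- betaADP(states[, "ADP_c"], p$MgBc$KMgADP, p$phys$MgtotC)
  states[, "Mg_c"] <- p$phys$MgtotC - states[, "mADP_c"]
  states[, "ADP_i"] <- states[, "ADP_x"]
  states[, "ATP_i"] <- states[, "ATP_x"]

  fluxes <- raw[, c(.fluxNames(), .thermoNames()), drop = FALSE]
  new("SimulationResult", times = unname(times), states = states,
      fluxes = fluxes, protocol = protocol, settings = settings,
      model = model, diagnostics = diag)
}

#' Find the chemical steady state under constant oxygen
#'
#' Integrates the system under a constant vessel-oxygen fraction until the
#' scaled residual max_i |dC_i/dt| / max(|C_i|, floor) over all ODE species
#' falls below `tol`, and returns the settled state.
#'
#' @param model A [CardioModel-class].
#' @param o2Fraction constant vessel O2 (fraction of physiological).
#' @param settings A [SolverSettings-class].
#' @param tol convergence tolerance on the scaled residual (1/s).
#' @param floor concentration floor in the residual scaling (mM).
#' @param chunk integration span between residual checks (s).
#' @param maxTime give up (with an error) beyond this simulated time (s).
#' @param initState optional starting state.
#' @param exclude species ignored by the convergence criterion.  The lactate
#'   and lactic-acid pools are terminal accumulation sinks that drift on a
#'   much slower timescale than the energetic state and are excluded by
#'   default.
#' @return named full state vector at steady state, with attribute
#'   \code{residual}.
#' @export
findSteadyState <- function(model, o2Fraction = 1, settings = solverSettings(),
                            tol = 1e-5, floor = 1e-4, chunk = 5000,
                            maxTime = 2e5, initState = NULL,
                            exclude = c("LAC_c", "LACH_c")) {
  stopifnot(o2Fraction > 0, o2Fraction <= 1)
  physO2 <- model@species$initial[model@species$name == "O2_v"]
  pvec <- .paramVector(model, fraction = o2Fraction)
  state <- if (is.null(initState)) initialState(model) else initState
  state <- applyAssignments(state[.speciesOrder()], model)
  state["O2_v"] <- o2Fraction * physO2
  odesp <- .odeSpecies()

  watch <- setdiff(odesp, exclude)
  residual <- function(st) {
    d <- .Call(C_modelDerivs, as.numeric(st[.speciesOrder()]), as.numeric(pvec))
    names(d) <- .speciesOrder()
    max(abs(d[watch]) / pmax(abs(st[watch]), floor))
  }
  elapsed <- 0
  res <- residual(state)
  while (res > tol) {
    if (elapsed >= maxTime)
      stop(sprintf("no steady state within %g s (scaled residual %.3g)",
                   maxTime, res))
    sol <- .integrateSegment(state[odesp], c(0, chunk), pvec, settings)
    state[odesp] <- sol$out[nrow(sol$out), odesp]
    state <- applyAssignments(state, model)
    elapsed <- elapsed + chunk
    res <- residual(state)
  }
  attr(state, "residual") <- res
  state
}
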