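#' @import methods
NULL

#' Cardiomyocyte metabolic model
#'
#' Container for the complete kinetic model: the five-compartment geometry,
#' the species registry (names, compartments, units, initial values and
#' dynamics kind: \code{ode}, \code{assignment} or \code{constant}) and the
#' kinetic parameter set, nested by reaction.
#'
#' @slot compartments data.frame with columns \code{name}, \code{volume}
#'   (liters, cytosol = 1 l).
#' @slot species data.frame with columns \code{name}, \code{compartment},
#'   \code{unit}, \code{initial}, \code{kind}.
#' @slot parameters named list of per-reaction parameter lists plus the
#'   \code{phys} block of physical/structural constants.
#'
#' @seealso [defaultModel()], [applyOverrides()], [runSimulation()]
#' @export
setClass("CardioModel",
  representation(
    compartments = "data.frame",
    species      = "data.frame",
    parameters   = "list"
  )
)

setValidity("CardioModel", function(object) {
  msg <- character()
  cmp <- object@compartments
  if (!identical(sort(cmp$name),
                 sort(c("vessel", "extracellular", "cytosol", "ims", "matrix"))))
    msg <- c(msg, "compartments must be exactly vessel/extracellular/cytosol/ims/matrix")
  if (any(cmp$volume <= 0)) msg <- c(msg, "compartment volumes must be positive")
  sp <- object@species
  need <- c("name", "compartment", "unit", "initial", "kind")
  if (!all(need %in% names(sp))) {
    msg <- c(msg, "species table missing columns")
  } else {
    if (!identical(sp$name, .speciesOrder()))
      msg <- c(msg, "species must follow the canonical registry ordering")
    if (!all(sp$kind %in% c("ode", "assignment", "constant")))
      msg <- c(msg, "species kind must be ode/assignment/constant")
    if (anyNA(sp$initial)) msg <- c(msg, "species initial values must be finite")
  }
  flat <- tryCatch(.flattenParams(object@parameters), error = function(e) e)
  if (inherits(flat, "error")) {
    msg <- c(msg, conditionMessage(flat))
  } else {
    signed <- grepl("\\.dG0$", names(flat)) | names(flat) %in% "phys.aDH"
    isConst <- grepl("^const\\.", names(flat))
    if (any(flat[!signed & !isConst] <= 0))
      msg <- c(msg, "kinetic parameters (other than dG0 terms) must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Piecewise-constant vessel-oxygen schedule
#'
#' Ordered, contiguous segments of constant vessel oxygen, expressed as a
#' fraction of the physiological level (0.1326 mM).
#'
#' @slot segments data.frame with columns \code{start}, \code{end} (s) and
#'   \code{fraction} (of physiological vessel oxygen, in (0, 1]).
#' @slot label character protocol label.
#' @export
setClass("OxygenProtocol",
  representation(segments = "data.frame", label = "character")
)

setValidity("OxygenProtocol", function(object) {
  seg <- object@segments
  msg <- character()
  if (!all(c("start", "end", "fraction") %in% names(seg)))
    msg <- c(msg, "segments need start/end/fraction columns")
  else {
    if (nrow(seg) < 1) msg <- c(msg, "at least one segment required")
    if (any(seg$end <= seg$start)) msg <- c(msg, "segments must have end > start")
    if (nrow(seg) > 1 && any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-9))
      msg <- c(msg, "segments must be contiguous and non-overlapping")
    if (any(seg$fraction <= 0 | seg$fraction > 1))
      msg <- c(msg, "oxygen fractions must lie in (0, 1]")
    if (seg$start[1] != 0) msg <- c(msg, "protocol must start at t = 0")
  }
  if (length(msg)) msg else TRUE
})

#' Stiff-solver settings
#'
#' @slot rtol relative tolerance.
#' @slot atolConc absolute tolerance for concentrations (mM).
#' @slot atolPsi absolute tolerance for the membrane potential (mV).
#' @slot maxStep maximum internal step (s).
#' @slot gridDt output grid spacing (s).
#' @slot refineDt refined output spacing applied after each oxygen step-up (s).
#' @slot refineWindow duration of the refined window (s).
#' @slot method deSolve integrator identifier (stiff-capable).
#' @export
setClass("SolverSettings",
  representation(rtol = "numeric", atolConc = "numeric", atolPsi = "numeric",
                 maxStep = "numeric", gridDt = "numeric", refineDt = "numeric",
                 refineWindow = "numeric", method = "character")
)

setValidity("SolverSettings", function(object) {
  ok <- all(c(object@rtol, object@atolConc, object@atolPsi, object@maxStep,
              object@gridDt, object@refineDt, object@refineWindow) > 0)
  if (!ok) "all solver tolerances and step sizes must be positive" else TRUE
})

#' Time-course simulation result
#'
#' @slot times output time grid (s).
#' @slot states matrix (time x species) of the full state, including constant
#'   and assignment species and \code{dPsi}.
#' @slot fluxes matrix (time x flux) of all reaction/transport fluxes (mM/s).
#' @slot protocol the [OxygenProtocol-class] that was simulated.
#' @slot settings the [SolverSettings-class] used.
#' @slot model the [CardioModel-class] that was simulated.
#' @slot diagnostics list of solver diagnostics (per-segment step counts, ...).
#' @export
setClass("SimulationResult",
  representation(times = "numeric", states = "matrix", fluxes = "matrix",
                 protocol = "OxygenProtocol", settings = "SolverSettings",
                 model = "CardioModel", diagnostics = "list")
)

setValidity("SimulationResult", function(object) {
  msg <- character()
  if (length(object@times) != nrow(object@states))
    msg <- c(msg, "times and states disagree in length")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "time grid must be strictly increasing")
  if (nrow(object@fluxes) && nrow(object@fluxes) != length(object@times))
    msg <- c(msg, "flux trajectory must match the time grid")
  if (length(msg)) msg else TRUE
})

#' Finite-difference sensitivity analysis
#'
#' Relative sensitivities of every non-constant species to every
#' enzyme/transport activity, at one or more evaluation timepoints.
#'
#' @slot coefficients 3-d array (species x enzyme x timepoint) of relative
#'   sensitivity coefficients (dimensionless).
#' @slot timepoints named numeric vector of evaluation times (s).
#' @slot delta relative perturbation used for the central difference.
#' @slot protocol the protocol the perturbed trajectories followed.
#' @export
setClass("SensitivityAnalysis",
  representation(coefficients = "array", timepoints = "numeric",
                 delta = "numeric", protocol = "OxygenProtocol")
)

setMethod("show", "CardioModel", function(object) {
  sp <- object@species
  cat("CardioModel: cardiomyocyte energy metabolism\n")
  cat(sprintf("  %d compartments, %d species (%d ode, %d assignment, %d constant) + dPsi\n",
              nrow(object@compartments), nrow(sp) - 1L,
              sum(sp$kind == "ode") - 1L, sum(sp$kind == "assignment"),
              sum(sp$kind == "constant")))
  cat(sprintf("  %d reaction parameter blocks; [ATP]c = %g mM, dPsi = %g mV\n",
              length(object@parameters) - 1L,
              sp$initial[sp$name == "ATP_c"], sp$initial[sp$name == "dPsi"]))
})

setMethod("show", "OxygenProtocol", function(object) {
  cat(sprintf("OxygenProtocol '%s': %d segment(s), t in [0, %g] s\n",
              object@label, nrow(object@segments), max(object@segments$end)))
  seg <- object@segments
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  [%6g, %6g) s : %5.1f%% O2\n",
                seg$start[i], seg$end[i], 100 * seg$fraction[i]))
})

setMethod("show", "SolverSettings", function(object) {
  cat(sprintf("SolverSettings: %s, rtol %g, atol %g mM / %g mV, grid %g s\n",
              object@method, object@rtol, object@atolConc, object@atolPsi,
              object@gridDt))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d timepoints over [%g, %g] s (protocol '%s')\n",
              length(object@times), min(object@times), max(object@times),
              object@protocol@label))
  cat(sprintf("  %d state columns, %d flux columns\n",
              ncol(object@states), ncol(object@fluxes)))
})

setMethod("show", "SensitivityAnalysis", function(object) {
  d <- dim(object@coefficients)
  cat(sprintf("SensitivityAnalysis: %d species x %d enzymes x %d timepoint(s), delta = %g\n",
              d[1], d[2], d[3], object@delta))
})
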