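# The acceptance suite intentionally keeps several red reproduction
# checks; never let the progress reporter abort the run early over them.
options(testthat.progress.max_fails = 1e6)

# Shared expensive fixtures, computed once per test run.
.cache <- new.env(parent = emptyenv())

cachedModel <- function() {
  if (is.null(.cache$model)) .cache$model <- defaultModel()
  .cache$model
}

cachedSteadyState <- function() {
  if (is.null(.cache$steady))
    .cache$steady <- findSteadyState(cachedModel(), 1)
  .cache$steady
}

cachedSim <- function(fraction) {
  key <- paste0("sim", fraction)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- runSimulation(cachedModel(), standardProtocol(fraction),
                                   initState = cachedSteadyState())
  .cache[[key]]
}

# random strictly positive full states around the tabulated values
randomStates <- function(n, seed = 42) {
  set.seed(seed)
  m <- cachedModel()
  base <- applyAssignments(initialState(m), m)
  lapply(seq_len(n), function(i) {
    s <- base
    s[] <- base * exp(stats::runif(length(base), -0.5, 0.5))
    s["dPsi"] <- stats::runif(1, 20, 200)
    applyAssignments(s, m)
  })
}

# build a synthetic SimulationResult with prescribed traces (for metric tests)
syntheticResult <- function(times, states, fluxes, protocol) {
  m <- cachedModel()
  init <- initialState(m)
  sm <- matrix(rep(init, each = length(times)), nrow = length(times),
               dimnames = list(NULL, names(init)))
  for (nm in names(states)) sm[, nm] <- states[[nm]]
  fm <- matrix(0, length(times),
               length(cardiomyosim:::.fluxNames()) +
                 length(cardiomyosim:::.thermoNames()),
               dimnames = list(NULL, c(cardiomyosim:::.fluxNames(),
                                       cardiomyosim:::.thermoNames())))
  for (nm in names(fluxes)) fm[, nm] <- fluxes[[nm]]
  new("SimulationResult", times = times, states = sm, fluxes = fm,
      protocol = protocol, settings = solverSettings(), model = m,
      diagnostics = list())
}
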