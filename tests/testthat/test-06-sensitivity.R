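# Finite-difference sensitivity analysis on a shortened protocol (the full
# control table is exercised by the acceptance suite).

shortProtocol <- function() standardProtocol(0.01, tIschStart = 60,
                                             tRep = 120, tEnd = 180)

test_that("perturbation size is validated", {
  m <- cachedModel()
  expect_error(relativeSensitivities(m, shortProtocol(), delta = 0),
               "delta")
  expect_error(relativeSensitivities(m, shortProtocol(), delta = 0.5),
               "delta")
  expect_error(relativeSensitivities(m, shortProtocol(),
                                     timepoints = c(late = 999)),
               "within the protocol")
})

test_that("relative sensitivities are scale-free and rank consistently", {
  m <- cachedModel()
  ss <- cachedSteadyState()
  tps <- c(physiol = 60, ischemia = 120, reperfusion = 180)
  enz <- c("HK", "PFK", "ATPase", "Hle")
  sens <- relativeSensitivities(m, shortProtocol(), timepoints = tps,
                                enzymes = enz, initState = ss)
  expect_equal(dim(sens@coefficients)[2:3], c(length(enz), 3))
  expect_true(all(is.finite(sens@coefficients) | is.na(sens@coefficients)))

  rep <- sensitivityReport(sens)
  expect_setequal(unique(rep$enzyme), enz)
  expect_true(all(rep$S >= 0))
  # ranks are a permutation within each timepoint
  for (tp in names(tps))
    expect_setequal(rep$rank[rep$timepoint == tp], seq_along(enz))
  # glycolytic enzymes dominate the passive leak at the physiological point
  phys <- rep[rep$timepoint == "physiol", ]
  expect_gt(phys$S[phys$enzyme == "HK"], phys$S[phys$enzyme == "Hle"])
})

test_that("central differences agree with forward differences to O(delta)", {
  m <- cachedModel()
  ss <- cachedSteadyState()
  tps <- c(physiol = 60)
  delta <- 0.02
  sens <- relativeSensitivities(m, shortProtocol(), timepoints = tps,
                                delta = delta, enzymes = "HK",
                                initState = ss)
  # forward difference computed from the same machinery
  base <- cardiomyosim:::.statesAt(m, shortProtocol(), 60, solverSettings(),
                                   ss)
  up <- cardiomyosim:::.statesAt(
    cardiomyosim:::.scaleActivity(m, "HK", 1 + delta),
    shortProtocol(), 60, solverSettings(), ss)
  rows <- dimnames(sens@coefficients)[[1]]
  fwd <- (up[1, rows] - base[1, rows]) / (delta * base[1, rows])
  cen <- sens@coefficients[, "HK", 1]
  big <- abs(cen) > 0.05
  expect_true(any(big))
  expect_lt(max(abs(fwd[big] - cen[big]) / abs(cen[big])), 5 * delta * 10)
})

test_that("aggregation of an all-zero matrix gives lexicographic ranks", {
  sens <- new("SensitivityAnalysis",
              coefficients = array(0, c(3, 3, 1),
                                   dimnames = list(c("a", "b", "c"),
                                                   c("HK", "AK", "CK"),
                                                   "physiol")),
              timepoints = c(physiol = 1), delta = 0.01,
              protocol = shortProtocol())
  rep <- sensitivityReport(sens)
  expect_equal(rep$enzyme[order(rep$rank)], c("AK", "CK", "HK"))
})
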