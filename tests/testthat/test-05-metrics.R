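# Metric extraction on constructed trajectories with known answers, plus
# grid-invariance on a simulated run.

test_that("depletion time interpolates the threshold crossing", {
  prot <- standardProtocol(0.5, tIschStart = 100, tRep = 300, tEnd = 400)
  times <- seq(0, 400, by = 1)
  atp <- rep(8, length(times))
  # linear fall from 8 at t=100 to 0 at t=300: crosses 5% (0.4) at t=290
  fall <- times >= 100 & times <= 300
  atp[fall] <- 8 * (1 - (times[fall] - 100) / 200)
  atp[times > 300] <- 8
  res <- syntheticResult(times, list(ATP_c = atp), list(), prot)
  expect_equal(atpDepletionTime(res, 0.05), 190)
  # crossing exactly at a grid point
  expect_equal(atpDepletionTime(res, 0.5), 100)   # 4 reached at t=200
  expect_equal(atpDepletionTime(res, atp[times == 123][1] / 8 + 1e-12) + 100,
               123, tolerance = 1e-6)
  # never-crossing trace
  res2 <- syntheticResult(times, list(ATP_c = rep(8, length(times))),
                          list(), prot)
  expect_true(is.na(atpDepletionTime(res2)))
})

test_that("recovery time detects enter-and-remain settling", {
  prot <- standardProtocol(0.5, tIschStart = 100, tRep = 300, tEnd = 500)
  times <- seq(0, 500, by = 1)
  # exponential recovery from 2 to 8 after t=300 with tau=40:
  # within 5% of 8 (>7.6) from t = 300 - 40*log(0.4/6) ~ 408.3, then stays
  atp <- rep(8, length(times))
  rec <- times >= 300
  atp[rec] <- 8 - 6 * exp(-(times[rec] - 300) / 40)
  res <- syntheticResult(times, list(ATP_c = atp), list(), prot)
  final <- 8 - 6 * exp(-200 / 40)
  bandEntry <- 40 * log(6 / (0.05 * final + (8 - final)))
  expect_equal(recoveryTime(res, "ATP_c", 0.05), bandEntry, tolerance = 0.02)
  # constant trajectory settles immediately
  res2 <- syntheticResult(times, list(ATP_c = rep(8, length(times))),
                          list(), prot)
  expect_equal(recoveryTime(res2, "ATP_c"), 0)
})

test_that("membrane-potential readouts use the protocol landmarks", {
  prot <- standardProtocol(0.5, tIschStart = 100, tRep = 300, tEnd = 500)
  times <- seq(0, 500, by = 1)
  psi <- rep(160, length(times))
  psi[times > 100 & times <= 300] <- 60       # ischemic plateau
  spike <- times > 300 & times <= 360
  psi[spike] <- 320                           # 60 s overshoot
  res <- syntheticResult(times, list(dPsi = psi), list(), prot)
  dm <- dpsiMetrics(res)
  expect_equal(dm$plateau, 60)
  expect_equal(dm$spikeRatio, 2)
  expect_equal(dm$spikeDuration, 60, tolerance = 2)
})

test_that("reverse-electron-transport interval finds the negative run", {
  prot <- standardProtocol(0.5, tIschStart = 100, tRep = 300, tEnd = 500)
  times <- seq(0, 500, by = 1)
  c1 <- rep(0.5, length(times))
  c1[times >= 310 & times <= 340] <- -0.2
  res <- syntheticResult(times, list(), list(C1 = c1), prot)
  iv <- retInterval(res)
  expect_equal(unname(iv["start"]), 310)
  expect_equal(unname(iv["end"]), 340)
  res2 <- syntheticResult(times, list(), list(C1 = rep(0.5, length(times))),
                          prot)
  expect_null(retInterval(res2))
})

test_that("complex-III spike ratio is one for a constant rate", {
  prot <- standardProtocol(0.5, tIschStart = 100, tRep = 300, tEnd = 500)
  times <- seq(0, 500, by = 1)
  res <- syntheticResult(times, list(), list(C3 = rep(0.4, length(times))),
                         prot)
  expect_equal(c3SpikeRatio(res), 1)
  # spike within the 60 s window is picked up
  c3 <- rep(0.4, length(times)); c3[times == 310] <- 1.2
  res2 <- syntheticResult(times, list(), list(C3 = c3), prot)
  expect_equal(c3SpikeRatio(res2), 3)
  # error when the pre-ischemic rate is not positive
  c3z <- rep(0, length(times))
  res3 <- syntheticResult(times, list(), list(C3 = c3z), prot)
  expect_error(c3SpikeRatio(res3), "not positive")
})

test_that("extracted times are stable under grid refinement", {
  m <- cachedModel()
  ss <- cachedSteadyState()
  prot <- standardProtocol(0.005, tIschStart = 50, tRep = 650, tEnd = 750)
  s1 <- solverSettings()
  s2 <- solverSettings(gridDt = 0.5)
  a <- runSimulation(m, prot, s1, initState = ss)
  b <- runSimulation(m, prot, s2, initState = ss)
  da <- atpDepletionTime(a); db <- atpDepletionTime(b)
  expect_equal(da, db, tolerance = 1.5 / max(da, 1))  # within one coarse cell
  expect_equal(dpsiMetrics(a)$plateau, dpsiMetrics(b)$plateau,
               tolerance = 1e-6)
})

test_that("irMetrics aggregates every readout on a real run", {
  mets <- irMetrics(cachedSim(0.005))
  expect_named(mets, c("atp_depletion_time", "atp_recovery_time",
                       "dpsi_ischemic_plateau", "dpsi_spike_ratio",
                       "dpsi_spike_duration", "ret_interval",
                       "c3_spike_ratio", "crp_recovery_time",
                       "atp_adp_settle_time"))
  expect_gt(mets$dpsi_spike_ratio, 0)
  expect_gt(mets$c3_spike_ratio, 0)
  expect_true(is.na(mets$atp_depletion_time) || mets$atp_depletion_time > 0)
})
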