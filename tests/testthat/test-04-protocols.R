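# Oxygen schedules, time-course integration, steady-state search.

test_that("protocol constructors build the canonical designs", {
  p <- standardProtocol(0.01)
  expect_equal(nrow(p@segments), 3)
  expect_equal(p@segments$fraction, c(1, 0.01, 1))
  expect_equal(oxygenAt(p, c(0, 999, 1000, 1999, 2000, 3000)),
               c(1, 1, 0.01, 0.01, 1, 1))
  # 1% of the physiological 0.1326 mM vessel oxygen
  expect_equal(0.01 * 0.1326, 0.001326)

  q <- twoStepProtocol(0.005, 0.05)
  expect_equal(q@segments$fraction, c(1, 0.005, 0.05, 1))
  expect_equal(max(q@segments$end), 4000)
  # degenerate two-step (full first step) equals the standard design
  r <- twoStepProtocol(0.01, 1, tEnd = 4000)
  expect_equal(oxygenAt(r, c(500, 1500, 2500, 3500)), c(1, 0.01, 1, 1))

  expect_error(standardProtocol(0), "0, 1")
  expect_error(standardProtocol(1.5), "0, 1")
  expect_error(twoStepProtocol(0.01, 0), "0, 1")
  expect_error(oxygenAt(standardProtocol(0.01), 3001), "undefined")
})

test_that("the physiological steady state is a fixed point", {
  m <- cachedModel()
  ss <- cachedSteadyState()
  expect_lt(attr(ss, "residual"), 1e-5)
  const <- oxygenProtocol(data.frame(start = 0, end = 1000, fraction = 1),
                          "constant")
  sim <- runSimulation(m, const, initState = ss)
  first <- sim@states[1, ]
  last <- sim@states[nrow(sim@states), ]
  # energetic core stays put to 0.01% over a further 1000 s (slow terminal
  # pools - lactate/lactic acid and the glycogen-turnover intermediates -
  # drift on a far longer timescale and are assessed separately)
  core <- c("ATP_c", "ADP_c", "CrP_c", "Pi_c", "dPsi", "NADH_x", "Q_x",
            "Cred_i", "O2_c", "Pi_x", "H_x", "ATP_x")
  expect_lt(max(abs(last[core] - first[core]) / pmax(abs(first[core]), 1e-8)),
            1e-4)
  # constant species never move
  kinds <- stats::setNames(speciesTable(m)$kind, speciesTable(m)$name)
  consts <- setdiff(names(kinds)[kinds == "constant"], "O2_v")
  for (nm in consts)
    expect_true(all(sim@states[, nm] == sim@states[1, nm]))
})

test_that("conserved pools drift below 1e-6 relative over a full protocol", {
  sim <- cachedSim(0.01)
  for (pool in cardiomyosim:::.conservedPools()) {
    tot <- rowSums(sim@states[, pool, drop = FALSE])
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("simulation results are structurally sound", {
  sim <- cachedSim(0.01)
  expect_true(validObject(sim))
  expect_true(!is.unsorted(resultTimes(sim), strictly = TRUE))
  expect_true(all(is.finite(sim@states)))
  expect_true(all(is.finite(sim@fluxes)))
  # first row equals the (assignment-completed) initial state
  init <- applyAssignments(cachedSteadyState(), cachedModel())
  expect_equal(unname(sim@states[1, "ATP_c"]), unname(init["ATP_c"]))
  # refinement grid present after the reperfusion step-up
  dts <- diff(resultTimes(sim))
  expect_true(any(dts < 0.1))
})

test_that("halving solver tolerances leaves the potential trace stable", {
  m <- cachedModel()
  ss <- cachedSteadyState()
  prot <- standardProtocol(0.01, tIschStart = 100, tRep = 250, tEnd = 400)
  s1 <- solverSettings()
  s2 <- solverSettings(rtol = s1@rtol / 2, atolConc = s1@atolConc / 2,
                       atolPsi = s1@atolPsi / 2)
  a <- runSimulation(m, prot, s1, initState = ss)
  b <- runSimulation(m, prot, s2, initState = ss)
  common <- intersect(resultTimes(a), resultTimes(b))
  ia <- match(common, resultTimes(a)); ib <- match(common, resultTimes(b))
  rel <- max(abs(a@states[ia, "dPsi"] - b@states[ib, "dPsi"])) /
    max(abs(a@states[, "dPsi"]))
  expect_lt(rel, 1e-3)
})

test_that("deeper ischemia leaves less ATP at the end of the insult", {
  ends <- vapply(c(0.005, 0.01, 0.02), function(fr) {
    sim <- cachedSim(fr)
    i <- which.min(abs(resultTimes(sim) - 2000))
    sim@states[i, "ATP_c"]
  }, numeric(1))
  expect_true(all(diff(ends) > 0))
})

test_that("steady-state search reports failure when unreachable", {
  m <- cachedModel()
  expect_error(findSteadyState(m, 1, tol = 1e-14, maxTime = 5000,
                               chunk = 5000),
               "no steady state")
})
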