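# Right-hand-side assembly: stoichiometric cancellations, assignment rules,
# constant species, determinism.

test_that("assignment rules are idempotent and satisfy their definitions", {
  m <- cachedModel()
  for (st in randomStates(10, seed = 7)) {
    a1 <- applyAssignments(st, m)
    a2 <- applyAssignments(a1, m)
    expect_equal(a1, a2)
    expect_equal(unname(a1["mADP_c"]), betaADP(a1[["ADP_c"]]))
    expect_equal(unname(a1["Mg_c"] + a1["mADP_c"]), 5)
    expect_equal(unname(a1["ADP_x"]), unname(a1["fADP_x"] + a1["mADP_x"]))
    expect_equal(unname(a1["ADP_i"]), unname(a1["ADP_x"]))
    expect_equal(unname(a1["ATP_i"]), unname(a1["ATP_x"]))
  }
})

test_that("conserved pairs have exactly cancelling derivative rows", {
  m <- cachedModel()
  for (st in randomStates(10, seed = 11)) {
    d <- modelDerivatives(0, st, m)$derivatives
    expect_equal(unname(d["Cr_c"] + d["CrP_c"]), 0)
    expect_equal(unname(d["Mb_c"] + d["MbO2_c"]), 0)
    expect_equal(unname(d["Q_x"] + d["QH2_x"]), 0)
    expect_equal(unname(d["NAD_x"] + d["NADH_x"]), 0)
    expect_equal(unname(d["Cox_i"] + d["Cred_i"]), 0)
    # total matrix adenine: ANT and F1 shuffle within the pool
    expect_equal(unname(d["fADP_x"] + d["mADP_x"] + d["fATP_x"] + d["mATP_x"]),
                 0)
    # matrix magnesium: free + bound conserved
    expect_equal(unname(d["Mg_x"] + d["mADP_x"] + d["mATP_x"]), 0)
  }
})

test_that("constant-kind species have zero derivatives", {
  m <- cachedModel()
  kinds <- stats::setNames(speciesTable(m)$kind, speciesTable(m)$name)
  for (st in randomStates(5, seed = 13)) {
    d <- modelDerivatives(0, st, m)$derivatives
    expect_true(all(d[names(kinds)[kinds == "constant"]] == 0))
    expect_true(all(is.na(d[names(kinds)[kinds == "assignment"]])))
  }
})

test_that("the derivative of the matrix total adenine matches the printed rows", {
  # d[ADP]x = (J_ANT - J_F1)/Vx and d[ATP]x = (J_F1 - J_ANT)/Vx must emerge
  # from the free/bound split rows
  m <- cachedModel()
  Vx <- kineticParameters(m)$phys$Vx
  for (st in randomStates(5, seed = 17)) {
    res <- modelDerivatives(0, st, m)
    J <- res$fluxes
    d <- res$derivatives
    expect_equal(unname(d["fADP_x"] + d["mADP_x"]),
                 unname((J["ANT"] - J["F1"]) / Vx))
    expect_equal(unname(d["fATP_x"] + d["mATP_x"]),
                 unname((J["F1"] - J["ANT"]) / Vx))
  }
})

test_that("the RHS is deterministic and side-effect free", {
  m <- cachedModel()
  st <- randomStates(1, seed = 23)[[1]]
  d1 <- modelDerivatives(0, st, m)
  d2 <- modelDerivatives(100, st, m)  # autonomous given the vessel oxygen
  expect_identical(d1$derivatives, d2$derivatives)
  pv <- cardiomyosim:::.paramVector(m, fraction = 1)
  so <- cardiomyosim:::.speciesOrder()
  c1 <- .Call(cardiomyosim:::C_modelDerivs, as.numeric(st[so]), as.numeric(pv))
  c2 <- .Call(cardiomyosim:::C_modelDerivs, as.numeric(st[so]), as.numeric(pv))
  expect_identical(c1, c2)
})

test_that("membrane potential decays under a pure proton leak", {
  # with all charge-carrying fluxes silenced except the leak, the potential
  # relaxes monotonically (Table row reduces to -J_Hle/C_IM)
  m <- cachedModel()
  quiet <- applyOverrides(m, lapply(
    c("C1.X", "C3.X", "C4.X", "F1.X", "ANT.X"),
    parameterOverride, value = 1e-300))
  st <- applyAssignments(initialState(quiet), quiet)
  psis <- numeric(0); psi <- 170
  for (i in 1:5) {
    st["dPsi"] <- psi
    d <- modelDerivatives(0, st, quiet)$derivatives
    expect_lt(unname(d["dPsi"]), 0)
    psi <- psi - 20
  }
})
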