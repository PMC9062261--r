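# Rate laws: frozen hand-computed values, equilibrium zeros, monotonicity,
# and reference/compiled equivalence.

evalFluxes <- function(state) computeFluxes(state, cachedModel())

test_that("fluxes at the tabulated state match direct hand substitution", {
  m <- cachedModel()
  st <- applyAssignments(initialState(m), m)
  f <- evalFluxes(st)$fluxes
  # creatine kinase: 1e4 * (1.66e6 * 1e-5 * 25 * 7.94e-4 - 7 * 0)
  expect_equal(unname(f["CK"]), 3295.1, tolerance = 1e-10)
  # adenylate kinase: 1e4 * ((1e-5)^2 - 7 * 1e-5)
  expect_equal(unname(f["AK"]), 1e4 * (1e-10 - 7e-5), tolerance = 1e-12)
  # ATP consumption with the energy-state feedback
  expect_equal(unname(f["ATPase"]),
               0.39 / (1 + 0.0658 * 7 * 1e-5 / 7), tolerance = 1e-12)
  # phosphofructokinase: 1.328 * (0.041/0.265) / (1 + 0.127/7)
  expect_equal(unname(f["PFK"]),
               1.328 * (0.041 / 0.265) / (1 + 0.127 / 7), tolerance = 1e-12)
  # phosphoglucomutase hand substitution
  expect_equal(unname(f["PGluM"]),
               (1.933 * 0.02 / 0.045 - 1.12 * 0.169 / 0.67) /
                 (1 + 0.02 / 0.045 + 0.169 / 0.67), tolerance = 1e-12)
  # lactate/H cotransport at the tabulated lactate levels
  expect_equal(unname(f["LHX"]),
               0.048 * 0.33 / (0.33 + 2.2) - 0.182 * 0.247 / (0.247 + 6.92),
               tolerance = 1e-12)
  # vessel -> extracellular oxygen: 50 * 0.284 * (0.1326 - 0.1289)
  expect_equal(unname(f["O2VE"]), 50 * 0.284 * (0.1326 - 0.1289),
               tolerance = 1e-12)
  # myoglobin: 15400 * 0.00543 * 0.11017 - 60 * 0.18457
  expect_equal(unname(f["MB"]), 15400 * 0.00543 * 0.11017 - 60 * 0.18457,
               tolerance = 1e-12)
})

test_that("proton-motive energy and leak match hand substitution", {
  m <- cachedModel()
  st <- applyAssignments(initialState(m), m)
  ev <- computeFluxes(st, m)
  RT <- 8.314 * 310 / 1000
  expect_equal(unname(ev$thermo["dGH"]),
               0.096484 * 170 + RT * log(7.94e-5 / 6.31e-5), tolerance = 1e-12)
  u <- 0.096484 * 170 / RT
  expect_equal(unname(ev$fluxes["Hle"]),
               0.25 * 170 * (7.94e-5 * exp(u) - 6.31e-5) / (exp(u) - 1),
               tolerance = 1e-12)
})

test_that("reversible fluxes vanish at their printed equilibria", {
  m <- cachedModel()
  p <- kineticParameters(m)
  st <- applyAssignments(initialState(m), m)
  # creatine kinase equilibrium
  st["Cr_c"] <- p$CK$K * st[["ADP_c"]] * st[["CrP_c"]] * st[["H_c"]] /
    st[["ATP_c"]]
  # adenylate kinase equilibrium
  st["AMP_c"] <- p$AK$K * st[["ADP_c"]]^2 / st[["ATP_c"]]
  # isomerase equilibrium: Vf [G6P]/Kmf = Vr [F6P]/Kmr
  st["F6P_c"] <- p$PGI$Vf * st[["G6P_c"]] * p$PGI$Kmr /
    (p$PGI$Kmf * p$PGI$Vr)
  # phosphoglucomutase equilibrium
  st["G1P_c"] <- p$PGluM$Vr * st[["G6P_c"]] * p$PGluM$Kmf /
    (p$PGluM$Kmr * p$PGluM$Vf)
  # lactic-acid association equilibrium
  st["LACH_c"] <- st[["LAC_c"]] * st[["H_c"]] / p$LA$Km
  # K/H antiport equilibrium
  st["K_x"] <- st[["K_i"]] * st[["H_x"]] / st[["H_i"]]
  # vessel/extracellular oxygen equality
  st["O2_e"] <- st[["O2_v"]]
  # IMS Mg binding equilibria
  st["mADP_i"] <- st[["fADP_i"]] * p$phys$MgI / p$MgB$KMgADP
  f <- computeFluxes(st, m, check = FALSE)$fluxes
  # bound: double roundoff amplified by the 1e4-scale mass-action constants
  for (nm in c("CK", "AK", "PGI", "PGluM", "LA", "KH", "O2VE", "MgADPi"))
    expect_lt(abs(f[[nm]]), 1e-9)
})

test_that("Michaelis-Menten fluxes are monotone in substrate and product", {
  m <- cachedModel()
  st <- applyAssignments(initialState(m), m)
  bump <- function(sp, fac) { s <- st; s[sp] <- s[[sp]] * fac; s }
  f0 <- evalFluxes(st)$fluxes
  # substrate up -> flux up
  expect_gt(evalFluxes(bump("G6P_c", 1.3))$fluxes[["PGI"]], f0[["PGI"]])
  expect_gt(evalFluxes(bump("DHAP_c", 1.3))$fluxes[["TPI"]], f0[["TPI"]])
  expect_gt(evalFluxes(bump("F6P_c", 1.3))$fluxes[["PFK"]], f0[["PFK"]])
  # product up -> flux down
  expect_lt(evalFluxes(bump("F6P_c", 1.3))$fluxes[["PGI"]], f0[["PGI"]])
  expect_lt(evalFluxes(bump("G6P_c", 1.3))$fluxes[["HK"]], f0[["HK"]])
  expect_lt(evalFluxes(bump("PEP_c", 1.3))$fluxes[["Enolase"]],
            f0[["Enolase"]])
})

test_that("complex IV shuts down as cytosolic oxygen vanishes", {
  m <- cachedModel()
  st <- applyAssignments(initialState(m), m)
  o2 <- c(1e-1, 1e-3, 1e-5, 1e-7)
  j <- vapply(o2, function(x) {
    s <- st; s["O2_c"] <- x
    computeFluxes(s, m)$fluxes[["C4"]]
  }, numeric(1))
  expect_true(all(diff(j) < 0))
  expect_lt(abs(j[length(j)]), 1e-3 * abs(j[1]))
})

test_that("compiled fluxes and derivatives match the R reference to 1e-10", {
  m <- cachedModel()
  pv <- cardiomyosim:::.paramVector(m, fraction = 1)
  so <- cardiomyosim:::.speciesOrder()
  odesp <- cardiomyosim:::.odeSpecies()
  for (st in randomStates(100)) {
    cf <- .Call(cardiomyosim:::C_modelFluxes, as.numeric(st[so]),
                as.numeric(pv))
    rf <- computeFluxes(st, m, check = FALSE)
    rall <- c(rf$fluxes, rf$thermo)
    expect_lt(max(abs(cf - rall) / pmax(abs(rall), 1e-10)), 1e-10)
    cd <- .Call(cardiomyosim:::C_modelDerivs, as.numeric(st[so]),
                as.numeric(pv))
    names(cd) <- so
    rd <- modelDerivatives(0, st, m)$derivatives
    sel <- names(rd)[!is.na(rd)]
    expect_lt(max(abs(cd[sel] - rd[sel]) / pmax(abs(rd[sel]), 1e-10)), 1e-10)
  }
})

test_that("negative concentrations raise a domain error in the reference path", {
  m <- cachedModel()
  st <- applyAssignments(initialState(m), m)
  st["PYR_c"] <- -0.01
  expect_error(computeFluxes(st, m), "negative concentration")
})

test_that("the s1 saturation modifier is pluggable", {
  m <- cachedModel()
  st <- applyAssignments(initialState(m), m)
  f1 <- computeFluxes(st, m)$fluxes
  f2 <- computeFluxes(st, m, s1 = function(x) 0.5)$fluxes
  # halving s1 halves the PGM forward and reverse terms jointly
  expect_equal(unname(f2["PGM"]), unname(f1["PGM"]) / 2, tolerance = 1e-12)
  # laws without s1 are unaffected
  expect_equal(unname(f2["PGI"]), unname(f1["PGI"]))
})
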