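# Species registry, parameter set, overrides and serialization.

test_that("default model reproduces the tabulated initial values", {
  m <- cachedModel()
  init <- initialState(m)
  expect_equal(unname(init["ATP_c"]), 7)
  expect_equal(unname(init["CrP_c"]), 25)
  expect_equal(unname(init["O2_v"]), 0.1326)
  expect_equal(unname(init["dPsi"]), 170)
  expect_equal(unname(init["Cox_i"]), 1.7)
  expect_equal(unname(init["Cred_i"]), 1)
  expect_equal(unname(init["H_x"]), 6.31e-5)
  expect_equal(unname(init["GLY_c"]), 21.4)

  cmp <- compartmentTable(m)
  expect_setequal(cmp$name,
                  c("vessel", "extracellular", "cytosol", "ims", "matrix"))
  # hand sum of the compartment-volume column
  expect_equal(sum(cmp$volume), 2.02405)
  expect_equal(cmp$volume[cmp$name == "cytosol"], 1)
})

test_that("registry is internally consistent", {
  m <- cachedModel()
  sp <- speciesTable(m)
  expect_true(all(sp$kind %in% c("ode", "assignment", "constant")))
  # every flat parameter path resolves and is finite
  flat <- cardiomyosim:::.flattenParams(kineticParameters(m))
  expect_true(all(is.finite(flat)))
  # signed entries are only the standard free energies
  signed <- flat[flat < 0]
  expect_true(all(grepl("\\.dG0$", names(signed))))
  # every activity-map parameter resolves in the flat layout
  amap <- cardiomyosim:::.activityMap()
  pars <- unlist(lapply(amap, `[[`, "pars"))
  expect_true(all(pars %in% names(flat)))
})

test_that("overrides are pure, composable and validated", {
  m <- cachedModel()
  m2 <- applyOverrides(m, list(parameterOverride("HK.Vf", 1.01, TRUE)))
  expect_equal(kineticParameters(m2)$HK$Vf, 0.550 * 1.01)
  # base unchanged
  expect_equal(kineticParameters(m)$HK$Vf, 0.550)
  # everything else identical
  m2b <- applyOverrides(m2, list(parameterOverride("HK.Vf", 1 / 1.01, TRUE)))
  expect_equal(kineticParameters(m2b), kineticParameters(m))

  m3 <- applyOverrides(m, list(parameterOverride("initial.O2_v", 0.001326)))
  expect_equal(unname(initialState(m3)["O2_v"]), 0.001326)

  expect_identical(applyOverrides(m, list()), m)
  expect_error(applyOverrides(m, list(parameterOverride("HK.NoSuch", 1))),
               "cannot resolve")
  expect_error(applyOverrides(m, list(parameterOverride("initial.Xyz", 1))),
               "cannot resolve")
})

test_that("the alternative Mg-ATP dissociation preset applies", {
  m <- applyOverrides(cachedModel(), kMgATPF1TablePreset())
  expect_equal(kineticParameters(m)$MgB$KMgATP, 2.45e-5)
})

test_that("model serialization round-trips byte-identically", {
  m <- cachedModel()
  f1 <- tempfile(fileext = ".yaml"); f2 <- tempfile(fileext = ".yaml")
  writeModel(m, f1)
  m2 <- readModel(f1)
  writeModel(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(kineticParameters(m2), kineticParameters(m))
  expect_equal(speciesTable(m2)$initial, speciesTable(m)$initial)
  # the shipped document equals the in-memory registry
  shipped <- system.file("extdata", "default_model.yaml",
                         package = "cardiomyosim")
  expect_identical(readLines(shipped), readLines(f1))
})

test_that("malformed model documents are rejected with clear errors", {
  f <- tempfile(fileext = ".yaml")
  writeLines("compartments:\n  cytosol: 1", f)
  expect_error(readModel(f), "missing section")
  expect_error(readModel(tempfile()), "not found")
})
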