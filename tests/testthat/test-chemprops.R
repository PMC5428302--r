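test_that("vapor pressure follows the van 't Hoff correction", {
  chem <- chemical_profile("x", 200, 0.5, 1, 1e4, dU_vap = 7e4)
  # at the reference temperature the correction factor is exp(0) = 1
  expect_identical(vapor_pressure_at(chem, chem$T_ref), chem$vapor_pressure)
  # zero energy removes all temperature dependence
  flat <- chemical_profile("x", 200, 0.5, 2.5, 1e4, dU_vap = 0)
  expect_equal(vapor_pressure_at(flat, 250), 2.5)
  expect_equal(vapor_pressure_at(flat, 320), 2.5)
  # dU = R * T_ref * T makes the exponent exactly (T - T_ref)
  for (T in c(280, 298.15, 310)) {
    tuned <- chemical_profile("x", 200, 0.5, 1, 1e4,
                              dU_vap = 8.314462618 * 298.15 * T)
    expect_equal(vapor_pressure_at(tuned, T), exp(T - 298.15),
                 tolerance = 1e-12)
  }
  # monotone increasing in T for positive vaporization energy
  Ts <- seq(260, 320, by = 5)
  expect_true(all(diff(vapor_pressure_at(chem, Ts)) > 0))
  expect_error(vapor_pressure_at(chem, -1), "positive")
})

test_that("Henry's law constant is Vp*M/S with van 't Hoff correction", {
  expect_equal(henry_constant(unit_chem()), 1)
  chem <- chemical_profile("pcb28ish", 257.5, 0.27, 0.034, 3e4)
  expect_equal(henry_constant(chem), 32.42, tolerance = 2e-4)
  # doubling solubility halves H at fixed temperature
  half <- chemical_profile("pcb28ish", 257.5, 0.54, 0.034, 3e4)
  expect_equal(henry_constant(half, 285), henry_constant(chem, 285) / 2)
  # monotone increasing in T for positive energy
  Ts <- seq(260, 320, by = 5)
  expect_true(all(diff(henry_constant(chem, Ts)) > 0))
  expect_error(chemical_profile("bad", 1, 0, 1, 1), "solubility")
})

test_that("leaching potential is S/(Koc*Vp) and scale-consistent", {
  expect_equal(leaching_potential(unit_chem()), 1)
  chem <- chemical_profile("a", 100, 2, 0.5, 10)
  expect_equal(leaching_potential(chem), 2 / (10 * 0.5))
  # doubling Koc halves Lp
  chem2 <- chemical_profile("a", 100, 2, 0.5, 20)
  expect_equal(leaching_potential(chem2), leaching_potential(chem) / 2)
  # a common positive rescaling of S and Vp across chemicals preserves
  # the ordering of the index
  set.seed(42)
  for (i in 1:5) {
    s <- runif(3, 0.1, 10); vp <- runif(3, 0.01, 1); koc <- runif(3, 1, 1e5)
    lp <- s / (koc * vp)
    scale_s <- runif(1, 0.5, 20); scale_vp <- runif(1, 0.5, 20)
    lp2 <- (s * scale_s) / (koc * vp * scale_vp)
    expect_identical(order(lp), order(lp2))
  }
})

test_that("degradation rate is ln2 over half-life with Arrhenius correction", {
  chem <- chemical_profile("d", 100, 1, 1, 1,
                           half_life = c(air = log(2), soil = 693))
  expect_equal(degradation_rate(chem, "air"), 1)
  expect_equal(degradation_rate(chem, "soil"), log(2) / 693,
               tolerance = 1e-12)
  expect_equal(degradation_rate(chem, "soil"), 1.0003e-3, tolerance = 1e-3)
  # doubling the half-life halves the rate exactly at T_ref
  chem2 <- chemical_profile("d", 100, 1, 1, 1,
                            half_life = c(air = 2 * log(2)))
  expect_equal(degradation_rate(chem2, "air"), 0.5)
  # zero activation energy: rate independent of temperature
  flat <- chemical_profile("d", 100, 1, 1, 1, Ea_deg = 0,
                           half_life = c(air = 100))
  expect_equal(degradation_rate(flat, "air", 260),
               degradation_rate(flat, "air", 310))
  expect_error(degradation_rate(chem, "sediment"), "sediment")
})

test_that("the bundled PCB28 profile reads from YAML and matches the code", {
  path <- system.file("extdata", "pcb28.yaml", package = "fugrid")
  chem <- read_chemical_profile(path)
  ref <- pcb28_profile()
  expect_equal(chem$molar_mass, ref$molar_mass)
  expect_equal(chem$koc, ref$koc, tolerance = 1e-5)
  expect_equal(leaching_potential(chem), leaching_potential(ref),
               tolerance = 1e-5)
})

test_that("chemical profile files are validated", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("name: x", "molar_mass: 100"), bad)
  expect_error(read_chemical_profile(bad), "solubility")
  writeLines(c("name: x", "molar_mass: 100", "solubility: 1",
               "vapor_pressure: 1", "koc: 1", "mystery: 2"), bad)
  expect_error(read_chemical_profile(bad), "mystery")
})
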