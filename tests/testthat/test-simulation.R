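test_that("source cells are classified by cumulative emission threshold", {
  inv <- array(0, c(2, 2, 2))
  expect_false(any(classify_source_cells(inv)))
  inv[1, 2, 1] <- 3
  m <- classify_source_cells(inv)
  expect_identical(which(m), 2L) # exactly that cell
  # threshold enumeration: eps = 10 over cumulative {5, 15, 0}
  inv2 <- array(0, c(1, 3, 1)); inv2[1, , 1] <- c(5, 15, 0)
  expect_identical(as.vector(classify_source_cells(inv2, eps = 10)),
                   c(FALSE, TRUE, FALSE))
  expect_error(classify_source_cells(-inv2), "non-negative")
})

test_that("the emission factor is the emission/residue ratio", {
  expect_identical(emission_factor(0, 5), 0)
  r <- 3.7e4
  expect_equal(emission_factor(2e-6 * r, r), 2e-6)
  expect_true(is.na(emission_factor(0, 0)))
  expect_warning(out <- emission_factor(1, 0), "zero residue")
  expect_true(is.na(out))
  expect_error(emission_factor(-1, 1), ">= 0")
})

test_that("the ledger audit measures relative closure", {
  mk <- function(inp, out, hold) {
    structure(list(primary_emission_in = inp, advective_export = out,
                   degradation_loss = 0, deep_leaching_loss = 0,
                   burial_loss = 0, holdings_initial = 0,
                   holdings_final = hold), class = "mass_ledger")
  }
  expect_equal(mass_balance_audit(mk(100, 90, 10)), 0)
  expect_equal(mass_balance_audit(mk(100, 90, 5)), 5)
  expect_true(is.na(mass_balance_audit(mk(0, 0, 0))))
})

test_that("Pearson evaluation matches hand-computed values", {
  expect_equal(evaluate_pearson(1:5, 2 * (1:5))$R, 1)
  expect_equal(evaluate_pearson(1:5, -(1:5))$R, -1)
  # hand computation with the covariance formula gives R = 3/5
  res <- evaluate_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$R, 0.6)
  expect_true(res$p > 0 && res$p < 1)
  expect_warning(flat <- evaluate_pearson(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(flat$R))
  # exclusion list removes pairs before the comparison
  withr::with_seed(2, {
    x <- rnorm(10); y <- x + rnorm(10, 0, 0.1)
  })
  full <- evaluate_pearson(x, y)
  excl <- evaluate_pearson(c(x, 100), c(y, -100), exclude = 11L)
  expect_equal(excl$R, full$R)
  expect_identical(excl$n, 10L)
  expect_error(evaluate_pearson(1:2, 1:2), "at least 3")
})

test_that("inventory units convert to mol/day via the molar mass", {
  chem <- pcb28_profile()
  expect_equal(emission_mol_day(1, chem), 1e6 / 257.5 / 365)
  expect_equal(emission_mol_day(1, chem), 10.64, tolerance = 1e-3)
  expect_error(emission_mol_day(-1, chem), ">= 0")
})

test_that("a zero-emission run stays identically zero", {
  sp <- synth_spec(nlat = 2, nlon = 2, years = 1, seed = 4, total_t_yr = 0)
  run <- run_simulation(pcb28_profile(), sp$grid, synth_landsurface(sp),
                        synth_met(sp), synth_emissions(sp))
  expect_identical(run$ledger$holdings_final, 0)
  expect_identical(run$ledger$degradation_loss, 0)
  expect_identical(sum(run$cumulative$residue), 0)
  expect_false(any(run$source_mask))
  expect_true(is.na(run$audit)) # no inputs: closure undefined
})

test_that("simulations are deterministic given config and seed", {
  sp <- synth_spec(nlat = 3, nlon = 3, years = 1, seed = 6, total_t_yr = 5,
                   source_pattern = "single-cell")
  args <- list(pcb28_profile(), sp$grid, synth_landsurface(sp),
               synth_met(sp), synth_emissions(sp))
  r1 <- do.call(run_simulation, args)
  r2 <- do.call(run_simulation, args)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$final_amounts, r2$final_amounts)
  expect_identical(r1$monthly$ff, r2$monthly$ff)
})

test_that("the run ledger closes on a short gridded simulation", {
  sp <- synth_spec(nlat = 4, nlon = 4, years = 1, seed = 13)
  run <- run_simulation(pcb28_profile(), sp$grid, synth_landsurface(sp),
                        synth_met(sp), synth_emissions(sp),
                        sites = rbind(c(1, 1), c(4, 4)))
  expect_lt(run$audit, 1e-6)
  expect_gt(run$ledger$advective_export, 0)
  expect_gt(run$ledger$degradation_loss, 0)
  # non-source soils acquired residue purely from deposition
  ns <- !run$source_mask
  expect_gt(sum(run$cumulative$residue[ns]), 0)
  expect_identical(sum(run$cumulative$emission[ns]), 0)
  # site series are complete daily records
  expect_length(run$sites, 2L)
  expect_identical(nrow(run$sites[[1]]), 365L)
  expect_false(any(is.na(run$sites[[2]]$soil_burden)))
  # monthly EF on non-source cells is finite and non-negative once
  # deposition has arrived
  ef <- monthly_ef(run)
  late <- ef[ef$month == 12, ]
  expect_true(all(is.finite(late$ef)))
  expect_true(all(late$ef >= 0))
})

test_that("mismatched input shapes are rejected at startup", {
  sp <- synth_spec(nlat = 3, nlon = 3, years = 1, seed = 1,
                   source_pattern = "single-cell")
  big <- synth_spec(nlat = 4, nlon = 3, years = 1, seed = 1,
                    source_pattern = "single-cell")
  expect_error(
    run_simulation(pcb28_profile(), sp$grid, synth_landsurface(sp),
                   synth_met(big), synth_emissions(sp)),
    "met field")
  expect_error(
    run_simulation(pcb28_profile(), sp$grid, synth_landsurface(sp),
                   synth_met(sp), synth_emissions(big)),
    "emissions")
})

test_that("fugacity-fraction fields report equilibrium and deposition", {
  g <- grid_spec(20, 100, 2, 2, dlat = 1, dlon = 1)
  f_eq <- matrix(1, 4, 28)
  expect_equal(fugacity_fraction_field(f_eq, g),
               matrix(0.5, 2, 2))
  # freshly emitted to air over clean soil: pure net deposition
  f_air <- matrix(0, 4, 28); f_air[, 1] <- 2
  expect_equal(fugacity_fraction_field(f_air, g), matrix(0, 2, 2))
  expect_error(fugacity_fraction_field(f_eq, g, soil_type = "moon"),
               "unknown soil type")
})
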