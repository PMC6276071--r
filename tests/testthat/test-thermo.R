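test_that("site energy gap follows RT ln(KD_in/KD_out) with the right sign", {
  expect_equal(site_energy_gap(3, 3), 0)
  g <- site_energy_gap(30, 3) # weaker inside site: positive gap
  expect_equal(g, 8.314462618 * 303.15 * log(10) / 1000, tolerance = 1e-12)
  expect_equal(g, 5.803, tolerance = 1e-3)
  expect_equal(site_energy_gap(3, 30), -g)
  expect_error(site_energy_gap(-1, 3), "positive")
})

test_that("vacant-site distribution and required empty-rate ratio are KD_in/KD_out", {
  expect_equal(vacant_ratio_from_KD(30, 3), 10)
  expect_equal(vacant_ratio_from_KD(3, 3), 1)
  expect_equal(vacant_ratio_from_KD(3, 30), 1 / vacant_ratio_from_KD(30, 3))
  expect_equal(empty_rate_ratio_from_vacant_ratio(10), 10)
  expect_equal(empty_rate_ratio_from_vacant_ratio(1), 1)
  # consistency: building the carrier with that rate ratio reproduces the
  # distribution at the equal-bath steady state
  m <- build_asymmetric_carrier()
  occ <- occ_vec(solve_steady_state(m, clamps = list(out = 2, `in` = 2)))
  expect_equal(occ[["C_in"]] / occ[["C_out"]],
               vacant_ratio_from_KD(30, 3), tolerance = 1e-8)
})

test_that("rate-asymmetry free energy reproduces the quoted tenfold value at 30 C", {
  e <- rate_asymmetry_energy(10, 1)
  expect_equal(e, -5.803, tolerance = 1e-3)
  expect_equal(e, -5.76, tolerance = 0.02) # quoted rounding, 2% band
  expect_equal(rate_asymmetry_energy(1, 1), 0)
  expect_equal(rate_asymmetry_energy(1, 10), -e)
  # bookkeeping cancellation: the affinity gap is exactly offset by the
  # empty-rate asymmetry it enforces
  expect_equal(site_energy_gap(30, 3) + rate_asymmetry_energy(10, 1), 0)
})

test_that("chemical potentials and activity coefficients honour phase equality", {
  ctx <- energy_context(303.15)
  expect_equal(chemical_potential(thermo_state(mu0 = -3, mole_fraction = 1), ctx), -3)
  # ideal form is the gamma = 1 special case
  expect_equal(chemical_potential(thermo_state(0, 0.2, 1), ctx),
               0 + ctx$R * ctx$T * log(0.2) / 1000)
  # tenfold mole-fraction asymmetry needs a reciprocal coefficient ratio
  expect_equal(activity_coefficient_ratio(10, 1), 10)
  x_i <- 0.1; x_j <- 0.01
  g_ratio <- activity_coefficient_ratio(x_i, x_j) # gamma_j / gamma_i
  g_i <- 1.3
  mu_i <- chemical_potential(thermo_state(2, x_i, g_i), ctx)
  mu_j <- chemical_potential(thermo_state(2, x_j, g_i * g_ratio), ctx)
  expect_equal(mu_i, mu_j, tolerance = 1e-12)
  expect_error(chemical_potential(thermo_state(0, 0, 1)), "zero activity")
})

test_that("partition ratio tracks the raw occupancy sums across ligand levels", {
  m <- build_asymmetric_carrier()
  ss0 <- solve_steady_state(m, clamps = list(out = 0, `in` = 0))
  expect_equal(partition_ratio(ss0), 1 / 10, tolerance = 1e-10)
  ms <- build_symmetric_carrier()
  expect_equal(partition_ratio(solve_steady_state(ms, clamps = list(out = 4, `in` = 4))),
               1, tolerance = 1e-10)
  for (G in c(0.3, 3, 30)) {
    ss <- solve_steady_state(m, clamps = list(out = G, `in` = G))
    occ <- occ_vec(ss)
    expect_equal(partition_ratio(ss),
                 (occ[["C_out"]] + occ[["GC_out"]]) /
                   (occ[["C_in"]] + occ[["GC_in"]]))
  }
})

test_that("the equilibrium audit separates balanced, tampered and gradient conditions", {
  expect_true(equilibrium_audit(build_multisite_chain(), 10)$uniform)
  expect_true(equilibrium_audit(build_asymmetric_carrier(), 5)$uniform)

  # tampered rate (broken cycle): audit must fail at equal baths
  m <- build_asymmetric_carrier()
  i <- which(m$transitions$kind == "conformational" & m$transitions$from == "C_in")
  m$transitions$rate[i] <- m$transitions$rate[i] * 3
  expect_false(check_detailed_balance(m)$passed)
  expect_false(equilibrium_audit(m, 5)$uniform)

  # unequal baths: not an equilibrium, gradient reported
  au <- equilibrium_audit(build_multisite_chain(), 10, tolerance = 1e-6)
  m2 <- build_multisite_chain()
  sp <- "glucose"
  ss <- solve_steady_state(m2, clamps = list(out = c(glucose = 10),
                                             `in` = c(glucose = 0)))
  expect_gt(max(abs(ss$fluxes$net)), 1e-6)
})
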