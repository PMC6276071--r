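test_that("symmetric carrier at equal baths gives the mirror-symmetric state", {
  m <- build_symmetric_carrier()
  ss <- solve_steady_state(m, clamps = list(out = 3, `in` = 3))
  occ <- occ_vec(ss)
  expect_equal(occ[["C_out"]], occ[["C_in"]], tolerance = 1e-12)
  expect_equal(occ[["GC_out"]], occ[["GC_in"]], tolerance = 1e-12)
  expect_equal(sum(occ), 1, tolerance = 1e-12)
})

test_that("asymmetric detailed-balanced carrier distributes vacant sites as KD_in/KD_out", {
  m <- build_asymmetric_carrier() # KD 3 / 30, auto-closed
  for (G in c(0, 1, 10)) {
    ss <- solve_steady_state(m, clamps = list(out = G, `in` = G))
    occ <- occ_vec(ss)
    expect_equal(occ[["C_in"]] / occ[["C_out"]], 10, tolerance = 1e-8)
  }
})

test_that("direct linear solve and ODE relaxation agree on random networks", {
  for (s in 1:20) {
    net <- random_bath_network(6, seed = s)
    cl <- list(out = runif(1, 0, 20), `in` = runif(1, 0, 20))
    lin <- solve_steady_state(net, cl, method = "linear")
    ode <- solve_steady_state(net, cl, method = "ode")
    expect_true(lin$converged)
    expect_true(ode$converged)
    expect_equal(occ_vec(ode), occ_vec(lin), tolerance = 1e-8)
    expect_equal(sum(occ_vec(lin)), 1, tolerance = 1e-12)
  }
})

test_that("detailed-balanced models at equal baths carry no net flux on any edge", {
  models <- list(build_symmetric_carrier(), build_asymmetric_carrier(),
                 build_asymmetric_carrier(random_closed_carrier(7)))
  for (m in models) {
    ss <- solve_steady_state(m, clamps = list(out = 5, `in` = 5))
    denom <- pmax(ss$fluxes$forward, ss$fluxes$backward)
    expect_lt(max(abs(ss$fluxes$net) / denom), 1e-10)
  }
})

test_that("unidirectional flux equals net flux under zero-trans conditions", {
  m <- build_asymmetric_carrier()
  m2 <- expand_tracer(m, 1e-6, cis = "out")
  ss <- solve_steady_state(m2, clamps = list(
    out = c(glucose = 5 * (1 - 1e-6), glucose_lab = 5e-6),
    `in` = c(glucose = 0, glucose_lab = 0)))
  uni <- unidirectional_flux(ss, "in", 1e-6)
  net <- bath_net_delivery(ss, "in")
  expect_equal(uni, net, tolerance = 1e-8)
})

test_that("unidirectional flux is invariant to the labelled fraction (tracer linearity)", {
  m <- build_asymmetric_carrier()
  flux_at <- function(phi) {
    m2 <- expand_tracer(m, phi, cis = "out")
    ss <- solve_steady_state(m2, clamps = list(
      out = c(glucose = 10 * (1 - phi), glucose_lab = 10 * phi),
      `in` = c(glucose = 10, glucose_lab = 0)))
    unidirectional_flux(ss, "in", phi)
  }
  expect_equal(flux_at(1e-6), flux_at(1e-3), tolerance = 1e-8)
})

test_that("equilibrium unidirectional influx equals efflux", {
  m <- build_asymmetric_carrier()
  g <- default_conc_grid(n = 6)
  fin <- run_equilibrium_exchange(m, "influx", g)
  fef <- run_equilibrium_exchange(m, "efflux", g)
  expect_equal(fin$flux, fef$flux, tolerance = 1e-8)
})

test_that("time courses conserve carrier and total ligand", {
  m <- with_finite_inside(build_symmetric_carrier(), volume = 0.5)
  m <- set_concentration(m, "in", "glucose", 20)
  tc <- integrate_time_course(m, t_grid = c(0.1, 1, 5, 20),
                              clamps = list(out = 0))
  occ <- tc[tc$variable == "occupancy", ]
  tot <- tapply(occ$value, occ$time, sum)
  expect_true(all(abs(tot - 1) < 1e-10))

  # with every reservoir finite, total ligand (baths*volume + bound) is
  # conserved along the trajectory
  m2 <- with_finite_inside(with_finite_inside(build_symmetric_carrier(),
                                              volume = 2, bath = "out"),
                           volume = 0.5, bath = "in")
  m2 <- set_concentration(m2, "out", "glucose", 10)
  tc2 <- integrate_time_course(m2, t_grid = c(0.1, 1, 10, 40))
  lig <- sapply(unique(tc2$time), function(t) {
    sub <- tc2[tc2$time == t, ]
    bound <- sum(sub$value[sub$variable == "occupancy" & !is.na(sub$species)])
    baths <- sub[sub$variable == "concentration", ]
    vols <- c(out = 2, `in` = 0.5)
    bound + sum(baths$value * vols[baths$id])
  })
  expect_true(all(abs(lig - lig[1]) < 1e-9 * lig[1]))
})

test_that("with equal clamped baths all net fluxes decay away along the trajectory", {
  m <- build_asymmetric_carrier()
  # start far from the stationary distribution
  tc <- integrate_time_course(
    m, t_grid = c(0.01, 50),
    clamps = list(out = 5, `in` = 5),
    initial_occupancy = c(C_out = 1, GC_out = 0, GC_in = 0, C_in = 0))
  late <- tc[tc$variable == "occupancy" & tc$time == 50, ]
  ss <- solve_steady_state(m, clamps = list(out = 5, `in` = 5))
  expect_equal(setNames(late$value, late$id)[ss$occupancy$state],
               occ_vec(ss), tolerance = 1e-6)
  expect_error(integrate_time_course(m, t_grid = c(3, 2, 1)), "increasing")
})
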