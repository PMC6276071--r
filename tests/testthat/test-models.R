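test_that("symmetric defaults follow the reference rate hierarchy", {
  m <- build_symmetric_carrier()
  tr <- m$transitions
  koff <- tr$rate[tr$kind == "release"]
  expect_equal(unique(koff), 3000) # KD * k_on = 3 * 1000
  expect_equal(unique(tr$rate[tr$kind == "binding"]), 1000)
  expect_equal(sort(unique(tr$rate[tr$kind == "conformational"])), c(1, 10))
  expect_error(build_symmetric_carrier(carrier_params(KD_out = 3, KD_in = 30)),
               "symmetric")
})

test_that("cycle closure derives the slow empty rate and flags conflicts", {
  p <- carrier_params(KD_out = 3, KD_in = 30)
  expect_equal(p$b_in_out, 0.1)
  expect_silent(carrier_params(KD_out = 3, KD_in = 30, b_in_out = 0.1))
  expect_error(carrier_params(KD_out = 3, KD_in = 30, b_in_out = 0.5),
               "auto_close conflict")
  expect_error(carrier_params(b_in_out = NULL, auto_close = FALSE), "b_in_out")
  # disabling auto_close with inconsistent rates must fail the balance check
  bad <- build_asymmetric_carrier(
    carrier_params(KD_out = 3, KD_in = 30, b_in_out = 1, auto_close = FALSE))
  expect_false(check_detailed_balance(bad)$passed)
})

test_that("builders are deterministic", {
  a <- build_asymmetric_carrier()
  b <- build_asymmetric_carrier()
  expect_identical(a$transitions, b$transitions)
  expect_identical(a$states, b$states)
  x <- build_multisite_chain(multisite_params(exchange_site = TRUE))
  y <- build_multisite_chain(multisite_params(exchange_site = TRUE))
  expect_identical(x$transitions, y$transitions)
})

test_that("symmetric carrier influx and efflux curves coincide", {
  m <- build_symmetric_carrier()
  g <- default_conc_grid(n = 8)
  expect_equal(run_zero_trans(m, "influx", g)$flux,
               run_zero_trans(m, "efflux", g)$flux, tolerance = 1e-10)
})

test_that("multisite voids equilibrate exactly at the bath concentration", {
  for (p in list(multisite_params(), multisite_params(exchange_site = TRUE))) {
    au <- equilibrium_audit(build_multisite_chain(p), bath_conc = 10)
    expect_true(au$uniform)
    voids <- au$concentrations[!au$concentrations$clamped &
                                 au$concentrations$species == "glucose", ]
    expect_equal(voids$conc, rep(10, nrow(voids)), tolerance = 1e-9)
  }
})

test_that("two open branches are flux-equivalent to one branch of doubled rate", {
  g <- default_conc_grid(n = 6)
  m_two <- build_branched_multisite(FALSE, multisite_params(branch_rates = c(50, 50)))
  m_one <- build_branched_multisite(FALSE, multisite_params(branch_rates = c(100, 0)))
  for (dir in c("influx", "efflux")) {
    expect_equal(run_zero_trans(m_two, dir, g)$flux,
                 run_zero_trans(m_one, dir, g)$flux, tolerance = 1e-8)
  }
})

test_that("arrhenius scaling is inert at Ea = 0 or T = T_ref and raises cold exchange/net ratios", {
  expect_equal(arrhenius_scale(7, 0, 277), 7)
  expect_equal(arrhenius_scale(7, 55, 303.15, 303.15), 7)
  expect_error(arrhenius_scale(1, 10, -3), "positive")

  # exchange-path rates (liganded transit) carry a lower activation energy
  # than dissociation and empty transit; cooling must then raise
  # Vm(exchange)/Vm(net influx)
  Ea_ex <- 10; Ea_net <- 35
  ratio_at <- function(T_K) {
    sc_ex <- function(r) arrhenius_scale(r, Ea_ex, T_K)
    sc_net <- function(r) arrhenius_scale(r, Ea_net, T_K)
    p0 <- carrier_params()
    p <- carrier_params(KD_out = sc_net(p0$KD_out * p0$k_on) / p0$k_on,
                        KD_in = sc_net(p0$KD_in * p0$k_on) / p0$k_on,
                        b_out_in = sc_net(p0$b_out_in), b_in_out = NULL,
                        f_out_in = sc_ex(p0$f_out_in), f_in_out = sc_ex(p0$f_in_out),
                        k_on = p0$k_on)
    m <- build_symmetric_carrier_from <- portersim:::.build_carrier(p)
    g <- default_conc_grid(n = 8)
    fit_michaelis_menten(run_equilibrium_exchange(m, "influx", g))$Vmax /
      fit_michaelis_menten(run_zero_trans(m, "influx", g))$Vmax
  }
  expect_gt(ratio_at(277), ratio_at(303.15))
})
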