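test_that("zero-trans curves rise monotonically to saturation", {
  for (m in list(build_asymmetric_carrier(),
                 build_multisite_chain())) {
    cv <- run_zero_trans(m, "influx", default_conc_grid(n = 10))
    expect_true(all(diff(cv$flux) > 0))
    expect_gt(cv$flux[10], cv$flux[1])
    expect_true(all(cv$flux >= 0))
  }
  expect_error(run_zero_trans(build_symmetric_carrier(), grid = c(2, 1)),
               "increasing")
})

test_that("fitted protocol kinetics match the rapid-equilibrium algebra within 1%", {
  # association (1000/mM/s) is fast against transit (<= ~50/s): the
  # rapid-equilibrium closed forms are the independent oracle
  for (s in c(2, 5)) {
    p <- random_closed_carrier(s)
    m <- build_asymmetric_carrier(p)
    or <- re_carrier_oracle(p)
    g <- default_conc_grid()
    f_in <- fit_michaelis_menten(run_zero_trans(m, "influx", g))
    f_ee <- fit_michaelis_menten(run_equilibrium_exchange(m, "influx", g))
    expect_equal(f_in$Km, or$km_zt_influx, tolerance = 0.01)
    expect_equal(f_in$Vmax, or$vm_zt_influx, tolerance = 0.01)
    expect_equal(f_ee$Km, or$km_ee, tolerance = 0.01)
    expect_equal(f_ee$Vmax, or$vm_ee, tolerance = 0.01)
  }
})

test_that("exchange is accelerated iff liganded transit beats the slow empty transit", {
  g <- default_conc_grid()
  vm_ratio <- function(f) {
    m <- build_symmetric_carrier(carrier_params(f_out_in = f, f_in_out = f))
    fit_michaelis_menten(run_equilibrium_exchange(m, "influx", g))$Vmax /
      fit_michaelis_menten(run_zero_trans(m, "influx", g))$Vmax
  }
  # symmetric carrier: Vm_ee/Vm_zt = (b + f) / (2b) with b = 1
  expect_equal(vm_ratio(10), (1 + 10) / 2, tolerance = 0.01)
  expect_gt(vm_ratio(10), 1)
  # liganded transit slower than empty transit: exchange is retarded
  expect_lt(vm_ratio(0.2), 1)
  expect_equal(vm_ratio(0.2), (1 + 0.2) / 2, tolerance = 0.01)
})

test_that("counterflow overshoots for the carrier and the exchange-site chain, not otherwise", {
  tg <- seq(0.5, 150, by = 0.5)
  mc <- with_finite_inside(build_symmetric_carrier(), volume = 1)
  cf <- run_counterflow(mc, inside_load = 100, tracer_outside = 1, t_grid = tg)
  expect_gt(max(cf$ratio), 1)
  # transient: the excursion decays once the unlabelled gradient dissipates
  expect_lt(cf$ratio[length(cf$ratio)], max(cf$ratio))

  mx <- with_finite_inside(
    build_multisite_chain(multisite_params(exchange_site = TRUE)), volume = 1)
  cfx <- run_counterflow(mx, 100, 1, tg)
  expect_gt(max(cfx$ratio), 1)
  expect_equal(cfx$ratio[length(cfx$ratio)], 1, tolerance = 0.05)

  # no preload: tracer equilibrates from below, never uphill
  cf0 <- run_counterflow(mc, inside_load = 0, tracer_outside = 1,
                         t_grid = seq(1, 60, by = 1))
  expect_true(all(cf0$ratio <= 1 + 1e-9))
  expect_true(!is.unsorted(cf0$ratio))

  expect_error(run_counterflow(build_symmetric_carrier(), 100, 1),
               "finite inside bath")
})

test_that("the branch block selectively throttles net efflux", {
  g <- default_conc_grid()
  fits <- lapply(c(FALSE, TRUE), function(blk) {
    m <- build_branched_multisite(blk)
    list(influx = fit_michaelis_menten(run_zero_trans(m, "influx", g)),
         efflux = fit_michaelis_menten(run_zero_trans(m, "efflux", g)))
  })
  ctrl <- fits[[1]]; blk <- fits[[2]]
  vm_drop_eff <- 1 - blk$efflux$Vmax / ctrl$efflux$Vmax
  vm_drop_inf <- 1 - blk$influx$Vmax / ctrl$influx$Vmax
  km_drop_eff <- 1 - blk$efflux$Km / ctrl$efflux$Km
  km_drop_inf <- 1 - blk$influx$Km / ctrl$influx$Km
  expect_gt(vm_drop_eff, 0.15)            # efflux Vmax clearly reduced
  expect_gt(vm_drop_eff, vm_drop_inf + 0.1) # ... much more than influx
  expect_gt(km_drop_eff, 0)               # efflux Km reduced
  expect_gt(km_drop_eff, km_drop_inf)     # ... more than influx
  h_ctrl <- haldane_ratio(ctrl$influx, ctrl$efflux)
  h_blk <- haldane_ratio(blk$influx, blk$efflux)
  expect_lt(h_blk, 1)
  expect_lt(abs(h_ctrl - 1), 0.25)        # control stays near unity
})
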