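test_that("the cached calibration evaluator equals the reference pipeline", {
  g <- default_conc_grid(n = 12)
  ev <- portersim:::.make_carrier_evaluator(g)
  for (s in c(1, 4)) {
    p <- random_closed_carrier(s)
    p <- carrier_params(KD_out = p$KD_out, KD_in = p$KD_in,
                        b_out_in = p$b_out_in, f_out_in = p$f_out_in,
                        f_in_out = p$f_in_out, k_on = 1000)
    expect_equal(ev(p), portersim:::.carrier_observables(p, g),
                 tolerance = 1e-12)
  }
})

test_that("calibration recovers observables generated by a known carrier", {
  truth <- carrier_params(KD_out = 2, KD_in = 20, b_out_in = 2,
                          f_out_in = 15, f_in_out = 25)
  obs <- portersim:::.carrier_observables(truth, default_conc_grid(n = 12))
  cal <- calibrate_carrier(
    targets = kinetic_targets(
      km_influx = obs[["km_influx"]],
      km_exchange = obs[["km_exchange"]],
      vm_efflux_over_influx = obs[["vm_efflux_over_influx"]],
      vm_influx_over_exchange = obs[["vm_influx_over_exchange"]]),
    n_starts = 8, refine_top = 1, seed = 5, kd_ratio_tiebreak = 1e-3)
  nm <- c("km_influx", "km_exchange", "vm_efflux_over_influx",
          "vm_influx_over_exchange")
  expect_lt(max(abs(log(cal$observed[nm] / obs[nm]))^2), 1e-6)
  expect_true(check_detailed_balance(cal$model, 1e-9)$passed)
})

test_that("calibration arguments are validated", {
  expect_error(calibrate_carrier(weights = c(nonsense = 1)), "named after targets")
  expect_error(calibrate_carrier(weights = c(km_influx = 0)), "positive weight")
})
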