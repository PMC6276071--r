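test_that("exact Michaelis-Menten data is recovered exactly", {
  cv <- generate_noisy_curve(Km = 5, Vmax = 2, noise = noise_spec(cv = 0))
  f <- fit_michaelis_menten(cv)
  expect_true(f$converged)
  expect_equal(f$Km, 5, tolerance = 1e-9)
  expect_equal(f$Vmax, 2, tolerance = 1e-9)
  expect_lt(f$rss, 1e-18)
  expect_equal(tidy(f)$estimate, c(5, 2), tolerance = 1e-9)
  expect_true(glance(f)$converged)
})

test_that("fitting guards on grid size and span", {
  expect_error(fit_michaelis_menten(tibble::tibble(
    concentration = c(1, 2, 3, 4), flux = 1:4)), "at least 5")
  expect_error(fit_michaelis_menten(tibble::tibble(
    concentration = c(1, 2, 3, 4, 5), flux = 1:5)), "100-fold")
})

test_that("noisy curves are reproducible under a fixed seed and unbiased on average", {
  a <- generate_noisy_curve(5, 2, noise = noise_spec(cv = 0.05, seed = 42))
  b <- generate_noisy_curve(5, 2, noise = noise_spec(cv = 0.05, seed = 42))
  expect_identical(a$flux, b$flux)
  c2 <- generate_noisy_curve(5, 2, noise = noise_spec(cv = 0.05, seed = 43))
  expect_false(identical(a$flux, c2$flux))

  # lognormal mean correction: E[J/J_true] = 1 within 3 standard errors
  set.seed(7)
  s <- sqrt(log(1 + 0.2^2))
  draws <- rlnorm(1e4, -s^2 / 2, s)
  expect_lt(abs(mean(draws) - 1), 3 * sd(draws) / sqrt(1e4))
})

test_that("Km recovery from 5% noise is nearly unbiased over 50 replicates", {
  st <- parameter_recovery_study(Km = 5, Vmax = 2,
                                 noise = noise_spec(cv = 0.05, seed = 11,
                                                    replicates = 50))
  expect_equal(st$summary$n_converged[1], 50)
  expect_lt(abs(st$summary$median_bias[st$summary$parameter == "Km"]), 0.02)
  expect_lt(abs(st$summary$median_bias[st$summary$parameter == "Vmax"]), 0.02)
})

test_that("recovery error shrinks with the noise level", {
  rmse_at <- function(cv) {
    st <- parameter_recovery_study(5, 2, noise_spec(cv, seed = 3, replicates = 30))
    st$summary$rmse[st$summary$parameter == "Km"]
  }
  e <- vapply(c(0.10, 0.05, 0.01), rmse_at, numeric(1))
  expect_true(all(diff(e) < 0))
})
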