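#' Fit a Michaelis-Menten saturation curve
#'
#' Nonlinear least squares of `J = Vmax * G / (Km + G)` to a flux curve.
#' Starting values come from the Hanes-Woolf linearisation (`G/J` on `G`),
#' which is used only for initialisation — the reported parameters are the
#' full nonlinear fit (linearised estimators bias Km under realistic noise).
#'
#' @param curve A [flux_curve][run_zero_trans()] or any data frame with
#'   columns `concentration` and `flux`; at least 5 points spanning a
#'   100-fold or wider concentration range.
#' @return A `saturation_fit`: `Km` (mmol/L), `Vmax` (amount/s), standard
#'   errors, residual sum of squares, `converged`, and the underlying `nls`
#'   object. Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_michaelis_menten <- function(curve) {
  df <- as.data.frame(curve)[, c("concentration", "flux")]
  if (nrow(df) < 5) abort("need at least 5 points to fit a saturation curve")
  rng <- range(df$concentration)
  if (rng[2] / rng[1] < 100) {
    abort("concentration grid must span at least a 100-fold range")
  }
  pos <- df[df$flux > 0, ]
  if (nrow(pos) < 3) abort("too few positive fluxes to fit")

  hw <- lm(I(concentration / flux) ~ concentration, data = pos)
  v0 <- unname(1 / coef(hw)[2])
  k0 <- unname(coef(hw)[1] * v0)
  if (!is.finite(v0) || v0 <= 0) v0 <- max(pos$flux)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(pos$concentration)

  fit <- tryCatch(
    minpack.lm::nlsLM(flux ~ Vmax * concentration / (Km + concentration),
                      data = df, start = list(Vmax = v0, Km = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(Km = NA_real_, Vmax = NA_real_,
                          se_Km = NA_real_, se_Vmax = NA_real_,
                          rss = NA_real_, n = nrow(df), converged = FALSE,
                          message = conditionMessage(fit), fit = NULL,
                          curve = as_tibble(df)),
                     class = "saturation_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  out <- structure(list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
                        se_Km = unname(se["Km"]), se_Vmax = unname(se["Vmax"]),
                        rss = sum(stats::resid(fit)^2), n = nrow(df),
                        converged = est["Km"] > 0 && est["Vmax"] > 0,
                        message = NULL, fit = fit, curve = as_tibble(df)),
                   class = "saturation_fit")
  if (!out$converged) {
    out$message <- "fit converged to a non-positive parameter"
  }
  out
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<saturation_fit> FAILED:", x$message %||% "did not converge", "\n")
    return(invisible(x))
  }
  cat(sprintf("<saturation_fit> Km = %.4g mmol/L (se %.2g), Vmax = %.4g (se %.2g), rss = %.3g, n = %d\n",
              x$Km, x$se_Km, x$Vmax, x$se_Vmax, x$rss, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(term = c("Km", "Vmax"),
         estimate = c(x$Km, x$Vmax),
         std.error = c(x$se_Km, x$se_Vmax))
}

#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged)
}

#' Haldane ratio from zero-trans fits
#'
#' `(Vmax_efflux / Km_efflux) / (Vmax_influx / Km_influx)`: the ratio of the
#' first-order transport coefficients in the two directions. A passive
#' single-cycle transporter obeying detailed balance must return 1; fitted
#' deviations from 1 in multi-branch fixed-site models quantify apparent
#' kinetic asymmetry of the saturation curves.
#'
#' @param influx_fit,efflux_fit Converged [saturation_fit][fit_michaelis_menten()]s.
#' @return Dimensionless scalar.
#' @export
haldane_ratio <- function(influx_fit, efflux_fit) {
  if (!isTRUE(influx_fit$converged) || !isTRUE(efflux_fit$converged)) {
    abort("both fits must have converged")
  }
  (efflux_fit$Vmax / efflux_fit$Km) / (influx_fit$Vmax / influx_fit$Km)
}

#' Full kinetic characterisation of a transporter model
#'
#' Runs zero-trans influx, zero-trans efflux and equilibrium-exchange influx
#' protocols, fits each saturation curve, and derives the standard
#' asymmetry/exchange ratios and the Haldane ratio.
#'
#' @param model A `transport_network`.
#' @param grid Concentration grid, mmol/L.
#' @param labelled_fraction Tracer fraction for the exchange protocol.
#' @return A `kinetic_summary`: named fits (`zt_influx`, `zt_efflux`,
#'   `ee_influx`), and ratios `vm_exchange_over_influx`,
#'   `km_influx_over_exchange`, `vm_efflux_over_influx`, `haldane`.
#'   Supports `tidy()`.
#' @export
kinetic_summary <- function(model, grid = default_conc_grid(),
                            labelled_fraction = 1e-6) {
  fits <- list(
    zt_influx = fit_michaelis_menten(run_zero_trans(model, "influx", grid)),
    zt_efflux = fit_michaelis_menten(run_zero_trans(model, "efflux", grid)),
    ee_influx = fit_michaelis_menten(
      run_equilibrium_exchange(model, "influx", grid, labelled_fraction)))
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    abort("one or more saturation fits failed; inspect the curves")
  }
  structure(
    list(fits = fits,
         vm_exchange_over_influx = fits$ee_influx$Vmax / fits$zt_influx$Vmax,
         km_influx_over_exchange = fits$zt_influx$Km / fits$ee_influx$Km,
         vm_efflux_over_influx = fits$zt_efflux$Vmax / fits$zt_influx$Vmax,
         haldane = haldane_ratio(fits$zt_influx, fits$zt_efflux)),
    class = "kinetic_summary")
}

#' @export
tidy.kinetic_summary <- function(x, ...) {
  tibble(
    quantity = c("km_influx", "km_efflux", "km_exchange",
                 "vm_influx", "vm_efflux", "vm_exchange",
                 "vm_exchange_over_influx", "km_influx_over_exchange",
                 "vm_efflux_over_influx", "haldane"),
    value = c(x$fits$zt_influx$Km, x$fits$zt_efflux$Km, x$fits$ee_influx$Km,
              x$fits$zt_influx$Vmax, x$fits$zt_efflux$Vmax, x$fits$ee_influx$Vmax,
              x$vm_exchange_over_influx, x$km_influx_over_exchange,
              x$vm_efflux_over_influx, x$haldane))
}

#' Qualitative asymmetry/exchange signature of a kinetic summary
#'
#' The standard checklist for an asymmetric exchange-capable transporter:
#' Km(influx) < Km(efflux), Vmax(influx) < Vmax(efflux),
#' Vmax(exchange) > Vmax(net influx), Km(exchange) > Km(net influx), and a
#' near-unity Haldane ratio for the net fluxes.
#'
#' @param x A [kinetic_summary()].
#' @param haldane_tol Relative tolerance on `|haldane - 1|` for the
#'   near-unity check.
#' @return Tibble with columns `property`, `satisfied`.
#' @export
asymmetry_signature <- function(x, haldane_tol = 0.15) {
  f <- x$fits
  tibble(
    property = c("km_influx < km_efflux", "vm_influx < vm_efflux",
                 "vm_exchange > vm_influx", "km_exchange > km_influx",
                 "haldane ~ 1"),
    satisfied = c(f$zt_influx$Km < f$zt_efflux$Km,
                  f$zt_influx$Vmax < f$zt_efflux$Vmax,
                  f$ee_influx$Vmax > f$zt_influx$Vmax,
                  f$ee_influx$Km > f$zt_influx$Km,
                  abs(x$haldane - 1) <= haldane_tol))
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat("<kinetic_summary>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}
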