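#' Energy context (gas constant and temperature)
#'
#' @param T_K Absolute temperature, K. Default 303.15 K (30 degrees C), the
#'   temperature at which the reference free-energy figures for the
#'   asymmetric carrier are quoted.
#' @return An `energy_context` list with `R` (8.314462618 J/(mol K)) and `T`.
#' @export
energy_context <- function(T_K = .T_DEFAULT) {
  if (T_K <= 0) abort("temperature must be positive (K)")
  structure(list(R = .R_GAS, T = T_K), class = "energy_context")
}

#' Gibbs free-energy gap between binding sites of unequal affinity
#'
#' `RT ln(KD_in / KD_out)` in kJ/mol: positive when the inside site is the
#' weaker binder (KD_in > KD_out). This is the energy difference a ligand
#' experiences between the two faces of an asymmetric transporter.
#'
#' @param KD_in,KD_out Dissociation constants, mmol/L.
#' @param ctx An [energy_context()].
#' @return kJ/mol.
#' @export
site_energy_gap <- function(KD_in, KD_out, ctx = energy_context()) {
  if (any(c(KD_in, KD_out) <= 0)) abort("KD values must be positive")
  ctx$R * ctx$T * log(KD_in / KD_out) / 1000
}

#' Equilibrium vacant-carrier distribution ratio implied by asymmetric KDs
#'
#' At equal bath concentrations a detailed-balanced carrier with unequal
#' face affinities is forced into an unequal empty-state distribution:
#' `C_in / C_out = KD_in / KD_out`.
#'
#' @inheritParams site_energy_gap
#' @return Dimensionless ratio.
#' @export
vacant_ratio_from_KD <- function(KD_in, KD_out) {
  if (any(c(KD_in, KD_out) <= 0)) abort("KD values must be positive")
  KD_in / KD_out
}

#' Empty-carrier rate asymmetry required by a vacant-site distribution
#'
#' At equilibrium the one-way empty-carrier flows balance
#' (`C_out * k_out_in = C_in * k_in_out`), so sustaining a vacant ratio
#' `C_in/C_out = r` requires `k_out_in / k_in_out = r`.
#'
#' @param ratio Vacant distribution ratio `C_in / C_out`.
#' @return Required rate-constant ratio `k_out_in / k_in_out`.
#' @export
empty_rate_ratio_from_vacant_ratio <- function(ratio) {
  if (any(ratio <= 0)) abort("ratio must be positive")
  ratio
}

#' Free energy of an asymmetric unidirectional rate pair
#'
#' `-RT ln(k_out_in / k_in_out)` in kJ/mol: the free-energy difference that
#' would have to be expended to sustain unequal opposing unidirectional rate
#' constants. Negative when the out-to-in rate is the faster one; for a
#' tenfold asymmetry at 30 degrees C the magnitude is RT ln 10 =
#' 5.80 kJ/mol.
#'
#' @param k_oi,k_io Unidirectional rate constants (out-to-in, in-to-out), s^-1.
#' @param ctx An [energy_context()].
#' @return kJ/mol.
#' @export
rate_asymmetry_energy <- function(k_oi, k_io, ctx = energy_context()) {
  if (any(c(k_oi, k_io) <= 0)) abort("rates must be positive")
  -ctx$R * ctx$T * log(k_oi / k_io) / 1000
}

#' Thermodynamic state of a mixture component
#'
#' @param mu0 Standard chemical potential, kJ/mol.
#' @param mole_fraction Mole fraction in `[0, 1]`.
#' @param activity_coefficient Dimensionless, > 0 (1 for an ideal mixture).
#' @return A `thermo_state` list; `activity = mole_fraction *
#'   activity_coefficient`.
#' @export
thermo_state <- function(mu0 = 0, mole_fraction, activity_coefficient = 1) {
  if (mole_fraction < 0 || mole_fraction > 1) abort("mole fraction must be in [0, 1]")
  if (activity_coefficient <= 0) abort("activity coefficient must be positive")
  structure(list(mu0 = mu0, mole_fraction = mole_fraction,
                 activity_coefficient = activity_coefficient,
                 activity = mole_fraction * activity_coefficient),
            class = "thermo_state")
}

#' Chemical potential of a mixture component
#'
#' `mu = mu0 + RT ln(a)` with activity `a = x * gamma`; reduces to the
#' ideal mole-fraction form when `gamma = 1`.
#'
#' @param state A [thermo_state()].
#' @param ctx An [energy_context()].
#' @return kJ/mol.
#' @export
chemical_potential <- function(state, ctx = energy_context()) {
  if (state$activity <= 0) abort("chemical potential undefined at zero activity")
  state$mu0 + ctx$R * ctx$T * log(state$activity) / 1000
}

#' Activity-coefficient ratio demanded by equal activities across phases
#'
#' If a mobile component has unequal mole fractions `x_i`, `x_j` in two
#' connected phases at equilibrium, equality of its activities requires the
#' activity coefficients to be reciprocally distributed:
#' `gamma_j / gamma_i = x_i / x_j`. A tenfold concentration asymmetry is
#' therefore exactly cancelled by a 1/10 coefficient ratio — it stores no
#' usable free energy.
#'
#' @param x_i,x_j Mole fractions (> 0) in phases i and j.
#' @return `gamma_j / gamma_i`.
#' @export
activity_coefficient_ratio <- function(x_i, x_j) {
  if (any(c(x_i, x_j) <= 0)) abort("mole fractions must be positive")
  x_i / x_j
}

#' Carrier partition ratio (total outward / total inward carrier)
#'
#' `(C_out + GC_out) / (C_in + GC_in)` at a steady state of a four-state
#' carrier model, as a function of the prevailing ligand concentrations.
#'
#' @param ss A `steady_state` of a carrier model (states tagged with
#'   `location` "outward"/"inward").
#' @return Dimensionless ratio.
#' @export
partition_ratio <- function(ss) {
  occ <- ss$occupancy
  if (!all(c("outward", "inward") %in% occ$location)) {
    abort("partition_ratio needs a carrier model with outward/inward state tags")
  }
  sum(occ$occupancy[occ$location == "outward"]) /
    sum(occ$occupancy[occ$location == "inward"])
}

#' Equilibrium uniformity audit
#'
#' Clamps both baths at the same concentration, solves the steady state, and
#' checks the equilibrium signature of a thermodynamically consistent
#' passive network: every internal void and finite bath sits at the bath
#' concentration (uniform ligand activity at all nodes) and every elementary
#' step carries zero net flux.
#'
#' @param model A `transport_network` with baths `"out"` and `"in"`.
#' @param bath_conc Common bath concentration, mmol/L.
#' @param tolerance Relative tolerance for both checks.
#' @return An `equilibrium_audit`: `uniform` flag, `max_conc_deviation`
#'   (relative), `max_flux_imbalance` (net flux relative to the larger
#'   one-way flux), the solved concentration and flux tables.
#' @export
equilibrium_audit <- function(model, bath_conc = 10, tolerance = 1e-6) {
  sp <- .primary_species(model)
  zero <- setNames(rep(0, nrow(model$species)), model$species$name)
  cv <- zero; cv[sp] <- bath_conc
  ss <- solve_steady_state(model, clamps = list(out = cv, `in` = cv))

  conc <- ss$concentrations
  internal <- conc[!conc$clamped & conc$species == sp, ]
  conc_dev <- if (nrow(internal)) {
    max(abs(internal$conc - bath_conc)) / max(bath_conc, .Machine$double.eps)
  } else 0

  fx <- ss$fluxes
  # judge each edge against its own one-way fluxes, floored by a global flux
  # scale so identically idle edges (e.g. absent tracer) are not 0/0 noise
  floor_ <- max(fx$forward, fx$backward, 1) * 1e-9
  denom <- pmax(pmax(fx$forward, fx$backward), floor_)
  flux_imb <- max(abs(fx$net) / denom)

  structure(list(uniform = conc_dev <= tolerance && flux_imb <= tolerance,
                 max_conc_deviation = conc_dev,
                 max_flux_imbalance = flux_imb,
                 bath_conc = bath_conc, tolerance = tolerance,
                 concentrations = conc, fluxes = fx,
                 steady_state = ss),
            class = "equilibrium_audit")
}

#' @export
print.equilibrium_audit <- function(x, ...) {
  cat(sprintf("<equilibrium_audit> baths at %g mmol/L: %s\n", x$bath_conc,
              if (x$uniform) "uniform (equilibrium)" else "NOT uniform"))
  cat(sprintf("  max relative concentration deviation: %.3g\n",
              x$max_conc_deviation))
  cat(sprintf("  max relative net-flux imbalance:      %.3g\n",
              x$max_flux_imbalance))
  invisible(x)
}
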