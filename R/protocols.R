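# Transport-protocol drivers. All "initial rate" protocols are realised as
# clamped-bath steady states: the bathing solutions are held fixed and the
# transporter's internal states (and any void concentrations) are solved to
# stationarity, which is what an initial-rate measurement samples.

#' Default protocol concentration grid
#'
#' Log-spaced cis/ambient concentrations spanning 0.03-300 mmol/L, which
#' covers the half-saturation constants of all packaged models by more than
#' 30-fold on either side.
#'
#' @param n Number of grid points.
#' @param from,to Range, mmol/L.
#' @return Numeric vector, strictly increasing.
#' @export
default_conc_grid <- function(n = 24, from = 0.03, to = 300) {
  exp(seq(log(from), log(to), length.out = n))
}

.check_grid <- function(grid) {
  if (length(grid) < 2 || any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    abort("concentration grid must be positive and strictly increasing")
  }
  grid
}

# Indices of transitions delivering ligand into / removing it from a bath,
# optionally restricted to a species subset.
.delivery_idx <- function(cm, bath, species = NULL) {
  tr <- cm$model$transitions
  keep_in <- if (is.null(species)) rep(TRUE, nrow(tr)) else
    (!is.na(tr$species) & tr$species %in% species)
  keep_out <- if (is.null(species)) rep(TRUE, nrow(tr)) else
    (!is.na(tr$species2) & tr$species2 %in% species)
  at_bath <- !is.na(tr$compartment) & tr$compartment == bath
  list(
    gain = which((keep_in & ((tr$kind == "release" & at_bath) |
                               (tr$kind == "void_diffusion" & tr$to == bath))) |
                   (keep_out & tr$kind == "exchange" & at_bath)),
    loss = which(keep_in & (((tr$kind == "binding" | tr$kind == "exchange") & at_bath) |
                              (tr$kind == "void_diffusion" & tr$from == bath))))
}

# Solve a sequence of clamped-bath conditions on one compiled network,
# reusing the previous solution as a warm start for nonlinear models.
# `conditions` is a list of clamp lists; returns a list of per-transition
# flux vectors.
.sweep_steady_fluxes <- function(model, conditions) {
  cm <- .compile_network(model, NULL)
  prev <- NULL
  lapply(conditions, function(cl) {
    conc <- .conc_matrix(model, cl)
    cmi <- .patch_clamps(cm, conc)
    if (cmi$bath_only) {
      x <- .solve_linear(cmi)
      .fluxes(cmi, x, numeric())
    } else {
      y0 <- prev %||% .relax_ode(cmi, c(cmi$x0, cmi$c0), rtol = 1e-6)
      ns <- .newton_polish(cmi, y0)
      if (!ns$converged) {
        y0 <- .relax_ode(cmi, c(cmi$x0, cmi$c0), rtol = 1e-8)
        ns <- .newton_polish(cmi, y0)
      }
      if (!ns$converged) abort("steady-state solve failed during protocol sweep")
      prev <<- ns$y
      .fluxes(cmi, ns$y[seq_len(cmi$n_x)], ns$y[cmi$n_x + seq_len(cmi$n_c)])
    }
  })
}

.primary_species <- function(model) setdiff(model$species$name,
                                            labelled_species(model))[1]

new_flux_curve <- function(df, protocol, direction) {
  df <- as_tibble(df)
  class(df) <- c("flux_curve", class(df))
  attr(df, "protocol") <- protocol
  attr(df, "direction") <- direction
  df
}

#' Zero-trans net flux saturation curve
#'
#' For each grid concentration the cis bath is clamped at that value and the
#' trans bath at zero; the steady-state net delivery into the trans bath is
#' recorded. With zero trans ligand there is no back-flux, so the net flux
#' equals the unidirectional flux.
#'
#' @param model A `transport_network` with baths named `"out"` and `"in"`.
#' @param direction `"influx"` (cis = out) or `"efflux"` (cis = in).
#' @param grid Cis concentrations, mmol/L.
#' @return A `flux_curve` tibble: `concentration` (mmol/L), `flux`
#'   (amount/s, i.e. per total carrier per second when `C_T = 1`).
#' @export
run_zero_trans <- function(model, direction = c("influx", "efflux"),
                           grid = default_conc_grid()) {
  direction <- match.arg(direction)
  .check_grid(grid)
  cis <- if (direction == "influx") "out" else "in"
  trans <- setdiff(c("out", "in"), cis)
  sp <- .primary_species(model)
  zero <- setNames(rep(0, nrow(model$species)), model$species$name)
  conds <- lapply(grid, function(G) {
    cv <- zero; cv[sp] <- G
    setNames(list(cv, zero), c(cis, trans))
  })
  cm <- .compile_network(model, NULL)
  di <- .delivery_idx(cm, trans)
  fl <- tryCatch(.sweep_steady_fluxes(model, conds), error = function(e) {
    abort(sprintf("zero-trans %s sweep failed (%s)", direction, conditionMessage(e)))
  })
  flux <- vapply(fl, function(f) sum(f[di$gain]) - sum(f[di$loss]), numeric(1))
  flux[abs(flux) < 1e-14] <- 0
  new_flux_curve(tibble(concentration = grid, flux = flux),
                 paste0("zero_trans_", direction), direction)
}

# Prepare a two-species (labelled/unlabelled) version of a model, reusing an
# existing isotope pair when the model was built with one.
.tracer_model <- function(model, labelled_fraction, cis) {
  if (length(labelled_species(model))) model
  else expand_tracer(model, labelled_fraction, cis)
}

#' Equilibrium-exchange unidirectional flux curve
#'
#' Both baths are clamped at the same total concentration; a small labelled
#' fraction is placed in the cis bath and the steady-state labelled delivery
#' into the trans bath, scaled back by the labelled fraction, gives the
#' unidirectional exchange flux.
#'
#' @inheritParams run_zero_trans
#' @param labelled_fraction Tracer fraction in the cis bath (default 1e-6;
#'   the measured flux is invariant to it in the tracer-linear regime).
#' @return A `flux_curve` tibble.
#' @export
run_equilibrium_exchange <- function(model, direction = c("influx", "efflux"),
                                     grid = default_conc_grid(),
                                     labelled_fraction = 1e-6) {
  direction <- match.arg(direction)
  .check_grid(grid)
  cis <- if (direction == "influx") "out" else "in"
  trans <- setdiff(c("out", "in"), cis)
  m2 <- .tracer_model(model, labelled_fraction, cis)
  unlab <- .primary_species(m2)
  lab <- labelled_species(m2)[1]
  conds <- lapply(grid, function(G) {
    cis_v <- setNames(c((1 - labelled_fraction) * G, labelled_fraction * G),
                      c(unlab, lab))
    trans_v <- setNames(c(G, 0), c(unlab, lab))
    setNames(list(cis_v, trans_v), c(cis, trans))
  })
  cm <- .compile_network(m2, NULL)
  di <- .delivery_idx(cm, trans, species = lab)
  fl <- tryCatch(.sweep_steady_fluxes(m2, conds), error = function(e) {
    abort(sprintf("equilibrium-exchange %s sweep failed (%s)",
                  direction, conditionMessage(e)))
  })
  flux <- vapply(fl, function(f) sum(f[di$gain]) - sum(f[di$loss]), numeric(1)) /
    labelled_fraction
  flux[abs(flux) < 1e-14] <- 0
  new_flux_curve(tibble(concentration = grid, flux = flux),
                 paste0("equilibrium_exchange_", direction), direction)
}

#' Reconfigure the inside bath as a finite, ligand-conserving compartment
#'
#' Counterflow experiments load a closed intracellular compartment; this
#' helper converts the (clamped by default) `"in"` bath to a `finite_bath`
#' of the given volume.
#'
#' @param model A `transport_network`.
#' @param volume Inside volume, litres.
#' @param bath Bath name, default `"in"`.
#' @return The modified model.
#' @export
with_finite_inside <- function(model, volume = 1, bath = "in") {
  i <- match(bath, model$compartments$name)
  if (is.na(i)) abort("unknown bath")
  model$compartments$kind[i] <- "finite_bath"
  model$compartments$volume[i] <- volume
  validate_transport_network(model)
}

#' Set a default/initial compartment concentration
#'
#' @param model A `transport_network`.
#' @param compartment,species Identifiers.
#' @param conc Concentration, mmol/L.
#' @return The modified model.
#' @export
set_concentration <- function(model, compartment, species, conc) {
  if (!compartment %in% model$compartments$name) abort("unknown compartment")
  if (!species %in% model$species$name) abort("unknown species")
  cc <- model$concentrations
  hit <- cc$compartment == compartment & cc$species == species
  if (any(hit)) cc$conc[hit] <- conc
  else cc <- bind_rows(cc, tibble(compartment = compartment,
                                  species = species, conc = conc))
  model$concentrations <- cc
  model
}

#' Counterflow (countercurrent overshoot) time course
#'
#' The inside bath is preloaded with unlabelled sugar; the outside bath is
#' clamped with labelled sugar only. The labelled concentration ratio
#' inside/outside is followed over time: transport mechanisms that couple
#' the downhill unlabelled efflux to labelled influx drive the ratio
#' transiently above 1 (uphill tracer movement) before it decays back as the
#' unlabelled gradient dissipates.
#'
#' @param model A `transport_network` whose `"in"` bath has been made finite
#'   (see [with_finite_inside()]).
#' @param inside_load Initial unlabelled concentration inside, mmol/L.
#' @param tracer_outside Clamped labelled concentration outside, mmol/L.
#' @param t_grid Output times, s.
#' @return A tibble (`counterflow_course`): `time`, `inside_label`,
#'   `outside_label`, `ratio`.
#' @export
run_counterflow <- function(model, inside_load = 100, tracer_outside = 1,
                            t_grid = NULL) {
  ik <- model$compartments$kind[match("in", model$compartments$name)]
  if (!identical(ik, "finite_bath")) {
    abort("counterflow needs a finite inside bath; see with_finite_inside()")
  }
  if (is.null(t_grid)) t_grid <- seq(0.5, 200, by = 0.5)
  m2 <- .tracer_model(model, labelled_fraction = 1, cis = "out")
  unlab <- .primary_species(m2)
  lab <- labelled_species(m2)[1]
  m2 <- set_concentration(m2, "out", lab, tracer_outside)
  m2 <- set_concentration(m2, "out", unlab, 0)
  m2 <- set_concentration(m2, "in", unlab, inside_load)
  m2 <- set_concentration(m2, "in", lab, 0)
  tc <- integrate_time_course(m2, t_grid)
  inside <- tc[tc$variable == "concentration" & tc$id == "in" &
                 tc$species == lab, c("time", "value")]
  out <- tibble(time = inside$time, inside_label = inside$value,
                outside_label = tracer_outside,
                ratio = inside$value / tracer_outside)
  class(out) <- c("counterflow_course", class(out))
  out
}
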