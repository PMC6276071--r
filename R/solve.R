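# Numerical core: compiled network representation, mass-action derivative,
# direct linear steady-state solve, ODE relaxation, damped Newton polish,
# and time-course integration.

# Compile a model (+ clamps) into flat index vectors for fast evaluation.
# Free variables are state occupancies plus (compartment, species) pairs of
# every non-clamped compartment.
.compile_network <- function(model, clamps = NULL) {
  st <- model$states; tr <- model$transitions
  cp <- model$compartments; spn <- model$species$name
  n_x <- nrow(st)
  conc <- .conc_matrix(model, clamps)

  free_cp <- cp$name[cp$kind != "clamped_bath"]
  cf <- expand.grid(compartment = free_cp, species = spn,
                    stringsAsFactors = FALSE)
  n_c <- nrow(cf)
  cf_key <- if (n_c) paste(cf$compartment, cf$species) else character()
  cvol <- if (n_c) cp$volume[match(cf$compartment, cp$name)] else numeric()

  m <- nrow(tr)
  t_rate <- tr$rate
  t_xfrom <- integer(m); t_cidx <- integer(m); t_cconst <- rep(1, m)
  # provenance of clamped concentration factors, for fast re-clamping
  t_src_comp <- rep(NA_character_, m); t_src_sp <- rep(NA_character_, m)
  Sx <- matrix(0, n_x, m); Sc <- matrix(0, max(n_c, 1), m)
  sidx <- function(id) match(id, st$id)
  cidx <- function(comp, sp) match(paste(comp, sp), cf_key)

  for (j in seq_len(m)) {
    k <- tr$kind[j]
    if (k == "conformational") {
      f <- sidx(tr$from[j]); t <- sidx(tr$to[j])
      t_xfrom[j] <- f; Sx[f, j] <- -1; Sx[t, j] <- 1
    } else if (k == "binding") {
      f <- sidx(tr$from[j]); t <- sidx(tr$to[j])
      t_xfrom[j] <- f; Sx[f, j] <- -1; Sx[t, j] <- 1
      ci <- cidx(tr$compartment[j], tr$species[j])
      if (is.na(ci)) {
        t_cconst[j] <- conc[tr$compartment[j], tr$species[j]]
        t_src_comp[j] <- tr$compartment[j]; t_src_sp[j] <- tr$species[j]
      } else { t_cidx[j] <- ci; Sc[ci, j] <- -1 }
    } else if (k == "release") {
      f <- sidx(tr$from[j]); t <- sidx(tr$to[j])
      t_xfrom[j] <- f; Sx[f, j] <- -1; Sx[t, j] <- 1
      ci <- cidx(tr$compartment[j], tr$species[j])
      if (!is.na(ci)) Sc[ci, j] <- 1
    } else if (k == "exchange") {
      # bound species2 swaps with free species: flux = k * x[from] * c(comp, species)
      f <- sidx(tr$from[j]); t <- sidx(tr$to[j])
      t_xfrom[j] <- f; Sx[f, j] <- -1; Sx[t, j] <- 1
      ci_in <- cidx(tr$compartment[j], tr$species[j])
      if (is.na(ci_in)) {
        t_cconst[j] <- conc[tr$compartment[j], tr$species[j]]
        t_src_comp[j] <- tr$compartment[j]; t_src_sp[j] <- tr$species[j]
      } else { t_cidx[j] <- ci_in; Sc[ci_in, j] <- -1 }
      ci_out <- cidx(tr$compartment[j], tr$species2[j])
      if (!is.na(ci_out)) Sc[ci_out, j] <- Sc[ci_out, j] + 1
    } else { # void_diffusion: flux = rate * conc[from] (amount/s at 1 L ref)
      ci_from <- cidx(tr$from[j], tr$species[j])
      if (is.na(ci_from)) {
        t_cconst[j] <- conc[tr$from[j], tr$species[j]]
        t_src_comp[j] <- tr$from[j]; t_src_sp[j] <- tr$species[j]
      } else { t_cidx[j] <- ci_from; Sc[ci_from, j] <- -1 }
      ci_to <- cidx(tr$to[j], tr$species[j])
      if (!is.na(ci_to)) Sc[ci_to, j] <- 1
    }
  }

  groups <- split(seq_len(n_x), st$group[seq_len(n_x)])
  totals <- setNames(model$totals$total, model$totals$group)[names(groups)]

  c0 <- if (n_c) conc[cbind(match(cf$compartment, rownames(conc)),
                            match(cf$species, colnames(conc)))] else numeric()
  x0 <- numeric(n_x)
  for (g in seq_along(groups)) x0[groups[[g]]] <- totals[[g]] / length(groups[[g]])

  list(model = model, n_x = n_x, n_c = n_c, cf = cf, cvol = cvol,
       t_rate = t_rate, t_xfrom = t_xfrom, t_cidx = t_cidx,
       t_cconst = t_cconst, t_src_comp = t_src_comp, t_src_sp = t_src_sp,
       Sx = Sx, Sc = Sc,
       groups = groups, totals = totals, x0 = x0, c0 = c0,
       bath_only = n_c == 0L)
}

# Re-clamp a compiled network's bath concentrations without recompiling.
# `conc` is a named matrix [compartment, species] as from .conc_matrix().
.patch_clamps <- function(cm, conc) {
  sel <- which(!is.na(cm$t_src_comp))
  cm$t_cconst[sel] <- conc[cbind(cm$t_src_comp[sel], cm$t_src_sp[sel])]
  cm
}

# Per-transition fluxes (amount/s) at state y = c(x, conc_free).
.fluxes <- function(cm, x, cfree) {
  fac <- cm$t_cconst
  if (cm$n_c) {
    sel <- cm$t_cidx > 0L
    fac[sel] <- cfree[cm$t_cidx[sel]]
  }
  a <- rep(1, length(cm$t_rate))
  sel <- cm$t_xfrom > 0L
  a[sel] <- x[cm$t_xfrom[sel]]
  cm$t_rate * a * fac
}

.deriv <- function(cm, y) {
  x <- y[seq_len(cm$n_x)]
  cfree <- if (cm$n_c) y[cm$n_x + seq_len(cm$n_c)] else numeric()
  fl <- .fluxes(cm, x, cfree)
  dx <- drop(cm$Sx %*% fl)
  if (cm$n_c) c(dx, drop(cm$Sc %*% fl)[seq_len(cm$n_c)] / cm$cvol) else dx
}

# Residual with conservation rows substituted (first state of each group).
.newton_resid <- function(cm, y) {
  r <- .deriv(cm, y)
  x <- y[seq_len(cm$n_x)]
  for (g in seq_along(cm$groups)) {
    idx <- cm$groups[[g]]
    r[idx[1]] <- sum(x[idx]) - cm$totals[[g]]
  }
  r
}

.num_jacobian <- function(fn, y, eps = 1e-7) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- eps * max(1, abs(y[i]))
    yp <- y; yp[i] <- yp[i] + h
    ym <- y; ym[i] <- ym[i] - h
    J[, i] <- (fn(yp) - fn(ym)) / (2 * h)
  }
  J
}

# Direct solve of the master equation for bath-only networks: build the rate
# matrix, substitute one conservation row per group.
.solve_linear <- function(cm) {
  A <- matrix(0, cm$n_x, cm$n_x)
  for (j in seq_along(cm$t_rate)) {
    f <- cm$t_xfrom[j]
    A[, f] <- A[, f] + cm$Sx[, j] * cm$t_rate[j] * cm$t_cconst[j]
  }
  rhs <- numeric(cm$n_x)
  for (g in seq_along(cm$groups)) {
    idx <- cm$groups[[g]]
    A[idx[1], ] <- 0
    A[idx[1], idx] <- 1
    rhs[idx[1]] <- cm$totals[[g]]
  }
  solve(A, rhs)
}

# ODE relaxation towards steady state: integrate in doubling stages until the
# derivative norm drops below rtol * ||y|| or max_time is exhausted.
.relax_ode <- function(cm, y0, rtol = 1e-10, t0 = 1, max_stage = 24) {
  fn <- function(t, y, p) list(.deriv(cm, y))
  y <- y0
  tt <- t0
  for (s in seq_len(max_stage)) {
    # convergence is judged on the residual below, so an early lsoda return
    # in one stage is harmless; it resumes in the next doubling stage
    sol <- suppressWarnings(
      deSolve::ode(y, c(0, tt), fn, NULL, method = "lsoda",
                   rtol = 1e-10, atol = 1e-12, maxsteps = 5e4))
    y <- sol[nrow(sol), -1]
    res <- max(abs(.deriv(cm, y)))
    if (res <= rtol * .resid_scale(cm, y)) break
    tt <- tt * 2
  }
  unname(y)
}

# Residual scale: the largest one-way flux in the system (plus the
# conservation totals); convergence is judged relative to it, since the
# steady-state residual is a cancellation of one-way fluxes.
.resid_scale <- function(cm, y) {
  x <- y[seq_len(cm$n_x)]
  cfree <- if (cm$n_c) y[cm$n_x + seq_len(cm$n_c)] else numeric()
  max(abs(.fluxes(cm, x, cfree)), cm$totals, 1)
}

.newton_polish <- function(cm, y0, tol = 1e-12, max_iter = 100) {
  y <- y0
  for (it in seq_len(max_iter)) {
    scale <- .resid_scale(cm, y)
    r <- .newton_resid(cm, y)
    if (max(abs(r)) <= tol * scale) {
      return(list(y = y, converged = TRUE, residual = max(abs(r)), iter = it - 1L))
    }
    J <- .num_jacobian(function(z) .newton_resid(cm, z), y)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:25) {
      y_new <- y + lambda * step
      r_new <- .newton_resid(cm, y_new)
      if (all(is.finite(r_new)) && max(abs(r_new)) < max(abs(r))) {
        y <- y_new; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  r <- .newton_resid(cm, y)
  list(y = y, converged = max(abs(r)) <= tol * .resid_scale(cm, y),
       residual = max(abs(r)), iter = max_iter)
}

.assemble_steady_state <- function(cm, y, method, converged, residual) {
  model <- cm$model
  x <- y[seq_len(cm$n_x)]
  x[x < 0 & x > -1e-12] <- 0
  cfree <- if (cm$n_c) y[cm$n_x + seq_len(cm$n_c)] else numeric()
  fl <- .fluxes(cm, x, cfree)
  tr <- model$transitions
  fluxes <- tibble(
    id = tr$id, from = tr$from, to = tr$to, kind = tr$kind,
    compartment = tr$compartment, species = tr$species,
    species2 = tr$species2,
    forward = fl, backward = fl[tr$pair], net = fl - fl[tr$pair])

  # effective concentrations: clamps as compiled, free pairs at solved values
  conc_full <- attr(cm, "conc_effective") %||% .conc_matrix(model)
  if (cm$n_c) {
    conc_full[cbind(match(cm$cf$compartment, rownames(conc_full)),
                    match(cm$cf$species, colnames(conc_full)))] <- cfree
  }
  clamped_names <- model$compartments$name[model$compartments$kind == "clamped_bath"]
  conc_tbl <- tibble(
    compartment = rep(rownames(conc_full), ncol(conc_full)),
    species = rep(colnames(conc_full), each = nrow(conc_full)),
    conc = as.vector(conc_full))
  conc_tbl$clamped <- conc_tbl$compartment %in% clamped_names

  structure(
    list(occupancy = tibble(state = model$states$id,
                            group = model$states$group,
                            location = model$states$location,
                            occupant = model$states$occupant,
                            occupancy = x),
         concentrations = conc_tbl,
         fluxes = fluxes,
         converged = converged, residual_norm = residual,
         method = method, model = model),
    class = "steady_state")
}

#' Solve a transport network to steady state
#'
#' For networks whose only dynamic variables are carrier-state occupancies
#' (all compartments clamped), the steady state is a direct linear solve of
#' the master equation under the conservation constraints. Networks with
#' internal voids or finite baths are nonlinear (binding fluxes couple
#' occupancies to void concentrations); these are relaxed by stiff ODE
#' integration and polished by a damped Newton iteration to a residual of
#' 1e-12.
#'
#' @param model A `transport_network`.
#' @param clamps Named list of clamped-bath concentrations overriding the
#'   model defaults, e.g. `list(out = 5, in = 0)`; values may be named
#'   per-species vectors.
#' @param method `"auto"` (default: linear where possible, otherwise
#'   ODE + Newton), `"linear"`, `"ode"` (relaxation only), or `"newton"`.
#' @param max_iter Newton iteration cap.
#' @return A `steady_state` object: tibbles `occupancy`, `concentrations`,
#'   `fluxes` (per directed transition: forward, backward = its reverse
#'   partner's flux, net), plus `converged`, `residual_norm`, `method`.
#' @export
solve_steady_state <- function(model, clamps = NULL,
                               method = c("auto", "linear", "ode", "newton"),
                               max_iter = 100) {
  method <- match.arg(method)
  cm <- .compile_network(model, clamps)
  attr(cm, "conc_effective") <- .conc_matrix(model, clamps)
  if (method == "linear" && !cm$bath_only) {
    abort("method = 'linear' needs a bath-only (fully clamped) network")
  }
  if (method == "auto") method <- if (cm$bath_only) "linear" else "newton"

  if (method == "linear") {
    x <- .solve_linear(cm)
    y <- c(x, cm$c0)
    res <- max(abs(.newton_resid(cm, y)))
    out <- .assemble_steady_state(cm, y, "linear",
                                  res <= 1e-8 * .resid_scale(cm, y), res)
  } else if (method == "ode") {
    y <- .relax_ode(cm, c(cm$x0, cm$c0))
    res <- max(abs(.deriv(cm, y)))
    out <- .assemble_steady_state(cm, y, "ode",
                                  res <= 1e-8 * .resid_scale(cm, y), res)
  } else {
    y <- .relax_ode(cm, c(cm$x0, cm$c0), rtol = 1e-6)
    ns <- .newton_polish(cm, y, max_iter = max_iter)
    if (!ns$converged) {
      abort(sprintf("steady-state solve did not converge (residual %.3g after %d iterations)",
                    ns$residual, ns$iter))
    }
    out <- .assemble_steady_state(cm, ns$y, "newton", TRUE, ns$residual)
  }
  if (any(out$occupancy$occupancy < -1e-9)) {
    abort("steady-state solve produced negative occupancies")
  }
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> method=%s converged=%s residual=%.3g\n",
              x$method, x$converged, x$residual_norm))
  print(x$occupancy)
  invisible(x)
}

#' Net ligand delivery rate into a compartment
#'
#' Sums release fluxes into minus binding fluxes out of the compartment, plus
#' net diffusion, optionally restricted to a species subset. Units: amount/s
#' (carrier amounts per second when the total carrier is 1).
#'
#' @param ss A `steady_state`.
#' @param bath Compartment name.
#' @param species Optional species subset.
#' @return Numeric scalar.
#' @export
bath_net_delivery <- function(ss, bath, species = NULL) {
  fx <- ss$fluxes
  keep_in <- if (is.null(species)) !is.na(fx$species) else
    (!is.na(fx$species) & fx$species %in% species)
  keep_out <- if (is.null(species)) !is.na(fx$species2) else
    (!is.na(fx$species2) & fx$species2 %in% species)
  gain <- sum(fx$forward[keep_in & fx$kind == "release" & fx$compartment == bath],
              fx$forward[keep_in & fx$kind == "void_diffusion" & fx$to == bath],
              fx$forward[keep_out & fx$kind == "exchange" & fx$compartment == bath])
  loss <- sum(fx$forward[keep_in & fx$kind == "binding" & fx$compartment == bath],
              fx$forward[keep_in & fx$kind == "void_diffusion" & fx$from == bath],
              fx$forward[keep_in & fx$kind == "exchange" & fx$compartment == bath])
  gain - loss
}

#' Unidirectional (tracer) flux into the trans bath
#'
#' The labelled delivery rate into `trans_bath` divided by the labelled
#' fraction: the standard isotope measure of one-way flux. For a zero-trans
#' protocol this equals the net flux; at equilibrium influx and efflux
#' unidirectional fluxes are equal while the net flux vanishes.
#'
#' @param ss A converged `steady_state` of a tracer-expanded (or two-species)
#'   model.
#' @param trans_bath Name of the receiving bath.
#' @param labelled_fraction The labelled fraction used when expanding the
#'   tracer (see [expand_tracer()]).
#' @return Flux in amount/s.
#' @export
unidirectional_flux <- function(ss, trans_bath, labelled_fraction = 1e-6) {
  if (!isTRUE(ss$converged)) abort("steady state did not converge")
  lab <- labelled_species(ss$model)
  if (!length(lab)) abort("model has no labelled species; expand the tracer first")
  bath_net_delivery(ss, trans_bath, species = lab) / labelled_fraction
}

#' Integrate the mass-action time course of a transport network
#'
#' Stiff ODE integration (lsoda) of state occupancies and free compartment
#' concentrations. Carrier totals are conserved exactly by the mass-action
#' structure; for systems with finite baths total ligand
#' (baths + voids + bound) is conserved as well.
#'
#' @param model A `transport_network`.
#' @param t_grid Increasing vector of output times (s).
#' @param clamps Clamped-bath overrides as in [solve_steady_state()].
#' @param initial_occupancy Optional named vector of initial state
#'   occupancies (defaults to a uniform split of each group's total).
#' @return A tibble in long format: `time`, `variable` (`"occupancy"` or
#'   `"concentration"`), `id` (state or compartment), `species` (for
#'   concentrations), `value`; classed `time_course`.
#' @export
integrate_time_course <- function(model, t_grid, clamps = NULL,
                                  initial_occupancy = NULL) {
  if (is.unsorted(t_grid, strictly = TRUE)) abort("t_grid must be strictly increasing")
  cm <- .compile_network(model, clamps)
  attr(cm, "conc_effective") <- .conc_matrix(model, clamps)
  x0 <- cm$x0
  if (!is.null(initial_occupancy)) {
    idx <- match(names(initial_occupancy), model$states$id)
    if (anyNA(idx)) abort("unknown state in initial_occupancy")
    x0[idx] <- initial_occupancy
    for (g in seq_along(cm$groups)) {
      s <- sum(x0[cm$groups[[g]]])
      if (abs(s - cm$totals[[g]]) > 1e-9 * max(1, cm$totals[[g]])) {
        abort("initial occupancies violate a conservation total")
      }
    }
  }
  y0 <- c(x0, cm$c0)
  fn <- function(t, y, p) list(.deriv(cm, y))
  tt <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  sol <- deSolve::ode(y0, tt, fn, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12, maxsteps = 5e4)
  if (attr(sol, "istate")[1] < 0) abort("stiff ODE integration failed")
  sol <- sol[sol[, 1] %in% t_grid, , drop = FALSE]

  n_t <- nrow(sol)
  occ <- tibble(
    time = rep(sol[, 1], each = cm$n_x),
    variable = "occupancy",
    id = rep(model$states$id, n_t),
    species = rep(model$states$occupant, n_t),
    value = as.vector(t(sol[, 1 + seq_len(cm$n_x), drop = FALSE])))
  out <- occ
  if (cm$n_c) {
    conc <- tibble(
      time = rep(sol[, 1], each = cm$n_c),
      variable = "concentration",
      id = rep(cm$cf$compartment, n_t),
      species = rep(cm$cf$species, n_t),
      value = as.vector(t(sol[, 1 + cm$n_x + seq_len(cm$n_c), drop = FALSE])))
    out <- bind_rows(occ, conc)
  }
  class(out) <- c("time_course", class(out))
  attr(out, "model") <- model
  out
}
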