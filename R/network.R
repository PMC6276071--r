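#' Define a transported ligand species
#'
#' Species in the same isotope class are kinetically indistinguishable: every
#' transition involving one member must have an identically parameterised twin
#' for each other member (this is how radiolabelled and unlabelled sugar are
#' represented).
#'
#' @param name Species identifier.
#' @param isotope_class Isotope-class identifier; defaults to `name`.
#' @return One-row tibble with columns `name`, `isotope_class`.
#' @export
ligand_species <- function(name, isotope_class = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  tibble(name = name, isotope_class = isotope_class)
}

#' Define a compartment
#'
#' Compartments hold free ligand. A `clamped_bath` has fixed concentrations
#' (pseudo-first-order boundary condition), a `finite_bath` conserves ligand
#' amount (`concentration * volume`), and an `internal_void` is an
#' intramolecular diffusion sink whose concentration is a state variable.
#'
#' @param name Compartment identifier.
#' @param kind One of `"clamped_bath"`, `"finite_bath"`, `"internal_void"`.
#' @param volume Volume in litre-equivalents; required for `finite_bath`,
#'   defaults to 0.01 for `internal_void` (irrelevant at steady state, sets the
#'   void relaxation time scale in time courses), `NA` for clamped baths.
#' @return One-row tibble.
#' @export
compartment <- function(name, kind = c("clamped_bath", "finite_bath", "internal_void"),
                        volume = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "finite_bath" && (is.na(volume) || volume <= 0)) {
    abort("a finite_bath compartment needs a positive volume")
  }
  if (kind == "internal_void" && is.na(volume)) volume <- 0.01
  tibble(name = name, kind = kind, volume = as.numeric(volume))
}

#' Define a carrier/site state
#'
#' @param id State identifier (unique within a model).
#' @param group Conservation group: the occupancies of all states in a group
#'   sum to that group's total amount (one group for a mobile carrier, one per
#'   binding site for fixed-site models).
#' @param location Free-form tag, e.g. `"outward"`, `"inward"`, or a site
#'   index; used by [partition_ratio()] to identify facing.
#' @param occupant Species name bound in this state, or `NA` for an empty
#'   state (dual-occupancy states leave this `NA` and declare their contents
#'   via the model's `bound` table).
#' @return One-row tibble.
#' @export
carrier_state <- function(id, group = "carrier", location = NA_character_,
                          occupant = NA_character_) {
  tibble(id = id, group = group, location = location, occupant = occupant)
}

# Internal transition-row constructors used by the model builders. Rates are
# s^-1 except binding, which is (mmol/L)^-1 s^-1 and is multiplied by the
# coupled compartment's concentration at run time.
tr_conformational <- function(from, to, rate) {
  tibble(from = from, to = to, kind = "conformational", rate = rate,
         compartment = NA_character_, species = NA_character_)
}
tr_binding <- function(from, to, rate, compartment, species) {
  tibble(from = from, to = to, kind = "binding", rate = rate,
         compartment = compartment, species = species)
}
tr_release <- function(from, to, rate, compartment, species) {
  tibble(from = from, to = to, kind = "release", rate = rate,
         compartment = compartment, species = species)
}
tr_diffusion <- function(from, to, rate, species) {
  tibble(from = from, to = to, kind = "void_diffusion", rate = rate,
         compartment = NA_character_, species = species)
}
# Associative exchange: the ligand bound in `from` (species_out) swaps with a
# free ligand (species_in) from `compartment` in one bilinear step; `to` is
# the state bound with species_in. Rate units (mmol/L)^-1 s^-1.
tr_exchange <- function(from, to, rate, compartment, species_in, species_out) {
  tibble(from = from, to = to, kind = "exchange", rate = rate,
         compartment = compartment, species = species_in,
         species2 = species_out)
}

#' Assemble a mass-action transport network
#'
#' The central container of the package: carrier/site states, the mass-action
#' transitions between them, the compartments they exchange ligand with, and
#' conservation totals. Every transition must have a declared reverse partner
#' (microscopic reversibility of the network topology); binding/release pairs
#' are matched through their coupled compartment and species.
#'
#' @param states Tibble as produced by [carrier_state()].
#' @param transitions Tibble with columns `from`, `to`, `kind`, `rate`,
#'   `compartment`, `species`. For `conformational` transitions `from`/`to`
#'   are state ids; for `binding` (empty state -> liganded state, consuming
#'   one ligand from `compartment`) and `release` (the reverse) likewise; for
#'   `void_diffusion` they are compartment names.
#' @param compartments Tibble as produced by [compartment()].
#' @param species Tibble as produced by [ligand_species()].
#' @param concentrations Tibble `(compartment, species, conc)` of default
#'   concentrations in mmol/L; missing pairs default to 0.
#' @param totals Tibble `(group, total)` of conserved amounts; groups missing
#'   from it default to a total of 1.
#' @param bound Optional tibble `(state, species, count)` of bound ligand per
#'   state, for total-ligand accounting. Derived from `states$occupant` when
#'   omitted.
#' @param model_kind Free-form tag (`"carrier"`, `"multisite"`, ...) recording
#'   the builder family; consulted by [partition_ratio()].
#' @return A validated `transport_network` object.
#' @export
transport_network <- function(states, transitions, compartments, species,
                              concentrations = NULL, totals = NULL,
                              bound = NULL, model_kind = "generic") {
  states <- as_tibble(states)
  transitions <- as_tibble(transitions)
  compartments <- as_tibble(compartments)
  species <- as_tibble(species)
  if (is.null(concentrations)) {
    concentrations <- tibble(compartment = character(), species = character(),
                             conc = numeric())
  }
  if (is.null(totals)) totals <- tibble(group = character(), total = numeric())
  missing_groups <- setdiff(unique(states$group), totals$group)
  if (length(missing_groups)) {
    totals <- bind_rows(totals, tibble(group = missing_groups, total = 1))
  }
  if (is.null(bound)) {
    occ <- states[!is.na(states$occupant), c("id", "occupant")]
    bound <- tibble(state = occ$id, species = occ$occupant,
                    count = rep(1, nrow(occ)))
  }
  if (!"species2" %in% names(transitions)) {
    transitions$species2 <- NA_character_
  }
  transitions$id <- seq_len(nrow(transitions))
  x <- structure(
    list(states = states, transitions = transitions,
         compartments = compartments, species = species,
         concentrations = as_tibble(concentrations), totals = as_tibble(totals),
         bound = as_tibble(bound), model_kind = model_kind),
    class = "transport_network")
  validate_transport_network(x)
}

# Expected reverse-partner key of each transition; binding <-> release,
# exchange <-> the mirrored exchange (species roles swapped).
.tr_key <- function(kind, from, to, compartment, species, species2) {
  paste(kind, from, to,
        ifelse(is.na(compartment), ".", compartment),
        ifelse(is.na(species), ".", species),
        ifelse(is.na(species2), ".", species2), sep = "|")
}
.tr_reverse_key <- function(tr) {
  rk <- c(conformational = "conformational", binding = "release",
          release = "binding", void_diffusion = "void_diffusion",
          exchange = "exchange")[tr$kind]
  ex <- tr$kind == "exchange"
  sp <- ifelse(ex, tr$species2, tr$species)
  sp2 <- ifelse(ex, tr$species, tr$species2)
  .tr_key(rk, tr$to, tr$from, tr$compartment, sp, sp2)
}

#' Validate a transport network
#'
#' Checks identifier uniqueness and referential integrity, positivity of rate
#' constants and concentrations, presence of a reverse partner for every
#' transition, and strong connectivity of each conservation group's state
#' graph. Returns the model with a `pair` column (index of each transition's
#' reverse partner) added to `transitions`.
#'
#' @param x A `transport_network`.
#' @return The validated (annotated) model, invisibly classed as before.
#' @export
validate_transport_network <- function(x) {
  st <- x$states; tr <- x$transitions; cp <- x$compartments; sp <- x$species
  if (anyDuplicated(st$id)) abort("duplicate state ids")
  if (anyDuplicated(cp$name)) abort("duplicate compartment names")
  if (anyDuplicated(sp$name)) abort("duplicate species names")
  if (length(intersect(st$id, cp$name))) {
    abort("state ids and compartment names must not collide")
  }
  if (any(!is.finite(tr$rate)) || any(tr$rate <= 0)) {
    abort("all rate constants must be positive and finite")
  }
  if (nrow(x$concentrations) && any(x$concentrations$conc < 0)) {
    abort("concentrations must be non-negative")
  }
  ok_state_ref <- function(v) all(v %in% st$id)
  for (kind in c("conformational", "binding", "release", "exchange")) {
    sub <- tr[tr$kind == kind, ]
    if (!ok_state_ref(sub$from) || !ok_state_ref(sub$to)) {
      abort(paste0("unknown state referenced by a ", kind, " transition"))
    }
  }
  vd <- tr[tr$kind == "void_diffusion", ]
  if (!all(c(vd$from, vd$to) %in% cp$name)) {
    abort("unknown compartment referenced by a void_diffusion transition")
  }
  br <- tr[tr$kind %in% c("binding", "release"), ]
  if (any(is.na(br$compartment)) || any(is.na(br$species))) {
    abort("binding/release transitions need a coupled compartment and species")
  }
  ex <- tr[tr$kind == "exchange", ]
  if (any(is.na(ex$compartment)) || any(is.na(ex$species)) || any(is.na(ex$species2))) {
    abort("exchange transitions need a compartment and both species roles")
  }
  if (!all(c(br$compartment, ex$compartment) %in% cp$name)) {
    abort("unknown coupled compartment")
  }
  if (!all(c(br$species, vd$species, ex$species, ex$species2) %in% sp$name)) {
    abort("unknown coupled species")
  }

  keys <- .tr_key(tr$kind, tr$from, tr$to, tr$compartment, tr$species, tr$species2)
  if (anyDuplicated(keys)) abort("duplicated transition (same kind, endpoints, compartment, species)")
  pair <- match(.tr_reverse_key(tr), keys)
  if (anyNA(pair)) {
    bad <- tr[which(is.na(pair))[1], ]
    abort(sprintf("transition %s -> %s (%s) has no reverse partner",
                  bad$from, bad$to, bad$kind))
  }
  x$transitions$pair <- pair

  # strong connectivity within each conservation group's state graph
  stg <- tr[tr$kind != "void_diffusion", ]
  for (g in unique(st$group)) {
    ids <- st$id[st$group == g]
    if (length(ids) < 2) next
    sub <- stg[stg$from %in% ids & stg$to %in% ids, ]
    gr <- igraph::graph_from_data_frame(sub[, c("from", "to")],
                                        vertices = data.frame(name = ids))
    if (!igraph::is_connected(gr, mode = "strong")) {
      abort(sprintf("state graph of conservation group '%s' is not strongly connected", g))
    }
  }
  x
}

#' @export
print.transport_network <- function(x, ...) {
  cat(sprintf("<transport_network: %s>\n", x$model_kind))
  cat(sprintf("  %d states in %d conservation group(s), %d transitions\n",
              nrow(x$states), length(unique(x$states$group)),
              nrow(x$transitions)))
  cat(sprintf("  compartments: %s\n",
              paste(sprintf("%s (%s)", x$compartments$name,
                            sub("_bath|internal_", "", x$compartments$kind)),
                    collapse = ", ")))
  cat(sprintf("  species: %s\n", paste(x$species$name, collapse = ", ")))
  invisible(x)
}

# Resolve the full concentration table (all compartment x species pairs,
# defaults filled with 0, clamps applied) as a named matrix [comp, species].
.conc_matrix <- function(model, clamps = NULL) {
  cp <- model$compartments$name
  sp <- model$species$name
  m <- matrix(0, nrow = length(cp), ncol = length(sp),
              dimnames = list(cp, sp))
  cc <- model$concentrations
  if (nrow(cc)) m[cbind(match(cc$compartment, cp), match(cc$species, sp))] <- cc$conc
  if (!is.null(clamps)) {
    kinds <- setNames(model$compartments$kind, cp)
    for (b in names(clamps)) {
      if (!b %in% cp) abort(sprintf("unknown compartment '%s' in clamps", b))
      if (kinds[[b]] != "clamped_bath") {
        abort(sprintf("compartment '%s' is not a clamped bath", b))
      }
      v <- clamps[[b]]
      if (is.null(names(v))) {
        if (length(sp) != 1L && length(v) == 1L) {
          abort("scalar clamp is ambiguous for a multi-species model; name the species")
        }
        names(v) <- sp[seq_along(v)]
      }
      if (!all(names(v) %in% sp)) abort("unknown species in clamps")
      m[b, setdiff(sp, names(v))] <- 0
      m[b, names(v)] <- as.numeric(v)
    }
  }
  if (any(m < 0)) abort("clamped concentrations must be non-negative")
  m
}

#' Duplicate the transported species into labelled and unlabelled twins
#'
#' Expands a single-isotope-class model for tracer work: a labelled twin
#' species is added to the same isotope class, every ligand-bound state and
#' every ligand-coupled transition is duplicated with identical rate
#' constants, and the cis bath's default concentration is split
#' (`labelled_fraction` labelled, remainder unlabelled). Totals are unchanged,
#' so bulk kinetics are unaffected; the labelled subsystem is linear in the
#' tracer, which is what makes unidirectional fluxes well defined.
#'
#' Only single-occupancy models can be expanded generically; models with
#' dual-occupancy (exchange-site) states must be built with both species from
#' the start (see [build_multisite_chain()]'s `n_species`).
#'
#' @param model A `transport_network` with exactly one ligand isotope class
#'   and one species.
#' @param labelled_fraction Fraction of the cis bath assigned to the labelled
#'   twin, in (0, 1]. Default 1e-6: small enough for tracer linearity, large
#'   enough for numerical conditioning.
#' @param cis Name of the bath whose content is labelled.
#' @return An expanded `transport_network`.
#' @export
expand_tracer <- function(model, labelled_fraction = 1e-6, cis) {
  if (!is.numeric(labelled_fraction) || labelled_fraction <= 0 || labelled_fraction > 1) {
    abort("labelled_fraction must be in (0, 1]")
  }
  if (any(model$transitions$kind == "exchange")) {
    abort("model carries exchange transitions; build it with two species directly")
  }
  if (length(unique(model$species$isotope_class)) != 1L || nrow(model$species) != 1L) {
    abort("expand_tracer needs a model with exactly one species in one isotope class")
  }
  if (!cis %in% model$compartments$name) abort("unknown cis compartment")
  base_sp <- model$species$name[1]
  lab_sp <- paste0(base_sp, "_lab")
  suffix <- "*"

  st <- model$states
  occ <- st[!is.na(st$occupant) & st$occupant == base_sp, ]
  twin <- occ
  twin$id <- paste0(occ$id, suffix)
  twin$occupant <- lab_sp
  states <- bind_rows(st, twin)

  tid <- function(id) ifelse(id %in% occ$id, paste0(id, suffix), id)
  tr <- model$transitions[, c("from", "to", "kind", "rate", "compartment", "species")]
  touches <- tr$kind %in% c("binding", "release", "void_diffusion") |
    tr$from %in% occ$id | tr$to %in% occ$id
  dup <- tr[touches, ]
  dup$from <- tid(dup$from)
  dup$to <- tid(dup$to)
  dup$species[!is.na(dup$species)] <- lab_sp
  transitions <- bind_rows(tr, dup)

  species <- bind_rows(model$species,
                       tibble(name = lab_sp,
                              isotope_class = model$species$isotope_class[1]))

  cc <- .conc_matrix(model)
  conc <- tibble(
    compartment = rep(rownames(cc), 2),
    species = rep(c(base_sp, lab_sp), each = nrow(cc)),
    conc = c(cc[, base_sp], rep(0, nrow(cc))))
  i_cis <- conc$compartment == cis
  tot <- cc[cis, base_sp]
  conc$conc[i_cis & conc$species == base_sp] <- (1 - labelled_fraction) * tot
  conc$conc[i_cis & conc$species == lab_sp] <- labelled_fraction * tot

  transport_network(states, transitions, model$compartments, species,
                    concentrations = conc[conc$conc != 0 | i_cis, ],
                    totals = model$totals, model_kind = model$model_kind)
}

#' Names of labelled species (the tracer twins) in a model
#' @param model A `transport_network`.
#' @return Character vector (possibly empty).
#' @export
labelled_species <- function(model) {
  grep("_lab$", model$species$name, value = TRUE)
}
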