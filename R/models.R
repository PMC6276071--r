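#' Parameters of a four-state alternating (mobile) carrier
#'
#' The single-cycle carrier has empty states facing out/in (`C_out`, `C_in`)
#' and liganded states (`GC_out`, `GC_in`). Rates follow the conventional
#' scheme: empty transit `b_out_in`/`b_in_out` (s^-1), liganded transit
#' `f_out_in`/`f_in_out` (s^-1), second-order association `k_on`
#' ((mmol/L)^-1 s^-1, both faces), dissociation `k_off = KD * k_on` on each
#' face.
#'
#' Defaults are the conventional reference parameterisation: base empty rate
#' 1 s^-1 (the fast, out-to-in direction), liganded transit 10x the base
#' empty rate, association 1000x the base empty rate per mmol/L, and
#' `KD = 3` mmol/L on both faces.
#'
#' With `auto_close = TRUE` the slow empty rate `b_in_out` is derived from
#' the cycle-closure identity (product of clockwise rates = product of
#' anticlockwise rates), so the model satisfies detailed balance by
#' construction:
#' `b_in_out = b_out_in * (f_in_out / f_out_in) * (KD_out / KD_in)`.
#'
#' @param KD_out,KD_in Site dissociation constants, mmol/L.
#' @param b_out_in Empty-carrier transit rate out->in, s^-1.
#' @param b_in_out Empty-carrier transit rate in->out, s^-1, or `NULL` to
#'   derive it from cycle closure (requires `auto_close`).
#' @param f_out_in,f_in_out Liganded transit rates, s^-1.
#' @param k_on Association rate constant, (mmol/L)^-1 s^-1, both faces.
#' @param auto_close Derive/verify `b_in_out` from the detailed-balance cycle
#'   closure.
#' @param total Total carrier amount `C_T` (dimensionless; default 1).
#' @return A `carrier_params` list.
#' @export
carrier_params <- function(KD_out = 3, KD_in = 3,
                           b_out_in = 1, b_in_out = NULL,
                           f_out_in = 10, f_in_out = 10,
                           k_on = 1000, auto_close = TRUE, total = 1) {
  vals <- c(KD_out = KD_out, KD_in = KD_in, b_out_in = b_out_in,
            f_out_in = f_out_in, f_in_out = f_in_out, k_on = k_on)
  if (any(vals <= 0)) abort("all carrier parameters must be positive")
  closed <- b_out_in * (f_in_out / f_out_in) * (KD_out / KD_in)
  if (is.null(b_in_out)) {
    if (!auto_close) abort("b_in_out must be given when auto_close = FALSE")
    b_in_out <- closed
  } else if (auto_close && abs(b_in_out / closed - 1) > 1e-9) {
    abort(sprintf(paste0(
      "auto_close conflict: supplied b_in_out = %g but cycle closure ",
      "b_out_in * (f_in_out/f_out_in) * (KD_out/KD_in) requires %g"),
      b_in_out, closed))
  }
  structure(list(KD_out = KD_out, KD_in = KD_in,
                 b_out_in = b_out_in, b_in_out = b_in_out,
                 f_out_in = f_out_in, f_in_out = f_in_out,
                 k_on = k_on, auto_close = auto_close, total = total),
            class = "carrier_params")
}

.build_carrier <- function(p) {
  states <- bind_rows(
    carrier_state("C_out", "carrier", "outward", NA),
    carrier_state("GC_out", "carrier", "outward", "glucose"),
    carrier_state("GC_in", "carrier", "inward", "glucose"),
    carrier_state("C_in", "carrier", "inward", NA))
  transitions <- bind_rows(
    tr_conformational("C_out", "C_in", p$b_out_in),
    tr_conformational("C_in", "C_out", p$b_in_out),
    tr_conformational("GC_out", "GC_in", p$f_out_in),
    tr_conformational("GC_in", "GC_out", p$f_in_out),
    tr_binding("C_out", "GC_out", p$k_on, "out", "glucose"),
    tr_release("GC_out", "C_out", p$KD_out * p$k_on, "out", "glucose"),
    tr_binding("C_in", "GC_in", p$k_on, "in", "glucose"),
    tr_release("GC_in", "C_in", p$KD_in * p$k_on, "in", "glucose"))
  compartments <- bind_rows(compartment("out", "clamped_bath"),
                            compartment("in", "clamped_bath"))
  m <- transport_network(states, transitions, compartments,
                         ligand_species("glucose"),
                         totals = tibble(group = "carrier", total = p$total),
                         model_kind = "carrier")
  attr(m, "params") <- p
  m
}

#' Build the symmetric four-state carrier
#'
#' Equal dissociation constants and transit rates on both faces; the model
#' trivially satisfies detailed balance and gives identical influx and efflux
#' kinetics.
#'
#' @param params A [carrier_params()]; defaults are the symmetric reference
#'   set (KD 3 mmol/L both faces, liganded transit 10x and association 1000x
#'   the unit empty rate).
#' @return A `transport_network`.
#' @export
build_symmetric_carrier <- function(params = carrier_params()) {
  if (params$KD_out != params$KD_in || params$b_out_in != params$b_in_out ||
      params$f_out_in != params$f_in_out) {
    abort("build_symmetric_carrier needs symmetric parameters; use build_asymmetric_carrier")
  }
  m <- .build_carrier(params)
  attr(m, "builder") <- list(type = "symmetric")
  m
}

#' Build the asymmetric four-state carrier
#'
#' The conventional asymmetric alternating carrier: a high-affinity outside
#' face (default KD 3 mmol/L) and a low-affinity inside face (default KD 30
#' mmol/L). With `auto_close` (the default) the slow empty transit rate is
#' derived from cycle closure, which forces the equal-bath vacant-site
#' distribution `C_in/C_out = KD_in/KD_out` (= 10 at the defaults) and an
#' empty-rate asymmetry `b_out_in/b_in_out` of the same factor.
#'
#' @param params A [carrier_params()]; default asymmetric set
#'   `carrier_params(KD_out = 3, KD_in = 30)`.
#' @return A `transport_network` passing [check_detailed_balance()] when
#'   auto-closed.
#' @export
build_asymmetric_carrier <- function(params = carrier_params(KD_out = 3, KD_in = 30)) {
  m <- .build_carrier(params)
  attr(m, "builder") <- list(type = "asymmetric")
  m
}

#' Parameters of the fixed-site (staged-diffusion) transporter
#'
#' The transporter is an array of fixed binding sites (one dissociation
#' constant per site, presented to both of its faces) separated by diffusive
#' voids; ligand moves bath -> vestibule -> site -> void -> ... -> bath by
#' association/dissociation and void diffusion only, with no translocating
#' carrier states. An optional dual-occupancy central exchange site can hold
#' two ligands (one per slot) and swap them, which is what couples labelled
#' and unlabelled flows in exchange and counterflow protocols.
#'
#' @param site_KD Ordered site dissociation constants, mmol/L, outside
#'   first; default `c(3, 30)` (high-affinity outer, 10x lower-affinity
#'   inner site).
#' @param diffusion_rate Gate/void diffusion rate, s^-1 (each direction);
#'   default 100, fast relative to translocation bottlenecks but finite.
#' @param k_on Site association rate on the vestibule-facing faces,
#'   (mmol/L)^-1 s^-1; default 100. Dissociation on each face is
#'   `KD * k_on(face)` (one KD per site, both faces, so the chain is
#'   detailed-balanced and equilibrates uniformly).
#' @param central_slowdown Factor by which association/dissociation on the
#'   central-facing faces of both sites is slower than on the vestibule
#'   faces (the central bottleneck that rate-limits net transfer between
#'   the sites); default 10.
#' @param branch_rates Association rates ((mmol/L)^-1 s^-1) of the two
#'   parallel access branches between the outside bath and the external
#'   vestibule (branched model only). Each branch is a saturable relay site
#'   (KD `branch_KD`, throughput ceiling `branch_KD * rate` per direction):
#'   what a mutation occludes is a glucose-docking site at the tunnel
#'   opening, and only a saturable exit can produce the efflux tailback.
#'   Defaults give a per-branch ceiling of 150 s^-1 — well above the
#'   central-bottleneck influx ceiling but below the unconstrained efflux
#'   ceiling — with fast association, so low-concentration kinetics are
#'   branch-insensitive while net exit saturates under load: the regime in
#'   which blocking one branch selectively throttles efflux.
#' @param exchange_site Add associative-exchange steps at the central faces
#'   of both sites: the bound ligand swaps with a free ligand from the
#'   central void in one fast bilinear step, so labelled/unlabelled exchange
#'   bypasses the slow net dissociation. Requires (and implies) a
#'   two-species build.
#' @param branch_KD Branch relay-site dissociation constant, mmol/L
#'   (default 3, matching the outer transport site).
#' @param exchange_rate Associative exchange rate, (mmol/L)^-1 s^-1.
#' @param void_volume Nominal void volume (litre-equivalents) for time
#'   courses.
#' @param total Amount of each site (dimensionless).
#' @return A `multisite_params` list.
#' @export
multisite_params <- function(site_KD = c(3, 30), diffusion_rate = 100,
                             k_on = 100, central_slowdown = 10,
                             branch_rates = c(50, 50), branch_KD = 3,
                             exchange_site = FALSE, exchange_rate = 100,
                             void_volume = 0.01, total = 1) {
  if (length(site_KD) < 2) abort("at least 2 binding sites are required")
  if (any(site_KD <= 0) || diffusion_rate <= 0 || k_on <= 0 ||
      central_slowdown <= 0 || exchange_rate <= 0 || branch_KD <= 0) {
    abort("site KDs and rates must be positive")
  }
  if (any(branch_rates < 0)) abort("branch rates must be >= 0 (0 = blocked)")
  structure(list(site_KD = site_KD, diffusion_rate = diffusion_rate,
                 k_on = k_on, central_slowdown = central_slowdown,
                 branch_rates = branch_rates, branch_KD = branch_KD,
                 exchange_site = exchange_site, exchange_rate = exchange_rate,
                 void_volume = void_volume, total = total),
            class = "multisite_params")
}

# Single-occupancy site block: empty state + one liganded state per species,
# binding/release towards the void on each side with the same KD (per-face
# association rates may differ; dissociation is KD * k_on(face), which keeps
# every face edge individually balanced at a uniform concentration).
# `exchange_right` > 0 adds associative-exchange steps towards the right
# void: the bound ligand swaps with a free one in a single bilinear step.
.site_block <- function(name, KD, void_left, void_right, k_on_left, k_on_right,
                        species, total, exchange_right = 0) {
  empty <- carrier_state(paste0(name, "_e"), name, name, NA)
  states <- empty
  transitions <- NULL
  for (sp in species) {
    occ_id <- paste0(name, "_", sp)
    states <- bind_rows(states, carrier_state(occ_id, name, name, sp))
    transitions <- bind_rows(
      transitions,
      tr_binding(empty$id, occ_id, k_on_left, void_left, sp),
      tr_release(occ_id, empty$id, KD * k_on_left, void_left, sp),
      tr_binding(empty$id, occ_id, k_on_right, void_right, sp),
      tr_release(occ_id, empty$id, KD * k_on_right, void_right, sp))
  }
  if (exchange_right > 0 && length(species) > 1) {
    prs <- utils::combn(species, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      transitions <- bind_rows(
        transitions,
        tr_exchange(paste0(name, "_", a), paste0(name, "_", b),
                    exchange_right, void_right, species_in = b, species_out = a),
        tr_exchange(paste0(name, "_", b), paste0(name, "_", a),
                    exchange_right, void_right, species_in = a, species_out = b))
    }
  }
  list(states = states, transitions = transitions,
       total = tibble(group = name, total = total))
}

.build_multisite <- function(p, branch_rates = NULL, species = "glucose",
                             isotope_class = "sugar") {
  if (length(p$site_KD) != 2) {
    abort("the packaged multisite topology uses 2 sites; extend site_KD support before use")
  }
  if (p$exchange_site && length(species) < 2) {
    species <- c("glucose", "glucose_lab")
  }
  sp_tbl <- tibble(name = species, isotope_class = isotope_class)
  voids <- c("vest_out", "central", "vest_in")
  compartments <- bind_rows(
    compartment("out", "clamped_bath"),
    purrr::map(voids, ~ compartment(.x, "internal_void", p$void_volume)),
    compartment("in", "clamped_bath"))

  ex <- if (p$exchange_site) p$exchange_rate else 0
  k_on_c <- p$k_on / p$central_slowdown
  s1 <- .site_block("site_out", p$site_KD[1], "vest_out", "central",
                    k_on_left = p$k_on, k_on_right = k_on_c,
                    species, p$total, exchange_right = ex)
  # the inner site's central face is its left side; reuse the block with
  # voids swapped so the slow face points at the central void
  s2 <- .site_block("site_in", p$site_KD[2], "vest_in", "central",
                    k_on_left = p$k_on, k_on_right = k_on_c,
                    species, p$total, exchange_right = ex)
  blocks <- list(s1, s2)

  diff_tr <- NULL
  for (sp in species) {
    if (is.null(branch_rates)) {
      diff_tr <- bind_rows(diff_tr,
                           tr_diffusion("out", "vest_out", p$diffusion_rate, sp),
                           tr_diffusion("vest_out", "out", p$diffusion_rate, sp))
    }
    diff_tr <- bind_rows(diff_tr,
                         tr_diffusion("vest_in", "in", p$diffusion_rate, sp),
                         tr_diffusion("in", "vest_in", p$diffusion_rate, sp))
  }
  if (!is.null(branch_rates)) {
    # each open branch is a saturable low-affinity relay site between the
    # outside bath and the external vestibule
    for (b in which(branch_rates > 0)) {
      blocks <- append(blocks, list(
        .site_block(paste0("branch", b), p$branch_KD, "out", "vest_out",
                    k_on_left = branch_rates[b], k_on_right = branch_rates[b],
                    species, p$total)))
    }
  }

  m <- transport_network(
    states = bind_rows(purrr::map(blocks, "states")),
    transitions = bind_rows(bind_rows(purrr::map(blocks, "transitions")), diff_tr),
    compartments = compartments,
    species = sp_tbl,
    totals = bind_rows(purrr::map(blocks, "total")),
    model_kind = "multisite")
  attr(m, "params") <- p
  m
}

#' Build the fixed-site staged-diffusion chain
#'
#' Default topology: outside bath, external vestibule, high-affinity outer
#' site (KD 3 mmol/L), central void, low-affinity inner site (KD 30 mmol/L),
#' internal vestibule, inside bath. The central-facing faces of both sites
#' are slowed by `central_slowdown`, making net transfer between the sites
#' the rate-limiting "chicane"; with `exchange_site = TRUE` associative
#' exchange steps at those faces let isotopes swap across the bottleneck
#' without net dissociation (see [multisite_params()]).
#'
#' Each site presents the same dissociation constant to both adjacent voids,
#' so the chain is detailed-balanced for any positive rate assignment and, at
#' equal bath concentrations, every void equilibrates exactly at the bath
#' concentration.
#'
#' @param params A [multisite_params()].
#' @param n_species Build with this many kinetically identical species (all
#'   in one isotope class); use 2 for explicit labelled/unlabelled work with
#'   the exchange site.
#' @return A `transport_network`.
#' @export
build_multisite_chain <- function(params = multisite_params(), n_species = 1) {
  species <- if (n_species == 1) "glucose" else c("glucose", "glucose_lab")
  m <- .build_multisite(params, branch_rates = NULL, species = species)
  attr(m, "builder") <- list(type = "multisite", n_species = n_species)
  m
}

#' Build the branched fixed-site model (two parallel external access branches)
#'
#' Adds two parallel diffusion branches between the outside bath and the
#' external vestibule to the staged-diffusion chain. Blocking the right
#' branch removes that branch's transitions entirely, modelling a mutation
#' that occludes one of the two access tunnels; the remaining topology is
#' still a valid passive network.
#'
#' @param block_right_branch If `TRUE`, the second branch's rates are
#'   blocked.
#' @param params A [multisite_params()]; `branch_rates` gives the two branch
#'   rates.
#' @param n_species As in [build_multisite_chain()].
#' @return A `transport_network`.
#' @export
build_branched_multisite <- function(block_right_branch = FALSE,
                                     params = multisite_params(),
                                     n_species = 1) {
  br <- params$branch_rates
  if (length(br) != 2) abort("branch_rates must have length 2")
  if (block_right_branch) br[2] <- 0
  species <- if (n_species == 1) "glucose" else c("glucose", "glucose_lab")
  m <- .build_multisite(params, branch_rates = br, species = species)
  attr(m, "builder") <- list(type = "branched", n_species = n_species,
                             block_right_branch = block_right_branch)
  m
}

#' Arrhenius temperature scaling of a rate constant
#'
#' `rate(T) = rate(T_ref) * exp(-Ea/R * (1/T - 1/T_ref))`. Applying a lower
#' activation energy to exchange-path rates (liganded transit, slot swap)
#' than to dissociation/empty-transit rates makes the exchange-to-net flux
#' ratio grow as the temperature falls.
#'
#' @param rate Rate constant at `T_ref` (s^-1 or (mmol/L)^-1 s^-1).
#' @param Ea Activation energy, kJ/mol.
#' @param T_K Target temperature, K.
#' @param T_ref Reference temperature, K (default 303.15).
#' @return Scaled rate constant at `T_K`.
#' @export
arrhenius_scale <- function(rate, Ea, T_K, T_ref = .T_DEFAULT) {
  if (any(T_K <= 0) || any(T_ref <= 0)) abort("temperatures must be positive (K)")
  rate * exp(-Ea * 1000 / .R_GAS * (1 / T_K - 1 / T_ref))
}
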