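# Shared fixtures: all built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random bath-only network: n states in one conservation group, a
# conformational ring (guaranteeing strong connectivity) plus random chords,
# and binding/release pairs linking two states to the clamped baths.
random_bath_network <- function(n_states = 6, seed = 1) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n_states))
  states <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    carrier_state(ids[i], "carrier",
                  location = if (i <= n_states / 2) "outward" else "inward",
                  occupant = if (i %% 2 == 0) "glucose" else NA_character_)
  }))
  r <- function() rlnorm(1, log(5), 1)
  tr <- NULL
  for (i in seq_along(ids)) {
    j <- if (i == n_states) 1 else i + 1
    tr <- dplyr::bind_rows(tr,
                           portersim:::tr_conformational(ids[i], ids[j], r()),
                           portersim:::tr_conformational(ids[j], ids[i], r()))
  }
  # one chord across the ring
  tr <- dplyr::bind_rows(tr,
                         portersim:::tr_conformational(ids[1], ids[4], r()),
                         portersim:::tr_conformational(ids[4], ids[1], r()))
  # ligand coupling: empty state 1 binds from "out", empty state 3 from "in"
  tr <- dplyr::bind_rows(
    tr,
    portersim:::tr_binding(ids[1], ids[2], r(), "out", "glucose"),
    portersim:::tr_release(ids[2], ids[1], r(), "out", "glucose"),
    portersim:::tr_binding(ids[3], ids[4], r(), "in", "glucose"),
    portersim:::tr_release(ids[4], ids[3], r(), "in", "glucose"))
  transport_network(
    states, tr,
    dplyr::bind_rows(compartment("out", "clamped_bath"),
                     compartment("in", "clamped_bath")),
    ligand_species("glucose"), model_kind = "carrier")
}

# Random detailed-balance-enforced asymmetric carrier.
random_closed_carrier <- function(seed = 1) {
  set.seed(seed)
  carrier_params(KD_out = rlnorm(1, log(3), 0.5),
                 KD_in = rlnorm(1, log(30), 0.5),
                 b_out_in = rlnorm(1, 0, 0.5),
                 f_out_in = rlnorm(1, log(10), 0.5),
                 f_in_out = rlnorm(1, log(10), 0.5),
                 k_on = 1000, auto_close = TRUE)
}

occ_vec <- function(ss) setNames(ss$occupancy$occupancy, ss$occupancy$state)

# Rapid-equilibrium closed forms for the four-state carrier (binding assumed
# equilibrated): the independent algebraic oracle for protocol outputs.
re_carrier_oracle <- function(p) {
  r <- p$b_out_in / p$b_in_out           # C_in/C_out at equilibrium
  phi_o <- p$f_out_in / p$b_in_out
  list(
    km_zt_influx = p$KD_out * (p$b_in_out + p$b_out_in) / (p$b_in_out + p$f_out_in),
    vm_zt_influx = p$f_out_in * p$b_in_out / (p$b_in_out + p$f_out_in),
    km_zt_efflux = p$KD_in * (p$b_in_out + p$b_out_in) / (p$b_out_in + p$f_in_out),
    vm_zt_efflux = p$f_in_out * p$b_out_in / (p$b_out_in + p$f_in_out),
    km_ee = p$KD_out * p$KD_in * (1 + r) / (p$KD_in + r * p$KD_out),
    vm_ee = p$f_out_in * p$KD_in / (p$KD_in + r * p$KD_out))
}
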