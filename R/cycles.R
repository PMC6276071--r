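# Cycle analysis and the detailed-balance (Wegscheider) condition: around
# any closed transport cycle the product of forward rate constants must equal
# the product of the reverse rate constants, with second-order association
# steps entered at a reference ligand concentration. For cycles that bind and
# release in the same compartments the reference cancels; the equal-bath
# reference of 1 mmol/L makes the remaining cases the equilibrium the
# condition speaks about.

# Undirected support multigraph: one edge per reversible transition pair.
# Conformational and binding/release edges connect carrier states;
# void-diffusion edges connect compartments.
.support_edges <- function(model) {
  tr <- model$transitions
  canon <- tr[tr$id < tr$pair, ]
  ep_from <- canon$from
  ep_to <- canon$to
  tibble(from = ep_from, to = ep_to, tid = canon$id, pid = canon$pair,
         kind = canon$kind, compartment = canon$compartment,
         species = canon$species, rate_fwd = canon$rate,
         rate_rev = tr$rate[match(canon$pair, tr$id)])
}

# Directed rate of an edge traversed forward (from -> to) or backward, with
# association steps entered at the reference concentration.
.edge_rate <- function(e, forward, ref_conc) {
  k <- if (forward) e$rate_fwd else e$rate_rev
  kind <- if (forward) e$kind else
    c(conformational = "conformational", binding = "release",
      release = "binding", void_diffusion = "void_diffusion",
      exchange = "exchange")[[e$kind]]
  # second-order steps (association, associative exchange) enter at the
  # reference concentration
  if (kind %in% c("binding", "exchange")) k <- k * ref_conc
  k
}

#' Enumerate an independent cycle basis of a transport network
#'
#' Builds the undirected support multigraph (states joined by
#' conformational/binding edges, compartments by diffusion edges), takes a
#' spanning forest, and returns one fundamental cycle per non-forest edge.
#' The basis size is `E - V + C` (edges, vertices, connected components).
#' For each cycle the clockwise and anticlockwise rate-constant products are
#' evaluated with association steps at `ref_conc`.
#'
#' @param model A `transport_network`.
#' @param ref_conc Reference concentration, mmol/L, applied to second-order
#'   association steps (default 1).
#' @return A tibble with one row per basis cycle: `cycle`, `length`,
#'   `vertices` and `transitions` (list-columns of the closed walk),
#'   `forward_product`, `reverse_product`, `ratio`. Zero rows when the
#'   network is acyclic.
#' @export
enumerate_cycles <- function(model, ref_conc = 1) {
  ed <- .support_edges(model)
  verts <- unique(c(model$states$id, model$compartments$name))
  g <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::E(g)$row <- seq_len(nrow(ed))
  forest <- igraph::mst(g)
  in_forest <- rep(FALSE, nrow(ed))
  in_forest[igraph::E(forest)$row] <- TRUE

  out <- list()
  for (r in which(!in_forest)) {
    u <- ed$from[r]; v <- ed$to[r]
    sp <- igraph::shortest_paths(forest, from = v, to = u, output = "both")
    pverts <- names(sp$vpath[[1]])
    prows <- igraph::E(forest)$row[as.integer(sp$epath[[1]])]
    walk_rows <- c(r, prows)
    walk_verts <- c(u, pverts) # u -> v -> ... -> u
    fwd <- rev <- 1
    tids <- integer(0)
    for (k in seq_along(walk_rows)) {
      e <- ed[walk_rows[k], ]
      forward <- identical(e$from, walk_verts[k])
      fwd <- fwd * .edge_rate(e, forward, ref_conc)
      rev <- rev * .edge_rate(e, !forward, ref_conc)
      tids <- c(tids, if (forward) e$tid else e$pid)
    }
    out[[length(out) + 1]] <- tibble(
      cycle = length(out) + 1L, length = length(walk_rows),
      vertices = list(c(walk_verts, u)), transitions = list(tids),
      forward_product = fwd, reverse_product = rev, ratio = fwd / rev)
  }
  if (!length(out)) {
    return(tibble(cycle = integer(), length = integer(),
                  vertices = list(), transitions = list(),
                  forward_product = numeric(), reverse_product = numeric(),
                  ratio = numeric()))
  }
  bind_rows(out)
}

#' Check detailed balance of a transport network
#'
#' A passive transport network is thermodynamically consistent iff every
#' cycle's forward and reverse rate products are equal; it suffices to check
#' an independent cycle basis, since any cycle ratio is a product of basis
#' ratios.
#'
#' @param model A `transport_network` (every transition must have a reverse
#'   partner; validation enforces this).
#' @param tolerance Relative tolerance on `|ratio - 1|`.
#' @param ref_conc Reference concentration for association steps, mmol/L.
#' @return A `cycle_report`: tibble of basis cycles (see
#'   [enumerate_cycles()]), `tolerance`, and `passed` (all ratios within
#'   tolerance of 1).
#' @export
check_detailed_balance <- function(model, tolerance = 1e-9, ref_conc = 1) {
  cyc <- enumerate_cycles(model, ref_conc)
  passed <- nrow(cyc) == 0 || all(abs(cyc$ratio - 1) <= tolerance)
  structure(list(cycles = cyc, tolerance = tolerance, passed = passed),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle_report> %d basis cycle(s), tolerance %.1g: %s\n",
              nrow(x$cycles), x$tolerance,
              if (x$passed) "PASSED" else "FAILED"))
  if (nrow(x$cycles)) {
    print(x$cycles[, c("cycle", "length", "forward_product",
                       "reverse_product", "ratio")])
  }
  invisible(x)
}

#' @export
tidy.cycle_report <- function(x, ...) {
  x$cycles[, c("cycle", "length", "forward_product", "reverse_product", "ratio")]
}
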