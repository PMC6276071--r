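test_that("network validation enforces referential integrity and reversibility", {
  st <- dplyr::bind_rows(carrier_state("A", "g"), carrier_state("B", "g"))
  cp <- compartment("out", "clamped_bath")
  sp <- ligand_species("glucose")

  # missing reverse partner
  tr <- portersim:::tr_conformational("A", "B", 1)
  expect_error(transport_network(st, tr, cp, sp), "reverse partner")

  # unknown state
  tr2 <- dplyr::bind_rows(portersim:::tr_conformational("A", "Z", 1),
                          portersim:::tr_conformational("Z", "A", 1))
  expect_error(transport_network(st, tr2, cp, sp), "unknown state")

  # non-positive rate
  tr3 <- dplyr::bind_rows(portersim:::tr_conformational("A", "B", 0),
                          portersim:::tr_conformational("B", "A", 1))
  expect_error(transport_network(st, tr3, cp, sp), "positive")

  # duplicate transition
  tr4 <- dplyr::bind_rows(portersim:::tr_conformational("A", "B", 1),
                          portersim:::tr_conformational("A", "B", 2),
                          portersim:::tr_conformational("B", "A", 1))
  expect_error(transport_network(st, tr4, cp, sp), "duplicated")

  # disconnected group
  st3 <- dplyr::bind_rows(st, carrier_state("C", "g"))
  tr5 <- dplyr::bind_rows(portersim:::tr_conformational("A", "B", 1),
                          portersim:::tr_conformational("B", "A", 1))
  expect_error(transport_network(st3, tr5, cp, sp), "strongly connected")
})

test_that("clamps are checked against compartment kinds and names", {
  m <- build_symmetric_carrier()
  expect_error(solve_steady_state(m, clamps = list(nowhere = 1)), "unknown compartment")
  mf <- with_finite_inside(m)
  expect_error(solve_steady_state(mf, clamps = list(`in` = 1)), "not a clamped bath")
  expect_error(solve_steady_state(m, clamps = list(out = -1)), "non-negative")
})

test_that("tracer expansion duplicates liganded states with identical rates", {
  m <- build_symmetric_carrier()
  m2 <- expand_tracer(m, labelled_fraction = 1e-3, cis = "out")
  expect_equal(nrow(m2$states), 6) # two liganded states duplicated
  expect_equal(nrow(m2$species), 2)
  expect_equal(unique(m2$species$isotope_class), "glucose")

  # every labelled edge has an unlabelled twin with the same rate constant
  lab <- labelled_species(m2)
  tw <- m2$transitions
  base_key <- function(tr) paste(tr$kind, sub("\\*$", "", tr$from),
                                 sub("\\*$", "", tr$to), tr$compartment)
  labelled_rows <- tw[grepl("\\*$", tw$from) | grepl("\\*$", tw$to) |
                        (!is.na(tw$species) & tw$species %in% lab), ]
  for (i in seq_len(nrow(labelled_rows))) {
    twin <- tw[base_key(tw) == base_key(labelled_rows[i, ]) &
                 tw$id != labelled_rows$id[i], ]
    expect_true(any(twin$rate == labelled_rows$rate[i]))
  }

  # cis bath split preserves the total
  cc <- portersim:::.conc_matrix(m2)
  expect_equal(sum(cc["out", ]), portersim:::.conc_matrix(m)["out", "glucose"])

  expect_error(expand_tracer(m, 0, "out"), "labelled_fraction")
  expect_error(expand_tracer(m, 1.5, "out"), "labelled_fraction")
  mx <- build_multisite_chain(multisite_params(exchange_site = TRUE))
  expect_error(expand_tracer(mx, 1e-6, "out"), "exchange")
})
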