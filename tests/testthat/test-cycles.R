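test_that("cycle basis size follows E - V + C for the packaged topologies", {
  expect_equal(nrow(enumerate_cycles(build_symmetric_carrier())), 1)
  # each fixed site sits between two voids: one two-edge cycle per site
  expect_equal(nrow(enumerate_cycles(build_multisite_chain())), 2)
  # each open saturable branch adds one more site loop
  expect_equal(nrow(enumerate_cycles(build_branched_multisite(FALSE))), 4)
  expect_equal(nrow(enumerate_cycles(build_branched_multisite(TRUE))), 3)
})

test_that("an acyclic conformational chain has an empty cycle basis", {
  st <- dplyr::bind_rows(carrier_state("A", "g"), carrier_state("B", "g"),
                         carrier_state("C", "g"))
  tr <- dplyr::bind_rows(portersim:::tr_conformational("A", "B", 1),
                         portersim:::tr_conformational("B", "A", 2),
                         portersim:::tr_conformational("B", "C", 3),
                         portersim:::tr_conformational("C", "B", 4))
  m <- transport_network(st, tr, compartment("out", "clamped_bath"),
                         ligand_species("glucose"))
  cyc <- enumerate_cycles(m)
  expect_equal(nrow(cyc), 0)
  expect_true(check_detailed_balance(m)$passed)
})

test_that("the auto-closed asymmetric carrier cycle multiplies out to equal products", {
  m <- build_asymmetric_carrier() # KD 3/30, b 1/0.1, f 10/10, k_on 1000
  cyc <- enumerate_cycles(m)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$length, 4)
  # association 1000 (at 1 mmol/L) * liganded transit 10 * dissociation
  # 30000 * empty return 0.1, against the anticlockwise 1000*10*3000*1
  expect_equal(sort(c(cyc$forward_product, cyc$reverse_product)),
               c(3e7, 3e7))
  expect_equal(cyc$ratio, 1, tolerance = 1e-12)
  expect_true(check_detailed_balance(m, tolerance = 1e-12)$passed)
})

test_that("tampering with a single rate is flagged with the expected cycle ratio", {
  m <- build_asymmetric_carrier()
  i <- which(m$transitions$kind == "conformational" &
               m$transitions$from == "GC_out")
  m$transitions$rate[i] <- 2 * m$transitions$rate[i]
  rep <- check_detailed_balance(m)
  expect_false(rep$passed)
  r <- rep$cycles$ratio
  expect_equal(max(r, 1 / r), 2, tolerance = 1e-12) # orientation-free

})

test_that("auto-closed builders pass detailed balance for random parameter draws", {
  for (s in 1:10) {
    m <- build_asymmetric_carrier(random_closed_carrier(s))
    expect_true(check_detailed_balance(m, tolerance = 1e-12)$passed)
  }
  for (s in 1:5) {
    set.seed(100 + s)
    p <- multisite_params(site_KD = rlnorm(2, log(10), 1),
                          diffusion_rate = rlnorm(1, log(100), 0.5),
                          k_on = rlnorm(1, log(100), 0.5),
                          central_slowdown = rlnorm(1, log(10), 0.3))
    expect_true(check_detailed_balance(build_multisite_chain(p))$passed)
  }
})

test_that("composite cycles inherit balance from the basis", {
  # two independent loops sharing an edge: walk the outer (non-basis) loop
  # by hand and check its ratio is the product of the basis ratios
  m <- build_branched_multisite(FALSE)
  cyc <- enumerate_cycles(m)
  expect_true(all(abs(cyc$ratio - 1) < 1e-12))
  tr <- m$transitions
  # outer walk: branch1 out-face up, branch1 vest-face down,
  # branch2 vest-face up, branch2 out-face down
  pick <- function(from, to, comp) {
    tr[tr$from == from & tr$to == to & !is.na(tr$compartment) &
         tr$compartment == comp, ]
  }
  walk <- dplyr::bind_rows(
    pick("branch1_e", "branch1_glucose", "out"),
    pick("branch1_glucose", "branch1_e", "vest_out"),
    pick("branch2_e", "branch2_glucose", "vest_out"),
    pick("branch2_glucose", "branch2_e", "out"))
  fwd <- prod(ifelse(walk$kind == "binding", walk$rate * 1, walk$rate))
  rev_rows <- tr[walk$pair, ]
  rev <- prod(ifelse(rev_rows$kind == "binding", rev_rows$rate * 1, rev_rows$rate))
  expect_equal(fwd / rev, 1, tolerance = 1e-12)
})
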