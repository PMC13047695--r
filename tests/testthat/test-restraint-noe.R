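test_that("atomistic-to-CG distance mapping follows the vector formula", {
  # atoms sitting on their beads: D collapses to d_ij
  a1 <- c(0, 0, 0); a2 <- c(1, 0, 0)
  expect_equal(map_atom_pair(a1, a2, a1, a2, 1.0), 1.0)
  expect_equal(map_atom_pair(a1, a2, a1, a2, 0.37), 0.37)
  set.seed(40)
  for (i in 1:50) {
    A1 <- rnorm(3); A2 <- rnorm(3); x1 <- rnorm(3); x2 <- rnorm(3)
    d <- runif(1, 0.1, 1)
    u <- (x2 - x1) / sqrt(sum((x2 - x1)^2))
    oracle <- sqrt(sum(((x1 - A1) + d * u + (A2 - x2))^2))
    expect_equal(map_atom_pair(A1, A2, x1, x2, d), oracle, tolerance = 1e-12)
  }
  expect_error(map_atom_pair(a1, a2, a1, a1, 0.5), "coincident")
})

test_that("r^-6 condensation weights the mapped distances", {
  expect_equal(condense_group(c(1.5, 1.5, 1.5), c(0.3, 0.5, 0.2)), 1.5)
  # printed two-contributor example, by hand
  hand <- (1.0 * 0.2^-6 + 2.0 * 0.4^-6) / (0.2^-6 + 0.4^-6)
  expect_equal(condense_group(c(1.0, 2.0), c(0.2, 0.4)), hand)
  # the shorter atomistic distance dominates in the limit
  expect_equal(condense_group(c(1.0, 2.0), c(1e-4, 0.4)), 1.0, tolerance = 1e-8)
  expect_error(condense_group(c(1), c(0)), "zero")
})

test_that("apparent distance is the -6 power mean", {
  expect_equal(apparent_distance(0.7), 0.7)
  expect_equal(apparent_distance(c(0.7, 0.7)), 0.7 * 2^(-1 / 6))
  set.seed(41)
  for (i in 1:1000) {
    d <- runif(sample(1:6, 1), 0.1, 2)
    expect_lte(apparent_distance(d), min(d) + 1e-12)
  }
  expect_error(apparent_distance(numeric(0)), "empty")
})

test_that("bead-pair aggregation is the arithmetic mean", {
  expect_equal(aggregate_bead_pair(0.8), 0.8)
  expect_equal(aggregate_bead_pair(c(1.0, 2.0)), 1.5)
  set.seed(42)
  x <- runif(7)
  expect_equal(aggregate_bead_pair(x), sum(x) / 7)
})

test_that("conflict filtering drops contributors beyond d + slack", {
  target <- tiny_peptide(8, seed = 43)
  pa <- pseudo_atomistic(target)
  # one record with two i-side atoms: BB (at distance d) and SC1 (far)
  bbi <- cgnmr:::cg_bead_index(target, 1, "BB")
  bbj <- cgnmr:::cg_bead_index(target, 6, "BB")
  d_true <- sqrt(sum((target$coords[bbj, ] - target$coords[bbi, ])^2))
  noe <- data.frame(chain_i = "A", resid_i = 1, atoms_i = "BB|SC1",
                    chain_j = "A", resid_j = 6, atoms_j = "BB",
                    d = d_true - 0.45, r0 = 0, r1 = d_true, r2 = d_true + 0.5)
  class(noe) <- c("noe_table", "data.frame")
  out <- filter_conflicts(noe, pa$atomistic, slack = 0.2)
  # the BB contributor sits 0.45 nm over the reported d (> slack) -> dropped
  expect_equal(out$report$contributors_in, 2)
  expect_lt(out$report$contributors_out, 2)
  if (nrow(out$noe) > 0) expect_false(grepl("BB", out$noe$atoms_i))
  # widening the slack keeps everything
  all_in <- filter_conflicts(noe, pa$atomistic, slack = 10)
  expect_equal(all_in$report$contributors_out, 2)
  expect_equal(all_in$noe$atoms_i, "BB|SC1")
  # shrinking d so every contributor conflicts drops the record
  noe2 <- noe; noe2$d <- 0.01
  none <- filter_conflicts(noe2, pa$atomistic, slack = 0.01)
  expect_equal(nrow(none$noe), 0)
})

test_that("the full mapping pipeline is exact on the identity case", {
  target <- tiny_peptide(8, seed = 44)
  pa <- pseudo_atomistic(target)
  noe <- synth_noe_table(target, 6, bound_width = 0.05, seed = 45)
  rst <- build_cg_restraints(pa$atomistic, pa$mapping, target, noe, k_noe = 25)
  direct <- noe_table_to_restraints(target, noe, k_noe = 25)
  # identity mapping: same bead pairs, same bounds as the atomistic record
  ord <- order(rst$bead_i, rst$bead_j)
  ord2 <- order(direct$bead_i, direct$bead_j)
  expect_equal(rst$bead_i[ord], direct$bead_i[ord2])
  expect_equal(rst$r1[ord], direct$r1[ord2], tolerance = 1e-10)
  expect_equal(rst$r2[ord], direct$r2[ord2], tolerance = 1e-10)
  # restraints built from the structure's own geometry cost zero energy there
  prov <- noe_restraint_provider(rst)
  expect_equal(prov$eval(target$coords, 0)$energy, 0)
})

test_that("records sharing a bead pair condense into one restraint", {
  target <- tiny_peptide(8, seed = 46)
  pa <- pseudo_atomistic(target)
  noe1 <- synth_noe_table(target, 4, seed = 47)
  noe <- rbind(noe1, noe1[1, ])  # duplicate record on the same pair
  class(noe) <- c("noe_table", "data.frame")
  rst <- build_cg_restraints(pa$atomistic, pa$mapping, target, noe, k_noe = 25)
  expect_equal(nrow(rst), length(unique(paste(rst$bead_i, rst$bead_j))))
  expect_equal(nrow(rst), nrow(noe1))
})

test_that("the piecewise restraint potential is continuous, C1 and capped", {
  r <- list(r0 = 0.3, r1 = 0.5, r2 = 1.0, k_noe = 100)
  # flat bottom
  expect_equal(noe_energy(0.4, r), 0)
  expect_equal(noe_energy(0.3, r), 0)
  # harmonic below r0 and on [r1, r2)
  expect_equal(noe_energy(0.2, r), 0.5 * 100 * 0.1^2)
  expect_equal(noe_energy(0.7, r), 0.5 * 100 * 0.2^2)
  # continuity and C1-ness at all three knots
  for (knot in c(0.3, 0.5, 1.0)) {
    e <- noe_energy(knot + c(-1e-12, 1e-12), r)
    expect_lt(abs(diff(e)), 1e-9)
    slopes <- diff(noe_energy(knot + c(-2e-6, 0, 2e-6), r)) / 2e-6
    expect_lt(abs(diff(slopes)), 1e-3)
  }
  # both branch formulas agree at r2
  expect_equal(0.5 * r$k_noe * (r$r2 - r$r1)^2,
               0.5 * r$k_noe * (r$r2 - r$r1) * (2 * r$r2 - r$r2 - r$r1))
  # constant slope K (r2 - r1) beyond r2
  slope <- (noe_energy(1.6, r) - noe_energy(1.2, r)) / 0.4
  expect_equal(slope, 100 * (1.0 - 0.5))
  expect_equal(noe_force_scalar(2.5, r), -100 * 0.5)
})

test_that("instantaneous NOE forces obey -grad V and Newton's third law", {
  target <- tiny_peptide(8, seed = 48)
  rst <- noe_table_to_restraints(target, synth_noe_table(target, 6, seed = 49),
                                 k_noe = 150)
  prov <- noe_restraint_provider(rst)
  set.seed(50)
  coords <- target$coords + matrix(rnorm(length(target$coords), sd = 0.15),
                                   nrow(target$coords))
  expect_lt(provider_force_fd_error(prov, coords), 1e-4)
  F <- prov$eval(coords, 0)$forces
  expect_lt(max(abs(colSums(F))), 1e-10)
})

test_that("time averaging follows the r^-3 exponential recursion", {
  rst <- list(r0 = 0.2, r1 = 0.5, r2 = 1.0, k_noe = 80)
  st <- noe_timeavg_state(0.9, tau = 0.05, ramp_tau = 0.05)
  # direct recursion check for one step
  out <- noe_timeavg_force(st, 0.7, dt = 0.01, rst)
  w <- exp(-0.01 / 0.05)
  expect_equal(out$state$rbar, (w * 0.9^-3 + (1 - w) * 0.7^-3)^(-1 / 3),
               tolerance = 1e-14)
  expect_equal(out$k_t, 80 * (1 - exp(-0.01 / 0.05)))

  # a perturbed running average re-converges to a constant r within 1e-6
  # after 10 tau (the stated init rule rbar(0) = r keeps it exact throughout)
  st <- noe_timeavg_state(0.62 * 1.02, tau = 0.05)
  r <- 0.62
  for (i in 1:50) {  # 50 steps x 0.01 ps = 10 tau
    out <- noe_timeavg_force(st, r, dt = 0.01, rst)
    st <- out$state
  }
  expect_lt(abs(st$rbar - r), 1e-6)

  # mixed violation gives zero force ("otherwise" branch)
  st2 <- noe_timeavg_state(0.9, tau = 1e6)  # rbar pinned high
  out2 <- noe_timeavg_force(st2, 0.1, dt = 0.01, rst)  # r < r0 but rbar > r1
  expect_equal(out2$force, 0)

  # memoryless limit reduces to the instantaneous force
  for (r in c(0.15, 0.4, 0.7, 1.3)) {
    st3 <- noe_timeavg_state(0.9, tau = 1e-9, ramp_tau = 1e-9)
    out3 <- noe_timeavg_force(st3, r, dt = 0.01, rst)
    expect_equal(out3$force, noe_force_scalar(r, rst), tolerance = 1e-6)
  }
  # the literal product cap mode is available
  st4 <- noe_timeavg_state(0.9, tau = 1e-9, ramp_tau = 1e-9)
  out4 <- noe_timeavg_force(st4, 0.7, dt = 0.01, rst, cap_mode = "product")
  expect_equal(out4$force, -80 * min((0.7 - 0.5)^2, 0.5), tolerance = 1e-6)
})

test_that("monotonicity: shrinking a contributor never raises the apparent distance", {
  set.seed(51)
  for (i in 1:50) {
    d <- runif(4, 0.2, 1.5)
    k <- sample(4, 1)
    d2 <- d; d2[k] <- d2[k] * runif(1, 0.2, 0.99)
    expect_lte(apparent_distance(d2), apparent_distance(d) + 1e-12)
  }
})
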