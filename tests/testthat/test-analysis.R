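test_that("coordinate RMSD is zero after superposition of rigid copies", {
  s <- tiny_peptide(6, seed = 80)
  expect_equal(rmsd_coords(list(s$coords), s$coords), 0, tolerance = 1e-10)
  moved <- random_rigid_transform(s$coords, seed = 81)
  expect_equal(rmsd_coords(list(moved), s$coords), 0, tolerance = 1e-8)
  # known uniform displacement without rotation: pre-alignment oracle
  shifted <- s$coords + matrix(rep(c(0.1, 0, 0), each = nrow(s$coords)), ncol = 3)
  pre <- sqrt(mean(rowSums((shifted - s$coords)^2)))
  expect_equal(pre, 0.1)  # the hand value before alignment
  # after alignment a pure translation also vanishes
  expect_equal(rmsd_coords(list(shifted), s$coords), 0, tolerance = 1e-10)
  expect_error(rmsd_coords(list(s$coords), s$coords, selection = 1:2), "3 beads")
})

test_that("RMSF matches a two-pass variance oracle", {
  s <- tiny_peptide(4, seed = 82)
  static <- trajectory(s, list(s$coords, s$coords, s$coords))
  expect_equal(max(rmsf(static)), 0, tolerance = 1e-10)
  expect_error(rmsf(trajectory(s, list(s$coords))), "2 frames")
  # bead oscillating +/- d along one axis across 2 frames -> RMSF = d when
  # the superposition is anchored on the static beads
  base <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0), 4, 3, byrow = TRUE)
  f1 <- base; f2 <- base
  f1[1, 3] <- 0.2; f2[1, 3] <- -0.2
  r <- rmsf(list(f1, f2), selection = 1:4, align = 2:4)
  expect_equal(unname(r[1]), 0.2, tolerance = 1e-10)
  expect_equal(unname(r[2:4]), rep(0, 3), tolerance = 1e-10)
  # two-pass variance oracle on a random ensemble without alignment leakage
  set.seed(90)
  frames <- lapply(1:6, function(k) base + matrix(rnorm(12, sd = 0.02), 4, 3))
  rr <- rmsf(frames)
  arr <- simplify2array(lapply(frames, function(f)
    cgnmr:::align_coords(f, frames[[1]], 1:4)))
  mu <- apply(arr, c(1, 2), mean)
  oracle <- sqrt(vapply(1:4, function(b)
    mean(colSums((arr[b, , ] - mu[b, ])^2)), numeric(1)))
  expect_equal(unname(rr), oracle, tolerance = 1e-12)
})

test_that("dihedral RMSD wraps periodic differences", {
  s <- tiny_peptide(7, seed = 83)
  tr <- trajectory(s, list(s$coords, s$coords))
  expect_equal(max(dihedral_rmsd(tr)), 0, tolerance = 1e-10)
  expect_equal(cgnmr:::wrap_deg(350), -10)
  expect_equal(cgnmr:::wrap_deg(-350), 10)
  expect_equal(cgnmr:::wrap_deg(180), 180)
  expect_equal(cgnmr:::wrap_deg(c(10, 370)), c(10, 10))
  # adding 360 deg to any angle leaves the metric unchanged (via wrapping)
  d <- cgnmr:::wrap_deg(c(35, 35 + 360, 35 - 720))
  expect_true(all(d == 35))
})

test_that("pseudo-Ramachandran sampling excludes masked residues", {
  s <- tiny_peptide(6, seed = 84)
  tr <- trajectory(s, list(s$coords, s$coords, s$coords))
  pr <- pseudo_ramachandran(tr)
  # residues 1, 5(?) .. chain ends lack theta1 or theta2
  eligible <- sum(vapply(1:6, function(i) {
    a <- residue_angles(s, i); a$mask[["theta1"]] && a$mask[["theta2"]]
  }, logical(1)))
  expect_equal(nrow(pr), 3 * eligible)
  expect_false(any(pr$residue %in% c(1, 6)))
  # identical frames give a single point per residue
  expect_equal(nrow(unique(pr[, c("residue", "theta1", "theta2")])), eligible)
})

test_that("the S-matrix is 0 for identical and 2 for disjoint ensembles", {
  s <- tiny_peptide(5, seed = 85)
  frames_a <- lapply(1:4, function(k) s$coords + 0.001 * k)
  ens_a <- trajectory(s, frames_a)
  sm <- s_matrix(ens_a, ens_a)
  expect_equal(max(abs(sm$S)), 0)
  expect_equal(diag(sm$S), rep(0, 5))
  # scaled copy: all pairwise distances shifted far -> disjoint histograms
  ens_b <- trajectory(s, lapply(frames_a, function(f) f * 3))
  sm2 <- s_matrix(ens_a, ens_b)
  off <- sm2$S[upper.tri(sm2$S)]
  expect_true(all(abs(off - 2) < 1e-12))
  expect_true(isSymmetric(sm2$S))
  # hand-binned 2-frame toy: distances 0.15 and 0.35 vs 0.15 and 0.15
  two <- cg_structure(data.frame(chain = "A", resid = 1:2, restype = "GLY"),
                      1:2, c("BB", "BB"), rbind(c(0, 0, 0), c(0.15, 0, 0)))
  fa <- list(two$coords, rbind(c(0, 0, 0), c(0.35, 0, 0)))
  fb <- list(two$coords, two$coords)
  smh <- s_matrix(trajectory(two, fa), trajectory(two, fb),
                  breaks = seq(0, 1, by = 0.1))
  # P_a = (0.5, 0.5) on bins [0.1,0.2) and [0.3,0.4); P_b = (1, 0)
  expect_equal(smh$S[1, 2], abs(0.5 - 1) + abs(0.5 - 0))
  expect_error(s_matrix(trajectory(two, fa), trajectory(two, fb),
                        breaks = seq(0, 0.2, by = 0.1)), "cover")
})

test_that("tau/omega follow the printed bundle conventions", {
  # 5 parallel helices along z
  coords <- NULL
  helices <- list()
  for (h in 1:5) {
    coords <- rbind(coords, c(h, 0, 0), c(h, 0, 2))
    helices[[h]] <- c(2 * h - 1, 2 * h)
  }
  spec <- list(helices = helices, b0 = c(0, 0, 1))
  to <- tau_omega(list(coords), spec)
  expect_equal(to$tau, 0, tolerance = 1e-10)
  # h_bundle = mean(start) - mean(end) is antiparallel to each helix
  expect_equal(to$omega, 180, tolerance = 1e-10)
  # single helix: omega = 180 by the start-minus-end convention
  single <- tau_omega(list(coords), list(helices = helices[1], b0 = c(0, 0, 1)))
  expect_equal(single$omega, 180, tolerance = 1e-10)
  # symmetric cone at angle phi around b0: tau = phi
  phi <- 25 * pi / 180
  cone <- NULL; ch <- list()
  for (h in 1:5) {
    az <- 2 * pi * h / 5
    dir <- c(sin(phi) * cos(az), sin(phi) * sin(az), cos(phi))
    cone <- rbind(cone, c(cos(az), sin(az), 0), c(cos(az), sin(az), 0) + 2 * dir)
    ch[[h]] <- c(2 * h - 1, 2 * h)
  }
  to2 <- tau_omega(list(cone), list(helices = ch, b0 = c(0, 0, 1)))
  expect_equal(to2$tau, 25, tolerance = 1e-8)
})

test_that("free-energy profiles follow -kT ln H with bootstrap errors", {
  # two bins with density ratio e: delta F = kB T exactly
  x <- c(rep(0.5, 2718), rep(1.5, 1000))
  fe <- free_energy_profile(x, breaks = c(0, 1, 2), temperature = 300,
                            n_bootstrap = 10, seed = 1)
  expect_equal(fe$F[2] - fe$F[1], KB * 300 * log(2718 / 1000), tolerance = 1e-12)
  # all mass in one bin: F = -kT ln(1) = 0 there, NA (masked) elsewhere
  fe1 <- free_energy_profile(rep(0.5, 50), breaks = c(0, 1, 2),
                             temperature = 300, n_bootstrap = 20, seed = 2)
  expect_equal(fe1$F[1], 0)
  expect_true(is.na(fe1$F[2]))
  expect_equal(fe1$sigma[1], 0)  # degenerate sample: bootstrap sigma = 0
  # free-energy differences do not depend on the normalization constant
  fe2 <- free_energy_profile(c(x, x), breaks = c(0, 1, 2), temperature = 300,
                             n_bootstrap = 10, seed = 3)
  expect_equal(fe2$F[2] - fe2$F[1], fe$F[2] - fe$F[1], tolerance = 1e-12)
})

test_that("contact lifetimes follow the hysteresis rule exactly", {
  tr <- scripted_trajectory(c(1.2, 0.7, 0.9, 1.1), frame_spacing = 10)
  pairs <- data.frame(res_i = 1, res_j = 2)
  out <- contact_lifetimes(tr, pairs, r0 = 0.8, r1 = 1.0)
  expect_equal(nrow(out$events), 1)
  expect_equal(out$events$lifetime_ps, 20)  # 0.9 nm does not close the contact
  expect_equal(out$censored, 0L)
  # never below r0: no contacts at all
  none <- contact_lifetimes(scripted_trajectory(c(1.2, 0.9, 1.1)), pairs)
  expect_equal(nrow(none$events), 0)
  # constant contact: censored and excluded from means
  cens <- contact_lifetimes(scripted_trajectory(rep(0.7, 5)), pairs)
  expect_equal(nrow(cens$events), 0)
  expect_equal(cens$censored, 1L)
  expect_length(cens$per_residue, 0)
})

test_that("MSD fits recover diffusion and flag ballistic motion", {
  # static bead: D = 0
  s <- scripted_trajectory(brownian = list(D = 0, n_frames = 60, n_beads = 2),
                           frame_spacing = 10, seed = 1)
  out <- msd_diffusion(s, selection = 1, core = NA)
  expect_equal(out$D_nm2_per_ps, 0, tolerance = 1e-12)
  # ballistic drift: flagged superdiffusive
  nf <- 60
  drift <- lapply(seq_len(nf), function(k) {
    rbind(c(0.01 * k^1 * k, 0, 0), c(5, 5, 5))  # x ~ t^2
  })
  two <- cg_structure(data.frame(chain = "A", resid = 1:2, restype = "GLY"),
                      1:2, c("BB", "BB"), drift[[1]])
  trb <- trajectory(two, drift, frame_spacing = 10)
  outb <- msd_diffusion(trb, selection = 1, core = NA)
  expect_true(outb$superdiffusive)
  expect_error(msd_diffusion(trajectory(two, drift[1:3], frame_spacing = 10),
                             selection = 1), "window")
})

test_that("the radial profile normalizes counts by annular slab volume", {
  # one bead fixed at xy-distance 0.25, inside the z slab
  two <- cg_structure(data.frame(chain = "A", resid = 1:2, restype = "GLY"),
                      1:2, c("BB", "BB"), rbind(c(0.25, 0, 0.5), c(5, 5, -9)))
  tr <- trajectory(two, list(two$coords, two$coords), frame_spacing = 10)
  breaks <- seq(0, 1, by = 0.5)
  rp <- radial_profile(tr, selection = 1:2, attachment = c(0, 0),
                       z_range = c(0, 1), breaks = breaks,
                       excluded_fraction = 0)
  vol1 <- pi * 0.25 * 1  # pi (r1^2 - r0^2) (1 - f) (zmax - zmin)
  expect_equal(rp$concentration, c(1 / vol1, 0))
  # empty shell gives zero; doubling the slab height halves c
  rp2 <- radial_profile(tr, 1:2, c(0, 0), c(-0.5, 1.5), breaks, 0)
  expect_equal(rp2$concentration[1], 0.5 / vol1)
  # excluded fraction rescales the accessible area
  rp3 <- radial_profile(tr, 1:2, c(0, 0), c(0, 1), breaks, 0.5)
  expect_equal(rp3$concentration[1], 2 / vol1)
  expect_error(radial_profile(tr, 1:2, c(0, 0), c(0, 1), breaks, 1), "excluded")
})

test_that("uniform points in an annular slab give a flat radial profile", {
  set.seed(86)
  n <- 4000
  r <- sqrt(runif(n, 0, 1))  # uniform over a unit disc
  az <- runif(n, 0, 2 * pi)
  pts <- cbind(r * cos(az), r * sin(az), runif(n, 0, 1))
  s <- cg_structure(data.frame(chain = "A", resid = seq_len(n), restype = "GLY"),
                    seq_len(n), rep("BB", n), pts)
  tr <- trajectory(s, list(pts), frame_spacing = 1)
  rp <- radial_profile(tr, seq_len(n), c(0, 0), c(0, 1),
                       breaks = seq(0.2, 1, by = 0.2), excluded_fraction = 0)
  # flat within Poisson error (a few percent at these counts)
  expect_lt(max(abs(rp$concentration / mean(rp$concentration) - 1)), 0.15)
})

test_that("twist angles measure inter-layer rotation", {
  # two identical translated layers: 0 twist
  layer <- rbind(c(0, 0, 0), c(1, 0, 0))
  stack2 <- rbind(layer, sweep(layer, 2, c(0, 0, 1), `+`))
  lb <- list(c(1, 2), c(3, 4))
  tw <- twist_angle(list(stack2), lb)
  expect_equal(tw$per_frame, 0, tolerance = 1e-10)
  # rotating the upper layer by phi about z gives twist = phi
  phi <- 20 * pi / 180
  R <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
  stack_rot <- rbind(layer, sweep(layer %*% t(R), 2, c(0, 0, 1), `+`))
  tw2 <- twist_angle(list(stack_rot), lb)
  expect_equal(abs(tw2$per_frame), 20, tolerance = 1e-8)
  # per-frame mean matches a per-interface loop
  three <- rbind(layer, sweep(layer %*% t(R), 2, c(0, 0, 1), `+`),
                 sweep(layer %*% t(R %*% R), 2, c(0, 0, 2), `+`))
  tw3 <- twist_angle(list(three), list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(tw3$per_frame, mean(tw3$per_interface[1, ]))
  expect_warning(twist_angle(list(three), list(c(1, 2), c(3, 4), c(NA, 6))),
                 "missing")
})

test_that("the ADF test separates white noise from random walks", {
  set.seed(87)
  rejections <- 0
  for (k in 1:10) {
    wn <- rnorm(300)
    if (stationarity_test(wn)$p_value <= 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections, 8)  # white noise rejects the unit root in most runs
  walks <- 0
  for (k in 1:10) {
    rw <- cumsum(rnorm(300))
    if (stationarity_test(rw)$p_value > 0.05) walks <- walks + 1
  }
  expect_gte(walks, 8)       # random walks mostly fail to reject
  expect_error(stationarity_test(rnorm(10)), "20 points")
  expect_error(stationarity_test(rep(1, 50)), "constant")
})

test_that("the PCA representative is the frame nearest the projected mean", {
  s <- tiny_peptide(5, seed = 88)
  same <- lapply(1:4, function(k) s$coords)
  expect_equal(representative_structure(same), 1)  # ties -> lowest index
  # two clusters: 3 frames near A, 1 outlier; representative comes from the
  # majority cluster
  set.seed(89)
  a <- s$coords
  frames <- list(a + rnorm(length(a), sd = 0.005),
                 a + rnorm(length(a), sd = 0.005),
                 a + rnorm(length(a), sd = 0.005),
                 a * 1.6)  # a genuine conformational outlier, not a translation
  rep1 <- representative_structure(frames)
  expect_true(rep1 %in% 1:3)
  # invariant to frame order up to relabeling
  perm <- c(4, 2, 3, 1)
  rep2 <- representative_structure(frames[perm])
  expect_equal(frames[[rep1]], frames[perm][[rep2]])
})
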