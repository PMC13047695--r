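emb <- blosum_embedding()

test_that("the embedding extends BLOSUM62 with distinguishable CYO/PRC", {
  expect_equal(dim(emb), c(22, 22))
  expect_true(isSymmetric(emb))
  expect_equal(emb["CYO", 1:20], emb["CYS", 1:20])
  expect_equal(emb["CYO", "CYO"], emb["CYS", "CYS"] + 1)
  expect_equal(emb["PRC", "PRC"], emb["PRO", "PRO"] + 1)
})

test_that("feature vectors have the fixed 96-value tripeptide layout", {
  s <- tiny_peptide(5)
  for (i in 1:5) expect_length(build_feature_vector(s, i, emb), 96)
  # C-terminal residue: theta1/theta2 slots of its own (middle) block are 0
  f <- build_feature_vector(s, 5, emb)
  expect_equal(unname(f[32 + c(29, 30, 31, 32)]), rep(0, 4))
  # first residue: the i-1 block is all zero
  f1 <- build_feature_vector(s, 1, emb)
  expect_equal(unname(f1[1:32]), rep(0, 32))
  # rigid-body invariance
  s2 <- set_coords(s, random_rigid_transform(s$coords, seed = 9))
  for (i in 1:5) {
    expect_equal(build_feature_vector(s2, i, emb),
                 build_feature_vector(s, i, emb), tolerance = 1e-10)
  }
})

test_that("forward implements W_out ELU(W_hidden f + b) + b_out", {
  zero <- shift_model(matrix(0, 26, 96), rep(0, 26), matrix(0, 6, 26),
                      c(1, 2, 3, 4, 5, 6))
  expect_equal(unname(forward(zero, rnorm(96))), c(1, 2, 3, 4, 5, 6))

  # single effective hidden unit, positive preactivation: ELU is identity
  W1 <- matrix(0, 26, 96); W1[1, ] <- 1
  W2 <- matrix(0, 6, 26); W2[, 1] <- 1
  hand <- shift_model(W1, rep(0, 26), W2, rep(0.5, 6))
  f <- rep(0.25, 96)  # sum = 24 > 0
  expect_equal(unname(forward(hand, f)), rep(24 + 0.5, 6))

  set.seed(10)
  m <- make_teacher_model(4)
  x <- rnorm(96)
  oracle <- m$W_out %*% pmax(m$W_hidden %*% x + m$b_hidden, 0) +
    m$W_out %*% pmin(expm1(m$W_hidden %*% x + m$b_hidden), 0) + m$b_out
  expect_equal(unname(forward(m, x)), as.numeric(oracle), tolerance = 1e-10)
  expect_error(forward(shift_model(W1, rep(0, 26), W2, rep(0, 6),
                                   layout_version = "zzz"), f), "layout")
})

test_that("predict_shifts composes featurization and forward, masking GLY CB", {
  s <- make_toy_peptide(3, sequence = c("ALA", "GLY", "LEU"), seed = 6)
  m <- make_teacher_model(4)
  tab <- predict_shifts(m, s)
  expect_equal(nrow(tab), 3 * 6 - 1)  # GLY loses CB
  expect_false(any(tab$atom == "CB" & tab$resid == 2))
  for (i in c(1, 3)) {
    pred <- forward(m, build_feature_vector(s, i, emb))
    sub <- tab[tab$resid == i, ]
    expect_equal(sub$shift, unname(pred[sub$atom]))
  }
  expect_true(isTRUE(attr(tab, "secondary")))
})

test_that("predictions are invariant under rigid-body motion", {
  s <- tiny_peptide(6, seed = 13)
  m <- make_teacher_model(4)
  s2 <- set_coords(s, random_rigid_transform(s$coords, seed = 14))
  expect_equal(predict_shifts(m, s2)$shift, predict_shifts(m, s)$shift,
               tolerance = 1e-10)
})

test_that("the coordinate Jacobian matches finite differences", {
  m <- make_teacher_model(4)
  for (seed in c(31, 32)) {
    s <- tiny_peptide(7, seed = seed)
    for (i in c(1, 4, 7)) {
      jac <- shift_coordinate_jacobian(m, s, i)
      h <- 1e-6
      for (key in names(jac)) {
        b <- as.integer(key)
        for (d in 1:3) {
          cp <- s$coords; cp[b, d] <- cp[b, d] + h
          cm <- s$coords; cm[b, d] <- cm[b, d] - h
          num <- (forward(m, build_feature_vector(set_coords(s, cp), i, emb)) -
                    forward(m, build_feature_vector(set_coords(s, cm), i, emb))) / (2 * h)
          expect_lt(max(abs(num - jac[[key]][, d]) / pmax(abs(num), 1e-4)), 1e-4)
        }
      }
      # beads outside the Jacobian support have exactly zero influence
      outside <- setdiff(seq_len(nrow(s$coords)), as.integer(names(jac)))
      for (b in utils::head(outside, 2)) {
        cp <- s$coords; cp[b, 1] <- cp[b, 1] + 1e-4
        expect_equal(forward(m, build_feature_vector(set_coords(s, cp), i, emb)),
                     forward(m, build_feature_vector(s, i, emb)), tolerance = 1e-12)
      }
      # translation invariance: rows sum to zero over beads
      tot <- Reduce(`+`, jac)
      expect_lt(max(abs(tot)), 1e-9)
    }
  }
})

test_that("training-set preparation filters outliers and partitions by structure", {
  set.seed(20)
  structures <- lapply(1:40, function(k) make_toy_peptide(4, seed = 100 + k))
  tables <- lapply(structures, function(s) {
    tab <- data.frame(chain = "A", resid = 1:4, atom = "CA",
                      shift = rnorm(4, mean = 55, sd = 1))
    class(tab) <- c("shift_table", "data.frame")
    tab
  })
  # plant one 4-SD outlier and one exactly-3-SD boundary value
  tables[[1]]$shift[1] <- 55 + 4
  tables[[2]]$shift[1] <- 55 + 3
  stats_ref <- data.frame(atom = "CA", mean = 55, sd = 1)
  ts <- prepare_training_set(structures, tables, reference_stats = stats_ref,
                             fractions = c(0.9, 0.05, 0.05), seed = 3)
  expect_equal(ts$n_excluded, 1)          # strict inequality keeps the 3-SD entry
  expect_equal(dim(ts$features), c(96, 160))
  parts <- split(ts$structure_id, ts$partition)
  expect_length(intersect(parts$train, parts$validation), 0)
  expect_length(intersect(parts$train, parts$test), 0)
  expect_length(intersect(parts$validation, parts$test), 0)
  # each structure sits in exactly one partition
  per_struct <- tapply(ts$partition, ts$structure_id,
                       function(p) length(unique(p)))
  expect_true(all(per_struct == 1))
})

test_that("training converges on constant targets and is seed-deterministic", {
  teacher <- make_teacher_model(8)
  ts <- synth_training_set(teacher, n_structures = 30,
                           residues_per_structure = 5, noise_sd = 0, seed = 5)
  # constant-target variant: overwrite targets with a constant
  tsc <- ts
  tsc$targets[] <- 2.5
  m <- train_shift_model(tsc, lr = 0.01, seed = 1, patience = 30,
                         max_epochs = 800)
  rmse <- evaluate_shift_model(m, tsc)
  expect_lt(sqrt(mean(rmse^2)), 0.05)

  m1 <- train_shift_model(ts, seed = 9, max_epochs = 10)
  m2 <- train_shift_model(ts, seed = 9, max_epochs = 10)
  expect_identical(m1$W_hidden, m2$W_hidden)
  expect_identical(m1$b_out, m2$b_out)
})

test_that("evaluation reports per-atom RMSE matching a two-pass oracle", {
  teacher <- make_teacher_model(8)
  ts <- synth_training_set(teacher, n_structures = 20,
                           residues_per_structure = 5, noise_sd = 0.3, seed = 6)
  # the teacher itself is a perfect model for noiseless targets
  ts0 <- synth_training_set(teacher, n_structures = 10,
                            residues_per_structure = 5, noise_sd = 0, seed = 7)
  expect_equal(max(evaluate_shift_model(teacher, ts0), na.rm = TRUE), 0,
               tolerance = 1e-10)
  # single-example RMSE equals the absolute error
  one <- ts0
  keep <- which(one$partition == "test")[1]
  one$features <- one$features[, keep, drop = FALSE]
  one$targets <- one$targets[, keep, drop = FALSE] + 2
  one$mask <- one$mask[, keep, drop = FALSE]
  one$partition <- "test"
  expect_equal(unname(evaluate_shift_model(teacher, one)["CA"]), 2,
               tolerance = 1e-10)
  # two-pass mean-of-squares oracle on a random model
  m <- make_teacher_model(9)
  te <- cgnmr:::subset_training(ts, "test")
  P <- forward(m, te$X)
  oracle <- vapply(1:6, function(a) {
    k <- te$M[a, ]
    sqrt(sum((P[a, k] - te$Y[a, k])^2) / sum(k))
  }, numeric(1))
  expect_equal(unname(evaluate_shift_model(m, ts)), oracle, tolerance = 1e-12)
  # storing writes the tolerances into the model
  m2 <- evaluate_shift_model(m, ts, store = TRUE)
  expect_equal(unname(m2$epsilon), oracle, tolerance = 1e-12)
})

test_that("held-out RMSE shrinks toward the noise floor as data grows", {
  # scaled-down recovery curve: 3 seeds x 2 sizes, monotone in expectation
  sizes <- c(25, 120)
  mean_rmse <- vapply(sizes, function(ns) {
    mean(vapply(1:3, function(sd) {
      teacher <- make_teacher_model(40 + sd)
      ts <- synth_training_set(teacher, ns, 5, noise_sd = 0.1, seed = 50 + sd)
      m <- train_shift_model(ts, seed = sd, batch_size = 200, patience = 20,
                             max_epochs = 400)
      sqrt(mean(evaluate_shift_model(m, ts)^2, na.rm = TRUE))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_rmse[2], mean_rmse[1])
})
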