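# Flat-bottom harmonic chemical-shift restraint:
#   V_CS = K_CS * sum_n sum_a residual(pred - exp, eps_a)^2
# with the residual clipped to zero inside +/- eps_a. Forces flow through the
# analytic coordinate Jacobian of the shift network. K_CS multiplies squared
# ppm residuals; the ppm^2 factor is absorbed so V_CS is read in kJ/mol.

#' Configuration for the chemical-shift restraint
#'
#' @param k_cs force constant (kJ/mol per ppm^2, the ppm^2 absorbed).
#' @param ramp_rate K increase per integration step (default 0.001).
#' @param k_max ramp plateau (default \code{k_cs}).
#' @param epsilon six per-atom tolerances (ppm) in N, C, CA, CB, H, HA order;
#'   default all zero.
#' @return list of class \code{cs_restraint_config}.
#' @export
cs_restraint_config <- function(k_cs = 25, ramp_rate = 0.001, k_max = k_cs,
                                epsilon = rep(0, 6)) {
  stopif(k_cs < 0 || ramp_rate < 0 || k_max < 0 || any(epsilon < 0),
         "restraint parameters must be non-negative")
  structure(list(k_cs = k_cs, ramp_rate = ramp_rate, k_max = k_max,
                 epsilon = stats::setNames(as.numeric(epsilon), ATOM_TYPES)),
            class = "cs_restraint_config")
}

#' Clipped (flat-bottom) shift residual
#'
#' With d = pred - exp: returns d + eps when d < -eps, 0 when |d| <= eps,
#' and d - eps when d > eps. Vectorized.
#'
#' @param pred predicted secondary shift (ppm).
#' @param exp experimental secondary shift (ppm).
#' @param eps flat-bottom half width (ppm, >= 0).
#' @return clipped residual (ppm).
#' @export
cs_residual <- function(pred, exp, eps) {
  stopif(any(eps < 0), "eps must be non-negative")
  d <- pred - exp
  ifelse(d < -eps, d + eps, ifelse(d > eps, d - eps, 0))
}

# match experimental entries to residues; returns data.frame(residue_row,
# atom_index, value)
match_shift_entries <- function(structure, exp_table) {
  key <- paste(structure$residues$chain, structure$residues$resid)
  rows <- match(paste(exp_table$chain, exp_table$resid), key)
  ai <- match(exp_table$atom, ATOM_TYPES)
  keep <- !is.na(rows) & !is.na(ai)
  data.frame(residue_row = rows[keep], atom_index = ai[keep],
             value = exp_table$shift[keep])
}

#' Chemical-shift restraint energy
#'
#' @param model a \code{shift_model}.
#' @param structure a \code{cg_structure}.
#' @param exp_table \code{shift_table} of experimental secondary shifts
#'   (must be flagged secondary; raw tables are rejected).
#' @param config a \code{cs_restraint_config}.
#' @param k_cs override of the (possibly ramped) force constant.
#' @param embedding embedding matrix.
#' @return energy in kJ/mol.
#' @export
cs_energy <- function(model, structure, exp_table, config,
                      k_cs = config$k_cs, embedding = blosum_embedding()) {
  stopif(!isTRUE(attr(exp_table, "secondary")),
         "shift convention mismatch: expected secondary shifts")
  ent <- match_shift_entries(structure, exp_table)
  if (nrow(ent) == 0) return(0)
  total <- 0
  for (i in unique(ent$residue_row)) {
    pred <- forward(model, build_feature_vector(structure, i, embedding))
    sub <- ent[ent$residue_row == i, ]
    res <- cs_residual(pred[sub$atom_index], sub$value,
                       config$epsilon[sub$atom_index])
    total <- total + sum(res^2)
  }
  k_cs * total
}

#' Chemical-shift restraint forces
#'
#' F = -grad V_CS = -2 K_CS sum residual * d(pred)/d(coords). Exactly zero
#' for residuals inside the flat bottom.
#'
#' @inheritParams cs_energy
#' @return n_beads x 3 matrix of forces (kJ/mol/nm).
#' @export
cs_forces <- function(model, structure, exp_table, config,
                      k_cs = config$k_cs, embedding = blosum_embedding()) {
  stopif(!isTRUE(attr(exp_table, "secondary")),
         "shift convention mismatch: expected secondary shifts")
  ent <- match_shift_entries(structure, exp_table)
  F <- matrix(0, nrow(structure$coords), 3)
  if (nrow(ent) == 0 || k_cs == 0) return(F)
  for (i in unique(ent$residue_row)) {
    pred <- forward(model, build_feature_vector(structure, i, embedding))
    sub <- ent[ent$residue_row == i, ]
    res6 <- numeric(6)
    res6[sub$atom_index] <- cs_residual(pred[sub$atom_index], sub$value,
                                        config$epsilon[sub$atom_index])
    if (all(res6 == 0)) next
    jac <- shift_coordinate_jacobian(model, structure, i, embedding)
    for (key in names(jac)) {
      bead <- as.integer(key)
      # dV/dx = 2 K sum_a res_a * J[a, ]
      F[bead, ] <- F[bead, ] - 2 * k_cs * as.numeric(res6 %*% jac[[key]])
    }
  }
  F
}

# --- fast one-pass evaluation used by the force provider ---------------

# BB / SC1 bead index arrays, computed once per topology
bead_index_cache <- function(structure) {
  n <- nrow(structure$residues)
  bb <- integer(n); sc1 <- integer(n)
  for (i in seq_len(n)) {
    bb[i] <- cg_bead_index(structure, i, "BB")
    sc1[i] <- cg_bead_index(structure, i, "SC1")
  }
  list(bb = bb, sc1 = sc1)
}

# per-residue angle values and gradients computed once per structure
structure_angle_data <- function(structure, idx = NULL) {
  n <- nrow(structure$residues)
  idx <- idx %||% bead_index_cache(structure)
  bb <- idx$bb; sc1 <- idx$sc1
  chain <- structure$residues$chain
  X <- structure$coords
  res <- vector("list", n)
  pt <- function(i, j, which) {
    # bead `which` (1 = BB, 2 = SC1) of residue j, NA off-chain/absent
    if (j < 1 || j > n || chain[j] != chain[i]) return(NA_integer_)
    if (which == 1) bb[j] else sc1[j]
  }
  for (i in seq_len(n)) {
    specs <- angle_bead_spec(i)
    out <- vector("list", length(ANGLE_NAMES))
    names(out) <- ANGLE_NAMES
    for (k in seq_along(ANGLE_NAMES)) {
      sp <- specs[[k]]
      beads <- vapply(sp$pts, function(p) pt(i, p[1], p[2]), integer(1))
      if (any(is.na(beads))) { out[k] <- list(NULL); next }
      pts <- lapply(beads, function(b) X[b, ])
      if (sp$type == "angle") {
        out[[k]] <- list(beads = beads, value = do.call(vec_angle, pts),
                         grad = do.call(angle_gradient, pts))
      } else {
        out[[k]] <- list(beads = beads, value = do.call(vec_dihedral, pts),
                         grad = do.call(dihedral_gradient, pts))
      }
    }
    res[[i]] <- out
  }
  res
}

# feature blocks (32 x n) from precomputed angle data
feature_blocks_from <- function(structure, adata, embedding) {
  n <- nrow(structure$residues)
  B <- matrix(0, BLOCK_SIZE, n)
  for (j in seq_len(n)) {
    B[1:22, j] <- embedding[structure$residues$restype[j], ]
    for (k in seq_along(ANGLE_NAMES)) {
      a <- adata[[j]][[ANGLE_NAMES[k]]]
      if (!is.null(a)) {
        B[22 + 2 * k - 1, j] <- sin(a$value)
        B[22 + 2 * k, j] <- cos(a$value)
      }
    }
  }
  B
}

# energy and forces of the CS restraint in one pass (shared angle cache);
# ent_by_res: list residue_row -> list(atom = indices, value = shifts)
cs_eval_full <- function(model, structure, ent_by_res, config, k_cs,
                         embedding, idx = NULL, want_forces = TRUE) {
  n <- nrow(structure$residues)
  nb <- nrow(structure$coords)
  F <- matrix(0, nb, 3)
  if (length(ent_by_res) == 0 || k_cs == 0) {
    return(list(energy = 0, forces = F))
  }
  adata <- structure_angle_data(structure, idx)
  B <- feature_blocks_from(structure, adata, embedding)
  chain <- structure$residues$chain
  zero <- numeric(BLOCK_SIZE)
  blk <- function(i, j) {
    if (j < 1 || j > n || chain[j] != chain[i]) zero else B[, j]
  }
  total <- 0
  for (i in as.integer(names(ent_by_res))) {
    f <- c(blk(i, i - 1), blk(i, i), blk(i, i + 1))
    pre <- as.numeric(model$W_hidden %*% f + model$b_hidden)
    pred <- as.numeric(model$W_out %*% elu(pre) + model$b_out)
    sub <- ent_by_res[[as.character(i)]]
    res6 <- numeric(6)
    res6[sub$atom] <- cs_residual(pred[sub$atom], sub$value,
                                  config$epsilon[sub$atom])
    total <- total + sum(res6^2)
    if (!want_forces || all(res6 == 0)) next
    # dV/d(feature) = 2 k res' J; J = W_out diag(elu') W_hidden
    dV_dh <- as.numeric((2 * k_cs * res6) %*% model$W_out) * elu_prime(pre)
    dV_df <- as.numeric(dV_dh %*% model$W_hidden)  # length 96
    for (b in 1:3) {
      j <- i + b - 2
      if (j < 1 || j > n || chain[j] != chain[i]) next
      off <- (b - 1) * BLOCK_SIZE + 22
      for (k in seq_along(ANGLE_NAMES)) {
        a <- adata[[j]][[ANGLE_NAMES[k]]]
        if (is.null(a)) next
        dV_da <- dV_df[off + 2 * k - 1] * cos(a$value) -
                 dV_df[off + 2 * k] * sin(a$value)
        if (dV_da == 0) next
        for (p in seq_along(a$beads)) {
          F[a$beads[p], ] <- F[a$beads[p], ] - dV_da * a$grad[p, ]
        }
      }
    }
  }
  list(energy = k_cs * total, forces = F)
}

#' Ramped force constant at an integration step
#'
#' K(step) = min(step * rate, K_max).
#'
#' @param step integration step (0-based).
#' @param rate increase per step.
#' @param k_max plateau.
#' @return force constant.
#' @export
ramp_k <- function(step, rate, k_max) pmin(step * rate, k_max)

#' Reference-scaled chemical-shift RMSD
#'
#' Per atom type, RMSD(pred - exp) divided by that atom type's reference SD,
#' then averaged over atom types with data.
#'
#' @param pred,exp \code{shift_table}s on the same keys.
#' @param per_atom_sd named numeric (atom -> reference SD, ppm).
#' @return scalar scaled RMSD.
#' @export
cs_rmsd_scaled <- function(pred, exp, per_atom_sd) {
  keyp <- paste(pred$chain, pred$resid, pred$atom)
  keye <- paste(exp$chain, exp$resid, exp$atom)
  common <- intersect(keyp, keye)
  stopif(length(common) == 0, "no overlapping shift entries")
  dp <- pred$shift[match(common, keyp)] - exp$shift[match(common, keye)]
  atoms <- pred$atom[match(common, keyp)]
  vals <- vapply(unique(atoms), function(a) {
    sd_a <- per_atom_sd[[a]]
    if (is.null(sd_a) || is.na(sd_a)) return(NA_real_)
    sqrt(mean(dp[atoms == a]^2)) / sd_a
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Scan candidate K_CS values with short restrained runs
#'
#' Runs a short restrained simulation per candidate and returns the smallest
#' K whose mean scaled CS RMSD over the run ties the minimum (tolerance
#' \code{tie_tol}); diverged runs are marked invalid and skipped.
#'
#' @param system list with fields structure, model, exp_table, and optional
#'   toy force-field params (see \code{\link{toy_forcefield}}).
#' @param candidates ascending numeric vector of K_CS candidates.
#' @param short_run_length steps per probe run (default 500).
#' @param per_atom_sd reference SDs for the scaled RMSD (default all 1).
#' @param seed RNG seed.
#' @param temperature K.
#' @param tie_tol RMSE tie tolerance (default 1e-9).
#' @return the selected K_CS (scalar).
#' @export
scan_kcs <- function(system, candidates, short_run_length = 500,
                     per_atom_sd = NULL, seed = 1, temperature = 300,
                     tie_tol = 1e-9) {
  stopif(length(candidates) == 0, "need at least one candidate")
  candidates <- sort(candidates)
  if (length(candidates) == 1) return(candidates)
  if (is.null(per_atom_sd)) per_atom_sd <- stats::setNames(rep(1, 6), ATOM_TYPES)
  scores <- rep(NA_real_, length(candidates))
  for (ci in seq_along(candidates)) {
    K <- candidates[ci]
    cfg <- cs_restraint_config(k_cs = K, ramp_rate = Inf, k_max = K,
                               epsilon = system$model$epsilon)
    prov <- list(toy_forcefield(system$structure, system$params %||% list()),
                 cs_restraint_provider(system$model, system$exp_table, cfg))
    st <- sim_state(system$structure, temperature = temperature, seed = seed)
    res <- tryCatch({
      tr <- run_dynamics(st, prov, n_steps = short_run_length,
                         report_every = max(1, short_run_length %/% 10))
      rmses <- vapply(tr$frames, function(fr) {
        s2 <- set_coords(system$structure, fr)
        cs_rmsd_scaled(predict_shifts(system$model, s2), system$exp_table,
                       per_atom_sd)
      }, numeric(1))
      mean(rmses)
    }, error = function(e) NA_real_)
    scores[ci] <- res
  }
  stopif(all(is.na(scores)), "all candidate runs diverged")
  best <- min(scores, na.rm = TRUE)
  out <- candidates[which(!is.na(scores) & scores <= best + tie_tol)[1]]
  attr(out, "scores") <- stats::setNames(scores, candidates)
  out
}

#' Chemical-shift restraint as an engine force provider
#'
#' The provider owns the K ramp: at step s the active constant is
#' \code{min(s * ramp_rate, k_max)} (an infinite rate applies k_max from
#' step 0).
#'
#' @param model a \code{shift_model}.
#' @param exp_table experimental secondary \code{shift_table}.
#' @param config a \code{cs_restraint_config}.
#' @param embedding embedding matrix (precomputed once).
#' @return a force provider (see \code{\link{toy_forcefield}}).
#' @export
cs_restraint_provider <- function(model, exp_table, config,
                                  embedding = blosum_embedding()) {
  template <- NULL
  ent_by_res <- NULL
  idx <- NULL
  list(
    name = "cs_restraint",
    bind = function(structure) {
      template <<- structure
      ent <- match_shift_entries(structure, exp_table)
      ent_by_res <<- lapply(split(ent, ent$residue_row), function(s)
        list(atom = s$atom_index, value = s$value))
      idx <<- bead_index_cache(structure)
    },
    k_at = function(step) {
      if (is.infinite(config$ramp_rate)) config$k_max
      else ramp_k(step, config$ramp_rate, config$k_max)
    },
    eval = function(coords, step) {
      k <- if (is.infinite(config$ramp_rate)) config$k_max
           else ramp_k(step, config$ramp_rate, config$k_max)
      s <- template
      s$coords <- coords
      cs_eval_full(model, s, ent_by_res, config, k, embedding, idx = idx)
    })
}
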