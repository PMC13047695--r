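# Synthetic-data generators. Every generator is a pure function of its seed
# (RNG state is saved and restored), so fixtures are built in code at test
# time and nothing external is ever downloaded.

#' Random self-avoiding toy CG peptide
#'
#' BB beads chained at 0.35 nm spacing with randomized bond angles, rejected
#' until all inter-bead distances exceed 0.25 nm; non-glycine residues get
#' an SC1 bead 0.3 nm off the backbone.
#'
#' @param n_residues chain length (>= 1).
#' @param sequence optional character vector of residue codes (length
#'   \code{n_residues}); default random over the 20 standard codes.
#' @param seed RNG seed.
#' @param chain chain identifier (default "A").
#' @return a \code{cg_structure}.
#' @export
make_toy_peptide <- function(n_residues, sequence = NULL, seed = 1,
                             chain = "A") {
  stopif(n_residues < 1, "n_residues must be >= 1")
  with_seed(seed, {
    seqn <- sequence %||% sample(RESIDUE_CODES[1:20], n_residues, replace = TRUE)
    stopif(length(seqn) != n_residues, "sequence length mismatch")
    spacing <- 0.35
    min_sep <- 0.25
    bb <- matrix(0, n_residues, 3)
    if (n_residues > 1) bb[2, ] <- c(spacing, 0, 0)
    i <- 3
    while (i <= n_residues) {
      placed <- FALSE
      for (try in 1:200) {
        # bend 40-80 degrees off the previous bond direction
        prev <- unitv(bb[i - 1, ] - bb[i - 2, ])
        bend <- stats::runif(1, 40, 80) * pi / 180
        az <- stats::runif(1, 0, 2 * pi)
        # orthonormal frame around prev
        a1 <- if (abs(prev[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- unitv(cross3(prev, a1))
        e2 <- cross3(prev, e1)
        dir <- cos(bend) * prev + sin(bend) * (cos(az) * e1 + sin(az) * e2)
        cand <- bb[i - 1, ] + spacing * dir
        d <- sqrt(rowSums(sweep(bb[seq_len(i - 2), , drop = FALSE], 2, cand)^2))
        if (all(d > min_sep)) { bb[i, ] <- cand; placed <- TRUE; break }
      }
      stopif(!placed, "self-avoiding walk failed; try another seed")
      i <- i + 1
    }
    bead_res <- integer(0); bead_name <- character(0); coords <- NULL
    for (r in seq_len(n_residues)) {
      bead_res <- c(bead_res, r); bead_name <- c(bead_name, "BB")
      coords <- rbind(coords, bb[r, ])
      if (seqn[r] != "GLY") {
        placed <- FALSE
        for (try in 1:200) {
          cand <- bb[r, ] + unitv(stats::rnorm(3)) * 0.3
          others <- rbind(bb[-r, , drop = FALSE],
                          coords[bead_name == "SC1", , drop = FALSE])
          d <- if (nrow(others) > 0) {
            sqrt(rowSums(sweep(others, 2, cand)^2))
          } else 1
          if (all(d > min_sep)) {
            bead_res <- c(bead_res, r); bead_name <- c(bead_name, "SC1")
            coords <- rbind(coords, cand)
            placed <- TRUE
            break
          }
        }
        stopif(!placed, "side-chain placement failed; try another seed")
      }
    }
    cg_structure(
      residues = data.frame(chain = chain, resid = seq_len(n_residues),
                            restype = seqn, stringsAsFactors = FALSE),
      bead_residue = bead_res, bead_name = bead_name, coords = coords)
  })
}

#' Frozen random teacher model
#'
#' Random weights of the fixed 96-26-6 architecture (scaled so outputs are
#' O(1) on typical features); all tolerances epsilon are 0. Ground truth for
#' teacher-student parameter-recovery tests.
#'
#' @param seed RNG seed.
#' @return a \code{shift_model}.
#' @export
make_teacher_model <- function(seed = 1) {
  with_seed(seed, {
    shift_model(
      W_hidden = matrix(stats::rnorm(26 * 96, sd = 1 / sqrt(96)), 26, 96),
      b_hidden = stats::rnorm(26, sd = 0.1),
      W_out = matrix(stats::rnorm(6 * 26, sd = 1 / sqrt(26)), 6, 26),
      b_out = stats::rnorm(6, sd = 0.1))
  })
}

#' Synthetic shift table: teacher predictions plus Gaussian noise
#'
#' @param teacher a \code{shift_model}.
#' @param target a \code{cg_structure}.
#' @param noise_sd Gaussian noise in ppm (default 0.1).
#' @param seed RNG seed.
#' @return a secondary \code{shift_table} with provenance "synthetic".
#' @export
synth_shift_table <- function(teacher, target, noise_sd = 0.1, seed = 1) {
  tab <- predict_shifts(teacher, target)
  with_seed(seed, {
    tab$shift <- tab$shift + stats::rnorm(nrow(tab), sd = noise_sd)
  })
  attr(tab, "provenance") <- "synthetic"
  tab
}

#' Synthetic bead-resolved NOE table from a target conformation
#'
#' Samples \code{n_pairs} unique BB bead pairs separated by at least 3
#' residues in sequence and within \code{max_distance} in space; each record
#' carries d = the actual target distance and r1 = d + bound_width, so the
#' target satisfies every restraint with zero energy. Atom groups are named
#' "BB", making the table usable both directly (beads as their own atoms)
#' and through the identity mapping pipeline.
#'
#' @param target a \code{cg_structure}.
#' @param n_pairs number of restraints (>= 1).
#' @param bound_width flat-bottom width above d (nm, default 0.05).
#' @param max_distance eligibility cutoff (nm, default 1.5).
#' @param seed RNG seed.
#' @param lower_width optional lower-bound width: when given, r0 =
#'   max(0, d - lower_width) ("exact" two-sided restraints); default NULL
#'   keeps the upper-bound-only convention (r0 = 0).
#' @return a \code{noe_table}.
#' @export
synth_noe_table <- function(target, n_pairs, bound_width = 0.05,
                            max_distance = 1.5, seed = 1,
                            lower_width = NULL) {
  stopif(n_pairs < 1, "n_pairs must be >= 1")
  nb <- nrow(target$coords)
  elig <- list()
  for (a in seq_len(nb - 1)) {
    for (b in (a + 1):nb) {
      ri <- target$bead_residue[a]; rj <- target$bead_residue[b]
      if (abs(rj - ri) < 3) next
      d <- vnorm(target$coords[b, ] - target$coords[a, ])
      if (d <= max_distance) {
        elig[[length(elig) + 1]] <- list(i = ri, j = rj, d = d,
                                         bi = target$bead_name[a],
                                         bj = target$bead_name[b])
      }
    }
  }
  stopif(length(elig) < n_pairs,
         sprintf("only %d eligible pairs for %d requested", length(elig), n_pairs))
  pick <- with_seed(seed, sample(length(elig), n_pairs))
  rows <- lapply(elig[pick], function(e) {
    data.frame(chain_i = target$residues$chain[e$i],
               resid_i = target$residues$resid[e$i], atoms_i = e$bi,
               chain_j = target$residues$chain[e$j],
               resid_j = target$residues$resid[e$j], atoms_j = e$bj,
               d = e$d,
               r0 = if (is.null(lower_width)) 0 else max(0, e$d - lower_width),
               r1 = e$d + bound_width,
               r2 = e$d + bound_width + 0.5, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("noe_table", "data.frame")
  df
}

#' Bead-resolved CG restraints straight from a synthetic NOE table
#'
#' Shortcut that resolves the "BB" groups of \code{\link{synth_noe_table}}
#' against the target and emits \code{cg_restraints} without the atomistic
#' mapping pipeline.
#'
#' @param target the \code{cg_structure} the table was generated from.
#' @param noe a bead-resolved \code{noe_table}.
#' @param k_noe force constant.
#' @return a \code{cg_restraints} table.
#' @export
noe_table_to_restraints <- function(target, noe, k_noe = 25) {
  res_row <- function(chain, resid) {
    which(target$residues$chain == chain & target$residues$resid == resid)[1]
  }
  rows <- lapply(seq_len(nrow(noe)), function(r) {
    bi <- cg_bead_index(target, res_row(noe$chain_i[r], noe$resid_i[r]),
                        noe$atoms_i[r])
    bj <- cg_bead_index(target, res_row(noe$chain_j[r], noe$resid_j[r]),
                        noe$atoms_j[r])
    stopif(is.na(bi) || is.na(bj), "unresolvable bead in NOE table")
    data.frame(bead_i = bi, bead_j = bj, r0 = noe$r0[r], r1 = noe$r1[r],
               r2 = noe$r2[r], k_noe = k_noe)
  })
  cg_restraints(do.call(rbind, rows))
}

#' Pseudo-atomistic structure with atoms at bead centers
#'
#' Exercises the atomistic-to-CG mapping pipeline on the identity case: each
#' bead becomes an atom of the same name at the same position.
#'
#' @param target a \code{cg_structure}.
#' @return list: \code{atomistic} (an \code{atomistic_structure}),
#'   \code{mapping} (identity \code{mapping_table}).
#' @export
pseudo_atomistic <- function(target) {
  atoms <- data.frame(
    chain = target$residues$chain[target$bead_residue],
    resid = target$residues$resid[target$bead_residue],
    restype = target$residues$restype[target$bead_residue],
    atom = target$bead_name, element = "C",
    x = target$coords[, 1], y = target$coords[, 2], z = target$coords[, 3],
    stringsAsFactors = FALSE)
  map <- unique(data.frame(restype = atoms$restype, atom = atoms$atom,
                           bead = atoms$atom, stringsAsFactors = FALSE))
  class(map) <- c("mapping_table", "data.frame")
  list(atomistic = atomistic_structure(atoms), mapping = map)
}

#' Synthetic teacher-labelled training set
#'
#' Random toy peptides featurized and labelled with teacher predictions plus
#' Gaussian noise, partitioned by structure (0.8/0.1/0.1 by default).
#'
#' @param teacher a \code{shift_model}.
#' @param n_structures number of toy peptides.
#' @param residues_per_structure residues per peptide.
#' @param noise_sd label noise (ppm).
#' @param seed RNG seed.
#' @param fractions train/validation/test split fractions.
#' @return a \code{training_set}.
#' @export
synth_training_set <- function(teacher, n_structures, residues_per_structure,
                               noise_sd = 0.1, seed = 1,
                               fractions = c(0.8, 0.1, 0.1)) {
  stopif(n_structures < 1 || residues_per_structure < 1, "sizes must be >= 1")
  emb <- blosum_embedding()
  structures <- lapply(seq_len(n_structures), function(s)
    make_toy_peptide(residues_per_structure, seed = seed * 10000 + s))
  tables <- with_seed(seed + 1, {
    lapply(structures, function(st) {
      tab <- predict_shifts(teacher, st, embedding = emb)
      tab$shift <- tab$shift + stats::rnorm(nrow(tab), sd = noise_sd)
      tab
    })
  })
  prepare_training_set(structures, tables, random_coil = NULL,
                       reference_stats = NULL, fractions = fractions,
                       seed = seed + 2, embedding = emb)
}

#' Scripted two-bead (or Brownian) trajectory
#'
#' Distance mode: realizes a prescribed inter-bead distance series exactly
#' with two BB beads on the x axis. Brownian mode: n_beads independent
#' random walks with per-axis increments N(0, 2 D dt).
#'
#' @param distance_script numeric distance series (nm), or NULL for
#'   Brownian mode.
#' @param frame_spacing ps.
#' @param brownian list(D =, n_frames =, n_beads = 1) for Brownian mode.
#' @param seed RNG seed (Brownian mode).
#' @return a \code{trajectory}.
#' @export
scripted_trajectory <- function(distance_script = NULL, frame_spacing = 10,
                                brownian = NULL, seed = 1) {
  if (!is.null(distance_script)) {
    stopif(length(distance_script) == 0, "empty script")
    stopif(any(distance_script <= 0), "infeasible script: non-positive distance")
    s <- cg_structure(
      data.frame(chain = "A", resid = 1:2, restype = "GLY",
                 stringsAsFactors = FALSE),
      bead_residue = 1:2, bead_name = c("BB", "BB"),
      coords = rbind(c(0, 0, 0), c(distance_script[1], 0, 0)))
    frames <- lapply(distance_script, function(d)
      rbind(c(0, 0, 0), c(d, 0, 0)))
    return(trajectory(s, frames, frame_spacing))
  }
  stopif(is.null(brownian), "need a distance script or Brownian parameters")
  nb <- brownian$n_beads %||% 1
  nf <- brownian$n_frames
  sdstep <- sqrt(2 * brownian$D * frame_spacing)
  frames <- with_seed(seed, {
    x <- matrix(0, nb, 3)
    out <- list(x)
    for (f in seq_len(nf - 1)) {
      x <- x + matrix(stats::rnorm(nb * 3, sd = sdstep), nb, 3)
      out[[f + 1]] <- x
    }
    out
  })
  s <- cg_structure(
    data.frame(chain = "A", resid = seq_len(nb), restype = "GLY",
               stringsAsFactors = FALSE),
    bead_residue = seq_len(nb), bead_name = rep("BB", nb), coords = frames[[1]])
  trajectory(s, frames, frame_spacing)
}
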