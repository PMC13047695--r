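# NOE distance restraints: translate atomistic NOE records into CG bead-pair
# restraints (r^-6 condensation, per-bead-pair averaging, conflict
# filtering), evaluate the piecewise Torda-van Gunsteren potential, and apply
# it to exponentially time-averaged distances with a ramped force constant.

#' Construct a set of CG bead-pair restraints
#'
#' @param df data.frame with columns bead_i, bead_j (global bead indices),
#'   r0, r1, r2 (nm) and k_noe (kJ/mol/nm^2).
#' @return object of class \code{cg_restraints}.
#' @export
cg_restraints <- function(df) {
  need <- c("bead_i", "bead_j", "r0", "r1", "r2", "k_noe")
  stopif(!all(need %in% names(df)), "restraint table misses required columns")
  stopif(any(df$r0 < 0 | df$r0 > df$r1 | df$r1 > df$r2),
         "require 0 <= r0 <= r1 <= r2")
  class(df) <- c("cg_restraints", "data.frame")
  df
}

#' Map one atomistic NOE distance onto a CG bead pair
#'
#' D = | vec(A_i -> a_i) + d_ij * unit(a_i -> a_j) + vec(a_j -> A_j) |,
#' i.e. the bead-bead distance obtained by walking bead -> atom, the NOE
#' distance along the interatomic direction, then atom -> bead.
#'
#' @param bead_i_pos,bead_j_pos bead positions (nm).
#' @param atom_i_pos,atom_j_pos atom positions in the same reference frame.
#' @param d_ij NOE interatomic distance (nm, > 0).
#' @return CG NOE distance (nm).
#' @export
map_atom_pair <- function(bead_i_pos, bead_j_pos, atom_i_pos, atom_j_pos, d_ij) {
  stopif(d_ij <= 0, "d_ij must be positive")
  dv <- atom_j_pos - atom_i_pos
  stopif(vnorm(dv) < 1e-9, "coincident atoms in map_atom_pair()")
  vnorm((atom_i_pos - bead_i_pos) + d_ij * unitv(dv) + (bead_j_pos - atom_j_pos))
}

#' Apparent distance of a multi-atom NOE group
#'
#' d_hat = (sum d_n^-6)^(-1/6); the NOE signal scales with r^-6, so short
#' contributors dominate and d_hat <= min(d_n).
#'
#' @param distances positive distances (nm).
#' @return apparent distance (nm).
#' @export
apparent_distance <- function(distances) {
  stopif(length(distances) == 0, "empty distance set")
  stopif(any(distances <= 0), "distances must be positive")
  sum(distances^-6)^(-1 / 6)
}

#' Condense several mapped CG distances into one
#'
#' D_hat = sum_n D_n * r_n^-6 / sum_m r_m^-6, the r^-6-weighted mean of the
#' mapped CG distances, weighted by the atomistic interatomic distances r_n.
#'
#' @param cg_distances mapped CG distances D_n (nm).
#' @param atom_distances corresponding atomistic distances r_n (nm, > 0).
#' @return condensed CG distance (nm).
#' @export
condense_group <- function(cg_distances, atom_distances) {
  stopif(length(cg_distances) == 0, "empty contributor set")
  stopif(length(cg_distances) != length(atom_distances), "length mismatch")
  stopif(any(atom_distances <= 0), "zero atomistic distance")
  w <- atom_distances^-6
  sum(cg_distances * w) / sum(w)
}

#' Average condensed distances that share one bead pair
#'
#' Arithmetic mean of the condensed distances D_hat coming from distinct NOE
#' records that map onto the same bead pair.
#'
#' @param condensed numeric vector of D_hat values (nm).
#' @return mean CG distance (nm).
#' @export
aggregate_bead_pair <- function(condensed) {
  stopif(length(condensed) == 0, "no signals to aggregate")
  mean(condensed)
}

# expand "H1|H2" -> c("H1","H2")
split_atoms <- function(s) strsplit(s, "|", fixed = TRUE)[[1]]

#' Drop NOE contributors that conflict with a reference structure
#'
#' When several atom pairs contribute to a record, contributors whose
#' reference interatomic distance exceeds d_ij + slack are discarded; records
#' left without contributors are dropped entirely.
#'
#' @param noe a \code{noe_table}.
#' @param reference an \code{atomistic_structure} resolving every atom.
#' @param slack allowed excess over d_ij (nm, default 0.2).
#' @return list: \code{noe} (filtered table with pruned atom groups),
#'   \code{report} (data.frame record, contributors_in, contributors_out).
#' @export
filter_conflicts <- function(noe, reference, slack = 0.2) {
  keep_rows <- logical(nrow(noe))
  rep_rows <- list()
  for (r in seq_len(nrow(noe))) {
    ai <- split_atoms(noe$atoms_i[r]); aj <- split_atoms(noe$atoms_j[r])
    pairs <- expand.grid(a = ai, b = aj, stringsAsFactors = FALSE)
    d_ref <- vapply(seq_len(nrow(pairs)), function(p) {
      vnorm(atom_coord(reference, noe$chain_i[r], noe$resid_i[r], pairs$a[p]) -
              atom_coord(reference, noe$chain_j[r], noe$resid_j[r], pairs$b[p]))
    }, numeric(1))
    ok <- d_ref <= noe$d[r] + slack
    rep_rows[[r]] <- data.frame(record = r, contributors_in = nrow(pairs),
                                contributors_out = sum(ok))
    if (!any(ok)) { keep_rows[r] <- FALSE; next }
    keep_rows[r] <- TRUE
    noe$atoms_i[r] <- paste(unique(pairs$a[ok]), collapse = "|")
    noe$atoms_j[r] <- paste(unique(pairs$b[ok]), collapse = "|")
  }
  list(noe = noe[keep_rows, , drop = FALSE], report = do.call(rbind, rep_rows))
}

# map (chain, resid, atom) to a global bead index of the CG structure
resolve_bead <- function(cg, mapping, chain, resid, restype, atom) {
  hit <- which(mapping$restype == restype & mapping$atom == atom)
  stopif(length(hit) == 0,
         sprintf("no mapping for atom %s of %s", atom, restype))
  bead <- mapping$bead[hit[1]]
  i <- which(cg$residues$chain == chain & cg$residues$resid == resid)
  stopif(length(i) == 0,
         sprintf("residue %s/%d absent from CG structure", chain, resid))
  k <- cg_bead_index(cg, i[1], bead)
  stopif(is.na(k), sprintf("bead %s absent for residue %s/%d", bead, chain, resid))
  k
}

#' Build CG bead-pair restraints from an atomistic NOE table
#'
#' Full pipeline: every contributing atom pair is mapped through
#' \code{map_atom_pair}, pairs sharing a bead pair within one record are
#' condensed by \code{condense_group}, records sharing a bead pair are
#' averaged by \code{aggregate_bead_pair}, and the bounds r0/r1/r2 are
#' shifted by the bead-geometry offset (D' - d_ij, averaged the same way) so
#' the flat-bottom width is preserved.
#'
#' @param atomistic reference \code{atomistic_structure}.
#' @param mapping a \code{mapping_table}.
#' @param cg the CG structure the restraints act on.
#' @param noe a \code{noe_table}.
#' @param k_noe force constant (kJ/mol/nm^2).
#' @return a \code{cg_restraints} data.frame (one row per bead pair).
#' @export
build_cg_restraints <- function(atomistic, mapping, cg, noe, k_noe = 25) {
  acc <- list()  # key -> list of (Dhat, r0, r1, r2)
  for (r in seq_len(nrow(noe))) {
    ai <- split_atoms(noe$atoms_i[r]); aj <- split_atoms(noe$atoms_j[r])
    ri <- which(atomistic$atoms$chain == noe$chain_i[r] &
                  atomistic$atoms$resid == noe$resid_i[r])[1]
    rj <- which(atomistic$atoms$chain == noe$chain_j[r] &
                  atomistic$atoms$resid == noe$resid_j[r])[1]
    stopif(is.na(ri) || is.na(rj), "NOE record references an absent residue")
    rti <- atomistic$atoms$restype[ri]; rtj <- atomistic$atoms$restype[rj]
    per_pair <- list()  # bead-pair key -> list(D = c(), rat = c())
    for (a in ai) for (b in aj) {
      bi <- resolve_bead(cg, mapping, noe$chain_i[r], noe$resid_i[r], rti, a)
      bj <- resolve_bead(cg, mapping, noe$chain_j[r], noe$resid_j[r], rtj, b)
      if (bi == bj) next
      pa <- atom_coord(atomistic, noe$chain_i[r], noe$resid_i[r], a)
      pb <- atom_coord(atomistic, noe$chain_j[r], noe$resid_j[r], b)
      D <- map_atom_pair(cg$coords[bi, ], cg$coords[bj, ], pa, pb, noe$d[r])
      key <- paste(min(bi, bj), max(bi, bj))
      per_pair[[key]] <- list(D = c(per_pair[[key]]$D, D),
                              rat = c(per_pair[[key]]$rat, vnorm(pa - pb)))
    }
    for (key in names(per_pair)) {
      Dhat <- condense_group(per_pair[[key]]$D, per_pair[[key]]$rat)
      acc[[key]] <- append(acc[[key]] %||% list(),
                           list(list(Dhat = Dhat, d = noe$d[r], r0 = noe$r0[r],
                                     r1 = noe$r1[r], r2 = noe$r2[r])))
    }
  }
  stopif(length(acc) == 0, "no restraints could be built")
  rows <- lapply(names(acc), function(key) {
    sig <- acc[[key]]
    Dp <- aggregate_bead_pair(vapply(sig, `[[`, numeric(1), "Dhat"))
    # additive bead-geometry offset, averaged over the contributing records
    off <- mean(vapply(sig, function(s) s$Dhat - s$d, numeric(1)))
    beads <- as.integer(strsplit(key, " ")[[1]])
    data.frame(bead_i = beads[1], bead_j = beads[2],
               r0 = max(0, mean(vapply(sig, `[[`, numeric(1), "r0")) + off),
               r1 = mean(vapply(sig, `[[`, numeric(1), "r1")) + off,
               r2 = mean(vapply(sig, `[[`, numeric(1), "r2")) + off,
               d = Dp, k_noe = k_noe)
  })
  cg_restraints(do.call(rbind, rows))
}

#' Torda-van Gunsteren restraint energy at distance r
#'
#' Harmonic below r0, zero on [r0, r1), harmonic on [r1, r2), and linear with
#' constant slope K (r2 - r1) at and beyond r2 (continuous and C1 at all
#' three knots).
#'
#' @param r bead-pair distance (nm, may be a vector).
#' @param restraint one-row \code{cg_restraints} entry (or a list with r0,
#'   r1, r2, k_noe).
#' @return energy in kJ/mol.
#' @export
noe_energy <- function(r, restraint) {
  K <- restraint$k_noe; r0 <- restraint$r0; r1 <- restraint$r1; r2 <- restraint$r2
  ifelse(r < r0, 0.5 * K * (r - r0)^2,
  ifelse(r < r1, 0,
  ifelse(r < r2, 0.5 * K * (r - r1)^2,
         0.5 * K * (r2 - r1) * (2 * r - r2 - r1))))
}

#' Instantaneous restraint force magnitude (signed, along the bead axis)
#'
#' Returns -dV/dr: positive values push the beads apart (r < r0), negative
#' values pull them together (r > r1); the pull saturates at K (r2 - r1).
#'
#' @inheritParams noe_energy
#' @return signed force magnitude (kJ/mol/nm).
#' @export
noe_force_scalar <- function(r, restraint) {
  K <- restraint$k_noe; r0 <- restraint$r0; r1 <- restraint$r1; r2 <- restraint$r2
  ifelse(r < r0, -K * (r - r0),
  ifelse(r < r1, 0,
  ifelse(r < r2, -K * (r - r1), -K * (r2 - r1))))
}

#' Initialize time-averaging state for a restraint
#'
#' @param r initial bead-pair distance (nm); the running average starts here.
#' @param tau memory decay time (ps, default 0.05).
#' @param ramp_tau force-constant ramp time (ps, default \code{tau}).
#' @return list of class \code{noe_timeavg_state}.
#' @export
noe_timeavg_state <- function(r, tau = 0.05, ramp_tau = tau) {
  stopif(r <= 0, "initial distance must be positive")
  structure(list(rbar = r, tau = tau, ramp_tau = ramp_tau, t = 0),
            class = "noe_timeavg_state")
}

#' Time-averaged NOE restraint force
#'
#' The running average evolves in r^-3 space with memory exp(-dt/tau):
#' rbar(t) = [exp(-dt/tau) rbar(t-dt)^-3 + (1-exp(-dt/tau)) r(t)^-3]^(-1/3).
#' The force is nonzero only when the instantaneous and averaged distances
#' violate the same bound: below r0 (both) it pushes outward with magnitude
#' K^t (r0 - r); above r1 (both) it pulls inward with magnitude
#' K^t min(r - r1, r2 - r1) (\code{cap_mode = "linear"}, the default) or
#' K^t min((r - r1)(rbar - r1), r2 - r1) (\code{cap_mode = "product"},
#' the literal mixed-unit form). The ramped constant is
#' K^t = K (1 - exp(-t/ramp_tau)) with t the elapsed simulation time.
#'
#' @param state a \code{noe_timeavg_state}.
#' @param r current bead-pair distance (nm).
#' @param dt time step (ps, > 0).
#' @param restraint restraint row (r0, r1, r2, k_noe).
#' @param cap_mode "linear" or "product" (see above).
#' @return list: \code{force} signed scalar along the bead axis (positive =
#'   push apart), \code{state} updated state, \code{k_t} the ramped constant.
#' @export
noe_timeavg_force <- function(state, r, dt, restraint, cap_mode = c("linear", "product")) {
  cap_mode <- match.arg(cap_mode)
  stopif(dt <= 0, "dt must be positive")
  stopif(state$rbar <= 0, "running-average state corrupted (rbar <= 0)")
  w <- exp(-dt / state$tau)
  rbar <- (w * state$rbar^-3 + (1 - w) * r^-3)^(-1 / 3)
  state$rbar <- rbar
  state$t <- state$t + dt
  k_t <- restraint$k_noe * (1 - exp(-state$t / state$ramp_tau))
  r0 <- restraint$r0; r1 <- restraint$r1; r2 <- restraint$r2
  force <- 0
  if (r < r0 && rbar < r0) {
    force <- k_t * (r0 - r)
  } else if (r > r1 && rbar > r1) {
    mag <- if (cap_mode == "linear") min(r - r1, r2 - r1)
           else min((r - r1) * (rbar - r1), r2 - r1)
    force <- -k_t * mag
  }
  list(force = force, state = state, k_t = k_t)
}

#' NOE restraints as an engine force provider
#'
#' Instantaneous mode integrates the Torda-van Gunsteren potential exactly
#' (forces are -grad V); time-averaged mode applies
#' \code{\link{noe_timeavg_force}} per restraint, carrying the running
#' averages and the K ramp across steps (the reported energy is the
#' instantaneous potential for bookkeeping).
#'
#' @param restraints a \code{cg_restraints} table.
#' @param time_averaged logical.
#' @param dt time step used to advance the averaging state (ps).
#' @param tau,ramp_tau averaging and ramp time constants (ps).
#' @param cap_mode see \code{\link{noe_timeavg_force}}.
#' @return a force provider.
#' @export
noe_restraint_provider <- function(restraints, time_averaged = FALSE,
                                   dt = 0.01, tau = 0.05, ramp_tau = tau,
                                   cap_mode = "linear") {
  states <- NULL
  list(
    name = "noe_restraint",
    bind = function(structure) NULL,
    eval = function(coords, step) {
      n <- nrow(coords)
      F <- matrix(0, n, 3)
      E <- 0
      for (k in seq_len(nrow(restraints))) {
        bi <- restraints$bead_i[k]; bj <- restraints$bead_j[k]
        dvec <- coords[bj, ] - coords[bi, ]
        r <- vnorm(dvec)
        u <- dvec / r
        E <- E + noe_energy(r, restraints[k, ])
        if (time_averaged) {
          if (is.null(states)) states <<- vector("list", nrow(restraints))
          if (is.null(states[[k]])) states[[k]] <<- noe_timeavg_state(r, tau, ramp_tau)
          out <- noe_timeavg_force(states[[k]], r, dt, restraints[k, ], cap_mode)
          states[[k]] <<- out$state
          fmag <- out$force
        } else {
          fmag <- noe_force_scalar(r, restraints[k, ])
        }
        # fmag > 0 pushes apart: force on j along +u, on i along -u
        F[bj, ] <- F[bj, ] + fmag * u
        F[bi, ] <- F[bi, ] - fmag * u
      }
      list(energy = E, forces = F)
    })
}
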