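# Minimal CG simulation core. A force provider is a list with fields
#   name : character
#   bind : optional function(structure) called once before a run
#   eval : function(coords, step) -> list(energy kJ/mol, forces n x 3)
# Forces must be -grad(energy) (checked by finite differences in tests).
# Units: nm / ps / u / kJ/mol; k_B = 0.0083144621 kJ/(mol K).

#' Create a simulation state
#'
#' Velocities are drawn from the Maxwell-Boltzmann distribution at
#' \code{temperature} (zero when \code{temperature = 0}).
#'
#' @param structure a \code{cg_structure} (or a bare coordinate matrix).
#' @param masses per-bead masses (u); default 72 (the common CG bead mass).
#' @param temperature K.
#' @param seed RNG seed owning all stochastic elements of the run.
#' @return list of class \code{sim_state}.
#' @export
sim_state <- function(structure, masses = 72, temperature = 300, seed = 1) {
  coords <- if (inherits(structure, "cg_structure")) structure$coords
            else as.matrix(structure)
  n <- nrow(coords)
  masses <- rep_len(masses, n)
  stopif(any(masses <= 0), "masses must be positive")
  vel <- with_seed(seed, {
    if (temperature > 0) {
      sd <- sqrt(KB * temperature / masses)
      matrix(stats::rnorm(n * 3), n, 3) * sd
    } else matrix(0, n, 3)
  })
  structure(list(
    structure = if (inherits(structure, "cg_structure")) structure else NULL,
    coords = coords, velocities = vel, masses = masses, step = 0L,
    temperature = temperature, seed = seed), class = "sim_state")
}

eval_providers <- function(providers, coords, step) {
  E <- 0
  F <- matrix(0, nrow(coords), 3)
  per <- numeric(length(providers))
  for (p in seq_along(providers)) {
    out <- providers[[p]]$eval(coords, step)
    stopif(any(!is.finite(out$forces)) || !is.finite(out$energy),
           sprintf("provider '%s' returned non-finite values at step %d",
                   providers[[p]]$name %||% p, step))
    E <- E + out$energy
    F <- F + out$forces
    per[p] <- out$energy
  }
  list(energy = E, forces = F, per_provider = per)
}

bind_providers <- function(providers, state) {
  for (p in providers) {
    if (!is.null(p$bind) && !is.null(state$structure)) p$bind(state$structure)
  }
  invisible(NULL)
}

#' Toy CG force field
#'
#' A desk-scale bonded stand-in for a full CG potential: harmonic BB-BB
#' bonds along each chain (b0 = 0.35 nm, k = 5000 kJ/mol/nm^2), harmonic
#' BB-BB-BB angles (theta0 = 127 deg, k = 25 kJ/mol/rad^2), harmonic BB-SC1
#' bonds with equilibrium lengths taken from the input geometry, and a
#' purely repulsive harmonic excluded-volume term 0.5 k_rep (sigma - r)^2
#' for non-bonded pairs closer than sigma = 0.4 nm.
#'
#' @param structure the \code{cg_structure} defining the topology (and the
#'   BB-SC1 reference lengths).
#' @param params optional overrides: bond_b0, bond_k, angle_theta0 (rad),
#'   angle_k, sc_bond_k, sigma, k_rep.
#' @return a force provider.
#' @export
toy_forcefield <- function(structure, params = list()) {
  p <- utils::modifyList(list(bond_b0 = 0.35, bond_k = 5000,
                              angle_theta0 = 127 * pi / 180, angle_k = 25,
                              sc_bond_k = 5000, sigma = 0.4, k_rep = 500),
                         params)
  n_res <- nrow(structure$residues)
  bb <- cg_bb_indices(structure)
  chain <- structure$residues$chain
  bonds <- list()   # (i, j, b0, k)
  angles <- list()  # (i, j, k)
  for (i in seq_len(n_res - 1)) {
    if (chain[i] == chain[i + 1]) {
      bonds[[length(bonds) + 1]] <- c(bb[i], bb[i + 1], p$bond_b0, p$bond_k)
    }
  }
  for (i in seq_len(max(n_res - 2, 0))) {
    if (chain[i] == chain[i + 1] && chain[i + 1] == chain[i + 2]) {
      angles[[length(angles) + 1]] <- c(bb[i], bb[i + 1], bb[i + 2])
    }
  }
  for (i in seq_len(n_res)) {
    sc <- cg_bead_index(structure, i, "SC1")
    if (!is.na(sc)) {
      b0 <- vnorm(structure$coords[sc, ] - structure$coords[bb[i], ])
      bonds[[length(bonds) + 1]] <- c(bb[i], sc, b0, p$sc_bond_k)
    }
  }
  bonded <- matrix(FALSE, nrow(structure$coords), nrow(structure$coords))
  for (b in bonds) bonded[b[1], b[2]] <- bonded[b[2], b[1]] <- TRUE
  list(
    name = "toy_forcefield",
    eval = function(coords, step) {
      nb <- nrow(coords)
      E <- 0
      F <- matrix(0, nb, 3)
      for (b in bonds) {
        dvec <- coords[b[2], ] - coords[b[1], ]
        r <- vnorm(dvec)
        E <- E + 0.5 * b[4] * (r - b[3])^2
        f <- -b[4] * (r - b[3]) * dvec / r
        F[b[2], ] <- F[b[2], ] + f
        F[b[1], ] <- F[b[1], ] - f
      }
      for (a in angles) {
        th <- vec_angle(coords[a[1], ], coords[a[2], ], coords[a[3], ])
        g <- angle_gradient(coords[a[1], ], coords[a[2], ], coords[a[3], ])
        dth <- th - p$angle_theta0
        E <- E + 0.5 * p$angle_k * dth^2
        for (q in 1:3) F[a[q], ] <- F[a[q], ] - p$angle_k * dth * g[q, ]
      }
      # excluded volume over non-bonded pairs
      if (nb > 1) {
        for (i in seq_len(nb - 1)) {
          dvec <- sweep(coords[(i + 1):nb, , drop = FALSE], 2, coords[i, ])
          r <- sqrt(rowSums(dvec^2))
          close <- which(r < p$sigma & !bonded[i, (i + 1):nb])
          for (cidx in close) {
            j <- i + cidx
            rr <- r[cidx]
            E <- E + 0.5 * p$k_rep * (p$sigma - rr)^2
            f <- p$k_rep * (p$sigma - rr) * dvec[cidx, ] / rr
            F[j, ] <- F[j, ] + f
            F[i, ] <- F[i, ] - f
          }
        }
      }
      list(energy = E, forces = F)
    })
}

#' Flat-bottom upper-wall restraint on one bead's z coordinate
#'
#' Zero below \code{z_max}; 0.5 k (z - z_max)^2 above (continuous force at
#' the wall).
#'
#' @param bead global bead index.
#' @param z_max wall position (nm).
#' @param k force constant (kJ/mol/nm^2, >= 0).
#' @return a force provider.
#' @export
z_flat_bottom_restraint <- function(bead, z_max, k) {
  stopif(k < 0, "k must be non-negative")
  list(
    name = "z_wall",
    eval = function(coords, step) {
      F <- matrix(0, nrow(coords), 3)
      dz <- coords[bead, 3] - z_max
      E <- 0
      if (dz > 0) {
        E <- 0.5 * k * dz^2
        F[bead, 3] <- -k * dz
      }
      list(energy = E, forces = F)
    })
}

#' Harmonic positional restraint provider
#'
#' 0.5 k |x - x_ref|^2 summed over the selected beads (used for restrained
#' equilibration stages).
#'
#' @param ref_coords reference coordinate matrix (nm).
#' @param k force constant (kJ/mol/nm^2).
#' @param selection bead indices (default all).
#' @return a force provider.
#' @export
position_restraint <- function(ref_coords, k, selection = NULL) {
  sel <- selection %||% seq_len(nrow(ref_coords))
  list(
    name = "position_restraint",
    eval = function(coords, step) {
      d <- coords[sel, , drop = FALSE] - ref_coords[sel, , drop = FALSE]
      F <- matrix(0, nrow(coords), 3)
      F[sel, ] <- -k * d
      list(energy = 0.5 * k * sum(d^2), forces = F)
    })
}

#' Steepest-descent energy minimization
#'
#' Adaptive step length: grow by 1.2 on acceptance, halve on an energy
#' increase. Stops when the maximum force norm falls below \code{tol} or at
#' \code{max_steps}. Energy is monotone non-increasing across accepted moves.
#'
#' @param state a \code{sim_state}.
#' @param providers list of force providers.
#' @param max_steps iteration cap (default 1000).
#' @param tol force-norm convergence threshold (kJ/mol/nm, default 10).
#' @param step0 initial displacement of the largest force (nm).
#' @return updated \code{sim_state} (velocities untouched) with attributes
#'   \code{n_steps} and \code{energy}.
#' @export
minimize <- function(state, providers, max_steps = 1000, tol = 10,
                     step0 = 0.01) {
  bind_providers(providers, state)
  x <- state$coords
  cur <- eval_providers(providers, x, state$step)
  stopif(!is.finite(cur$energy), "non-finite starting energy")
  h <- step0
  taken <- 0
  for (it in seq_len(max_steps)) {
    fmax <- sqrt(max(rowSums(cur$forces^2)))
    if (fmax < tol) break
    trial <- x + cur$forces * (h / fmax)
    nxt <- tryCatch(eval_providers(providers, trial, state$step),
                    error = function(e) list(energy = Inf))
    if (is.finite(nxt$energy) && nxt$energy <= cur$energy) {
      x <- trial; cur <- nxt; h <- h * 1.2; taken <- taken + 1
    } else {
      h <- h / 2
      if (h < 1e-10) break
    }
  }
  state$coords <- x
  attr(state, "n_steps") <- taken
  attr(state, "energy") <- cur$energy
  state
}

# precomputed Langevin (BAOAB) coefficients
baoab_coeffs <- function(dt, gamma, temperature, masses) {
  c1 <- exp(-gamma * dt)
  list(c1 = c1, c2 = sqrt((1 - c1^2) * KB * temperature / masses))
}

#' One BAOAB Langevin step
#'
#' Splitting B(dt/2) A(dt/2) O(dt) A(dt/2) B(dt/2); the O block is the exact
#' Ornstein-Uhlenbeck velocity update. Deterministic given the RNG state.
#'
#' @param state a \code{sim_state}.
#' @param providers list of force providers.
#' @param dt time step (ps, default 0.01 = 10 fs).
#' @param gamma friction coefficient (1/ps, default 0.01).
#' @param temperature K (default the state's temperature).
#' @param forces optional cached forces for the current coordinates.
#' @return updated \code{sim_state}; attribute \code{forces} caches the
#'   forces at the new coordinates.
#' @export
langevin_step <- function(state, providers, dt = 0.01, gamma = 0.01,
                          temperature = state$temperature, forces = NULL) {
  cf <- baoab_coeffs(dt, gamma, temperature, state$masses)
  if (is.null(forces)) {
    forces <- eval_providers(providers, state$coords, state$step)$forces
  }
  v <- state$velocities + forces * (dt / 2) / state$masses
  x <- state$coords + v * (dt / 2)
  xi <- matrix(stats::rnorm(length(v)), nrow(v), 3)
  v <- cf$c1 * v + cf$c2 * xi
  x <- x + v * (dt / 2)
  new_forces <- eval_providers(providers, x, state$step + 1L)$forces
  v <- v + new_forces * (dt / 2) / state$masses
  state$coords <- x
  state$velocities <- v
  state$step <- state$step + 1L
  attr(state, "forces") <- new_forces
  state
}

#' Instantaneous kinetic temperature of a state
#' @param state a \code{sim_state}
#' @return temperature in K
#' @export
kinetic_temperature <- function(state) {
  sum(state$masses * rowSums(state$velocities^2)) /
    (3 * nrow(state$coords) * KB)
}

#' Run Langevin dynamics with per-step restraint schedules
#'
#' Providers that own a ramp (for example \code{cs_restraint_provider})
#' receive the global step index at every evaluation, so their schedules are
#' applied per integration step. Frames (and per-provider energy rows) are
#' recorded every \code{report_every} steps, starting with the initial state.
#'
#' @param state a \code{sim_state}.
#' @param providers list of force providers.
#' @param n_steps number of integration steps (0 gives a single-frame
#'   trajectory of the initial state).
#' @param report_every frame interval in steps (default 100).
#' @param dt,gamma,temperature integrator parameters (defaults 0.01 ps,
#'   0.01 1/ps, the state's temperature).
#' @return a \code{trajectory}; attribute \code{report} holds a data.frame
#'   (step, time_ps, energy per provider, total, kinetic_temperature, and
#'   k_cs for providers exposing \code{k_at}).
#' @export
run_dynamics <- function(state, providers, n_steps, report_every = 100,
                         dt = 0.01, gamma = 0.01,
                         temperature = state$temperature) {
  bind_providers(providers, state)
  frames <- list(state$coords)
  report <- list()
  record <- function(step, per, total) {
    row <- as.list(per)
    names(row) <- vapply(seq_along(providers),
                         function(p) providers[[p]]$name %||% paste0("p", p),
                         character(1))
    row$total <- total
    row$step <- step
    row$time_ps <- step * dt
    row$kinetic_temperature <- kinetic_temperature(state)
    for (p in providers) {
      if (!is.null(p$k_at)) row$k_cs <- p$k_at(step)
    }
    report[[length(report) + 1]] <<- as.data.frame(row)
  }
  ev <- eval_providers(providers, state$coords, state$step)
  record(state$step, ev$per_provider, ev$energy)
  cached <- ev$forces
  out <- with_seed(state$seed + 1e6, {
    for (s in seq_len(n_steps)) {
      state <- langevin_step(state, providers, dt = dt, gamma = gamma,
                             temperature = temperature, forces = cached)
      cached <- attr(state, "forces")
      if (s %% report_every == 0 || s == n_steps) {
        frames[[length(frames) + 1]] <- state$coords
        ev <- eval_providers(providers, state$coords, state$step)
        record(state$step, ev$per_provider, ev$energy)
      }
    }
    state
  })
  template <- out$structure %||% cg_structure(
    data.frame(chain = "A", resid = seq_len(nrow(out$coords)),
               restype = "GLY", stringsAsFactors = FALSE),
    seq_len(nrow(out$coords)), rep("BB", nrow(out$coords)), out$coords)
  tr <- trajectory(template, frames, frame_spacing = report_every * dt)
  attr(tr, "report") <- do.call(rbind, report)
  attr(tr, "final_state") <- out
  tr
}
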