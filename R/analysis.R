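# Ensemble metrics. Each function is a pure function of trajectories /
# coordinate ensembles; nothing here mutates engine state.

# Kabsch superposition: rotate+translate `mobile` onto `ref` using the rows
# in `sel`; returns the transformed full coordinate set
align_coords <- function(mobile, ref, sel) {
  pm <- mobile[sel, , drop = FALSE]
  pr <- ref[sel, , drop = FALSE]
  cm <- colMeans(pm); cr <- colMeans(pr)
  H <- t(sweep(pm, 2, cm)) %*% sweep(pr, 2, cr)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, cr, `+`)
}

frames_of <- function(ensemble) {
  if (inherits(ensemble, "trajectory")) ensemble$frames
  else if (is.list(ensemble)) ensemble
  else list(as.matrix(ensemble))
}

#' Per-frame coordinate RMSD to a reference after optimal superposition
#'
#' Each frame is rigid-body aligned to the reference on the selection
#' (Kabsch), then the RMSD over the selected beads is computed.
#'
#' @param ensemble a \code{trajectory} or list of coordinate matrices.
#' @param reference coordinate matrix (or \code{cg_structure}).
#' @param selection bead indices used for alignment and RMSD (default all;
#'   at least 3).
#' @return numeric vector of per-frame RMSD (nm).
#' @export
rmsd_coords <- function(ensemble, reference, selection = NULL) {
  ref <- if (inherits(reference, "cg_structure")) reference$coords else as.matrix(reference)
  sel <- selection %||% seq_len(nrow(ref))
  stopif(length(sel) < 3, "need at least 3 beads in the selection")
  vapply(frames_of(ensemble), function(fr) {
    al <- align_coords(as.matrix(fr), ref, sel)
    sqrt(mean(rowSums((al[sel, , drop = FALSE] - ref[sel, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Per-bead root-mean-square fluctuation
#'
#' Frames are aligned to the first frame on the selection; the RMSF of each
#' selected bead is the square root of its mean squared deviation from its
#' mean position.
#'
#' @param ensemble a \code{trajectory} or list of >= 2 coordinate matrices.
#' @param selection bead indices (default all).
#' @param align bead indices used for the superposition (default
#'   \code{selection}).
#' @return numeric vector, one value per selected bead (nm).
#' @export
rmsf <- function(ensemble, selection = NULL, align = NULL) {
  fr <- frames_of(ensemble)
  stopif(length(fr) < 2, "RMSF needs at least 2 frames")
  ref <- as.matrix(fr[[1]])
  sel <- selection %||% seq_len(nrow(ref))
  alsel <- align %||% sel
  al <- lapply(fr, function(f) align_coords(as.matrix(f), ref, alsel)[sel, , drop = FALSE])
  arr <- simplify2array(al)                      # beads x 3 x frames
  mu <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mu)^2
  sqrt(apply(dev2, 1, mean) * 3)                 # mean over 3*frames entries * 3
}

# all defined backbone dihedral quadruples (consecutive BB beads per chain)
bb_dihedral_quads <- function(structure) {
  bb <- cg_bb_indices(structure)
  ch <- structure$residues$chain
  quads <- list()
  for (i in seq_len(max(length(bb) - 3, 0))) {
    if (length(unique(ch[i:(i + 3)])) == 1) {
      quads[[length(quads) + 1]] <- bb[i:(i + 3)]
    }
  }
  quads
}

wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Per-frame backbone dihedral RMSD to a reference (degrees)
#'
#' RMSD over all defined backbone dihedrals, with differences wrapped
#' periodically into (-180, 180].
#'
#' @param ensemble a \code{trajectory}.
#' @param reference coordinate matrix (default the trajectory template).
#' @return numeric vector of per-frame dihedral RMSD (degrees).
#' @export
dihedral_rmsd <- function(ensemble, reference = NULL) {
  stopif(!inherits(ensemble, "trajectory"), "dihedral_rmsd needs a trajectory")
  quads <- bb_dihedral_quads(ensemble$structure)
  stopif(length(quads) == 0, "no backbone dihedrals defined")
  ref <- reference %||% ensemble$structure$coords
  dih_set <- function(coords) {
    vapply(quads, function(q)
      vec_dihedral(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ]) *
        180 / pi, numeric(1))
  }
  ref_d <- dih_set(as.matrix(ref))
  vapply(ensemble$frames, function(fr) {
    d <- wrap_deg(dih_set(as.matrix(fr)) - ref_d)
    sqrt(mean(d^2))
  }, numeric(1))
}

#' Pseudo-Ramachandran samples: (theta1, theta2) per residue per frame
#'
#' Residues whose theta1 or theta2 is masked (chain ends) are excluded.
#'
#' @param ensemble a \code{trajectory}.
#' @return data.frame (frame, residue, theta1, theta2) in degrees.
#' @export
pseudo_ramachandran <- function(ensemble) {
  stopif(!inherits(ensemble, "trajectory"), "needs a trajectory")
  s <- ensemble$structure
  rows <- list()
  for (f in seq_along(ensemble$frames)) {
    sf <- set_coords(s, ensemble$frames[[f]])
    for (i in seq_len(nrow(s$residues))) {
      a <- residue_angles(sf, i)
      if (a$mask["theta1"] && a$mask["theta2"]) {
        rows[[length(rows) + 1]] <- data.frame(
          frame = f, residue = i,
          theta1 = a$theta1 * 180 / pi, theta2 = a$theta2 * 180 / pi)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(frame = integer(), residue = integer(),
                      theta1 = numeric(), theta2 = numeric()))
  }
  do.call(rbind, rows)
}

#' Pairwise-distance distribution similarity matrix (S-matrix)
#'
#' For each residue pair (i, j), the backbone-bead distance is histogrammed
#' over fixed shared bins for both ensembles and S_ij is the L1 distance
#' between the two normalized histograms: 0 for identical distributions,
#' 2 for disjoint supports.
#'
#' @param ens_a,ens_b \code{trajectory} objects with the same residue count.
#' @param breaks histogram breaks (nm); default fixed 0.1 nm bins over
#'   [0, joint max + 0.1]. Breaks that do not cover the data are an error.
#' @return list of class \code{s_matrix}: \code{S} (N x N), \code{breaks}.
#' @export
s_matrix <- function(ens_a, ens_b, breaks = NULL) {
  bb_a <- cg_bb_indices(ens_a$structure)
  bb_b <- cg_bb_indices(ens_b$structure)
  stopif(length(bb_a) != length(bb_b), "ensembles map to different residue counts")
  n <- length(bb_a)
  dists <- function(frames, bb) {
    lapply(frames, function(fr) as.matrix(stats::dist(as.matrix(fr)[bb, , drop = FALSE])))
  }
  da <- dists(ens_a$frames, bb_a)
  db <- dists(ens_b$frames, bb_b)
  if (is.null(breaks)) {
    mx <- max(vapply(c(da, db), max, numeric(1)))
    breaks <- seq(0, mx + 0.1, by = 0.1)
  }
  rng <- range(breaks)
  allv <- unlist(lapply(c(da, db), function(m) m[upper.tri(m)]))
  stopif(any(allv < rng[1] | allv > rng[2]),
         "histogram breaks do not cover the observed distances")
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ha <- vapply(da, function(m) m[i, j], numeric(1))
      hb <- vapply(db, function(m) m[i, j], numeric(1))
      pa <- graphics::hist(ha, breaks = breaks, plot = FALSE)$counts
      pb <- graphics::hist(hb, breaks = breaks, plot = FALSE)$counts
      S[i, j] <- S[j, i] <- sum(abs(pa / sum(pa) - pb / sum(pb)))
    }
  }
  structure(list(S = S, breaks = breaks), class = "s_matrix")
}

angle_between <- function(a, b) {
  acos(max(-1, min(1, sum(a * b) / (vnorm(a) * vnorm(b))))) * 180 / pi
}

#' Helix tilt (tau) and bundle splay (omega) angles
#'
#' Per helix i, h_TMi = end bead - start bead. The bundle vector follows the
#' start-minus-end convention: h_bundle = mean(start) - mean(end), which is
#' antiparallel to the individual helix vectors; for a single ideal helix
#' omega is therefore 180 degrees. tau is the mean angle between the
#' membrane normal b0 and the helix vectors; omega the mean angle between
#' h_bundle and the helix vectors.
#'
#' @param ensemble a \code{trajectory} or list of coordinate matrices.
#' @param spec list: \code{helices} = list of c(start_bead, end_bead);
#'   \code{b0} = membrane normal (unit 3-vector).
#' @return data.frame (frame, tau, omega) in degrees.
#' @export
tau_omega <- function(ensemble, spec) {
  stopif(length(spec$helices) < 1, "need at least one helix")
  b0 <- unitv(spec$b0)
  fr <- frames_of(ensemble)
  out <- lapply(seq_along(fr), function(f) {
    x <- as.matrix(fr[[f]])
    hv <- lapply(spec$helices, function(h) {
      v <- x[h[2], ] - x[h[1], ]
      stopif(vnorm(v) < 1e-9, "zero-length helix vector")
      v
    })
    starts <- do.call(rbind, lapply(spec$helices, function(h) x[h[1], ]))
    ends <- do.call(rbind, lapply(spec$helices, function(h) x[h[2], ]))
    hb <- colMeans(starts) - colMeans(ends)
    data.frame(frame = f,
               tau = mean(vapply(hv, angle_between, numeric(1), b = b0)),
               omega = mean(vapply(hv, angle_between, numeric(1), a = hb)))
  })
  do.call(rbind, out)
}

#' Free-energy profile from reaction-coordinate samples
#'
#' F_i = -k_B T ln(H_i) with H_i the normalized density in bin i; empty bins
#' give NA (masked), never +/-Inf. Bin errors come from n_bootstrap
#' resamples: sigma_i = k_B T (1 / mean_n H_ni) sqrt((1/(N-1)) (mean_n
#' H_ni^2 - (mean_n H_ni)^2)).
#'
#' @param samples reaction-coordinate values.
#' @param breaks histogram breaks covering the samples.
#' @param temperature K (> 0).
#' @param n_bootstrap number of bootstrap resamples (default 100).
#' @param seed bootstrap seed.
#' @return data.frame of class \code{free_energy_profile}: bin_center, F
#'   (kJ/mol), sigma, density.
#' @export
free_energy_profile <- function(samples, breaks, temperature,
                                n_bootstrap = 100, seed = 1) {
  stopif(length(samples) < 1, "need at least one sample")
  stopif(temperature <= 0, "temperature must be positive")
  dens <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }
  H <- dens(samples)
  Fv <- ifelse(H > 0, -KB * temperature * log(H), NA_real_)
  Hb <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b)
      dens(sample(samples, replace = TRUE)), numeric(length(H)))
  })
  mu <- rowMeans(Hb)
  msq <- rowMeans(Hb^2)
  N <- n_bootstrap
  sigma <- ifelse(mu > 0,
                  KB * temperature / mu * sqrt(pmax(msq - mu^2, 0) / (N - 1)),
                  NA_real_)
  centers <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  out <- data.frame(bin_center = centers, F = Fv, sigma = sigma, density = H)
  class(out) <- c("free_energy_profile", "data.frame")
  out
}

# min distance between the beads of residue i and residue j in one frame
min_res_dist <- function(coords, beads_i, beads_j) {
  m <- Inf
  for (a in beads_i) {
    d2 <- rowSums(sweep(coords[beads_j, , drop = FALSE], 2, coords[a, ])^2)
    m <- min(m, min(d2))
  }
  sqrt(m)
}

# transition-based event extraction from one distance series: open when
# d < r0, close when d next exceeds r1 (hysteresis); events still open at
# the series end are censored
lifetime_events <- function(d, dt, r0, r1) {
  open_at <- NA_integer_
  lifetimes <- numeric(0)
  censored <- 0L
  for (t in seq_along(d)) {
    if (is.na(open_at)) {
      if (d[t] < r0) open_at <- t
    } else if (d[t] > r1) {
      lifetimes <- c(lifetimes, (t - open_at) * dt)
      open_at <- NA_integer_
    }
  }
  if (!is.na(open_at)) censored <- 1L
  list(lifetimes = lifetimes, censored = censored)
}

#' Transition-based contact lifetimes
#'
#' A residue-residue contact opens when the minimum bead-pair distance drops
#' below r0 and closes the next time it rises above r1 (hysteresis); the
#' lifetime is the elapsed time between the two transitions. Contacts still
#' open at the trajectory end are censored and excluded from the means;
#' pairs that never form a contact are not included either.
#'
#' @param traj a \code{trajectory}.
#' @param pairs data.frame (res_i, res_j) of residue-row pairs to monitor.
#' @param r0 formation cutoff (nm, default 0.8).
#' @param r1 breaking cutoff (nm, default 1.0).
#' @return list: \code{events} data.frame (res_i, res_j, lifetime_ps),
#'   \code{censored} per-pair censored counts, \code{per_residue} named
#'   mean lifetime per residue over its formed contacts.
#' @export
contact_lifetimes <- function(traj, pairs, r0 = 0.8, r1 = 1.0) {
  dt <- traj$frame_spacing
  s <- traj$structure
  beads_of <- function(i) which(s$bead_residue == i)
  ev_rows <- list()
  cens <- integer(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    bi <- beads_of(pairs$res_i[p]); bj <- beads_of(pairs$res_j[p])
    d <- vapply(traj$frames, function(fr)
      min_res_dist(as.matrix(fr), bi, bj), numeric(1))
    ev <- lifetime_events(d, dt, r0, r1)
    cens[p] <- ev$censored
    if (length(ev$lifetimes) > 0) {
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        res_i = pairs$res_i[p], res_j = pairs$res_j[p],
        lifetime_ps = ev$lifetimes)
    }
  }
  events <- if (length(ev_rows) > 0) do.call(rbind, ev_rows)
            else data.frame(res_i = integer(), res_j = integer(),
                            lifetime_ps = numeric())
  res_ids <- sort(unique(c(events$res_i, events$res_j)))
  per_res <- vapply(res_ids, function(r)
    mean(events$lifetime_ps[events$res_i == r | events$res_j == r]), numeric(1))
  list(events = events, censored = cens,
       per_residue = stats::setNames(per_res, res_ids))
}

#' Per-bead diffusion coefficients from MSD linear fits
#'
#' Frames are aligned on the core selection, the per-bead MSD(tau) is
#' averaged over all time origins, and D = slope / 6 from a linear fit over
#' the stated window. A curvature check on log MSD vs log tau flags
#' superdiffusive (ballistic-like) beads with exponent > 1.5.
#'
#' @param traj a \code{trajectory} covering the fit window.
#' @param selection beads to analyze.
#' @param core alignment selection (default all beads); NA skips alignment
#'   (free diffusion in the lab frame).
#' @param lag_min minimum lag (ps, default 10).
#' @param fit_window c(min, max) lag window for the linear fit (ps, default
#'   c(100, 500)).
#' @return data.frame (bead, D_nm2_per_ps, pearson_r, alpha,
#'   superdiffusive).
#' @export
msd_diffusion <- function(traj, selection, core = NULL, lag_min = 10,
                          fit_window = c(100, 500)) {
  dt <- traj$frame_spacing
  nf <- length(traj$frames)
  stopif((nf - 1) * dt < fit_window[2], "trajectory does not cover the fit window")
  ref <- as.matrix(traj$frames[[1]])
  core <- core %||% seq_len(nrow(ref))
  al <- if (length(core) == 1 && is.na(core[1])) {
    lapply(traj$frames, as.matrix)
  } else {
    lapply(traj$frames, function(f) align_coords(as.matrix(f), ref, core))
  }
  lags <- seq(max(1, round(lag_min / dt)), floor(fit_window[2] / dt))
  msd_of <- function(bead) {
    pos <- t(vapply(al, function(f) f[bead, ], numeric(3)))
    vapply(lags, function(L) {
      d <- pos[(1 + L):nf, , drop = FALSE] - pos[1:(nf - L), , drop = FALSE]
      mean(rowSums(d^2))
    }, numeric(1))
  }
  taus <- lags * dt
  out <- lapply(selection, function(bead) {
    msd <- msd_of(bead)
    win <- taus >= fit_window[1] & taus <= fit_window[2]
    fit <- stats::lm(msd[win] ~ taus[win])
    rr <- suppressWarnings(stats::cor(taus[win], msd[win]))
    pos_ok <- msd > 0
    alpha <- if (sum(pos_ok) > 2) {
      unname(stats::coef(stats::lm(log(msd[pos_ok]) ~ log(taus[pos_ok])))[2])
    } else NA_real_
    data.frame(bead = bead,
               D_nm2_per_ps = max(unname(stats::coef(fit)[2]), 0) / 6,
               pearson_r = rr, alpha = alpha,
               superdiffusive = !is.na(alpha) && alpha > 1.5)
  })
  do.call(rbind, out)
}

#' Radial concentration profile around an attachment point
#'
#' c(r_i) = [C(r_i) - C(r_{i-1})] / [pi (r_i^2 - r_{i-1}^2) (1 - f)
#' (z_max - z_min)], where C(r) counts selected beads within xy-distance r
#' of the attachment point, averaged per frame; beads outside the z slab
#' are excluded, and f is the fraction of the annular area occupied by an
#' excluded structured core.
#'
#' @param traj a \code{trajectory}.
#' @param selection bead indices to count.
#' @param attachment xy attachment point (length-2 numeric).
#' @param z_range c(z_min, z_max) of the core slab (nm).
#' @param breaks radial bin edges (nm, increasing from 0).
#' @param excluded_fraction f in [0, 1) (default 0.5).
#' @return data.frame (r_inner, r_outer, concentration per nm^3).
#' @export
radial_profile <- function(traj, selection, attachment, z_range, breaks,
                           excluded_fraction = 0.5) {
  f <- excluded_fraction
  stopif(f < 0 || f >= 1, "excluded_fraction must be in [0, 1)")
  stopif(z_range[2] <= z_range[1], "bad z range")
  counts <- numeric(length(breaks) - 1)
  for (fr in traj$frames) {
    x <- as.matrix(fr)[selection, , drop = FALSE]
    keep <- x[, 3] >= z_range[1] & x[, 3] <= z_range[2]
    if (!any(keep)) next
    r <- sqrt((x[keep, 1] - attachment[1])^2 + (x[keep, 2] - attachment[2])^2)
    r <- r[r >= min(breaks) & r <= max(breaks)]
    counts <- counts + graphics::hist(r, breaks = breaks, plot = FALSE)$counts
  }
  counts <- counts / length(traj$frames)
  area <- pi * (utils::tail(breaks, -1)^2 - utils::head(breaks, -1)^2)
  conc <- counts / (area * (1 - f) * (z_range[2] - z_range[1]))
  data.frame(r_inner = utils::head(breaks, -1), r_outer = utils::tail(breaks, -1),
             concentration = conc)
}

#' Inter-layer twist angle of a layered assembly
#'
#' For successive layers i and i+1 with reference beads (a1, a2) and
#' (b1, b2) (the same two chains in each layer), the twist at that interface
#' is the dihedral over (a2, a1, b1, b2): the hinge runs along the fibril
#' axis (a1 to b1), so purely translated layers read 0 and layers rotated
#' by phi about the axis read phi. Layers whose reference beads are missing
#' (NA) are skipped with a warning.
#'
#' @param ensemble a \code{trajectory} or list of coordinate matrices.
#' @param layer_beads list of length-2 integer vectors, one per layer
#'   (reference bead in each of the layer's two chains).
#' @return list: \code{per_frame} mean twist per frame (degrees),
#'   \code{per_interface} frames x interfaces matrix.
#' @export
twist_angle <- function(ensemble, layer_beads) {
  stopif(length(layer_beads) < 2, "need at least 2 layers")
  ok <- vapply(layer_beads, function(b) length(b) == 2 && !any(is.na(b)), logical(1))
  fr <- frames_of(ensemble)
  interfaces <- which(ok[-length(ok)] & ok[-1])
  if (length(interfaces) < length(ok) - 1) {
    warning("skipping interfaces with missing reference beads")
  }
  stopif(length(interfaces) == 0, "no resolvable interfaces")
  per <- t(vapply(fr, function(f) {
    x <- as.matrix(f)
    vapply(interfaces, function(i) {
      a <- layer_beads[[i]]; b <- layer_beads[[i + 1]]
      vec_dihedral(x[a[2], ], x[a[1], ], x[b[1], ], x[b[2], ]) * 180 / pi
    }, numeric(1))
  }, numeric(length(interfaces))))
  if (length(interfaces) == 1) per <- matrix(per, ncol = 1)
  list(per_frame = rowMeans(per), per_interface = per)
}

# asymptotic Dickey-Fuller quantiles for the constant, no-trend case
ADF_P <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
ADF_Q <- c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root regression with a constant:
#' diff(y_t) = a + rho y_{t-1} + sum_i phi_i diff(y_{t-i}) + e_t, with the
#' t-statistic of rho compared to the asymptotic Dickey-Fuller distribution
#' (p-values by interpolation, clamped to [0.01, 0.99]). Small p-values
#' reject the unit root, i.e. indicate stationarity.
#'
#' @param x numeric time series (>= 20 points, non-constant).
#' @param lags number of augmentation lags (default
#'   \code{trunc((length(x) - 1)^(1/3))}).
#' @return list of class \code{adf_test}: statistic, p_value, lags.
#' @export
stationarity_test <- function(x, lags = NULL) {
  stopif(length(x) < 20, "ADF test needs at least 20 points")
  stopif(stats::sd(x) == 0, "degenerate input: constant series")
  k <- lags %||% trunc((length(x) - 1)^(1 / 3))
  dy <- diff(x)
  n <- length(dy)
  ylag <- x[seq_len(n)]
  if (k > 0) {
    dlags <- sapply(seq_len(k), function(i) c(rep(NA, i), dy[seq_len(n - i)]))
    df <- data.frame(dy = dy, ylag = ylag, dlags)
    fit <- stats::lm(dy ~ ., data = stats::na.omit(df))
  } else {
    fit <- stats::lm(dy ~ ylag)
  }
  tstat <- summary(fit)$coefficients["ylag", "t value"]
  p <- stats::approx(ADF_Q, ADF_P, xout = tstat, rule = 2)$y
  structure(list(statistic = unname(tstat), p_value = p, lags = k),
            class = "adf_test")
}

#' Representative frame of an ensemble via PCA
#'
#' Frames are aligned to the first frame, flattened, projected onto the
#' principal components, and the frame closest to the projected ensemble
#' mean is returned (ties break to the lowest index).
#'
#' @param ensemble a \code{trajectory} or list of >= 2 coordinate matrices.
#' @param n_components number of PCs to keep (default all informative).
#' @return frame index (1-based).
#' @export
representative_structure <- function(ensemble, n_components = NULL) {
  fr <- frames_of(ensemble)
  stopif(length(fr) < 2, "need at least 2 frames")
  ref <- as.matrix(fr[[1]])
  sel <- seq_len(nrow(ref))
  X <- t(vapply(fr, function(f) as.numeric(align_coords(as.matrix(f), ref, sel)),
                numeric(length(ref))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- n_components %||% ncol(pc$x)
  proj <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
  mu <- colMeans(proj)
  d2 <- rowSums(sweep(proj, 2, mu)^2)
  which.min(d2)  # which.min breaks ties to the lowest index
}
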