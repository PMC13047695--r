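# Bead-based angles, dihedrals and their analytic Cartesian gradients.
# All positions are 3-vectors in nm; angles in radians.

#' Interior angle at p2 formed by p1-p2-p3
#'
#' @param p1,p2,p3 numeric 3-vectors (nm).
#' @return angle in radians, in \code{[0, pi]}.
#' @export
vec_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- vnorm(u); nv <- vnorm(v)
  stopif(nu < 1e-9 || nv < 1e-9, "degenerate geometry: coincident points in angle()")
  ct <- sum(u * v) / (nu * nv)
  ct <- max(-1, min(1, ct))
  acos(ct)
}

#' Signed dihedral (torsion) angle over p1-p2-p3-p4
#'
#' Convention: cis (eclipsed) arrangements give 0, planar trans gives pi;
#' the sign flips under mirror reflection. Range \code{(-pi, pi]}.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (nm).
#' @return signed torsion in radians.
#' @export
vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  stopif(vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9,
         "degenerate geometry: collinear points in dihedral()")
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  phi <- atan2(y, x)
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

#' Gradient of the interior angle w.r.t. the three points
#'
#' @inheritParams vec_angle
#' @return 3x3 matrix; row k is d(angle)/d(p_k).
#' @export
angle_gradient <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- vnorm(u); nv <- vnorm(v)
  stopif(nu < 1e-9 || nv < 1e-9, "degenerate geometry in angle_gradient()")
  uh <- u / nu; vh <- v / nv
  ct <- max(-1, min(1, sum(uh * vh)))
  st <- sqrt(max(1 - ct^2, 0))
  stopif(st < 1e-8, "degenerate geometry: collinear points in angle_gradient()")
  g1 <- -(vh - ct * uh) / (nu * st)
  g3 <- -(uh - ct * vh) / (nv * st)
  g2 <- -(g1 + g3)
  rbind(g1, g2, g3, deparse.level = 0)
}

#' Gradient of the signed dihedral w.r.t. the four points
#'
#' @inheritParams vec_dihedral
#' @return 4x3 matrix; row k is d(phi)/d(p_k).
#' @export
dihedral_gradient <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  A <- cross3(b1, b2)
  B <- cross3(b2, b3)
  nA2 <- sum(A * A); nB2 <- sum(B * B)
  nb2 <- vnorm(b2)
  stopif(nA2 < 1e-18 || nB2 < 1e-18,
         "degenerate geometry in dihedral_gradient()")
  # Blondel & Karplus (1996) form
  g1 <- -(nb2 / nA2) * A
  g4 <- (nb2 / nB2) * B
  tA <- (sum(b1 * b2) / (nA2 * nb2)) * A
  tB <- (sum(b3 * b2) / (nB2 * nb2)) * B
  g2 <- -g1 + tA + tB
  g3 <- -g4 - tA - tB
  # sign matched to the atan2 convention of vec_dihedral
  -rbind(g1, g2, g3, g4, deparse.level = 0)
}

#' Backbone/side-chain angle set for one residue of a CG structure
#'
#' With BB(j) the backbone bead of residue j and SC1(j) the first side-chain
#' bead: beta = angle(BB(i-1), BB(i), BB(i+1)); alpha = angle(SC1(i), BB(i),
#' BB(i-1)); gamma = angle(SC1(i), BB(i), BB(i+1)); theta1 =
#' dihedral(BB(i-2), BB(i-1), BB(i), BB(i+1)); theta2 = dihedral(BB(i-1),
#' BB(i), BB(i+1), BB(i+2)). An angle whose beads do not exist (chain ends,
#' glycine without SC1) is masked: its value is NA and its mask entry FALSE.
#'
#' @param structure a \code{cg_structure}.
#' @param i residue position (row in \code{structure$residues}).
#' @return list with numeric fields alpha, beta, gamma, theta1, theta2 (NA
#'   when masked) and a logical \code{mask} vector (TRUE = available).
#' @export
residue_angles <- function(structure, i) {
  bb <- function(j) cg_bead_coord(structure, j, "BB")
  sc <- function(j) cg_bead_coord(structure, j, "SC1")
  same_chain <- function(j) {
    j >= 1 && j <= nrow(structure$residues) &&
      structure$residues$chain[j] == structure$residues$chain[i]
  }
  get_bb <- function(j) if (same_chain(j)) bb(j) else NULL
  get_sc <- function(j) if (same_chain(j)) sc(j) else NULL

  p_m2 <- get_bb(i - 2); p_m1 <- get_bb(i - 1)
  p_0  <- get_bb(i)
  p_p1 <- get_bb(i + 1); p_p2 <- get_bb(i + 2)
  s_0  <- get_sc(i)

  ang <- function(a, b, cc) if (is.null(a) || is.null(b) || is.null(cc)) NA_real_ else vec_angle(a, b, cc)
  dih <- function(a, b, cc, d) if (is.null(a) || is.null(b) || is.null(cc) || is.null(d)) NA_real_ else vec_dihedral(a, b, cc, d)

  out <- list(
    alpha  = ang(s_0, p_0, p_m1),
    beta   = ang(p_m1, p_0, p_p1),
    gamma  = ang(s_0, p_0, p_p1),
    theta1 = dih(p_m2, p_m1, p_0, p_p1),
    theta2 = dih(p_m1, p_0, p_p1, p_p2)
  )
  out$mask <- !vapply(out[c("alpha", "beta", "gamma", "theta1", "theta2")],
                      is.na, logical(1))
  out
}
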