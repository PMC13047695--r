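# Core containers. A cg_structure holds an ordered residue table plus a flat
# bead array; beads are addressed by (residue row, bead name). Coordinates are
# nm everywhere in memory; PDB files on disk are Angstrom.

#' Construct a coarse-grained structure
#'
#' @param residues data.frame with columns chain, resid (1-based, strictly
#'   increasing within a chain), restype (3-letter code; 20 standard plus
#'   CYO and PRC).
#' @param bead_residue integer vector, one entry per bead: row index into
#'   \code{residues}.
#' @param bead_name character vector, one of BB, SC1..SC4.
#' @param coords numeric matrix (n_beads x 3), nm.
#' @return object of class \code{cg_structure}.
#' @export
cg_structure <- function(residues, bead_residue, bead_name, coords) {
  coords <- as.matrix(coords)
  stopif(ncol(coords) != 3, "coords must be an n x 3 matrix")
  stopif(length(bead_residue) != nrow(coords) ||
           length(bead_name) != nrow(coords),
         "bead arrays and coords are incongruent")
  stopif(any(!is.finite(coords)), "non-finite coordinates")
  stopif(!all(bead_name %in% c("BB", "SC1", "SC2", "SC3", "SC4")),
         "bead names must be BB or SC1..SC4")
  stopif(!all(residues$restype %in% RESIDUE_CODES),
         "unknown residue type code")
  for (ch in unique(residues$chain)) {
    r <- residues$resid[residues$chain == ch]
    stopif(any(diff(r) <= 0), "residue indices must strictly increase within a chain")
  }
  has_bb <- vapply(seq_len(nrow(residues)), function(i)
    any(bead_residue == i & bead_name == "BB"), logical(1))
  stopif(!all(has_bb), "every residue needs a BB bead")
  gly_sc <- any(residues$restype[bead_residue] == "GLY" & bead_name != "BB")
  stopif(gly_sc, "GLY must not carry side-chain beads")
  structure(
    list(residues = residues, bead_residue = as.integer(bead_residue),
         bead_name = as.character(bead_name), coords = coords),
    class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("<cg_structure> %d residues, %d beads, %d chain(s)\n",
              nrow(x$residues), nrow(x$coords), length(unique(x$residues$chain))))
  invisible(x)
}

# index of bead `name` of residue row i, or NA if absent
cg_bead_index <- function(structure, i, name) {
  if (i < 1 || i > nrow(structure$residues)) return(NA_integer_)
  hit <- which(structure$bead_residue == i & structure$bead_name == name)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# coordinate of bead `name` of residue row i, or NULL if absent
cg_bead_coord <- function(structure, i, name) {
  k <- cg_bead_index(structure, i, name)
  if (is.na(k)) NULL else structure$coords[k, ]
}

# indices of all BB beads in residue order
cg_bb_indices <- function(structure) {
  vapply(seq_len(nrow(structure$residues)),
         function(i) cg_bead_index(structure, i, "BB"), integer(1))
}

#' Replace the coordinates of a cg_structure
#' @param structure a \code{cg_structure}
#' @param coords n_beads x 3 matrix (nm)
#' @return updated structure
#' @export
set_coords <- function(structure, coords) {
  coords <- as.matrix(coords)
  stopif(!all(dim(coords) == dim(structure$coords)), "coordinate shape mismatch")
  structure$coords <- coords
  structure
}

#' Construct an atomistic structure
#'
#' @param atoms data.frame with columns chain, resid, restype, atom, element,
#'   x, y, z (nm).
#' @return object of class \code{atomistic_structure}.
#' @export
atomistic_structure <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  stopif(anyDuplicated(key) > 0, "duplicate (chain, resid, atom) keys")
  stopif(any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))),
         "non-finite coordinates")
  structure(list(atoms = atoms), class = "atomistic_structure")
}

# coordinate of one named atom; errors if unresolvable
atom_coord <- function(astruct, chain, resid, atom) {
  a <- astruct$atoms
  hit <- which(a$chain == chain & a$resid == resid & a$atom == atom)
  stopif(length(hit) == 0,
         sprintf("atom %s/%s/%s not found in atomistic structure", chain, resid, atom))
  as.numeric(a[hit[1], c("x", "y", "z")])
}

#' Construct a trajectory
#'
#' @param structure template \code{cg_structure} (bead identities).
#' @param frames list of coordinate matrices congruent with the template.
#' @param frame_spacing frame spacing in ps (> 0).
#' @param box optional 3-vector of box lengths (nm).
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(structure, frames, frame_spacing = 1, box = NULL) {
  stopif(frame_spacing <= 0, "frame_spacing must be > 0")
  nb <- nrow(structure$coords)
  ok <- vapply(frames, function(f) all(dim(as.matrix(f)) == c(nb, 3)), logical(1))
  stopif(!all(ok), "all frames must match the template bead count")
  structure(list(structure = structure, frames = frames,
                 frame_spacing = frame_spacing, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d beads, dt=%g ps\n",
              length(x$frames), nrow(x$structure$coords), x$frame_spacing))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}
#' @return integer
#' @export
n_frames <- function(traj) length(traj$frames)
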