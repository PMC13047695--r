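# On-disk formats. PDB for structures and multi-model trajectories (Angstrom
# on disk, nm in memory); CSV for shift/NOE/mapping/random-coil tables; a
# plain-text key-value format for model weights; YAML for run configs.

PDB_ATOM_FMT <- "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"

format_pdb_atom <- function(serial, name, restype, chain, resid, xyz_nm, element = "") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf(PDB_ATOM_FMT, serial, nm, restype, chain, resid,
          xyz_nm[1] * 10, xyz_nm[2] * 10, xyz_nm[3] * 10, element)
}

parse_pdb_atoms <- function(lines, path) {
  idx <- which(startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM"))
  recs <- lapply(idx, function(k) {
    ln <- lines[k]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed ATOM record at line %d of %s", k, path), call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop(sprintf("unparseable coordinates at line %d of %s", k, path), call. = FALSE)
    }
    list(line = k,
         name = trimws(substr(ln, 13, 16)),
         restype = trimws(substr(ln, 18, 20)),
         chain = trimws(substr(ln, 22, 22)),
         resid = suppressWarnings(as.integer(trimws(substr(ln, 23, 26)))),
         element = trimws(substr(ln, 77, 78)),
         xyz = xyz / 10)  # Angstrom -> nm
  })
  recs
}

# split raw PDB lines into models; a file without MODEL cards is one model
split_pdb_models <- function(lines) {
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts) == 0) return(list(lines))
  ends <- which(startsWith(lines, "ENDMDL"))
  stopif(length(ends) != length(starts), "unbalanced MODEL/ENDMDL cards")
  mapply(function(s, e) lines[(s + 1):(e - 1)], starts, ends, SIMPLIFY = FALSE)
}

records_to_cg <- function(recs, path) {
  bead_ok <- vapply(recs, function(r) r$name %in% c("BB", "SC1", "SC2", "SC3", "SC4"),
                    logical(1))
  if (!all(bead_ok)) {
    bad <- recs[[which(!bead_ok)[1]]]
    stop(sprintf("CG dialect error: atom name '%s' (line %d of %s) is not a bead name",
                 bad$name, bad$line, path), call. = FALSE)
  }
  key <- vapply(recs, function(r) paste(r$chain, r$resid), character(1))
  ukey <- unique(key)
  residues <- data.frame(
    chain = vapply(recs[match(ukey, key)], `[[`, character(1), "chain"),
    resid = vapply(recs[match(ukey, key)], `[[`, integer(1), "resid"),
    restype = vapply(recs[match(ukey, key)], `[[`, character(1), "restype"),
    stringsAsFactors = FALSE)
  cg_structure(
    residues = residues,
    bead_residue = match(key, ukey),
    bead_name = vapply(recs, `[[`, character(1), "name"),
    coords = do.call(rbind, lapply(recs, `[[`, "xyz")))
}

#' Read a protein structure from PDB
#'
#' CG files must use bead names (BB, SC1..SC4) in the atom-name column;
#' oxidized cysteine and cis-proline are encoded directly as residue names
#' CYO and PRC. Coordinates are converted from Angstrom to nm.
#'
#' @param path PDB file.
#' @param resolution "cg" or "atomistic".
#' @param all_models if TRUE return all models of a multi-model file as a
#'   \code{trajectory} (CG only); otherwise the first model.
#' @return a \code{cg_structure}, \code{atomistic_structure} or
#'   \code{trajectory}.
#' @export
read_structure <- function(path, resolution = c("cg", "atomistic"),
                           all_models = FALSE) {
  resolution <- match.arg(resolution)
  stopif(!file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  spacing <- 1
  sp_line <- grep("^REMARK   7 FRAME_SPACING_PS", lines, value = TRUE)
  if (length(sp_line) > 0) {
    spacing <- as.numeric(sub("^REMARK   7 FRAME_SPACING_PS *", "", sp_line[1]))
  }
  if (resolution == "atomistic") {
    recs <- parse_pdb_atoms(models[[1]], path)
    atoms <- data.frame(
      chain = vapply(recs, `[[`, character(1), "chain"),
      resid = vapply(recs, `[[`, integer(1), "resid"),
      restype = vapply(recs, `[[`, character(1), "restype"),
      atom = vapply(recs, `[[`, character(1), "name"),
      element = vapply(recs, `[[`, character(1), "element"),
      stringsAsFactors = FALSE)
    xyz <- do.call(rbind, lapply(recs, `[[`, "xyz"))
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    return(atomistic_structure(atoms))
  }
  first <- records_to_cg(parse_pdb_atoms(models[[1]], path), path)
  if (!all_models) return(first)
  frames <- lapply(models, function(m) {
    recs <- parse_pdb_atoms(m, path)
    do.call(rbind, lapply(recs, `[[`, "xyz"))
  })
  trajectory(first, frames, frame_spacing = spacing)
}

#' Write a CG structure or trajectory to PDB
#'
#' Trajectories become multi-model PDB files; the frame spacing is stored in
#' a REMARK 7 line so that \code{read_structure(..., all_models = TRUE)}
#' round-trips it.
#'
#' @param x a \code{cg_structure} or \code{trajectory}.
#' @param path output file.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "trajectory")) {
    out <- c(sprintf("REMARK   7 FRAME_SPACING_PS %.6f", x$frame_spacing))
    for (f in seq_along(x$frames)) {
      out <- c(out, sprintf("MODEL     %4d", f),
               cg_model_lines(set_coords(x$structure, x$frames[[f]])),
               "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else if (inherits(x, "cg_structure")) {
    writeLines(c(cg_model_lines(x), "END"), path)
  } else {
    stop("write_structure() expects a cg_structure or trajectory")
  }
  invisible(path)
}

cg_model_lines <- function(s) {
  vapply(seq_len(nrow(s$coords)), function(k) {
    i <- s$bead_residue[k]
    format_pdb_atom(k, s$bead_name[k], s$residues$restype[i],
                    s$residues$chain[i], s$residues$resid[i], s$coords[k, ])
  }, character(1))
}

#' Read a random-coil shift table
#'
#' CSV with columns restype, atom, shift (ppm). Must cover all 20 standard
#' residue types for each of the six predicted atom types (CB entries for
#' GLY are not required).
#'
#' @param path CSV file.
#' @return data.frame of class \code{random_coil_table}.
#' @export
read_random_coil <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopif(!all(c("restype", "atom", "shift") %in% names(df)),
         "random-coil table needs columns restype, atom, shift")
  class(df) <- c("random_coil_table", "data.frame")
  df
}

coil_lookup <- function(coil, restype, atom) {
  hit <- which(coil$restype == restype & coil$atom == atom)
  if (length(hit) == 0) NA_real_ else coil$shift[hit[1]]
}

#' Read a chemical-shift table
#'
#' CSV with columns chain, resid, atom, shift (ppm); a restype column is
#' required when \code{random_coil} is supplied, in which case stored values
#' are raw minus random-coil (secondary shifts). Rows with atom types outside
#' N, C, CA, CB, H, HA are skipped (counted in attribute
#' \code{skipped_rows}); duplicate keys are an error.
#'
#' @param path CSV file.
#' @param random_coil optional \code{random_coil_table}.
#' @return a \code{shift_table} data.frame (chain, resid, atom, shift).
#' @export
read_shift_table <- function(path, random_coil = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chain = "character"))
  stopif(!all(c("chain", "resid", "atom", "shift") %in% names(df)),
         "shift table needs columns chain, resid, atom, shift")
  keep <- df$atom %in% ATOM_TYPES
  skipped <- sum(!keep)
  if (skipped > 0) {
    warning(sprintf("skipped %d row(s) with unknown atom types", skipped))
  }
  df <- df[keep, , drop = FALSE]
  key <- paste(df$chain, df$resid, df$atom)
  if (anyDuplicated(key) > 0) {
    stop(sprintf("duplicate shift entry for key '%s'", key[duplicated(key)][1]),
         call. = FALSE)
  }
  if (!is.null(random_coil)) {
    stopif(!("restype" %in% names(df)),
           "a restype column is required to subtract random-coil shifts")
    rc <- mapply(coil_lookup, df$restype, df$atom,
                 MoreArgs = list(coil = random_coil))
    stopif(any(is.na(rc)), "random-coil table does not cover all rows")
    df$shift <- df$shift - rc
  }
  out <- df[, c("chain", "resid", "atom", "shift")]
  attr(out, "secondary") <- TRUE
  attr(out, "provenance") <- "experimental"
  attr(out, "skipped_rows") <- skipped
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Write a shift table to CSV
#' @param x a \code{shift_table}
#' @param path output CSV
#' @export
write_shift_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("chain", "resid", "atom", "shift")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an NOE distance-restraint table
#'
#' CSV columns: chain_i, resid_i, atoms_i, chain_j, resid_j, atoms_j, d, r0,
#' r1, r2 (nm); atom groups are "|"-separated names. Missing r0 defaults to
#' 0 and missing r2 to r1 + 0.5 nm; a missing r1 is an error.
#'
#' @param path CSV file.
#' @return a \code{noe_table} data.frame.
#' @export
read_noe_table <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = c(chain_i = "character",
                                                chain_j = "character")),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(chain_i = character(), resid_i = integer(),
                     atoms_i = character(), chain_j = character(),
                     resid_j = integer(), atoms_j = character(),
                     d = numeric(), r0 = numeric(), r1 = numeric(),
                     r2 = numeric(), stringsAsFactors = FALSE)
    class(df) <- c("noe_table", "data.frame")
    return(df)
  }
  need <- c("chain_i", "resid_i", "atoms_i", "chain_j", "resid_j", "atoms_j", "r1")
  stopif(!all(need %in% names(df)), "NOE table misses required columns")
  stopif(any(is.na(df$r1)), "r1 is required for every NOE record")
  if (!("d" %in% names(df))) df$d <- df$r1
  if (!("r0" %in% names(df))) df$r0 <- NA_real_
  if (!("r2" %in% names(df))) df$r2 <- NA_real_
  df$r0[is.na(df$r0)] <- 0
  df$r2[is.na(df$r2)] <- df$r1[is.na(df$r2)] + 0.5
  stopif(any(df$r0 > df$r1 | df$r1 > df$r2), "require r0 <= r1 <= r2")
  df <- df[, c("chain_i", "resid_i", "atoms_i", "chain_j", "resid_j",
               "atoms_j", "d", "r0", "r1", "r2")]
  class(df) <- c("noe_table", "data.frame")
  df
}

#' Write an NOE table to CSV
#' @param x a \code{noe_table}
#' @param path output CSV
#' @export
write_noe_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an atom-to-bead mapping table
#'
#' CSV columns restype, atom, bead. The map must be a function: one bead per
#' (restype, atom).
#'
#' @param path CSV file.
#' @return data.frame of class \code{mapping_table}.
#' @export
read_mapping_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopif(!all(c("restype", "atom", "bead") %in% names(df)),
         "mapping table needs columns restype, atom, bead")
  key <- paste(df$restype, df$atom)
  stopif(anyDuplicated(key) > 0, "mapping table maps an atom to two beads")
  class(df) <- c("mapping_table", "data.frame")
  df
}

#' Write a shift model to a plain-text weight file
#'
#' A documented key-value text format: a magic line, the feature-layout tag,
#' the six per-atom tolerances epsilon (ppm) and the four weight/bias blocks
#' at full double precision (lossless round-trip).
#'
#' @param model a \code{shift_model}.
#' @param path output file.
#' @export
write_shift_model <- function(model, path) {
  num <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = " ")
  lines <- c(
    "cgnmr_shift_model v1",
    paste("layout", model$layout_version),
    paste("epsilon", num(model$epsilon)),
    paste("b_hidden", num(model$b_hidden)),
    paste("b_out", num(model$b_out)),
    "W_hidden",
    vapply(seq_len(nrow(model$W_hidden)),
           function(i) num(model$W_hidden[i, ]), character(1)),
    "W_out",
    vapply(seq_len(nrow(model$W_out)),
           function(i) num(model$W_out[i, ]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a shift model from a weight file
#'
#' Refuses files whose feature-layout tag differs from the one this package
#' was built with. A file without an epsilon line loads with all tolerances
#' 0 and a warning.
#'
#' @param path weight file written by \code{write_shift_model}.
#' @return a \code{shift_model}.
#' @export
read_shift_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stopif(length(lines) < 5 || lines[1] != "cgnmr_shift_model v1",
         sprintf("not a cgnmr shift model file: %s", path))
  grab <- function(keyword) {
    hit <- grep(paste0("^", keyword, " "), lines)
    if (length(hit) == 0) return(NULL)
    as.numeric(strsplit(sub(paste0("^", keyword, " "), "", lines[hit[1]]), " +")[[1]])
  }
  layout <- sub("^layout ", "", grep("^layout ", lines, value = TRUE)[1])
  stopif(is.na(layout) || layout != FEATURE_LAYOUT_VERSION,
         sprintf("feature-layout version mismatch: file has '%s'", layout))
  eps <- grab("epsilon")
  if (is.null(eps)) {
    warning("weight file lacks epsilon; loading with all tolerances 0")
    eps <- rep(0, 6)
  }
  block <- function(keyword, nr, nc) {
    hit <- grep(paste0("^", keyword, "$"), lines)
    stopif(length(hit) == 0, sprintf("corrupted weight file: missing %s block", keyword))
    rows <- lines[(hit[1] + 1):(hit[1] + nr)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), " +")[[1]]),
                  numeric(nc)))
    stopif(any(is.na(m)), sprintf("corrupted %s block", keyword))
    dimnames(m) <- NULL
    m
  }
  b_hidden <- grab("b_hidden"); b_out <- grab("b_out")
  stopif(is.null(b_hidden) || is.null(b_out) ||
           length(b_hidden) != 26 || length(b_out) != 6,
         "corrupted weight file: bad bias blocks")
  shift_model(W_hidden = block("W_hidden", 26, 96), b_hidden = b_hidden,
              W_out = block("W_out", 6, 26), b_out = b_out,
              epsilon = eps)
}

#' Read a YAML run configuration
#' @param path YAML file
#' @return named list
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
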