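# Residue featurization and the 96 -> 26 (ELU) -> 6 (linear) secondary-shift
# network: forward pass, coordinate Jacobian via the chain rule through the
# angle derivatives, training-set preparation, Adam training with early
# stopping, and per-atom-type test RMSE (the flat-bottom tolerances).

# per-residue feature block layout: 22 embedding values, then
# (sin, cos) for alpha, beta, gamma, theta1, theta2 -> 32 values
BLOCK_SIZE <- 32
ANGLE_NAMES <- c("alpha", "beta", "gamma", "theta1", "theta2")

#' Amino-acid embedding derived from the BLOSUM62 substitution matrix
#'
#' The 20 standard residues use their BLOSUM62 rows (restricted to the 20
#' standard columns). The two extended codes copy an existing row/column —
#' oxidized cysteine (CYO) from CYS and cis-proline (PRC) from PRO — with the
#' copied diagonal entry incremented by 1 so the codes are distinguishable.
#'
#' @return 22 x 22 numeric matrix with row/column names in
#'   \code{RESIDUE_CODES} order.
#' @export
blosum_embedding <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B <- env$BLOSUM62
  one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  std <- B[one, one]
  dimnames(std) <- list(names(one), names(one))
  E <- matrix(0, 22, 22, dimnames = list(RESIDUE_CODES, RESIDUE_CODES))
  E[1:20, 1:20] <- std
  for (ext in list(c("CYO", "CYS"), c("PRC", "PRO"))) {
    E[ext[1], 1:20] <- std[ext[2], ]
    E[1:20, ext[1]] <- std[, ext[2]]
    E[ext[1], ext[1]] <- std[ext[2], ext[2]] + 1
    E[ext[1], ext[2]] <- std[ext[2], ext[2]]
    E[ext[2], ext[1]] <- std[ext[2], ext[2]]
  }
  E["CYO", "PRC"] <- E["CYS", "PRO"]; E["PRC", "CYO"] <- E["CYS", "PRO"]
  E
}

# one 32-value block for residue j (zero block if j outside the chain of i)
feature_block <- function(structure, j, embedding) {
  block <- numeric(BLOCK_SIZE)
  if (j < 1 || j > nrow(structure$residues)) return(block)
  block[1:22] <- embedding[structure$residues$restype[j], ]
  ang <- residue_angles(structure, j)
  for (k in seq_along(ANGLE_NAMES)) {
    if (ang$mask[k]) {
      a <- ang[[ANGLE_NAMES[k]]]
      block[22 + 2 * k - 1] <- sin(a)
      block[22 + 2 * k] <- cos(a)
    }
  }
  block
}

#' Tripeptide feature vector of residue i
#'
#' Concatenates the 32-value blocks of residues i-1, i, i+1 (96 values);
#' nonexistent neighbours (chain ends, other chains) contribute all-zero
#' blocks, and masked angles contribute 0 to both their sin and cos slots.
#'
#' @param structure a \code{cg_structure}.
#' @param i residue row.
#' @param embedding 22 x 22 embedding matrix (default
#'   \code{blosum_embedding()}).
#' @return numeric vector of length 96.
#' @export
build_feature_vector <- function(structure, i, embedding = blosum_embedding()) {
  same_chain <- function(j) {
    j >= 1 && j <= nrow(structure$residues) &&
      structure$residues$chain[j] == structure$residues$chain[i]
  }
  blk <- function(j) {
    if (same_chain(j)) feature_block(structure, j, embedding) else numeric(BLOCK_SIZE)
  }
  c(blk(i - 1), blk(i), blk(i + 1))
}

#' Construct a shift model
#'
#' @param W_hidden 26 x 96 weights; @param b_hidden length-26 bias.
#' @param W_out 6 x 26 weights; @param b_out length-6 bias.
#' @param epsilon six per-atom flat-bottom tolerances (ppm), order
#'   N, C, CA, CB, H, HA.
#' @param layout_version feature-layout tag; must match the featurizer.
#' @return object of class \code{shift_model}.
#' @export
shift_model <- function(W_hidden, b_hidden, W_out, b_out,
                        epsilon = rep(0, 6),
                        layout_version = FEATURE_LAYOUT_VERSION) {
  stopif(!all(dim(W_hidden) == c(26, 96)), "W_hidden must be 26 x 96")
  stopif(!all(dim(W_out) == c(6, 26)), "W_out must be 6 x 26")
  stopif(length(b_hidden) != 26 || length(b_out) != 6, "bad bias lengths")
  stopif(length(epsilon) != 6 || any(epsilon < 0), "epsilon must be 6 non-negatives")
  structure(list(W_hidden = unname(as.matrix(W_hidden)),
                 b_hidden = as.numeric(b_hidden),
                 W_out = unname(as.matrix(W_out)), b_out = as.numeric(b_out),
                 epsilon = stats::setNames(as.numeric(epsilon), ATOM_TYPES),
                 layout_version = layout_version),
            class = "shift_model")
}

elu <- function(x) {
  neg <- x < 0
  if (any(neg)) x[neg] <- expm1(x[neg])
  x
}
elu_prime <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- 1
  out[!pos] <- exp(x[!pos])
  out
}

check_layout <- function(model, layout = FEATURE_LAYOUT_VERSION) {
  stopif(model$layout_version != layout,
         "feature-layout version mismatch between model and featurizer")
}

#' Forward pass: six secondary shifts from one feature vector
#'
#' \code{out = W_out \%*\% ELU(W_hidden \%*\% f + b_hidden) + b_out}.
#' Accepts a single length-96 vector or a 96 x n matrix of columns.
#'
#' @param model a \code{shift_model}.
#' @param features length-96 vector or 96 x n matrix.
#' @return named length-6 vector (ppm) or a 6 x n matrix.
#' @export
forward <- function(model, features) {
  check_layout(model)
  f <- if (is.matrix(features)) features else matrix(features, ncol = 1)
  stopif(nrow(f) != 96, "feature vectors must have length 96")
  h <- elu(model$W_hidden %*% f + model$b_hidden)
  out <- model$W_out %*% h + model$b_out
  if (!is.matrix(features)) stats::setNames(as.numeric(out), ATOM_TYPES)
  else { rownames(out) <- ATOM_TYPES; out }
}

#' Predict secondary shifts for every residue of a CG structure
#'
#' CB predictions for glycine are masked (GLY has no CB).
#'
#' @param model a \code{shift_model}.
#' @param structure a \code{cg_structure}.
#' @param embedding embedding matrix (default \code{blosum_embedding()}).
#' @return a \code{shift_table} with provenance "predicted".
#' @export
predict_shifts <- function(model, structure, embedding = blosum_embedding()) {
  n <- nrow(structure$residues)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pred <- forward(model, build_feature_vector(structure, i, embedding))
    keep <- ATOM_TYPES
    if (structure$residues$restype[i] == "GLY") keep <- setdiff(keep, "CB")
    rows[[i]] <- data.frame(chain = structure$residues$chain[i],
                            resid = structure$residues$resid[i],
                            atom = keep, shift = as.numeric(pred[keep]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "secondary") <- TRUE
  attr(out, "provenance") <- "predicted"
  class(out) <- c("shift_table", "data.frame")
  out
}

# residues whose feature vectors involve residue j's angles: j-1, j, j+1;
# conversely residue i's features involve the angles of i-1, i, i+1, which
# touch beads BB(i-3..i+3) and SC1(i-1..i+1).

# d(angle)/d(bead coords) bookkeeping for one residue j: list of angle name ->
# list(beads = residue-local bead spec, grad = k x 3 matrix)
angle_bead_spec <- function(j) {
  list(
    alpha  = list(type = "angle", pts = list(c(j, 2), c(j, 1), c(j - 1, 1))),
    beta   = list(type = "angle", pts = list(c(j - 1, 1), c(j, 1), c(j + 1, 1))),
    gamma  = list(type = "angle", pts = list(c(j, 2), c(j, 1), c(j + 1, 1))),
    theta1 = list(type = "dihedral",
                  pts = list(c(j - 2, 1), c(j - 1, 1), c(j, 1), c(j + 1, 1))),
    theta2 = list(type = "dihedral",
                  pts = list(c(j - 1, 1), c(j, 1), c(j + 1, 1), c(j + 2, 1)))
  )
}

# resolve a (residue, which) point spec to a bead index (1 = BB, 2 = SC1);
# NA when the bead does not exist or falls on another chain
resolve_pt <- function(structure, anchor, spec) {
  j <- spec[1]
  if (j < 1 || j > nrow(structure$residues)) return(NA_integer_)
  if (structure$residues$chain[j] != structure$residues$chain[anchor]) {
    return(NA_integer_)
  }
  cg_bead_index(structure, j, if (spec[2] == 1) "BB" else "SC1")
}

#' Jacobian of the six shift predictions w.r.t. bead coordinates
#'
#' Chain rule through (d pred / d feature) x (d sin, cos / d angle) x
#' (d angle / d coords). Only beads entering residue i's tripeptide features
#' appear: BB(i-3..i+3) and SC1(i-1..i+1) where present. Masked angle slots
#' contribute exactly zero.
#'
#' @param model a \code{shift_model}.
#' @param structure a \code{cg_structure}.
#' @param i residue row.
#' @param embedding embedding matrix.
#' @return named list: bead index (as character) -> 6 x 3 matrix
#'   d(pred_atom)/d(coord).
#' @export
shift_coordinate_jacobian <- function(model, structure, i,
                                      embedding = blosum_embedding()) {
  check_layout(model)
  f <- build_feature_vector(structure, i, embedding)
  pre <- as.numeric(model$W_hidden %*% f + model$b_hidden)
  # d pred / d feature: 6 x 96
  dpred_df <- model$W_out %*% (model$W_hidden * elu_prime(pre))
  jac <- list()
  add <- function(bead, mat6x3) {
    key <- as.character(bead)
    jac[[key]] <<- (jac[[key]] %||% matrix(0, 6, 3)) + mat6x3
  }
  blocks <- c(i - 1, i, i + 1)
  for (b in seq_along(blocks)) {
    j <- blocks[b]
    if (j < 1 || j > nrow(structure$residues)) next
    if (structure$residues$chain[j] != structure$residues$chain[i]) next
    specs <- angle_bead_spec(j)
    for (k in seq_along(ANGLE_NAMES)) {
      spec <- specs[[ANGLE_NAMES[k]]]
      beads <- vapply(spec$pts, function(p) resolve_pt(structure, i, p), integer(1))
      if (any(is.na(beads))) next  # masked angle: zero contribution
      pts <- lapply(beads, function(bd) structure$coords[bd, ])
      g <- if (spec$type == "angle") {
        do.call(angle_gradient, pts)
      } else {
        do.call(dihedral_gradient, pts)
      }
      a <- if (spec$type == "angle") do.call(vec_angle, pts) else do.call(vec_dihedral, pts)
      slot_sin <- (b - 1) * BLOCK_SIZE + 22 + 2 * k - 1
      slot_cos <- slot_sin + 1
      # d pred / d angle: 6-vector
      dpa <- dpred_df[, slot_sin] * cos(a) - dpred_df[, slot_cos] * sin(a)
      for (p in seq_along(beads)) {
        add(beads[p], outer(dpa, g[p, ]))
      }
    }
  }
  jac
}

#' Assemble a training set from structures and shift tables
#'
#' Raw shifts are converted to secondary shifts with \code{random_coil};
#' entries whose raw value deviates from the reference mean by strictly more
#' than 3 reference SDs are discarded as outliers (boundary value retained).
#' Structures (not residues) are partitioned into train/validation/test so
#' no structure leaks across partitions.
#'
#' @param structures list of \code{cg_structure}.
#' @param shift_tables list of raw \code{shift_table}s, parallel to
#'   \code{structures}.
#' @param random_coil \code{random_coil_table}, or NULL if tables already
#'   hold secondary shifts.
#' @param reference_stats data.frame (atom, mean, sd) of raw-shift reference
#'   statistics used for outlier filtering, or NULL to skip filtering.
#' @param fractions length-3 train/validation/test fractions.
#' @param seed partition seed.
#' @param embedding embedding matrix.
#' @return list of class \code{training_set}: features (96 x n), targets
#'   (6 x n), mask (6 x n logical), structure_id (n), partition (n),
#'   n_excluded.
#' @export
prepare_training_set <- function(structures, shift_tables, random_coil = NULL,
                                 reference_stats = NULL,
                                 fractions = c(0.9, 0.05, 0.05), seed = 1,
                                 embedding = blosum_embedding()) {
  stopif(length(structures) != length(shift_tables),
         "structures and shift tables must be parallel lists")
  feats <- list(); targs <- list(); masks <- list(); sid <- integer(0)
  n_excluded <- 0
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    tab <- shift_tables[[s]]
    for (i in seq_len(nrow(st$residues))) {
      tgt <- rep(NA_real_, 6); names(tgt) <- ATOM_TYPES
      for (a in ATOM_TYPES) {
        hit <- which(tab$chain == st$residues$chain[i] &
                       tab$resid == st$residues$resid[i] & tab$atom == a)
        if (length(hit) == 0) next
        raw <- tab$shift[hit[1]]
        if (!is.null(reference_stats)) {
          rs <- reference_stats[reference_stats$atom == a, ]
          if (nrow(rs) == 1 && abs(raw - rs$mean[1]) > 3 * rs$sd[1]) {
            n_excluded <- n_excluded + 1
            next
          }
        }
        if (!is.null(random_coil)) {
          rc <- coil_lookup(random_coil, st$residues$restype[i], a)
          stopif(is.na(rc), "random-coil table does not cover a residue/atom")
          raw <- raw - rc
        }
        tgt[a] <- raw
      }
      feats[[length(feats) + 1]] <- build_feature_vector(st, i, embedding)
      targs[[length(targs) + 1]] <- tgt
      masks[[length(masks) + 1]] <- !is.na(tgt)
      sid <- c(sid, s)
    }
  }
  stopif(length(feats) == 0 || !any(unlist(masks)),
         "no training targets survive filtering")
  X <- do.call(cbind, feats)
  Y <- do.call(cbind, lapply(targs, function(t) ifelse(is.na(t), 0, t)))
  M <- do.call(cbind, masks)
  ids <- unique(sid)
  part_of <- with_seed(seed, {
    shuffled <- sample(ids)
    n_tr <- max(1, round(fractions[1] * length(ids)))
    n_va <- max(1, round(fractions[2] * length(ids)))
    p <- rep("test", length(ids))
    p[match(shuffled[seq_len(n_tr)], ids)] <- "train"
    rest <- shuffled[-seq_len(n_tr)]
    p[match(rest[seq_len(min(n_va, length(rest)))], ids)] <- "validation"
    p
  })
  structure(list(features = X, targets = Y, mask = M, structure_id = sid,
                 partition = part_of[match(sid, ids)], n_excluded = n_excluded),
            class = "training_set")
}

subset_training <- function(ts, part) {
  keep <- ts$partition == part
  list(X = ts$features[, keep, drop = FALSE],
       Y = ts$targets[, keep, drop = FALSE],
       M = ts$mask[, keep, drop = FALSE])
}

masked_mse <- function(model, X, Y, M) {
  P <- forward(model, X)
  sum(((P - Y) * M)^2) / sum(M)
}

#' Train a shift model by Adam with early stopping
#'
#' Mean-squared-error loss over available (masked) targets, minibatch Adam at
#' the given learning rate; training halts when the validation loss has not
#' strictly improved for \code{patience} consecutive epochs, and the
#' parameters with the best validation loss are returned. Deterministic for
#' a fixed seed.
#'
#' @param ts a \code{training_set} (must contain train and validation rows).
#' @param lr learning rate (default 0.001).
#' @param patience early-stopping patience in epochs (default 5).
#' @param seed RNG seed for weight init and batch shuffling.
#' @param batch_size minibatch size (default 64).
#' @param max_epochs hard cap on epochs (default 500).
#' @return a trained \code{shift_model} (epsilon all zero; see
#'   \code{\link{evaluate_shift_model}}).
#' @export
train_shift_model <- function(ts, lr = 0.001, patience = 5, seed = 1,
                              batch_size = 64, max_epochs = 500) {
  tr <- subset_training(ts, "train")
  va <- subset_training(ts, "validation")
  stopif(ncol(tr$X) == 0 || ncol(va$X) == 0,
         "need non-empty train and validation partitions")
  with_seed(seed, {
    sc <- 1 / sqrt(96)
    par <- list(W1 = matrix(stats::rnorm(26 * 96, sd = sc), 26, 96),
                b1 = numeric(26),
                W2 = matrix(stats::rnorm(6 * 26, sd = 1 / sqrt(26)), 6, 26),
                b2 = numeric(6))
    m <- lapply(par, function(p) p * 0)
    v <- lapply(par, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0
    as_model <- function(p) shift_model(p$W1, p$b1, p$W2, p$b2)
    best <- list(loss = Inf, par = par)
    stall <- 0
    n <- ncol(tr$X)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        X <- tr$X[, idx, drop = FALSE]
        Y <- tr$Y[, idx, drop = FALSE]
        Mk <- tr$M[, idx, drop = FALSE]
        pre <- par$W1 %*% X + par$b1
        H <- elu(pre)
        P <- par$W2 %*% H + par$b2
        nm <- max(sum(Mk), 1)
        dP <- 2 * (P - Y) * Mk / nm
        if (any(!is.finite(dP))) stop(sprintf("divergent loss at epoch %d", epoch))
        g <- list(W2 = dP %*% t(H), b2 = rowSums(dP))
        dH <- t(par$W2) %*% dP * elu_prime(pre)
        g$W1 <- dH %*% t(X); g$b1 <- rowSums(dH)
        t_step <- t_step + 1
        for (k in names(par)) {
          m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
          v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
          mhat <- m[[k]] / (1 - beta1^t_step)
          vhat <- v[[k]] / (1 - beta2^t_step)
          par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      vloss <- masked_mse(as_model(par), va$X, va$Y, va$M)
      if (is.na(vloss) || !is.finite(vloss)) {
        stop(sprintf("divergent loss at epoch %d", epoch))
      }
      if (vloss < best$loss) {
        best <- list(loss = vloss, par = par)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
    as_model(best$par)
  })
}

#' Per-atom-type RMSE on a test partition
#'
#' The six RMSEs are the natural candidates for the flat-bottom tolerances
#' epsilon. Atom types without any available target get NA.
#'
#' @param model a \code{shift_model}.
#' @param ts a \code{training_set}.
#' @param partition which partition to evaluate (default "test").
#' @param store if TRUE, return the model with epsilon set (NAs become 0);
#'   otherwise return the named RMSE vector.
#' @return named numeric vector of 6 RMSEs (ppm), or an updated model.
#' @export
evaluate_shift_model <- function(model, ts, partition = "test", store = FALSE) {
  te <- subset_training(ts, partition)
  stopif(ncol(te$X) == 0, "empty evaluation partition")
  P <- forward(model, te$X)
  rmse <- vapply(seq_along(ATOM_TYPES), function(a) {
    k <- te$M[a, ]
    if (!any(k)) return(NA_real_)
    sqrt(mean((P[a, k] - te$Y[a, k])^2))
  }, numeric(1))
  names(rmse) <- ATOM_TYPES
  if (!store) return(rmse)
  model$epsilon <- stats::setNames(ifelse(is.na(rmse), 0, rmse), ATOM_TYPES)
  model
}
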