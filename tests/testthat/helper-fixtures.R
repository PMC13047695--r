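# shared fixtures and finite-difference utilities

# central finite-difference gradient of scalar fn over a list of 3-vectors
fd_gradient <- function(fn, pts, h = 1e-6) {
  t(vapply(seq_along(pts), function(k) {
    vapply(1:3, function(d) {
      pp <- pts; pp[[k]][d] <- pp[[k]][d] + h
      pm <- pts; pm[[k]][d] <- pm[[k]][d] - h
      (do.call(fn, pp) - do.call(fn, pm)) / (2 * h)
    }, numeric(1))
  }, numeric(3)))
}

# max relative error between analytic forces and -dE/dx of a provider
provider_force_fd_error <- function(provider, coords, step = 0, h = 1e-6,
                                    floor = 1e-4) {
  o <- provider$eval(coords, step)
  maxrel <- 0
  for (b in seq_len(nrow(coords))) for (d in 1:3) {
    cp <- coords; cp[b, d] <- cp[b, d] + h
    cm <- coords; cm[b, d] <- cm[b, d] - h
    num <- -(provider$eval(cp, step)$energy - provider$eval(cm, step)$energy) / (2 * h)
    if (abs(num) > floor) {
      maxrel <- max(maxrel, abs(num - o$forces[b, d]) / abs(num))
    }
  }
  maxrel
}

# random rigid-body transform applied to an n x 3 coordinate matrix
random_rigid_transform <- function(coords, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  sweep(coords %*% t(Rz %*% Ry %*% Rx), 2, runif(3, -2, 2), `+`)
}

# small peptide reused across tests
tiny_peptide <- function(n = 6, seed = 11) make_toy_peptide(n, seed = seed)

ref_sds <- stats::setNames(rep(1, 6), c("N", "C", "CA", "CB", "H", "HA"))
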