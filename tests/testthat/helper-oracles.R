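# Independent numerical oracles and small fixture builders used across tests.

# Central finite-difference Hessian of a scalar function of a 3N vector.
fd_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      xpp <- x; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
      xpm <- x; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp <- x; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm <- x; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  H
}

# Pairwise-spring network energy (the elastic-network potential) for a
# 3N coordinate vector, springs fixed by the reference geometry.
network_energy <- function(xvec, ref_coords, kmat) {
  X <- matrix(xvec, ncol = 3, byrow = TRUE)
  n <- nrow(X)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (kmat[i, j] == 0) next
      d0 <- sqrt(sum((ref_coords[i, ] - ref_coords[j, ])^2))
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      e <- e + 0.5 * kmat[i, j] * (d - d0)^2
    }
  }
  e
}

# Dihedral angle via bio3d (degrees -> radians); independent of the
# package's own dihedral code.
bio3d_dihedral <- function(p4) {
  bio3d::torsion.xyz(as.numeric(t(p4)), atm.inc = 4) * pi / 180
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# Augmented-Lagrangian constrained minimiser for the seam problem
# min U_l s.t. U_l = U_r between two positive-definite quadratics; a
# different algorithm from the package's one-parameter root-finding.
al_seam_oracle <- function(Hl, al, Hr, ar, x0 = (al + ar) / 2) {
  Ul <- function(x) 0.5 * sum((x - al) * (Hl %*% (x - al)))
  Ur <- function(x) 0.5 * sum((x - ar) * (Hr %*% (x - ar)))
  lam <- 0
  mu <- 10
  x <- x0
  for (it in 1:60) {
    obj <- function(x) {
      c <- Ul(x) - Ur(x)
      Ul(x) + lam * c + 0.5 * mu * c^2
    }
    grad <- function(x) {
      c <- Ul(x) - Ur(x)
      gl <- as.numeric(Hl %*% (x - al))
      gr <- as.numeric(Hr %*% (x - ar))
      gl + (lam + mu * c) * (gl - gr)
    }
    x <- stats::optim(x, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))$par
    cval <- Ul(x) - Ur(x)
    lam <- lam + mu * cval
    if (abs(cval) < 1e-12) break
    mu <- min(mu * 2, 1e8)
  }
  list(x = x, U = Ul(x))
}

# Minimal all-atom fixtures: atom tables with standard names on a generic
# non-degenerate zig-zag geometry (only names/ordering matter for torsion
# enumeration; geometry must merely avoid collinearity).
make_peptide <- function(resnames, atom_names_per_res) {
  rows <- list()
  coords <- list()
  k <- 0
  for (r in seq_along(resnames)) {
    for (a in atom_names_per_res[[r]]) {
      k <- k + 1
      rows[[k]] <- data.frame(name = a, resname = resnames[r], resno = r,
                              chain = "A",
                              element = substr(a, 1, 1))
      coords[[k]] <- c(1.3 * k, 0.9 * sin(1.7 * k), 0.8 * cos(1.1 * k))
    }
  }
  path_structure(do.call(rbind, rows), do.call(rbind, coords),
                 selection = "all-atom")
}

bb <- function() c("N", "CA", "C", "O")

random_cluster <- function(n, seed = 42, spread = 3) {
  set.seed(seed)
  atoms <- data.frame(name = paste0("C", seq_len(n)), resname = "LIG",
                      resno = seq_len(n), chain = "A", element = "C")
  path_structure(atoms, matrix(stats::rnorm(3 * n, sd = spread), n, 3),
                 selection = "all-atom")
}

ca_pair_structure <- function(sep = 10) {
  atoms <- data.frame(name = "CA", resname = "UNK", resno = 1:2, chain = "A",
                      element = "C")
  path_structure(atoms, rbind(c(0, 0, 0), c(sep, 0, 0)), selection = "ca")
}

# Fake mode spectrum from a plain list of Hessian eigenvalues (plus
# rigid-body zeros), bypassing matrix construction.
fake_spectrum <- function(lambda, n_zero = 6) {
  vals <- c(rep(0, n_zero), sort(lambda))
  structure(list(values = vals,
                 vectors = diag(length(vals)),
                 zero = c(rep(TRUE, n_zero), rep(FALSE, length(lambda))),
                 covariance = 1 / sort(lambda)),
            class = "mode_spectrum")
}

rigid_body_basis <- function(coords) {
  n <- nrow(coords)
  centred <- sweep(coords, 2, colMeans(coords))
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    v <- t(apply(centred, 1, function(p) c(axes[k, 2] * p[3] - axes[k, 3] * p[2],
                                           axes[k, 3] * p[1] - axes[k, 1] * p[3],
                                           axes[k, 1] * p[2] - axes[k, 2] * p[1])))
    B[, 3 + k] <- as.numeric(t(v))
  }
  B
}
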