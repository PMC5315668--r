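test_that("backbone enumeration covers internal residues only", {
  ggg <- make_peptide(c("GLY", "GLY", "GLY"), list(bb(), bb(), bb()))
  topo <- enumerate_torsions(ggg)
  expect_equal(nrow(topo$quadruples), 2L)  # 1 phi + 1 psi, no chi
  expect_setequal(grepl("^phi", topo$labels), c(TRUE, FALSE))

  ala <- make_peptide("ALA", list(c(bb(), "CB")))
  expect_equal(nrow(enumerate_torsions(ala)$quadruples), 0L)

  lys <- make_peptide("LYS",
                      list(c(bb(), "CB", "CG", "CD", "CE", "NZ")))
  topo_k <- enumerate_torsions(lys)
  expect_equal(nrow(topo_k$quadruples), 4L)  # chi1..chi4
  expect_true(all(grepl("^chi", topo_k$labels)))

  expect_warning(enumerate_torsions(make_peptide("XXX", list(bb()))),
                 "unknown")
})

test_that("CA-only structures get pseudo-dihedrals over consecutive sites", {
  p <- polymer_pair(10, 20)$left
  topo <- enumerate_torsions(p)
  expect_equal(nrow(topo$quadruples), 10L - 3L)
  expect_true(all(apply(topo$quadruples, 1, function(q) all(diff(q) == 1))))
})

test_that("dihedral angle and gradient agree with bio3d and finite differences", {
  set.seed(5)
  for (rep in 1:5) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    if (is.null(dihedral_gradient(p))) next
    expect_equal(wrap_angle(dihedral_angle(p) - bio3d_dihedral(p)), 0,
                 tolerance = 1e-8)
    g <- dihedral_gradient(p)
    x0 <- as.numeric(t(p))
    gfd <- numeric(12)
    h <- 1e-6
    for (i in 1:12) {
      xp <- x0; xp[i] <- xp[i] + h
      xm <- x0; xm[i] <- xm[i] - h
      gfd[i] <- wrap_angle(
        dihedral_angle(matrix(xp, 4, 3, byrow = TRUE)) -
          dihedral_angle(matrix(xm, 4, 3, byrow = TRUE))) / (2 * h)
    }
    expect_equal(as.numeric(t(g)), gfd, tolerance = 1e-5)
  }
})

test_that("torsional Hessian matches finite differences of the angular restraint", {
  # butane-like 4-atom chain, one dihedral
  atoms <- data.frame(name = paste0("C", 1:4), resname = "LIG", resno = 1:4,
                      chain = "A", element = "C")
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0),
                  c(3.0, 1.8, 1.2))
  s <- path_structure(atoms, coords, selection = "all-atom")
  topo <- structure(list(quadruples = matrix(1:4, 1), labels = "chi",
                         k_torsion = 2.5), class = "torsion_topology")
  h <- build_torsional_hessian(s, topo)
  theta0 <- bio3d_dihedral(coords)
  energy <- function(x) {
    th <- bio3d_dihedral(matrix(x, 4, 3, byrow = TRUE))
    0.5 * 2.5 * wrap_angle(th - theta0)^2
  }
  Hfd <- fd_hessian(energy, as.numeric(t(coords)))
  expect_lt(max(abs(h$matrix - Hfd)) / max(abs(h$matrix)), 1e-6)

  # rigid motions of the 4 atoms are in the null space
  B <- rigid_body_basis(coords)
  expect_lt(max(abs(h$matrix %*% B)), 1e-8 * max(abs(h$matrix)))
})

test_that("degenerate and empty topologies are handled", {
  atoms <- data.frame(name = paste0("C", 1:4), resname = "LIG", resno = 1:4,
                      chain = "A", element = "C")
  col <- path_structure(atoms, cbind(1:4, 0, 0), selection = "all-atom")
  topo <- structure(list(quadruples = matrix(1:4, 1), labels = "d",
                         k_torsion = 1), class = "torsion_topology")
  expect_warning(h <- build_torsional_hessian(col, topo), "degenerate")
  expect_equal(max(abs(h$matrix)), 0)

  none <- structure(list(quadruples = matrix(integer(), 0, 4),
                         labels = character(), k_torsion = 1),
                    class = "torsion_topology")
  expect_equal(max(abs(build_torsional_hessian(col, none)$matrix)), 0)
})

test_that("combining Hessians is additive and raises the spectrum", {
  s <- random_cluster(5, seed = 12)
  anm <- build_anm_hessian(s, cutoff = 50)
  zero_tor <- structure(list(quadruples = matrix(integer(), 0, 4),
                             labels = character(), k_torsion = 1),
                        class = "torsion_topology")
  tor0 <- build_torsional_hessian(s, zero_tor)
  expect_equal(combine_hessians(anm, tor0)$matrix, anm$matrix)

  topo <- structure(list(quadruples = matrix(c(1, 2, 3, 4, 2, 3, 4, 5), 2,
                                             byrow = TRUE),
                         labels = c("d1", "d2"), k_torsion = 1.7),
                    class = "torsion_topology")
  tor <- build_torsional_hessian(s, topo)
  both <- combine_hessians(anm, tor)
  expect_equal(both$flavor, "anm_torsion")
  ea <- sort(eigen(anm$matrix, symmetric = TRUE, only.values = TRUE)$values)
  eb <- sort(eigen(both$matrix, symmetric = TRUE, only.values = TRUE)$values)
  expect_true(all(eb >= ea - 1e-10))  # Weyl: adding a PSD term cannot lower modes

  # sum equals finite differences of the summed potential
  D <- as.matrix(dist(s$coords))
  kmat <- ifelse(D > 0 & D <= 50, 1, 0)
  th0 <- apply(topo$quadruples, 1, function(q)
    bio3d_dihedral(s$coords[q, ]))
  energy <- function(x) {
    X <- matrix(x, ncol = 3, byrow = TRUE)
    e <- network_energy(x, s$coords, kmat)
    for (r in seq_len(nrow(topo$quadruples))) {
      th <- bio3d_dihedral(X[topo$quadruples[r, ], ])
      e <- e + 0.5 * 1.7 * wrap_angle(th - th0[r])^2
    }
    e
  }
  Hfd <- fd_hessian(energy, as.numeric(t(s$coords)))
  expect_lt(max(abs(both$matrix - Hfd)) / max(abs(both$matrix)), 1e-6)
})
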