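test_that("bundled diatomic end states read back with the printed coordinates", {
  l <- read_structure(system.file("extdata", "diatomic_left.pdb",
                                  package = "ompath"), "ca")
  r <- read_structure(system.file("extdata", "diatomic_right.pdb",
                                  package = "ompath"), "ca")
  expect_equal(n_atoms(l), 2L)
  expect_equal(unname(l$coords), rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(unname(r$coords), rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
})

test_that("PDB write/read round-trips coordinates to file precision", {
  s <- polymer_pair(8, 25)$left
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f, "ca")
  expect_equal(n_atoms(s2), n_atoms(s))
  expect_lt(max(abs(s2$coords - s$coords)), 1e-3)
})

test_that("CA selection keeps one site per residue and assigns residue masses", {
  helix <- make_peptide(c("ALA", "GLY", "SER"),
                        list(bb(), bb(), bb()))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(helix, f)
  ca <- read_structure(f, "ca")
  expect_equal(n_atoms(ca), 3L)
  expect_equal(ca$masses, c(71.08, 57.05, 87.08))
  expect_error(read_structure(tempfile(), "ca"), "not found")
})

test_that("end-state pairing keeps the symmetric atom intersection in order", {
  p <- polymer_pair(12, 15)
  same <- pair_end_states(p$left, p$left)
  expect_equal(n_atoms(same$left), n_atoms(p$left))

  # drop one atom from the right: both sides lose it
  r <- p$right
  keep <- -5
  r <- path_structure(r$atoms[keep, ], r$coords[keep, ], r$masses[keep], "ca")
  pr <- pair_end_states(p$left, r)
  expect_equal(n_atoms(pr$left), n_atoms(p$left) - 1L)
  expect_equal(n_atoms(pr$left), n_atoms(pr$right))
  expect_equal(pr$left$atoms$resno, pr$right$atoms$resno)

  expect_gt(superpose_rmsd(p$right, p$left)$rmsd, 0)
  other <- diatomic_pair()$left
  other$atoms$chain <- "B"  # no shared (chain, resno, name) keys
  expect_error(pair_end_states(p$left, other), "common atoms")
})

test_that("superposition is exact for rigid motions and symmetric in its arguments", {
  s <- random_cluster(7, seed = 3)
  expect_equal(superpose_rmsd(s, s)$rmsd, 0)

  moved <- s
  moved$coords <- hinge_rotate(s$coords, pivot = c(1, 2, 3),
                               axis = c(1, 1, 0), angle = 37) +
    matrix(rep(c(3, -2, 5), each = nrow(s$coords)), ncol = 3)
  expect_lt(superpose_rmsd(moved, s)$rmsd, 1e-8)

  a <- random_cluster(6, seed = 10)
  b <- random_cluster(6, seed = 11)
  expect_equal(superpose_rmsd(a, b)$rmsd, superpose_rmsd(b, a)$rmsd,
               tolerance = 1e-8)
  # invariance to rigid pre-transformation of either input
  a2 <- a
  a2$coords <- hinge_rotate(a$coords, c(0, 0, 0), c(0, 1, 1), 63)
  expect_equal(superpose_rmsd(a2, b)$rmsd, superpose_rmsd(a, b)$rmsd,
               tolerance = 1e-8)
})

test_that("minimised RMSD matches a brute-force rotation search and bio3d", {
  a <- random_cluster(4, seed = 21, spread = 2)
  b <- random_cluster(4, seed = 22, spread = 2)
  got <- superpose_rmsd(a, b)$rmsd

  # independent oracle: centre both, scan rotations (axis-angle grid then
  # local refinement) for the minimum RMSD
  ac <- sweep(a$coords, 2, colMeans(a$coords))
  bc <- sweep(b$coords, 2, colMeans(b$coords))
  rms_rot <- function(par) {
    ax <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    rot <- hinge_rotate(ac, c(0, 0, 0), ax, par[3] * 180 / pi)
    sqrt(sum((rot - bc)^2) / nrow(ac))
  }
  best <- Inf; bestp <- NULL
  for (th in seq(0, pi, length.out = 10))
    for (ph in seq(0, 2 * pi, length.out = 14))
      for (an in seq(0, 2 * pi, length.out = 14)) {
        v <- rms_rot(c(th, ph, an))
        if (v < best) { best <- v; bestp <- c(th, ph, an) }
      }
  ref <- stats::optim(bestp, rms_rot, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))$value
  expect_equal(got, ref, tolerance = 1e-4)

  # cross-check against bio3d's least-squares fit
  bfit <- bio3d::fit.xyz(fixed = as.numeric(t(b$coords)),
                         mobile = as.numeric(t(a$coords)))
  expect_equal(got, sqrt(mean((bfit - as.numeric(t(b$coords)))^2) * 3),
               tolerance = 1e-6)
})

test_that("all-by-all RMSD matrices are symmetric with zero diagonal", {
  base <- polymer_pair(10, 20)
  vs <- perturb_variants(base, n_sites = 2, target_rmsd = 0.1, seed = 7)
  structs <- lapply(vs$variants, function(p) p$left)
  M <- rmsd_matrix(structs)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(0, nrow(M)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rmsd_csv(M, f)
  back <- as.matrix(utils::read.csv(f, row.names = 1))
  expect_equal(unname(back), unname(M), tolerance = 1e-6)
})
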