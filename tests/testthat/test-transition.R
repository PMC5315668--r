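test_that("seam search solves symmetric and asymmetric one-dimensional wells", {
  sym <- ompath:::.seam_transition(matrix(1), -1, matrix(1), 1)
  expect_equal(sym$x, 0, tolerance = 1e-9)

  asym <- ompath:::.seam_transition(matrix(1), 0, matrix(2), 1)
  expect_equal(asym$x, 2 - sqrt(2), tolerance = 1e-8)
  expect_equal(asym$U_left, 0.5 * (2 - sqrt(2))^2, tolerance = 1e-8)
  expect_equal(asym$U_left, asym$U_right, tolerance = 1e-10)
})

test_that("seam search matches an augmented-Lagrangian oracle on random 2D wells", {
  set.seed(9)
  for (rep in 1:8) {
    Al <- matrix(rnorm(4), 2); Hl <- crossprod(Al) + 0.3 * diag(2)
    Ar <- matrix(rnorm(4), 2); Hr <- crossprod(Ar) + 0.3 * diag(2)
    al <- rnorm(2); ar <- al + rnorm(2, sd = 2)
    got <- ompath:::.seam_transition(Hl, al, Hr, ar)
    ref <- al_seam_oracle(Hl, al, Hr, ar)
    expect_equal(got$x, ref$x, tolerance = 1e-6)
    expect_equal(got$U_left, ref$U, tolerance = 1e-6)
    expect_lt(abs(got$U_left - got$U_right), 1e-8 * max(got$U_left, 1))
  }
})

test_that("the transition state of paired structures sits on the seam", {
  p <- polymer_pair(12, 25)
  right <- superpose_rmsd(p$right, p$left)$structure
  wl <- make_well(p$left, "amweh")
  wr <- make_well(right, "amweh")
  ts <- find_transition_state(wl, wr)
  expect_lt(abs(well_energy(ts$coords, wl) - well_energy(ts$coords, wr)),
            1e-8 * max(ts$U_left, 1))
  expect_gt(ts$U_left, 0)
})

test_that("time formulas follow their closed forms", {
  expect_identical(time_to_ts_heuristic(1), 2.303)
  expect_equal(time_to_ts_heuristic(2.303), 1.0)
  expect_equal(time_to_ts_heuristic(2), 1.1515)
  expect_error(time_to_ts_heuristic(0), "positive")

  expect_equal(time_of_state(5, 5, k_mean = 2, X = 1.7), 1.7 / 2)
  # 1%-energy start reproduces the heuristic origin of time
  # (2.303 is ln 10 to the printed precision, so t is zero to ~4e-4)
  expect_lt(abs(time_of_state(0.01 * 5, 5, k_mean = 1, X = 2.303)), 5e-4)
  U <- seq(0.06, 1, by = 0.01)
  tt <- time_of_state(U, 1, k_mean = 1)
  expect_true(all(diff(tt) > 0))
  expect_error(time_of_state(2, 1, 1), "exceeds")
  expect_error(time_of_state(-1, 1, 1), "positive")
})

test_that("the free-energy difference has the stated sign convention", {
  expect_equal(delta_g_conf(0, 1, 1), 0)
  expect_equal(delta_g_conf(-1, 2, 2), 1)
  expect_equal(delta_g_conf(0, 1, exp(1)), -1)
  expect_error(delta_g_conf(0, -1, 1), "positive")
  expect_warning(delta_g_conf(0, 1, 5, k_left = 1, k_right = 1), "disagree")
})

test_that("identical end states give a degenerate, zero-barrier run", {
  p <- polymer_pair(8, 0)  # zero bend: identical conformations
  run <- compute_convergence_parameters(p, "amweh", "im")
  expect_true(run$ts$degenerate)
  expect_equal(run$params$dE, 0)
  expect_equal(run$params$dG_conf, 0, tolerance = 1e-12)
  expect_equal(run$params$U_barrier_mean, 0)
})

test_that("swapping the wells flips the signs of dE and dG_conf and the times", {
  p <- polymer_pair(14, 30)
  swapped <- p
  swapped$left <- p$right
  swapped$right <- p$left
  fwd <- compute_convergence_parameters(p, "amweh", "im")
  rev <- compute_convergence_parameters(swapped, "amweh", "im")
  expect_equal(fwd$params$dG_conf, -rev$params$dG_conf, tolerance = 1e-8)
  expect_equal(fwd$params$dE, -rev$params$dE, tolerance = 1e-8)
  expect_equal(fwd$params$t_left, rev$params$t_right, tolerance = 1e-8)
  expect_equal(fwd$params$t_right, rev$params$t_left, tolerance = 1e-8)
})

test_that("identical inputs give identical convergence parameters", {
  p <- polymer_pair(10, 25)
  a <- compute_convergence_parameters(p, "amweh", "im")
  b <- compute_convergence_parameters(p, "amweh", "im")
  expect_identical(a$params, b$params)
})

test_that("the stitched trajectory is ordered with a single energy maximum", {
  p <- polymer_pair(12, 25)
  run <- compute_convergence_parameters(p, "anm", "im")
  tr <- run$trajectory
  expect_true(all(diff(tr$time) >= -1e-12))
  peak <- which.max(tr$energy)
  expect_true(all(diff(tr$energy[seq_len(peak)]) >= -1e-9))
  expect_true(all(diff(tr$energy[peak:length(tr$energy)]) <= 1e-9))
  expect_setequal(unique(tr$well), c("left", "right"))
  # branch endpoints: near-equilibrium start and end
  expect_lt(tr$energy[1], 0.02 * run$ts$U_left)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_params_tsv(run, f)
  expect_true(any(grepl("dG_conf", readLines(f))))
})
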