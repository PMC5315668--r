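# Minimal-norm solve M x = b via symmetric pseudo-inverse, anchored at x0:
# returns x0 + pinv(M) (b - M x0), i.e. the solution closest to x0.
.pinv_solve <- function(M, b, x0, tol = 1e-9) {
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  r <- b - M %*% x0
  y <- crossprod(e$vectors[, keep, drop = FALSE], r) / e$values[keep]
  as.numeric(x0 + e$vectors[, keep, drop = FALSE] %*% y)
}

# Transition state between two quadratic wells given raw matrices/vectors.
# Minimizes the common energy on the seam {x : U_l(x) = U_r(x)} via the
# stationarity family x(lambda) = [(1-l) H_l + l H_r]^+ [(1-l) H_l a_l +
# l H_r a_r], root-finding on U_l - U_r; the pseudo-inverse solution is
# anchored at the straight-line midpoint (tie-break: nearest the line).
.seam_transition <- function(Hl, al, Hr, ar, tol = .Machine$double.eps^0.75) {
  al <- as.numeric(al); ar <- as.numeric(ar)
  Ul <- function(x) 0.5 * sum((x - al) * (Hl %*% (x - al)))
  Ur <- function(x) 0.5 * sum((x - ar) * (Hr %*% (x - ar)))
  if (sqrt(mean((al - ar)^2)) < 1e-12) {
    return(list(x = al, U_left = 0, U_right = 0, lambda = 0.5,
                degenerate = TRUE))
  }
  mid <- (al + ar) / 2
  xs <- function(l) {
    M <- (1 - l) * Hl + l * Hr
    b <- (1 - l) * (Hl %*% al) + l * (Hr %*% ar)
    .pinv_solve(M, b, mid)
  }
  g <- function(l) { x <- xs(l); Ul(x) - Ur(x) }
  root <- stats::uniroot(g, c(1e-10, 1 - 1e-10), tol = tol,
                         check.conv = TRUE, maxiter = 200)
  x <- xs(root$root)
  ul <- Ul(x); ur <- Ur(x)
  if (abs(ul - ur) > 1e-8 * max(ul, ur, 1))
    stop(sprintf(
      "seam search failed to converge: U_left = %.6g, U_right = %.6g, |grad gap| = %.3g",
      ul, ur, abs(ul - ur)))
  list(x = x, U_left = ul, U_right = ur, lambda = root$root,
       degenerate = FALSE)
}

#' Transition state on the iso-energy seam between two wells
#'
#' Finds the structure x-dagger minimising the common energy on the seam
#' where the two quadratic surfaces (each measured from its own equilibrium)
#' are equal — the point at which the left- and right-well most-probable
#' trajectories meet. The constrained stationarity conditions reduce to a
#' one-parameter family of linear solves; a root of the energy gap along
#' that family gives the seam point, and among seam solutions the one
#' nearest the straight-line midpoint is kept.
#'
#' @param well_l,well_r `path_well` objects built on paired coordinates
#'   (identical atom ordering).
#' @return Object of class `transition_state`: `coords` (N x 3), `U_left`,
#'   `U_right` (the barrier heights seen from each well), `lambda`,
#'   `degenerate` (TRUE when the end states coincide).
#' @export
find_transition_state <- function(well_l, well_r) {
  al <- as.numeric(t(well_l$structure$coords))
  ar <- as.numeric(t(well_r$structure$coords))
  if (length(al) != length(ar)) stop("wells have different dimensions")
  ts <- .seam_transition(well_l$hessian$matrix, al, well_r$hessian$matrix, ar)
  structure(list(coords = matrix(ts$x, ncol = 3, byrow = TRUE),
                 U_left = ts$U_left, U_right = ts$U_right,
                 lambda = ts$lambda, degenerate = ts$degenerate),
            class = "transition_state")
}

#' @export
print.transition_state <- function(x, ...) {
  cat(sprintf("transition_state: U_left = %.6g, U_right = %.6g (lambda = %.4f)\n",
              x$U_left, x$U_right, x$lambda))
  invisible(x)
}

#' Heuristic time to the transition state
#'
#' The closed-form estimate `2.303 / k_mean` obtained by starting the clock
#' when the structure is displaced from equilibrium by 10% of the distance
#' to the transition state (1% of the barrier energy in a quadratic well).
#'
#' @param k_mean Mean force constant (> 0).
#' @return Time in reduced units.
#' @export
time_to_ts_heuristic <- function(k_mean) {
  if (any(k_mean <= 0)) stop("mean force constant must be positive")
  2.303 / k_mean
}

#' Energy-domain time of a state on the approach to the transition state
#'
#' Re-times the trajectory as a function of energy:
#' `t(U) = (1/k_mean) (X + 0.5 log(U / U_ts))`, so time accumulates only
#' while the structure is displaced from equilibrium. Energies below
#' `epsilon_U * U_ts` are clamped to the epsilon time. With the default
#' `X = 2.303` the time at the 1%-energy start is zero and the total time to
#' the transition state reduces exactly to the heuristic
#' [time_to_ts_heuristic()].
#'
#' @param U Energy (or vector of energies) of states along the branch.
#' @param U_ts Transition-state energy in the same well.
#' @param k_mean Mean force constant of the well.
#' @param X Dimensionless offset constant; default 2.303.
#' @param epsilon_U Lower energy clamp as a fraction of `U_ts`, in (0, 1).
#' @return Time(s) in reduced units.
#' @export
time_of_state <- function(U, U_ts, k_mean, X = 2.303, epsilon_U = 0.01) {
  stopifnot(k_mean > 0, U_ts > 0, epsilon_U > 0, epsilon_U < 1)
  if (any(U <= 0)) stop("energy must be positive")
  if (any(U > U_ts * (1 + 1e-8))) stop("energy exceeds the barrier")
  (X + 0.5 * log(pmax(U, epsilon_U * U_ts) / U_ts)) / k_mean
}

#' Conformational free-energy difference between the end states
#'
#' From the ratio of forward and reverse Arrhenius rates with collision
#' frequencies proportional to the wells' mean force constants:
#' `dG_conf = -dE - kBT log(t_right / t_left)`, where `dE` is the difference
#' between reverse and forward barrier heights and `t_left`, `t_right` the
#' times to the transition state. When the times derive from the heuristic
#' `2.303 / k_mean`, this is algebraically identical to
#' `-kBT log(k_left / k_right) - dE` (supply `k_left`/`k_right` to have the
#' identity checked).
#'
#' @param dE Barrier-height difference `U_right - U_left`.
#' @param t_left,t_right Times to the transition state from each well (> 0).
#' @param kBT Thermal energy in the same (reduced) units, default 1.
#' @param k_left,k_right Optional mean force constants for the cross-check.
#' @return `dG_conf` (scalar).
#' @export
delta_g_conf <- function(dE, t_left, t_right, kBT = 1,
                         k_left = NULL, k_right = NULL) {
  if (t_left <= 0 || t_right <= 0) stop("times must be positive")
  dg <- -dE - kBT * log(t_right / t_left)
  if (!is.null(k_left) && !is.null(k_right)) {
    dg13 <- -kBT * log(k_left / k_right) - dE
    if (abs(dg - dg13) > 1e-9 * max(abs(dg), abs(dg13), 1))
      warning("rate-form and time-form free energies disagree: the supplied ",
              "times do not derive from the mean force constants")
  }
  dg
}

# Seam-crossing point of the left-well escape trajectory computed with a
# modal time window Tw: the time at which the path from a_l to a_r crosses
# U_l = U_r. Used for the convergence-invariance check.
.ts_crossing <- function(well_l, well_r, Tw) {
  al <- well_l$structure$coords
  ar <- well_r$structure$coords
  frame_at <- function(t) {
    well_trajectory(al, ar, well_l, 0, Tw, t)$coords[[1]]
  }
  g <- function(t) {
    x <- frame_at(t)
    well_energy(x, well_l) - well_energy(x, well_r)
  }
  root <- stats::uniroot(g, c(0, Tw), tol = 1e-12 * Tw, maxiter = 200)
  frame_at(root$root)
}

#' Full PATH computation between two end states
#'
#' Builds both wells, locates the transition state on the iso-energy seam,
#' derives the convergence parameters (mean barrier height, barrier-height
#' difference, energy-domain times to the transition state from either side,
#' and the conformational free-energy difference), and stitches the two
#' in-well branches into one trajectory re-timed in the energy domain so
#' that time accumulates only outside the near-equilibrium region.
#'
#' A convergence-invariance check recomputes the seam-crossing point of the
#' left-well escape trajectory with the modal time window doubled; the
#' transition-state structure must move by less than `conv_tol` (RMSD,
#' Angstrom), the sign that the system was given enough time.
#'
#' @param pair An `end_state_pair` (see [pair_end_states()]).
#' @param flavor Hessian flavor: `"anm"`, `"anm_torsion"` or `"amweh"`.
#' @param mean_k Mean-force-constant estimator: `"im"`, `"trace"`, `"fpc"`.
#' @param variance_fraction Covariance fraction for the inverse-mean
#'   estimator, default 0.95.
#' @param k_anm,cutoff,k_torsion Hessian parameters.
#' @param kBT Thermal energy (reduced), default 1.
#' @param X Energy-domain time offset, default 2.303.
#' @param epsilon_U Lower energy clamp fraction, default 0.01.
#' @param n_frames Frames per branch in the emitted trajectory.
#' @param time_factor Modal time window as a multiple of the slowest mode
#'   period 1/lambda_min, default 12.
#' @param align Superpose the right structure onto the left before the
#'   computation (default TRUE).
#' @param check_convergence Run the window-doubling invariance check
#'   (default TRUE); failure is an error.
#' @param conv_tol RMSD tolerance of the invariance check, Angstrom.
#' @return Object of class `path_run`: `params` (one-row tibble with
#'   `U_barrier_mean`, `dE`, `t_left`, `t_right`, `dG_conf`, `k_left`,
#'   `k_right`, `flavor`, `mean_k`), `trajectory` (a `path_trajectory`),
#'   `ts` (the `transition_state`), `wells`.
#' @export
compute_convergence_parameters <- function(
    pair, flavor = c("anm", "anm_torsion", "amweh"),
    mean_k = c("im", "trace", "fpc"), variance_fraction = 0.95,
    k_anm = 1, cutoff = NULL, k_torsion = 1,
    kBT = 1, X = 2.303, epsilon_U = 0.01,
    n_frames = 60, time_factor = 12,
    align = TRUE, check_convergence = TRUE, conv_tol = 1e-4) {
  flavor <- match.arg(flavor)
  mean_k <- match.arg(mean_k)
  left <- pair$left
  right <- pair$right
  if (align) right <- superpose_rmsd(right, left)$structure
  wl <- make_well(left, flavor, k_anm, cutoff, k_torsion, mean_k,
                  variance_fraction)
  wr <- make_well(right, flavor, k_anm, cutoff, k_torsion, mean_k,
                  variance_fraction)
  ts <- find_transition_state(wl, wr)
  kl <- wl$k_mean$value
  kr <- wr$k_mean$value
  dE <- ts$U_right - ts$U_left
  if (ts$degenerate) {
    t_l <- X / kl
    t_r <- X / kr
    dG <- delta_g_conf(dE, t_l, t_r, kBT)
    traj <- well_trajectory(left$coords, left$coords, wl, 0, 1, c(0, 1))
    params <- tibble::tibble(
      U_barrier_mean = 0, dE = 0, t_left = t_l, t_right = t_r,
      dG_conf = dG, k_left = kl, k_right = kr,
      flavor = flavor, mean_k = mean_k)
    return(structure(list(params = params, trajectory = traj, ts = ts,
                          wells = list(left = wl, right = wr)),
                     class = "path_run"))
  }
  t_l <- time_of_state(ts$U_left, ts$U_left, kl, X, epsilon_U)
  t_r <- time_of_state(ts$U_right, ts$U_right, kr, X, epsilon_U)
  dG <- delta_g_conf(dE, t_l, t_r, kBT, k_left = kl, k_right = kr)

  if (check_convergence) {
    Tw <- time_factor / min(wl$spectrum$values[!wl$spectrum$zero])
    x1 <- .ts_crossing(wl, wr, Tw)
    x2 <- .ts_crossing(wl, wr, 2 * Tw)
    shift <- sqrt(mean((x1 - x2)^2) * 3)
    if (shift >= conv_tol)
      stop(sprintf(
        "transition state not converged: doubling the time window moved it by %.3g A (tolerance %.3g)",
        shift, conv_tol))
  }

  traj <- .energy_domain_trajectory(wl, wr, ts, kl, kr, X, epsilon_U,
                                    n_frames, time_factor, t_l, t_r)
  params <- tibble::tibble(
    U_barrier_mean = (ts$U_left + ts$U_right) / 2, dE = dE,
    t_left = t_l, t_right = t_r, dG_conf = dG,
    k_left = kl, k_right = kr, flavor = flavor, mean_k = mean_k)
  structure(list(params = params, trajectory = traj, ts = ts,
                 wells = list(left = wl, right = wr)),
            class = "path_run")
}

# Stitch the two in-well branches, re-timed in the energy domain. Each
# branch is the modal path between the well minimum and the seam structure;
# frames are sampled on the climb (energy >= epsilon_U * U_ts) and assigned
# Eq.-5-style times; the right branch descends after the transition state.
.energy_domain_trajectory <- function(wl, wr, ts, kl, kr, X, epsilon_U,
                                      n_frames, time_factor, t_l, t_r) {
  branch <- function(well, U_ts, side) {
    lam_min <- min(well$spectrum$values[!well$spectrum$zero])
    Tw <- time_factor / lam_min
    a <- well$structure$coords
    # energy along the path is monotone in t; find the epsilon start
    en_at <- function(t) well_trajectory(a, ts$coords, well, 0, Tw, t)$energy[1]
    f <- function(t) en_at(t) - epsilon_U * U_ts
    t_eps <- stats::uniroot(f, c(0, Tw), tol = 1e-12 * Tw)$root
    tt <- seq(t_eps, Tw, length.out = n_frames)
    well_trajectory(a, ts$coords, well, 0, Tw, tt, well_tag = side)
  }
  bl <- branch(wl, ts$U_left, "left")
  br <- branch(wr, ts$U_right, "right")
  tl_frames <- time_of_state(pmin(bl$energy, ts$U_left), ts$U_left, kl, X,
                             epsilon_U)
  tr_frames <- time_of_state(pmin(br$energy, ts$U_right), ts$U_right, kr, X,
                             epsilon_U)
  t_eps_l <- time_of_state(epsilon_U * ts$U_left, ts$U_left, kl, X, epsilon_U)
  t_eps_r <- time_of_state(epsilon_U * ts$U_right, ts$U_right, kr, X, epsilon_U)
  # left branch climbs 0 -> t_l - t_eps; right branch descends afterwards
  time_l <- tl_frames - t_eps_l
  time_r <- (t_l - t_eps_l) + (t_r - rev(tr_frames))
  rev_idx <- rev(seq_along(br$time))
  structure(list(
    coords = c(bl$coords, br$coords[rev_idx]),
    time = c(time_l, time_r),
    energy = c(bl$energy, br$energy[rev_idx]),
    well = c(bl$well, br$well[rev_idx])),
    class = "path_trajectory")
}

#' @export
print.path_run <- function(x, ...) {
  p <- x$params
  cat(sprintf("path_run [%s, %s]\n", p$flavor, p$mean_k))
  cat(sprintf("  <U+>     = %.6g\n", p$U_barrier_mean))
  cat(sprintf("  dE       = %.6g\n", p$dE))
  cat(sprintf("  t_left   = %.6g   t_right = %.6g\n", p$t_left, p$t_right))
  cat(sprintf("  dG_conf  = %.6g\n", p$dG_conf))
  cat(sprintf("  k_left   = %.6g   k_right = %.6g\n", p$k_left, p$k_right))
  invisible(x)
}

#' One-row parameter table of a PATH run
#' @param x A `path_run`.
#' @param ... Unused.
#' @return The one-row params tibble.
#' @method glance path_run
#' @export
glance.path_run <- function(x, ...) x$params

#' Write convergence parameters as key-value TSV
#' @param run A `path_run`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_params_tsv <- function(run, path) {
  p <- run$params
  num <- vapply(p, is.numeric, logical(1))
  df <- data.frame(key = names(p),
                   value = vapply(seq_along(p), function(i)
                     if (num[i]) format(p[[i]], digits = 15) else
                       as.character(p[[i]]), character(1)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
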