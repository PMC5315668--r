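#' Build a harmonic well around an equilibrium structure
#'
#' Bundles the equilibrium coordinates, the chosen Hessian flavor, its mode
#' spectrum and the mean force constant into the description of one
#' potential-energy well of the two-well transition problem.
#'
#' @param s Equilibrium [path_structure].
#' @param flavor `"anm"`, `"anm_torsion"` or `"amweh"`.
#' @param k_anm,cutoff ANM parameters (see [build_anm_hessian()]).
#' @param k_torsion Torsional stiffness (see [enumerate_torsions()]).
#' @param mean_k Mean-force-constant estimator (see [mean_force_constant()]).
#' @param variance_fraction Covariance fraction for the inverse-mean
#'   estimator.
#' @return Object of class `path_well`: `structure`, `hessian`, `spectrum`,
#'   `k_mean`.
#' @export
make_well <- function(s, flavor = c("anm", "anm_torsion", "amweh"),
                      k_anm = 1, cutoff = NULL, k_torsion = 1,
                      mean_k = c("im", "trace", "fpc"),
                      variance_fraction = 0.95) {
  flavor <- match.arg(flavor)
  mean_k <- match.arg(mean_k)
  h <- switch(flavor,
    anm = build_anm_hessian(s, k_anm, cutoff),
    anm_torsion = {
      anm <- build_anm_hessian(s, k_anm, cutoff)
      topo <- enumerate_torsions(s, k_torsion)
      if (nrow(topo$quadruples) == 0L) {
        warning("no torsional degrees of freedom found; ",
                "anm_torsion reduces to plain ANM")
        anm$flavor <- "anm_torsion"
        anm
      } else combine_hessians(anm, build_torsional_hessian(s, topo))
    },
    amweh = build_amweh_hessian(s)
  )
  spec <- eigendecompose(h)
  structure(list(structure = s, hessian = h, spectrum = spec,
                 k_mean = mean_force_constant(spec, mean_k, variance_fraction)),
            class = "path_well")
}

#' @export
print.path_well <- function(x, ...) {
  cat(sprintf("path_well [%s]: N = %d, k_mean(%s) = %.4g\n",
              x$hessian$flavor, n_atoms(x$structure),
              x$k_mean$method, x$k_mean$value))
  invisible(x)
}

#' Harmonic well energy of a coordinate state
#'
#' Half the quadratic form of the displacement from the well's equilibrium
#' structure under its Hessian; zero at equilibrium and along any rigid-body
#' (zero-mode) displacement.
#'
#' @param x Coordinates as an N x 3 matrix or 3N vector.
#' @param well A `path_well`.
#' @return Scalar energy (reduced units for ANM flavors; kJ mol^-1-scaled
#'   for AMWEH).
#' @export
well_energy <- function(x, well) {
  d <- as.numeric(t(x)) - as.numeric(t(well$structure$coords))
  if (length(d) != nrow(well$hessian$matrix)) stop("dimension mismatch")
  0.5 * sum(d * (well$hessian$matrix %*% d))
}

# sinh(u)/sinh(U) for 0 <= u <= U without overflow.
.sinh_ratio <- function(u, U) {
  exp(u - U) * (1 - exp(-2 * u)) / (1 - exp(-2 * U))
}

#' Most-probable in-well trajectory between two states
#'
#' The Onsager-Machlup stationary path inside one harmonic well, solved per
#' normal mode: each vibrational modal coordinate q (measured from the well
#' minimum) follows
#' `q(t) = [q1 sinh(G (t2 - t)) + q2 sinh(G (t - t1))] / sinh(G (t2 - t1))`
#' with G the mode's Hessian eigenvalue, which is the unique solution of the
#' modal boundary-value problem q'' = G^2 q with q(t1) = q1, q(t2) = q2.
#' Zero (rigid-body) modes interpolate linearly. Large exponents are handled
#' by the asymptotic exponential form.
#'
#' @param x1,x2 Boundary coordinate states (N x 3 or 3N).
#' @param well A `path_well`.
#' @param t1,t2 Boundary times, `t2 > t1`.
#' @param times Evaluation times within `[t1, t2]`.
#' @param well_tag Label stored with each frame (`"left"` or `"right"`).
#' @return Object of class `path_trajectory`: list with `coords` (list of
#'   N x 3 matrices), `time`, `energy` (well energy per frame), `well` tag.
#' @export
well_trajectory <- function(x1, x2, well, t1 = 0, t2, times,
                            well_tag = "left") {
  stopifnot(t2 > t1, all(times >= t1 - 1e-12), all(times <= t2 + 1e-12))
  a <- as.numeric(t(well$structure$coords))
  q1 <- crossprod(well$spectrum$vectors, as.numeric(t(x1)) - a)
  q2 <- crossprod(well$spectrum$vectors, as.numeric(t(x2)) - a)
  lam <- well$spectrum$values
  zero <- well$spectrum$zero
  n3 <- length(a)
  coords <- vector("list", length(times))
  energy <- numeric(length(times))
  for (f in seq_along(times)) {
    t <- min(max(times[f], t1), t2)
    q <- numeric(n3)
    s <- (t - t1) / (t2 - t1)
    q[zero] <- q1[zero] + (q2[zero] - q1[zero]) * s
    G <- lam[!zero]
    q[!zero] <- q1[!zero] * .sinh_ratio(G * (t2 - t), G * (t2 - t1)) +
      q2[!zero] * .sinh_ratio(G * (t - t1), G * (t2 - t1))
    x <- a + as.numeric(well$spectrum$vectors %*% q)
    coords[[f]] <- matrix(x, ncol = 3, byrow = TRUE)
    energy[f] <- 0.5 * sum(lam[!zero] * q[!zero]^2)
  }
  structure(list(coords = coords, time = times, energy = energy,
                 well = rep(well_tag, length(times))),
            class = "path_trajectory")
}

#' @export
print.path_trajectory <- function(x, ...) {
  cat(sprintf("path_trajectory: %d frames, t in [%.4g, %.4g], U in [%.4g, %.4g]\n",
              length(x$time), min(x$time), max(x$time),
              min(x$energy), max(x$energy)))
  invisible(x)
}

#' Convert a trajectory to a tidy frame table
#' @param x A `path_trajectory`.
#' @param ... Unused.
#' @return Tibble with one row per frame: `frame`, `time`, `energy`, `well`.
#' @method tidy path_trajectory
#' @export
tidy.path_trajectory <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$time), time = x$time,
                 energy = x$energy, well = x$well)
}

#' Write a trajectory as a multi-model PDB
#' @param traj A `path_trajectory`.
#' @param s The [path_structure] providing the atom table.
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_pdb <- function(traj, s, path) {
  write_structure(s, path, coords_list = traj$coords)
}
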