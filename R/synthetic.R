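#' Diatomic two-state toy system
#'
#' The minimal two-well system: two atoms on the x axis at separation 2
#' Angstrom in the left state (atoms at (1,0,0) and (-1,0,0)) and
#' separation 1 in the right state ((0.5,0,0), (-0.5,0,0)). The spring
#' constant to use when building its wells is stored in the `"k_anm"`
#' attribute.
#'
#' @param k Force constant for the single spring (reduced units).
#' @return An `end_state_pair` of two 2-atom structures.
#' @export
diatomic_pair <- function(k = 1) {
  stopifnot(k > 0)
  atoms <- tibble::tibble(name = "CA", resname = "UNK", resno = 1:2,
                          chain = "A", element = "C")
  left <- path_structure(atoms, rbind(c(1, 0, 0), c(-1, 0, 0)),
                         selection = "ca")
  right <- path_structure(atoms, rbind(c(0.5, 0, 0), c(-0.5, 0, 0)),
                          selection = "ca")
  pair <- pair_end_states(left, right)
  attr(pair, "k_anm") <- k
  pair
}

#' Synthetic CA helix with a hinge-bent second conformation
#'
#' An ideal CA-only alpha-helical chain (rise 1.5 Angstrom per residue,
#' radius 2.3 Angstrom, 100 degrees of twist per residue) as the left
#' state; the right state is the same chain with its second half rotated
#' rigidly about a hinge axis through the midpoint CA — the rigid-domain
#' motion typical of large conformational changes. All sites carry the mean
#' residue mass (110 amu). The construction is deterministic; `seed` is
#' accepted for interface uniformity.
#'
#' @param n_residues Chain length (>= 4).
#' @param bend_angle Hinge angle in degrees (0 gives identical states).
#' @param seed Unused by the deterministic geometry; kept for API symmetry.
#' @return An `end_state_pair` of CA-only structures.
#' @export
polymer_pair <- function(n_residues, bend_angle = 30, seed = 1) {
  stopifnot(n_residues >= 4)
  i <- seq_len(n_residues) - 1
  coords <- cbind(2.3 * cos(i * 100 * pi / 180),
                  2.3 * sin(i * 100 * pi / 180),
                  1.5 * i)
  atoms <- tibble::tibble(name = "CA", resname = "UNK",
                          resno = seq_len(n_residues), chain = "A",
                          element = "C")
  left <- path_structure(atoms, coords, selection = "ca")
  hinge <- ceiling(n_residues / 2)
  right_coords <- coords
  moving <- (hinge + 1):n_residues
  right_coords[moving, ] <- hinge_rotate(coords[moving, , drop = FALSE],
                                         pivot = coords[hinge, ],
                                         axis = c(1, 0, 0),
                                         angle = bend_angle)
  right <- path_structure(atoms, right_coords, selection = "ca")
  pair_end_states(left, right)
}

#' Rotate points rigidly about an axis through a pivot
#' @param x M x 3 coordinates.
#' @param pivot Point on the rotation axis.
#' @param axis Direction of the axis (normalised internally).
#' @param angle Rotation angle in degrees.
#' @return Rotated M x 3 coordinates.
#' @export
hinge_rotate <- function(x, pivot, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(x, 2, pivot) %*% t(R), 2, pivot, FUN = "+")
}

#' Combinatorial virtual-mutant perturbations of a structure pair
#'
#' Emulates locally perturbed variant models: for each of `n_sites` chosen
#' residues a smooth random displacement field is generated (Gaussian
#' 3-vectors on atoms within `radius` Angstrom of the site, damped as
#' exp(-d^2 / (2 (radius/2)^2))) and rescaled so that applying one site's
#' field alone changes the all-atom RMSD by about `target_rmsd`. The same
#' per-site field is added to both end states (matched atoms), so the
#' perturbations are comparable in the two wells, and all 2^n_sites
#' presence/absence combinations are returned.
#'
#' @param base An `end_state_pair` to perturb.
#' @param n_sites Number of mutated sites, default 4.
#' @param target_rmsd Per-site all-atom RMSD to the base, Angstrom
#'   (default 0.1).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param radius Neighbourhood radius of a site, Angstrom (default 6).
#' @param site_resnos Optional residue numbers of the sites; default evenly
#'   spaced along the chain.
#' @return Object of class `variant_set`: `variants` (named list of
#'   `end_state_pair`), `manifest` (tibble: variant id, sites present,
#'   RMSD of each state to base), `design` (the matching
#'   [factorial_design()]), `sites`.
#' @export
perturb_variants <- function(base, n_sites = 4, target_rmsd = 0.1, seed = 1,
                             radius = 6, site_resnos = NULL) {
  stopifnot(target_rmsd > 0)
  resnos <- sort(unique(base$left$atoms$resno))
  if (n_sites > length(resnos)) stop("more sites than residues")
  if (is.null(site_resnos))
    site_resnos <- resnos[round(seq(1, length(resnos),
                                    length.out = n_sites + 2))[2:(n_sites + 1)]]
  stopifnot(length(site_resnos) == n_sites)
  n <- n_atoms(base$left)
  set.seed(seed)
  fields <- lapply(site_resnos, function(rn) {
    site_idx <- which(base$left$atoms$resno == rn)
    centre <- colMeans(base$left$coords[site_idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(base$left$coords, 2, centre)^2))
    damp <- exp(-d^2 / (2 * (radius / 2)^2)) * (d <= radius)
    if (sum(damp > 0) < 1) stop("site ", rn, " has no atoms within radius")
    F <- matrix(stats::rnorm(3 * n), n, 3) * damp
    F * target_rmsd / sqrt(sum(F^2) / n)
  })
  design <- factorial_design(n_sites, coding = "01",
                             labels = paste0("S", site_resnos))
  apply_field <- function(s, disp) {
    out <- s
    out$coords <- s$coords + disp
    out
  }
  variants <- vector("list", nrow(design$variants))
  man <- vector("list", nrow(design$variants))
  for (v in seq_len(nrow(design$variants))) {
    pres <- as.numeric(design$variants[v, seq_len(n_sites)])
    disp <- Reduce(`+`, c(list(matrix(0, n, 3)),
                          fields[which(pres == 1)]))
    pv <- base
    pv$left <- apply_field(base$left, disp)
    pv$right <- apply_field(base$right, disp)
    class(pv) <- class(base)
    variants[[v]] <- pv
    man[[v]] <- tibble::tibble(
      variant = design$variants$variant[v],
      sites = paste(design$labels[pres == 1], collapse = "+"),
      rmsd_left = superpose_rmsd(pv$left, base$left)$rmsd,
      rmsd_right = superpose_rmsd(pv$right, base$right)$rmsd)
  }
  names(variants) <- design$variants$variant
  structure(list(variants = variants, manifest = do.call(rbind, man),
                 design = design, sites = site_resnos),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants over sites %s\n",
              length(x$variants), paste(x$sites, collapse = ", ")))
  invisible(x)
}

#' Simulate kinetic observables from a linear variant model
#'
#' Draws `y = X beta + N(0, sigma^2)` over the design matrix of a factorial
#' variant design — the synthetic stand-in for per-variant kinetic
#' measurements used to exercise the regression layer.
#'
#' @param design A `variant_design` or plain design matrix.
#' @param beta Coefficient vector matching the design columns.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return Numeric response vector, one value per design row.
#' @export
simulate_kinetics <- function(design, beta, sigma, seed = 1) {
  X <- if (inherits(design, "variant_design")) design$design else
    as.matrix(design)
  if (length(beta) != ncol(X))
    stop("beta length must match the number of design columns")
  stopifnot(sigma >= 0)
  set.seed(seed)
  as.numeric(X %*% beta + stats::rnorm(nrow(X), 0, sigma))
}
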