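#' Construct a Hessian model object
#'
#' Internal constructor shared by the ANM, torsional and AMWEH builders.
#' The matrix is symmetrised (guarding against last-bit asymmetry from
#' floating-point accumulation) and carries a flavor tag plus a reference to
#' the equilibrium structure it was built around.
#'
#' @param matrix 3N x 3N numeric matrix.
#' @param flavor One of `"anm"`, `"torsion"`, `"anm_torsion"`, `"amweh"`.
#' @param structure The [path_structure] the Hessian was built around.
#' @return Object of class `path_hessian`.
#' @keywords internal
new_path_hessian <- function(matrix, flavor, structure) {
  matrix <- (matrix + t(matrix)) / 2
  structure(list(matrix = matrix, flavor = flavor, structure = structure),
            class = "path_hessian")
}

#' @export
print.path_hessian <- function(x, ...) {
  cat(sprintf("path_hessian [%s]: %d x %d (N = %d atoms)\n",
              x$flavor, nrow(x$matrix), ncol(x$matrix), n_atoms(x$structure)))
  invisible(x)
}

.pair_dists <- function(coords) as.matrix(stats::dist(coords))

# Scatter per-pair spring constants into ANM super-element blocks:
# off-diagonal 3x3 block for pair (i,j) is -k_ij * d d^T / |d|^2 with
# d = x_i - x_j at equilibrium; diagonal blocks make block-rows sum to zero.
.assemble_network_hessian <- function(coords, kmat) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  idx <- function(i) (3 * (i - 1) + 1):(3 * i)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- kmat[i, j]
      if (k == 0) next
      d <- coords[i, ] - coords[j, ]
      B <- -k * tcrossprod(d) / sum(d^2)
      H[idx(i), idx(j)] <- B
      H[idx(j), idx(i)] <- B
      H[idx(i), idx(i)] <- H[idx(i), idx(i)] - B
      H[idx(j), idx(j)] <- H[idx(j), idx(j)] - B
    }
  }
  H
}

# Connected components of the spring network (pairs with k > 0).
.network_components <- function(kmat) {
  n <- nrow(kmat)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(kmat[v, ] > 0 & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  max(comp)
}

#' Build an anisotropic network model (ANM) Hessian
#'
#' All atom pairs closer than `cutoff` at equilibrium are connected by
#' identical Hookean springs of stiffness `k_anm`; the potential is the sum
#' of half k times the squared deviation of each pair distance from its
#' equilibrium value. The Hessian at the equilibrium structure has the
#' standard super-element form and annihilates rigid-body motions.
#'
#' @param s Equilibrium [path_structure].
#' @param k_anm Spring constant (reduced energy/A^2), default 1.
#' @param cutoff Interaction radius in Angstrom; default 12 for all-atom
#'   models and 15 for CA-only models.
#' @return A `path_hessian` with flavor `"anm"`.
#' @export
build_anm_hessian <- function(s, k_anm = 1, cutoff = NULL) {
  stopifnot(k_anm > 0)
  if (is.null(cutoff)) cutoff <- if (s$selection == "ca") 15 else 12
  stopifnot(cutoff > 0)
  D <- .pair_dists(s$coords)
  kmat <- ifelse(D > 0 & D <= cutoff, k_anm, 0)
  diag(kmat) <- 0
  if (all(kmat == 0))
    stop("no atom pairs within cutoff ", cutoff, " A")
  nc <- .network_components(kmat)
  if (nc > 1L)
    stop("spring network is disconnected (", nc, " components); ",
         "increase the cutoff")
  new_path_hessian(.assemble_network_hessian(s$coords, kmat), "anm", s)
}

#' Piecewise empirical CA-pair force constant
#'
#' Distance-dependent spring stiffness fitted to all-atom molecular-dynamics
#' fluctuations of CA pairs: a linear regime below 0.4 nm and an r^-6 decay
#' above it. The two branches are kept exactly as the published fit (they do
#' not meet at 0.4 nm; the discontinuity is intentional).
#'
#' @param r Separation in nm (vectorised).
#' @param slope,intercept Short-range branch parameters, kJ mol^-1 nm^-3 and
#'   kJ mol^-1 nm^-2.
#' @param long_coeff Long-range coefficient, kJ nm^4 mol^-1.
#' @param r_switch Branch switch distance, nm.
#' @return Stiffness in kJ mol^-1 nm^-2.
#' @export
amweh_force_constant <- function(r, slope = 8.6e5, intercept = 2.39e5,
                                 long_coeff = 128, r_switch = 0.4) {
  if (any(r <= 0)) stop("separation must be positive")
  ifelse(r < r_switch, slope * r - intercept, long_coeff * r^-6)
}

#' Build the mass-weighted empirical CA-only Hessian (AMWEH)
#'
#' ANM-style network over CA sites in which each pair spring takes the
#' empirical distance-dependent stiffness of [amweh_force_constant()]
#' (distances converted from Angstrom to nm), weighted by the masses of the
#' pair as sqrt(m_i m_j) normalised by the mean site mass. All pairs
#' interact (the r^-6 tail supplies a natural cutoff). The assembled matrix
#' is converted to kJ mol^-1 A^-2 so quadratic-form energies use the
#' package-wide Angstrom coordinates.
#'
#' @param s CA-only equilibrium [path_structure].
#' @return A `path_hessian` with flavor `"amweh"`.
#' @export
build_amweh_hessian <- function(s) {
  if (s$selection != "ca")
    stop("AMWEH is defined for CA-only structures")
  D_nm <- .pair_dists(s$coords) / 10
  m <- s$masses
  w <- sqrt(outer(m, m)) / mean(m)
  kmat <- matrix(0, nrow(D_nm), ncol(D_nm))
  off <- D_nm > 0
  kmat[off] <- amweh_force_constant(D_nm[off]) * w[off]
  if (any(kmat[off] <= 0))
    warning("nonpositive empirical force constant at very short CA-CA ",
            "separation (< 0.278 nm); check the input geometry")
  kmat <- kmat / 100  # kJ mol^-1 nm^-2 -> kJ mol^-1 A^-2
  new_path_hessian(.assemble_network_hessian(s$coords, kmat), "amweh", s)
}

#' Sum an ANM and a torsional Hessian
#'
#' Element-wise sum of the two stiffness matrices built around the same
#' equilibrium structure, giving the torsion-augmented network model.
#'
#' @param anm A `path_hessian` with flavor `"anm"`.
#' @param tor A `path_hessian` with flavor `"torsion"`.
#' @return A `path_hessian` with flavor `"anm_torsion"`.
#' @export
combine_hessians <- function(anm, tor) {
  if (!all(dim(anm$matrix) == dim(tor$matrix)))
    stop("dimension mismatch between Hessians")
  if (!isTRUE(all.equal(anm$structure$coords, tor$structure$coords)))
    stop("Hessians were built around different structures")
  new_path_hessian(anm$matrix + tor$matrix, "anm_torsion", anm$structure)
}

#' Export a Hessian as dense text
#' @param h A `path_hessian`.
#' @param path Output path (whitespace-separated dense matrix).
#' @return Invisibly, `path`.
#' @export
write_hessian <- function(h, path) {
  utils::write.table(h$matrix, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
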