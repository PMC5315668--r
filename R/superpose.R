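#' Least-squares rigid-body superposition and RMSD
#'
#' Superposes `mobile` onto `reference` by the optimal rotation + translation
#' (Kabsch, via SVD, with the determinant correction that excludes
#' reflections) and returns the fitted structure together with the minimised
#' root-mean-square deviation.
#'
#' @param mobile,reference Two [path_structure] objects with identical atom
#'   counts and ordering.
#' @param weights Optional per-atom weights (default uniform).
#' @return List with `structure` (the rotated/translated mobile) and `rmsd`
#'   in Angstrom.
#' @export
superpose_rmsd <- function(mobile, reference, weights = NULL) {
  X <- mobile$coords
  Y <- reference$coords
  if (!all(dim(X) == dim(Y))) stop("mismatched atom counts")
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  cx <- colSums(X * w)
  cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  A <- crossprod(Xc * w, Yc)            # 3x3 covariance
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(Xc %*% t(R), 2, cy, FUN = "+")
  rmsd <- sqrt(sum((fitted - Y)^2) / n)
  out <- mobile
  out$coords <- fitted
  list(structure = out, rmsd = rmsd)
}

#' All-by-all RMSD matrix over a set of structures
#'
#' Computes the symmetric matrix of pairwise post-superposition RMSDs for a
#' labelled list of structures — the layout used to survey how consistently
#' a panel of variant models perturbs a common scaffold.
#'
#' @param structures Named list of [path_structure] objects with identical
#'   atom ordering.
#' @return Symmetric numeric matrix (zero diagonal) with the list names as
#'   dimnames.
#' @export
rmsd_matrix <- function(structures) {
  n <- length(structures)
  lab <- names(structures)
  if (is.null(lab)) lab <- paste0("s", seq_len(n))
  M <- matrix(0, n, n, dimnames = list(lab, lab))
  if (n < 2) return(M)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- superpose_rmsd(structures[[i]], structures[[j]])$rmsd
      M[i, j] <- M[j, i] <- r
    }
  }
  M
}

#' Write an RMSD matrix as labelled CSV
#' @param m Matrix from [rmsd_matrix()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_rmsd_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
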