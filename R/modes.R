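#' Eigendecompose a Hessian into a normal-mode spectrum
#'
#' Full symmetric eigendecomposition with zero-mode bookkeeping: eigenvalues
#' below `zero_tol` times the largest are flagged as rigid-body modes, and
#' covariance eigenvalues (the pseudo-inverse convention: reciprocals of the
#' nonzero Hessian eigenvalues) are attached for the vibrational modes. A
#' clearly negative eigenvalue signals a broken Hessian and is an error.
#'
#' @param h A `path_hessian` (or a plain symmetric matrix).
#' @param zero_tol Relative zero-mode threshold, default 1e-9.
#' @return Object of class `mode_spectrum`: `values` (ascending), `vectors`
#'   (orthonormal columns, matching order), `zero` (logical mask),
#'   `covariance` (reciprocals of nonzero values, same length as nonzero
#'   modes).
#' @export
eigendecompose <- function(h, zero_tol = 1e-9) {
  M <- if (inherits(h, "path_hessian")) h$matrix else as.matrix(h)
  if (max(abs(M - t(M))) > 1e-10 * max(abs(M), 1))
    stop("Hessian is not symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  vmax <- max(abs(vals))
  if (vmax == 0) stop("zero matrix has no vibrational modes")
  if (any(vals < -1e-8 * vmax))
    stop("negative eigenvalue beyond tolerance: broken Hessian (min ",
         format(min(vals)), ")")
  zero <- vals < zero_tol * vmax
  if (all(zero)) stop("no nonzero modes")
  structure(list(values = vals, vectors = vecs, zero = zero,
                 covariance = 1 / vals[!zero]),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("mode_spectrum: %d modes (%d zero), lambda in [%.4g, %.4g]\n",
              length(x$values), sum(x$zero),
              min(x$values[!x$zero]), max(x$values)))
  invisible(x)
}

#' Mean force constant of a mode spectrum
#'
#' Three estimators of the average stiffness governing the approach to the
#' transition state:
#' \describe{
#'   \item{trace}{arithmetic mean of the nonzero Hessian eigenvalues (the
#'     mean of the trace over vibrational modes); dominated by high-frequency
#'     modes.}
#'   \item{fpc}{the first principal component — the largest-amplitude
#'     (lowest nonzero frequency) vibrational mode's Hessian eigenvalue.}
#'   \item{im}{inverse mean — the reciprocal of the mean covariance
#'     eigenvalue over the low-frequency modes whose cumulative covariance
#'     first reaches `variance_fraction` of the total, so soft modes that
#'     actually carry the conformational change dominate.}
#' }
#'
#' @param spec A `mode_spectrum`.
#' @param method `"trace"`, `"fpc"` or `"im"`.
#' @param variance_fraction Cumulative covariance fraction retained by the
#'   inverse-mean estimator, in (0, 1]; default 0.95.
#' @return List of class `mean_force_constant`: `value`, `method`,
#'   `variance_fraction`, `n_modes` (modes used) and `fraction_modes`
#'   (fraction of vibrational modes used).
#' @export
mean_force_constant <- function(spec, method = c("im", "trace", "fpc"),
                                variance_fraction = 0.95) {
  method <- match.arg(method)
  lam <- spec$values[!spec$zero]
  if (!length(lam)) stop("empty nonzero spectrum")
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]")
  if (method == "trace") {
    value <- mean(lam)
    used <- length(lam)
  } else if (method == "fpc") {
    value <- lam[1]  # smallest nonzero eigenvalue = largest-amplitude mode
    used <- 1L
  } else {
    cov <- sort(spec$covariance, decreasing = TRUE)
    cum <- cumsum(cov) / sum(cov)
    used <- which(cum >= variance_fraction - 1e-12)[1]
    value <- 1 / mean(cov[seq_len(used)])
  }
  structure(list(value = value, method = method,
                 variance_fraction = if (method == "im") variance_fraction else NA_real_,
                 n_modes = used, fraction_modes = used / length(lam)),
            class = "mean_force_constant")
}

#' Export a spectrum as two-column text (index, eigenvalue)
#' @param spec A `mode_spectrum`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(
    data.frame(index = seq_along(spec$values), eigenvalue = spec$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
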