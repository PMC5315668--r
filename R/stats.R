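#' Full factorial design over mutated sites
#'
#' Builds the 2^k presence/absence combinations over `k` sites and the
#' corresponding design matrix with intercept, main effects and all
#' interaction columns up to `max_order` (interaction columns are
#' element-wise products of main-effect columns). Under the plus/minus-one
#' coding the columns are mutually orthogonal.
#'
#' @param k Number of sites (1 to 8).
#' @param coding `"pm1"` (-1/+1, orthogonal) or `"01"` (presence/absence).
#' @param max_order Highest interaction order to include; default `k`.
#' @param labels Optional site labels (length `k`); default `S1..Sk`.
#' @return Object of class `variant_design`: `design` (2^k x p matrix with
#'   named columns), `variants` (tibble of 0/1 presence with a `variant`
#'   id), `coding`, `labels`.
#' @export
factorial_design <- function(k, coding = c("pm1", "01"), max_order = k,
                             labels = NULL) {
  coding <- match.arg(coding)
  stopifnot(k >= 1, k <= 8)
  if (max_order > k) stop("max_order cannot exceed the number of sites")
  if (is.null(labels)) labels <- paste0("S", seq_len(k))
  stopifnot(length(labels) == k)
  presence <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  colnames(presence) <- labels
  main <- if (coding == "pm1") 2 * presence - 1 else presence
  cols <- list(`(Intercept)` = rep(1, nrow(presence)))
  for (ord in seq_len(max_order)) {
    for (comb in utils::combn(k, ord, simplify = FALSE)) {
      nm <- paste(labels[comb], collapse = ":")
      cols[[nm]] <- apply(main[, comb, drop = FALSE], 1, prod)
    }
  }
  X <- do.call(cbind, cols)
  variants <- tibble::as_tibble(as.data.frame(presence))
  variants$variant <- apply(presence, 1, paste, collapse = "")
  structure(list(design = X, variants = variants, coding = coding,
                 labels = labels),
            class = "variant_design")
}

#' @export
print.variant_design <- function(x, ...) {
  cat(sprintf("variant_design: %d sites, %d variants, %d columns (%s coding)\n",
              length(x$labels), nrow(x$design), ncol(x$design), x$coding))
  invisible(x)
}

#' Ordinary least squares with classical inference
#'
#' Fits `y = X beta + e` by least squares (through `stats::lm`) and returns
#' coefficients with classical standard errors, two-sided t p-values, R
#' squared and the overall F test — the regression layer used to relate
#' transition-path convergence parameters and site patterns to kinetic
#' observables.
#'
#' @param X Design matrix (may include an intercept column named
#'   `(Intercept)`) or a `variant_design`.
#' @param y Numeric response, `length(y) == nrow(X)`.
#' @return Object of class `path_fit`; see [tidy.path_fit()] and
#'   [glance.path_fit()].
#' @export
fit_ols <- function(X, y) {
  if (inherits(X, "variant_design")) X <- X$design
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < p) stop("more columns than observations")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  has_int <- any(apply(X, 2, function(col) all(col == col[1] & col[1] != 0)))
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(p))  # syntactic names for lm
  df$.y <- y
  fm <- stats::lm(.y ~ . - 1, data = df)
  sm <- summary(fm)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(sm$coefficients[, 1]),
    std_error = unname(sm$coefficients[, 2]),
    t_ratio = unname(sm$coefficients[, 3]),
    p_value = unname(sm$coefficients[, 4])
  )
  rss <- sum(stats::residuals(fm)^2)
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  p_slopes <- if (has_int) p - 1 else p
  r2 <- if (tss > 0) 1 - rss / tss else 0
  dfree <- n - p
  fstat <- if (p_slopes > 0 && rss > 0)
    ((tss - rss) / p_slopes) / (rss / dfree) else NA_real_
  fp <- if (is.finite(fstat))
    stats::pf(fstat, p_slopes, dfree, lower.tail = FALSE) else NA_real_
  structure(list(coefficients = coefs, r_squared = r2,
                 f_statistic = fstat, f_pvalue = fp,
                 n = n, df = dfree, sigma = sqrt(rss / max(dfree, 1)),
                 fitted = unname(stats::fitted(fm)),
                 residuals = unname(stats::residuals(fm)),
                 response = y),
            class = "path_fit")
}

#' Coefficient table of a regression fit
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `t_ratio`,
#'   `p_value`.
#' @method tidy path_fit
#' @export
tidy.path_fit <- function(x, ...) x$coefficients

#' One-row model summary of a regression fit
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `sigma`, `statistic`, `p.value`, `df`,
#'   `nobs`.
#' @method glance path_fit
#' @export
glance.path_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma,
                 statistic = x$f_statistic, p.value = x$f_pvalue,
                 df = x$df, nobs = x$n)
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R2 = %.3f, F = %.2f (p = %.3g)\n\n",
              x$n, x$r_squared, x$f_statistic, x$f_pvalue))
  co <- x$coefficients
  cat(sprintf("%-24s %10s %10s %8s %10s\n",
              "Term", "Estimate", "Std Error", "t Ratio", "Prob > |t|"))
  for (i in seq_len(nrow(co)))
    cat(sprintf("%-24s %10.4g %10.4g %8.2f %10.3g\n",
                co$term[i], co$estimate[i], co$std_error[i],
                co$t_ratio[i], co$p_value[i]))
  invisible(x)
}

#' Four-parameter model relating PATH parameters to kinetic free energies
#'
#' Fits the published regression form: experimental activation free energy
#' as a linear function of the conformational free-energy difference
#' `dG_conf`, the mean barrier height, the negative log time to the
#' transition state from the reactant well, and the product of the first and
#' third, plus an intercept.
#'
#' @param params Data frame with one row per variant and numeric columns
#'   `dG_conf`, `U_barrier_mean`, `t_left` (e.g. stacked
#'   [glance.path_run()] rows).
#' @param y Experimental response, one value per variant.
#' @return A `path_fit`.
#' @export
table1_model <- function(params, y) {
  need <- c("dG_conf", "U_barrier_mean", "t_left")
  if (!all(need %in% names(params)))
    stop("params must contain columns: ", paste(need, collapse = ", "))
  if (nrow(params) < 5) stop("need at least 5 variants for the 4-term model")
  X <- table1_design(params)
  fit_ols(X, y)
}

#' Design matrix of the four-parameter kinetic model
#' @param params Data frame with `dG_conf`, `U_barrier_mean`, `t_left`.
#' @return Matrix with columns `(Intercept)`, `dG`, `U_barrier`,
#'   `neg_log_tl`, `dG:neg_log_tl`.
#' @export
table1_design <- function(params) {
  nlt <- -log(params$t_left)
  cbind(`(Intercept)` = 1,
        dG = params$dG_conf,
        U_barrier = params$U_barrier_mean,
        neg_log_tl = nlt,
        `dG:neg_log_tl` = params$dG_conf * nlt)
}

#' Pool parameter estimates from two Hessian models onto a common scale
#'
#' The all-atom torsional model and the CA-only empirical model yield
#' parameter values in different (arbitrary) unit scales. To use both as
#' independent observations per variant, the second set is rescaled onto the
#' first by a simple linear regression through the paired values and the
#' two sets are stacked.
#'
#' @param primary,secondary Numeric vectors, one value per variant, from the
#'   two models.
#' @param labels Optional variant labels.
#' @return Tibble with `variant`, `value` (common scale), `model`
#'   (`"primary"`/`"secondary"`).
#' @export
stack_model_estimates <- function(primary, secondary, labels = NULL) {
  stopifnot(length(primary) == length(secondary))
  if (is.null(labels)) labels <- paste0("v", seq_along(primary))
  sc <- stats::lm(primary ~ secondary)
  rescaled <- unname(stats::fitted(sc))
  tibble::tibble(
    variant = rep(labels, 2),
    value = c(primary, rescaled),
    model = rep(c("primary", "secondary"), each = length(primary))
  )
}
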