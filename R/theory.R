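#' Closed-form fraction for a flat singular-value spectrum
#'
#' When every singular value of the design equals \eqn{\lambda} (columns
#' orthogonal and of equal norm), the norm fraction achieved by ridge
#' penalty \eqn{\alpha} has the closed form
#' \eqn{\gamma = \lambda^2 / (\lambda^2 + \alpha)}, for any target.
#' Used as an independent oracle for the grid-interpolation solver.
#'
#' @param lam the common singular value, > 0.
#' @param alpha ridge penalty, >= 0 (vectorized).
#' @return fractions in (0, 1].
#' @export
flat_spectrum_gamma <- function(lam, alpha) {
  if (!is.numeric(lam) || any(lam <= 0)) stop("'lam' must be positive")
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  lam^2 / (lam^2 + alpha)
}

#' Closed-form penalty for a flat singular-value spectrum
#'
#' Inverse of \code{\link{flat_spectrum_gamma}}:
#' \eqn{\alpha = \lambda^2 (1/\gamma - 1)}. A fraction of 0 maps to
#' \code{Inf} (full shrinkage requires an infinite penalty).
#'
#' @param lam the common singular value, > 0.
#' @param gamma requested fraction in (0, 1] (vectorized); 0 gives `Inf`.
#' @return penalties >= 0.
#' @export
flat_spectrum_alpha <- function(lam, gamma) {
  if (!is.numeric(lam) || any(lam <= 0)) stop("'lam' must be positive")
  if (any(gamma < 0 | gamma > 1)) stop("'gamma' must lie in [0, 1]")
  ifelse(gamma == 0, Inf, lam^2 * (1 / gamma - 1))
}

#' Effective degrees of freedom of ridge regression
#'
#' \eqn{\sum_i \lambda_i^2 / (\lambda_i^2 + \alpha)}: the sum of the
#' per-component shrinkage factors, a standard monotone summary of
#' regularization strength. It equals the retained rank at
#' \eqn{\alpha = 0} and decreases strictly to 0 as \eqn{\alpha \to \infty}.
#'
#' @param lambda singular values (positive, non-increasing) or an
#'   \code{"frr_decomposition"}.
#' @param alpha ridge penalty, >= 0 (vectorized).
#' @return effective degrees of freedom, in (0, r].
#' @export
effective_dof <- function(lambda, alpha) {
  if (inherits(lambda, "frr_decomposition")) lambda <- lambda$lambda
  if (any(lambda <= 0)) stop("singular values must be positive")
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  lam2 <- lambda^2
  vapply(alpha, function(a) sum(lam2 / (lam2 + a)), numeric(1))
}

#' Rotated-space L1 shrinkage fraction (equal-coefficient special case)
#'
#' If the rotated OLS coefficients all have the same absolute value, the
#' L1-norm fraction retained by ridge penalty \eqn{\alpha} reduces to the
#' average of the per-component shrinkage factors,
#' \eqn{\sum_i \lambda_i^2/(\lambda_i^2+\alpha) / p} — i.e. the effective
#' degrees of freedom divided by the predictor count. The L1-norm here is
#' taken in the rotated space; it is generally not the L1-norm of the
#' coefficients in the original predictor space.
#'
#' @param lambda singular values or an \code{"frr_decomposition"}.
#' @param alpha ridge penalty, >= 0 (vectorized).
#' @param p predictor count (defaults to the number of singular values,
#'   i.e. assumes a full-rank design).
#' @return L1 shrinkage fractions.
#' @export
l1_fraction_rotated <- function(lambda, alpha, p = NULL) {
  if (inherits(lambda, "frr_decomposition")) {
    if (is.null(p)) p <- lambda$p
    lambda <- lambda$lambda
  }
  if (is.null(p)) p <- length(lambda)
  effective_dof(lambda, alpha) / p
}
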