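#' Decompose a design matrix for rotated-space ridge solving
#'
#' Computes the (possibly truncated) singular value decomposition
#' \eqn{X = U \Lambda V^\top} that underlies the fractional ridge solver.
#' Singular values smaller than \code{tol} times the largest singular value
#' are treated as zero and dropped, together with the corresponding columns
#' of \eqn{U} and \eqn{V}, so the returned rank \eqn{r} is the numerical
#' rank of \eqn{X}.
#'
#' When there are more rows than columns (\eqn{d > p}) the singular values
#' and right singular vectors can be obtained more cheaply from the
#' eigendecomposition of the \eqn{p \times p} Gram matrix \eqn{X^\top X},
#' whose eigenvalues are the squared singular values; the left vectors are
#' then reconstructed as \eqn{U = X V \Lambda^{-1}}. Both routes satisfy
#' the same contract and agree to high precision; \code{method = "auto"}
#' picks the Gram route when \eqn{d > p}.
#'
#' @param X numeric matrix (rows are data points, columns are predictors).
#' @param tol relative truncation threshold: singular values below
#'   \code{tol * max(singular values)} are zeroed. The default,
#'   \code{max(dim(X)) * .Machine$double.eps}, is the usual pseudoinverse
#'   convention.
#' @param method \code{"auto"}, \code{"svd"} (decompose \code{X} directly)
#'   or \code{"gram"} (eigendecompose \eqn{X^\top X}).
#'
#' @return An object of class \code{"frr_decomposition"}: a list with
#'   \code{lambda} (singular values, non-increasing, all positive),
#'   \code{u} (\eqn{d \times r}), \code{v} (\eqn{p \times r}),
#'   \code{rank}, \code{tol}, \code{d} and \code{p}.
#'
#' @examples
#' dec <- frr_decompose(diag(3))
#' dec$lambda   # 1 1 1
#' @export
frr_decompose <- function(X, tol = NULL, method = c("auto", "svd", "gram")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (!is.numeric(X) || nrow(X) < 1L || ncol(X) < 1L)
    stop("'X' must be a numeric matrix with at least one row and column")
  if (!all(is.finite(X)))
    stop("'X' contains non-finite entries")
  d <- nrow(X)
  p <- ncol(X)
  if (is.null(tol)) tol <- max(d, p) * .Machine$double.eps
  if (method == "auto") method <- if (d > p) "gram" else "svd"

  if (method == "gram") {
    e <- eigen(crossprod(X), symmetric = TRUE)
    lam2 <- pmax(e$values, 0)
    lam <- sqrt(lam2)
    # Eigenvalues of the Gram matrix carry numerical noise at the scale
    # eps * lambda_1^2, so truncation must act on that scale: a spurious
    # eigenvalue sqrt(eps)*lambda_1 would otherwise survive a threshold
    # stated on the singular-value scale.
    tol2 <- max(tol^2, max(d, p) * .Machine$double.eps)
    keep <- lam2 > tol2 * lam2[1L]
    if (!any(keep)) stop("degenerate design: all singular values are zero")
    lam <- lam[keep]
    v <- e$vectors[, keep, drop = FALSE]
    u <- X %*% sweep(v, 2L, lam, "/")
    # Gram eigenvectors of near-equal eigenvalues can lose orthogonality
    # at the level that matters here; re-orthonormalize u cheaply.
    qr_u <- qr(u)
    u <- qr.Q(qr_u) * rep(sign(diag(qr.R(qr_u))), each = d)
  } else {
    s <- svd(X)
    keep <- s$d > tol * s$d[1L]
    if (!any(keep)) stop("degenerate design: all singular values are zero")
    lam <- s$d[keep]
    u <- s$u[, keep, drop = FALSE]
    v <- s$v[, keep, drop = FALSE]
  }

  structure(
    list(lambda = lam, u = u, v = v, rank = length(lam),
         tol = tol, d = d, p = p),
    class = "frr_decomposition"
  )
}

#' @export
print.frr_decomposition <- function(x, ...) {
  cat(sprintf("Design decomposition: %d x %d, rank %d\n", x$d, x$p, x$rank))
  cat(sprintf("  singular values in [%.4g, %.4g], truncation tol %.3g\n",
              min(x$lambda), max(x$lambda), x$tol))
  invisible(x)
}

#' Rotate a target vector into the reduced space
#'
#' Projects a target \eqn{y} onto the left singular vectors
#' (\eqn{\tilde y = U^\top y}) and forms the rotated ordinary-least-squares
#' solution \eqn{\tilde\beta^{OLS}_i = \tilde y_i / \lambda_i} together with
#' its L2-norm, which is the denominator of the fraction \eqn{\gamma}.
#'
#' @param dec an \code{"frr_decomposition"}.
#' @param y numeric vector of length \code{dec$d}.
#' @return list with \code{y_rot}, \code{beta_ols_rot}, \code{ols_norm}.
#' @export
frr_rotate_target <- function(dec, y) {
  stopifnot(inherits(dec, "frr_decomposition"))
  y <- as.numeric(y)
  if (length(y) != dec$d)
    stop(sprintf("target length %d does not match design rows %d",
                 length(y), dec$d))
  if (!all(is.finite(y))) stop("'y' contains non-finite entries")
  y_rot <- drop(crossprod(dec$u, y))
  beta_ols_rot <- y_rot / dec$lambda
  list(y_rot = y_rot, beta_ols_rot = beta_ols_rot,
       ols_norm = sqrt(sum(beta_ols_rot^2)))
}

#' Rotate coefficients back to the original predictor space
#'
#' Left-multiplies rotated coefficients by the right singular vectors
#' (\eqn{\beta = V\tilde\beta}). Because \eqn{V} has orthonormal columns
#' the operation preserves column L2-norms, so fractions computed in the
#' rotated space carry over to the original space.
#'
#' @param dec an \code{"frr_decomposition"}.
#' @param beta_rot numeric matrix with \code{dec$rank} rows (or a vector).
#' @return a \code{p x ncol(beta_rot)} matrix.
#' @export
frr_unrotate <- function(dec, beta_rot) {
  stopifnot(inherits(dec, "frr_decomposition"))
  beta_rot <- as.matrix(beta_rot)
  if (nrow(beta_rot) != dec$rank)
    stop(sprintf("rotated coefficients have %d rows; rank is %d",
                 nrow(beta_rot), dec$rank))
  dec$v %*% beta_rot
}
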