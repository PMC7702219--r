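#' Candidate ridge-penalty grid from the singular-value range
#'
#' Builds the internal log-spaced grid of candidate penalties \eqn{\alpha}
#' on which the fraction curve \eqn{\gamma(\alpha)} is evaluated. The grid
#' spans \eqn{[10^{-3}\lambda_r^2,\; 10^{3}\lambda_1^2]} — far below the
#' smallest and far above the largest squared singular value, so the
#' achievable fractions cover essentially (0, 1) — with endpoints snapped
#' outward to integer multiples of \code{log_spacing} in \eqn{\log_{10}},
#' which makes grids reproducible for any design with the same
#' singular-value range.
#'
#' @param dec an \code{"frr_decomposition"}.
#' @param log_spacing grid spacing in \eqn{\log_{10}} units (default 0.2,
#'   fine enough that interpolated fractions land within about 1\% of the
#'   requested ones).
#' @return An object of class \code{"frr_alpha_grid"}: list with
#'   \code{alphas} (strictly increasing), \code{exponents} (their
#'   \eqn{\log_{10}} values, an exact lattice), \code{log_spacing}.
#' @export
frr_alpha_grid <- function(dec, log_spacing = 0.2) {
  stopifnot(inherits(dec, "frr_decomposition"))
  if (!is.numeric(log_spacing) || length(log_spacing) != 1L ||
      !is.finite(log_spacing) || log_spacing <= 0)
    stop("'log_spacing' must be a positive number")
  lam <- dec$lambda
  lo <- log10(1e-3 * lam[length(lam)]^2)
  hi <- log10(1e3 * lam[1L]^2)
  # snap outward onto the spacing lattice; the small slack keeps exact
  # lattice points (e.g. lambda = 1) from drifting one step outward
  k_lo <- floor(lo / log_spacing + 1e-9)
  k_hi <- ceiling(hi / log_spacing - 1e-9)
  exponents <- (k_lo:k_hi) * log_spacing
  structure(
    list(alphas = 10^exponents, exponents = exponents,
         log_spacing = log_spacing),
    class = "frr_alpha_grid"
  )
}

#' Per-component shrinkage factors over a penalty grid
#'
#' The ridge solution in the rotated space scales each ordinary-least-
#' squares component by \eqn{\lambda_i^2 / (\lambda_i^2 + \alpha)}.
#' This returns the full \eqn{r \times m} table of these factors for the
#' grid penalties in one vectorized outer operation; the table depends
#' only on the design, not on any target.
#'
#' @param dec an \code{"frr_decomposition"}.
#' @param grid an \code{"frr_alpha_grid"} (or numeric vector of penalties).
#' @return numeric matrix, rows follow \code{dec$lambda}, columns the grid.
#' @export
frr_shrinkage_factors <- function(dec, grid) {
  stopifnot(inherits(dec, "frr_decomposition"))
  alphas <- if (inherits(grid, "frr_alpha_grid")) grid$alphas else as.numeric(grid)
  lam2 <- dec$lambda^2
  lam2 / outer(lam2, alphas, "+")
}

#' Fraction curve of one target along the penalty grid
#'
#' For a rotated target, evaluates the achieved norm fraction
#' \eqn{\gamma_j = \|SF_{\cdot j} \odot \tilde\beta^{OLS}\|_2 /
#' \|\tilde\beta^{OLS}\|_2} at every grid penalty \eqn{\alpha_j}. The curve
#' is strictly decreasing in \eqn{\alpha} and lies in (0, 1).
#'
#' @param target result of \code{\link{frr_rotate_target}}.
#' @param sf shrinkage-factor table from \code{\link{frr_shrinkage_factors}}.
#' @return numeric vector of fractions, one per grid column.
#' @export
frr_gamma_curve <- function(target, sf) {
  if (target$ols_norm <= 0)
    stop("zero-norm target: the fraction is undefined (0/0)")
  sqrt(colSums((sf * target$beta_ols_rot)^2)) / target$ols_norm
}

#' Penalties achieving requested fractions, by grid interpolation
#'
#' Given the fraction curve evaluated on the penalty grid, finds for each
#' requested fraction the penalty \eqn{\alpha^*} by piecewise-linear
#' interpolation of \eqn{\log_{10}\alpha} as a function of \eqn{\gamma}
#' (the curve is smooth and near-linear in \eqn{\log\alpha} across the
#' transition region, which is what makes a 0.2-decade grid sufficient).
#' The endpoints bypass interpolation: a requested fraction of 1 maps to
#' \eqn{\alpha^* = 0} exactly and a requested fraction of 0 maps to the
#' \code{Inf} sentinel. A requested fraction above the largest fraction
#' achieved on the grid (possible because the grid minimum is positive) is
#' linearly extrapolated in the same coordinates.
#'
#' @param gammas_on_grid strictly decreasing fractions along the grid.
#' @param grid an \code{"frr_alpha_grid"}.
#' @param requested numeric vector of fractions in [0, 1].
#' @return numeric vector of penalties, same length as \code{requested};
#'   \code{Inf} marks full shrinkage.
#' @export
frr_interpolate_alphas <- function(gammas_on_grid, grid, requested) {
  stopifnot(inherits(grid, "frr_alpha_grid"))
  g <- gammas_on_grid
  if (any(diff(g) >= 0))
    stop("internal inconsistency: fraction curve is not strictly decreasing")
  if (any(requested < 0 | requested > 1))
    stop("requested fractions must lie in [0, 1]")
  out <- numeric(length(requested))
  out[requested == 0] <- Inf
  out[requested == 1] <- 0
  inner <- requested > 0 & requested < 1
  if (any(inner)) {
    # ascending in gamma for interpolation; exponents are descending along gamma
    gx <- rev(g)
    ex <- rev(grid$exponents)
    req <- requested[inner]
    loga <- stats::approx(gx, ex, xout = req, rule = 2, ties = "ordered")$y
    # linear extrapolation beyond the achieved range (rule = 2 clamps)
    hi_end <- req > gx[length(gx)]
    if (any(hi_end)) {
      n <- length(gx)
      slope <- (ex[n] - ex[n - 1L]) / (gx[n] - gx[n - 1L])
      loga[hi_end] <- ex[n] + slope * (req[hi_end] - gx[n])
    }
    lo_end <- req < gx[1L]
    if (any(lo_end)) {
      slope <- (ex[2L] - ex[1L]) / (gx[2L] - gx[1L])
      loga[lo_end] <- ex[1L] + slope * (req[lo_end] - gx[1L])
    }
    out[inner] <- 10^loga
  }
  out
}

#' Rotated-space ridge solutions at chosen penalties
#'
#' Applies the per-component shrinkage
#' \eqn{\tilde\beta_i = \lambda_i^2/(\lambda_i^2+\alpha^*)\,
#' \tilde\beta^{OLS}_i} for each penalty in \code{alphas_star}. A penalty
#' of 0 reproduces the rotated OLS solution exactly; the \code{Inf}
#' sentinel yields the zero vector.
#'
#' @param target result of \code{\link{frr_rotate_target}}.
#' @param dec an \code{"frr_decomposition"}.
#' @param alphas_star numeric vector of penalties (\code{Inf} allowed).
#' @return matrix of rotated coefficients, \code{dec$rank} rows, one
#'   column per penalty.
#' @export
frr_solve_target <- function(target, dec, alphas_star) {
  stopifnot(inherits(dec, "frr_decomposition"))
  if (any(alphas_star < 0, na.rm = TRUE))
    stop("penalties must be non-negative")
  lam2 <- dec$lambda^2
  sf <- lam2 / outer(lam2, alphas_star, "+")  # Inf penalty -> factor 0
  sf * target$beta_ols_rot
}

#' Fractional ridge regression over many targets (array interface)
#'
#' The core solver: decomposes the design once, rotates all targets in a
#' single matrix product, evaluates each target's fraction curve on a
#' shared log-spaced penalty grid, interpolates the penalties that achieve
#' the requested fractions, forms the shrunken solutions, and rotates all
#' of them back to predictor space in one multiplication.
#'
#' Targets whose OLS solution has zero norm (e.g. an all-zero target) have
#' an undefined fraction; they receive zero coefficients for every
#' requested fraction, with \code{NaN} recorded for the penalty and the
#' achieved fraction.
#'
#' @param X design matrix, \code{d x p}.
#' @param Y targets: a \code{d x t} matrix or a length-\code{d} vector.
#' @param fracs requested fractions in [0, 1]. Duplicates are solved once;
#'   output follows the order given here.
#' @param tol relative singular-value truncation threshold
#'   (see \code{\link{frr_decompose}}).
#' @param log_spacing penalty-grid spacing in \eqn{\log_{10}} units.
#' @return list with \code{coefs} (\code{p x f x t} array),
#'   \code{alphas} (\code{f x t}; 0 for fraction 1, \code{Inf} for
#'   fraction 0), \code{achieved} (\code{f x t} achieved fractions),
#'   \code{fracs}, and the \code{decomposition}.
#' @export
frr_core <- function(X, Y, fracs = seq(0, 1, by = 0.05),
                     tol = NULL, log_spacing = 0.2) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    stop(sprintf("'Y' has %d rows but 'X' has %d", nrow(Y), nrow(X)))
  if (!all(is.finite(Y))) stop("'Y' contains non-finite entries")
  fracs <- as.numeric(fracs)
  if (length(fracs) == 0L || any(!is.finite(fracs)) ||
      any(fracs < 0 | fracs > 1))
    stop("'fracs' must be a non-empty vector of fractions in [0, 1]")

  dec <- frr_decompose(X, tol = tol)
  t_n <- ncol(Y)
  f_n <- length(fracs)
  p <- dec$p

  # solve each distinct fraction once, then fan results back out
  uf <- sort(unique(fracs))
  map_back <- match(fracs, uf)
  uf_n <- length(uf)

  coefs <- array(0, dim = c(p, f_n, t_n),
                 dimnames = list(colnames(X), NULL, colnames(Y)))
  alphas <- matrix(NaN, f_n, t_n)
  achieved <- matrix(NaN, f_n, t_n)
  if (t_n == 0L)
    return(list(coefs = coefs, alphas = alphas, achieved = achieved,
                fracs = fracs, decomposition = dec))

  grid <- frr_alpha_grid(dec, log_spacing = log_spacing)
  sf <- frr_shrinkage_factors(dec, grid)

  y_rot_all <- crossprod(dec$u, Y)              # r x t
  beta_ols_all <- y_rot_all / dec$lambda        # r x t
  ols_norms <- sqrt(colSums(beta_ols_all^2))

  beta_rot_u <- array(0, dim = c(dec$rank, uf_n, t_n))
  alphas_u <- matrix(NaN, uf_n, t_n)
  achieved_u <- matrix(NaN, uf_n, t_n)

  for (tt in seq_len(t_n)) {
    target <- list(y_rot = y_rot_all[, tt],
                   beta_ols_rot = beta_ols_all[, tt],
                   ols_norm = ols_norms[tt])
    if (target$ols_norm <= 0) next  # degenerate: zeros, NaN markers
    g <- frr_gamma_curve(target, sf)
    a_star <- frr_interpolate_alphas(g, grid, uf)
    b <- frr_solve_target(target, dec, a_star)
    beta_rot_u[, , tt] <- b
    alphas_u[, tt] <- a_star
    achieved_u[, tt] <- sqrt(colSums(b^2)) / target$ols_norm
  }

  # one back-rotation for all targets and fractions
  beta_flat <- dec$v %*% matrix(beta_rot_u, nrow = dec$rank)
  coefs_u <- array(beta_flat, dim = c(p, uf_n, t_n))

  coefs[] <- coefs_u[, map_back, , drop = FALSE]
  alphas[] <- alphas_u[map_back, , drop = FALSE]
  achieved[] <- achieved_u[map_back, , drop = FALSE]

  list(coefs = coefs, alphas = alphas, achieved = achieved,
       fracs = fracs, decomposition = dec)
}

#' Direct ridge regression by the normal equations
#'
#' Solves \eqn{(X^\top X + \alpha I)\beta = X^\top y} by explicit matrix
#' inversion. This is deliberately the textbook route, independent of the
#' SVD machinery, so it can serve as a brute-force oracle for the
#' fractional solver's output. At \eqn{\alpha = 0} on a rank-deficient
#' design the system is singular and the Moore-Penrose pseudoinverse of
#' \eqn{X} is used instead (with a warning).
#'
#' @param X design matrix, \code{d x p}.
#' @param y a single target vector (or one-column matrix) of length
#'   \code{d}, or a \code{d x t} matrix solved column by column.
#' @param alpha ridge penalty, a single finite value \eqn{\ge 0}.
#' @return coefficient vector of length \code{p} (or \code{p x t} matrix).
#' @export
ridge_direct <- function(X, y, alpha) {
  X <- as.matrix(X)
  y <- as.matrix(y)
  if (nrow(y) != nrow(X)) stop("row counts of 'X' and 'y' differ")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stop("'alpha' must be a single finite value >= 0")
  xtx <- crossprod(X)
  xty <- crossprod(X, y)
  A <- xtx + diag(alpha, ncol(X))
  beta <- if (alpha == 0 && rcond(A) < 1e-12) NULL else
    tryCatch(solve(A, xty), error = function(e) NULL)
  if (is.null(beta)) {
    if (alpha > 0) stop("ridge system unexpectedly singular")
    warning("singular system at alpha = 0; using the pseudoinverse")
    beta <- MASS::ginv(X) %*% y
  }
  if (ncol(y) == 1L) drop(beta) else beta
}
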