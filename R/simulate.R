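#' Specify a synthetic regression scenario
#'
#' Bundles the parameters of the synthetic benchmark scenarios: a
#' correlated Gaussian design with \code{d} data points and \code{p}
#' predictors, Gaussian ground-truth coefficients, and additive Gaussian
#' noise. By default the number of correlation-induction rounds is
#' \code{2 * p} and the noise standard deviation matches each target's
#' signal standard deviation (\code{"match-signal"}), i.e. an SNR of 1.
#'
#' All randomness derives from \code{seed}: the design draws use
#' \code{seed} and the coefficient/noise draws use \code{seed + 1}, two
#' fixed streams so that regenerating either piece is reproducible.
#'
#' @param d number of data points (>= 4).
#' @param p number of predictors (>= 2).
#' @param correlation_rounds rounds of pairwise correlation induction
#'   (default \code{2 * p}).
#' @param noise_sd positive number, or \code{"match-signal"} (default) to
#'   set each target's noise SD equal to its noiseless-signal SD.
#' @param beta_sd standard deviation of the ground-truth coefficients.
#' @param seed integer seed.
#' @return list of class \code{"frr_scenario"}.
#' @export
frr_scenario <- function(d = 100L, p = 100L, correlation_rounds = 2L * p,
                         noise_sd = "match-signal", beta_sd = 1,
                         seed = 1L) {
  if (d < 4L || p < 2L) stop("need d >= 4 and p >= 2")
  if (correlation_rounds < 0L) stop("'correlation_rounds' must be >= 0")
  if (is.character(noise_sd)) {
    if (noise_sd != "match-signal")
      stop("'noise_sd' must be a positive number or \"match-signal\"")
  } else if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be a positive number or \"match-signal\"")
  }
  if (beta_sd <= 0) stop("'beta_sd' must be positive")
  structure(list(d = as.integer(d), p = as.integer(p),
                 correlation_rounds = as.integer(correlation_rounds),
                 noise_sd = noise_sd, beta_sd = beta_sd,
                 seed = as.integer(seed)),
            class = "frr_scenario")
}

# z-score with population SD so every column has unit SD exactly
.zscore_cols <- function(X) {
  X <- sweep(X, 2L, colMeans(X))
  sds <- sqrt(colMeans(X^2))
  if (any(sds == 0)) stop("zero-variance column after correlation rounds")
  sweep(X, 2L, sds, "/")
}

#' Generate a correlated, z-scored Gaussian design matrix
#'
#' Draws a standard-normal \code{d x p} matrix, then induces predictor
#' correlation: for each round, two distinct predictors are chosen
#' uniformly at random and the first is replaced by the sum of the two
#' plus fresh standard-normal noise. Finally every column is z-scored
#' (mean 0, population SD 1).
#'
#' @param spec an \code{"frr_scenario"}.
#' @return a \code{d x p} design matrix.
#' @export
make_correlated_design <- function(spec) {
  stopifnot(inherits(spec, "frr_scenario"))
  set.seed(spec$seed)
  X <- matrix(stats::rnorm(spec$d * spec$p), spec$d, spec$p)
  for (i in seq_len(spec$correlation_rounds)) {
    pair <- sample.int(spec$p, 2L)
    X[, pair[1L]] <- X[, pair[1L]] + X[, pair[2L]] + stats::rnorm(spec$d)
  }
  .zscore_cols(X)
}

#' Simulate ground-truth coefficients and noisy targets
#'
#' Draws coefficients \eqn{\beta \sim N(0, \code{beta_sd}^2)} per target,
#' forms the signal \eqn{X\beta}, and adds Gaussian noise. With
#' \code{noise_sd = "match-signal"} the noise SD for each target equals
#' the population SD of that target's noiseless signal.
#'
#' @param X design matrix (typically from
#'   \code{\link{make_correlated_design}}).
#' @param spec the \code{"frr_scenario"} (provides \code{noise_sd},
#'   \code{beta_sd} and the seed stream).
#' @param t number of targets.
#' @return list with \code{beta_true} (\code{p x t}) and \code{Y}
#'   (\code{d x t}).
#' @export
simulate_targets <- function(X, spec, t = 1L) {
  stopifnot(inherits(spec, "frr_scenario"))
  if (t < 1L) stop("'t' must be >= 1")
  X <- as.matrix(X)
  d <- nrow(X); p <- ncol(X)
  set.seed(spec$seed + 1L)
  beta_true <- matrix(stats::rnorm(p * t, sd = spec$beta_sd), p, t)
  signal <- X %*% beta_true
  sds <- if (identical(spec$noise_sd, "match-signal")) {
    apply(signal, 2L, function(s) sqrt(mean((s - mean(s))^2)))
  } else {
    rep(spec$noise_sd, t)
  }
  eps <- matrix(stats::rnorm(d * t), d, t) * rep(sds, each = d)
  list(beta_true = beta_true, Y = signal + eps)
}

#' Heuristic penalty grid for standard ridge regression
#'
#' The conventional log-spaced grid used as the standard-ridge baseline:
#' 0 followed by \eqn{10^{-4}, 10^{-3.5}, \dots, 10^{5.5}} (21 values).
#'
#' @param lo,hi,step \eqn{\log_{10}} range and spacing of the positive part.
#' @return numeric vector, ascending, first element 0.
#' @export
srr_alpha_grid <- function(lo = -4, hi = 5.5, step = 0.5) {
  c(0, 10^seq(lo, hi, by = step))
}

#' Standard ridge solutions by per-penalty pseudo-inversion
#'
#' The naive baseline: for each penalty \eqn{\alpha} in the grid, solves
#' \eqn{(X^\top X + \alpha I)\beta = X^\top Y} with a fresh Moore-Penrose
#' pseudo-inversion, independently of every other penalty. At
#' \eqn{\alpha = 0} this is the pseudoinverse OLS solution.
#'
#' @param X design matrix \code{d x p}.
#' @param Y targets \code{d x t}.
#' @param grid penalties (see \code{\link{srr_alpha_grid}}).
#' @return array \code{p x length(grid) x t}.
#' @export
srr_solve_naive <- function(X, Y, grid = srr_alpha_grid()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X); t_n <- ncol(Y); f_n <- length(grid)
  xtx <- crossprod(X); xty <- crossprod(X, Y)
  out <- array(NA_real_, dim = c(p, f_n, t_n))
  for (j in seq_len(f_n)) {
    beta <- MASS::ginv(xtx + diag(grid[j], p)) %*% xty
    out[, j, ] <- beta
  }
  out
}

#' Standard ridge solutions via a single SVD
#'
#' The rotation-based baseline: one SVD of the design, per-component
#' scalar shrinkage \eqn{\lambda_i/(\lambda_i^2 + \alpha)\,\tilde y_i}
#' for every penalty, and one back-rotation. Produces the same solutions
#' as \code{\link{srr_solve_naive}} at a fraction of the cost.
#'
#' @inheritParams srr_solve_naive
#' @return array \code{p x length(grid) x t}.
#' @export
srr_solve_rotated <- function(X, Y, grid = srr_alpha_grid()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  dec <- frr_decompose(X)
  y_rot <- crossprod(dec$u, Y)                    # r x t
  f_n <- length(grid); t_n <- ncol(Y)
  lam <- dec$lambda
  out <- array(NA_real_, dim = c(ncol(X), f_n, t_n))
  for (j in seq_len(f_n)) {
    scale <- lam / (lam^2 + grid[j])
    out[, j, ] <- dec$v %*% (y_rot * scale)
  }
  out
}

#' Compare fractional and standard ridge on a synthetic scenario
#'
#' Runs the full benchmark on one scenario: generates the correlated
#' design and noisy targets, splits rows 50/50 into training and testing,
#' fits fractional ridge at the requested fractions and standard ridge on
#' its heuristic penalty grid, and tabulates — per method, regularization
#' level and target — training and test \eqn{R^2}, the fractional
#' L2-norm relative to the training OLS solution, and the effective
#' degrees of freedom.
#'
#' @param spec an \code{"frr_scenario"}.
#' @param t number of targets.
#' @param frr_fractions fractions for the fractional method.
#' @param srr_grid penalty grid for the standard method.
#' @param split_seed seed for the 50/50 row split.
#' @return a data frame with columns \code{method} ("frr"/"srr"),
#'   \code{level} (requested fraction or grid penalty), \code{target_id},
#'   \code{train_r2}, \code{test_r2}, \code{frac_norm}, \code{dof},
#'   \code{alpha}.
#' @export
compare_frr_srr <- function(spec, t = 10L,
                            frr_fractions = seq(0, 1, by = 0.05),
                            srr_grid = srr_alpha_grid(),
                            split_seed = spec$seed) {
  stopifnot(inherits(spec, "frr_scenario"))
  X <- make_correlated_design(spec)
  sim <- simulate_targets(X, spec, t)
  Y <- sim$Y
  d <- nrow(X)

  set.seed(split_seed)
  train <- sort(sample.int(d, round(d / 2)))
  test <- setdiff(seq_len(d), train)
  Xtr <- X[train, , drop = FALSE]; Ytr <- Y[train, , drop = FALSE]
  Xte <- X[test, , drop = FALSE]; Yte <- Y[test, , drop = FALSE]

  dec <- frr_decompose(Xtr)
  ols <- dec$v %*% (crossprod(dec$u, Ytr) / dec$lambda)
  ols_norms <- sqrt(colSums(ols^2))

  fit <- frr(Xtr, Ytr, fracs = frr_fractions)
  srr <- srr_solve_rotated(Xtr, Ytr, srr_grid)

  score_block <- function(coefs, levels, method, alphas) {
    f_n <- length(levels)
    rows <- vector("list", f_n * t)
    k <- 0L
    for (tt in seq_len(t)) {
      for (ff in seq_len(f_n)) {
        b <- coefs[, ff, tt]
        a <- alphas[ff, tt]
        k <- k + 1L
        rows[[k]] <- data.frame(
          method = method, level = levels[ff], target_id = tt,
          train_r2 = r2_score(Ytr[, tt], Xtr %*% b),
          test_r2 = r2_score(Yte[, tt], Xte %*% b),
          frac_norm = sqrt(sum(b^2)) / ols_norms[tt],
          dof = if (is.finite(a)) effective_dof(dec$lambda, a) else 0,
          alpha = a)
      }
    }
    do.call(rbind, rows)
  }

  out <- rbind(
    score_block(fit$coefs, fit$fracs, "frr", fit$alphas),
    score_block(srr, srr_grid, "srr",
                matrix(srr_grid, length(srr_grid), t))
  )
  rownames(out) <- NULL
  out
}
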