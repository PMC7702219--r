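#' Fit fractional ridge regression
#'
#' Fits ridge-regression solutions for many targets at once, with the
#' regularization level specified as the fraction
#' \eqn{\gamma = \|\beta^{RR}\|_2 / \|\beta^{OLS}\|_2 \in [0, 1]} of the
#' unregularized coefficient norm to retain, instead of the penalty
#' \eqn{\alpha} itself. Internally the design is decomposed once by SVD,
#' the fraction curve \eqn{\gamma(\alpha)} of each target is evaluated on
#' a log-spaced penalty grid, and the penalties achieving the requested
#' fractions are found by interpolation; the achieved fractions typically
#' land within about 1\% of the requested ones.
#'
#' Predictors may optionally be standardized before fitting. With
#' \code{standardize = "center"} the predictor columns and the targets are
#' mean-centered (so the fit corresponds to a regression with an implicit
#' intercept, which predictions restore); \code{"zscore"} additionally
#' scales each predictor column to unit standard deviation. The fraction
#' then refers to the coefficients of the standardized predictors.
#'
#' @param X design matrix (\code{d} data points \eqn{\times} \code{p}
#'   predictors).
#' @param Y targets: vector of length \code{d} or \code{d x t} matrix.
#' @param fracs requested fractions in [0, 1]; default 0 to 1 by 0.05.
#' @param standardize \code{"none"} (default), \code{"center"}, or
#'   \code{"zscore"}.
#' @param tol relative singular-value truncation threshold.
#' @param log_spacing penalty-grid spacing in \eqn{\log_{10}} units
#'   (default 0.2).
#' @return An object of class \code{"frr"}; see Details. Components
#'   include \code{coefs} (\code{p x f x t} array, standardized-predictor
#'   scale), \code{alphas} and \code{achieved} (\code{f x t}),
#'   \code{fracs}, \code{standardize} bookkeeping, and the design
#'   decomposition.
#'
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4)
#' y <- X %*% rnorm(4) + rnorm(50)
#' fit <- frr(X, y, fracs = c(0.25, 0.5, 1))
#' fit
#' round(fit$achieved, 3)
#' @seealso \code{\link{frr_core}} for the array-in/array-out solver,
#'   \code{\link{frr_cv}} for cross-validated fraction selection.
#' @export
frr <- function(X, Y, fracs = seq(0, 1, by = 0.05),
                standardize = c("none", "center", "zscore"),
                tol = NULL, log_spacing = 0.2) {
  standardize <- match.arg(standardize)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    stop(sprintf("'Y' has %d rows but 'X' has %d", nrow(Y), nrow(X)))

  x_center <- rep(0, ncol(X))
  x_scale <- rep(1, ncol(X))
  y_center <- rep(0, ncol(Y))
  if (standardize != "none") {
    x_center <- colMeans(X)
    y_center <- colMeans(Y)
    if (standardize == "zscore") {
      x_scale <- apply(X, 2L, stats::sd)
      bad <- which(x_scale <= 0 | !is.finite(x_scale))
      if (length(bad))
        stop(sprintf("zero-variance predictor(s) cannot be scaled: column %s",
                     paste(bad, collapse = ", ")))
    }
    X <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
    Y <- sweep(Y, 2L, y_center)
  }

  core <- frr_core(X, Y, fracs = fracs, tol = tol,
                   log_spacing = log_spacing)

  structure(
    list(coefs = core$coefs, alphas = core$alphas,
         achieved = core$achieved, fracs = core$fracs,
         decomposition = core$decomposition,
         standardize = list(kind = standardize, x_center = x_center,
                            x_scale = x_scale, y_center = y_center),
         X = X, Y = Y,
         call = match.call()),
    class = "frr"
  )
}

#' @export
print.frr <- function(x, ...) {
  d <- dim(x$coefs)
  cat("Fractional ridge regression fit\n")
  cat(sprintf("  %d data points, %d predictors (rank %d), %d target(s)\n",
              x$decomposition$d, d[1L], x$decomposition$rank, d[3L]))
  cat(sprintf("  requested fractions: %s\n",
              paste(format(x$fracs, trim = TRUE), collapse = " ")))
  dev <- abs(x$achieved - x$fracs)
  if (any(is.finite(dev)))
    cat(sprintf("  max |achieved - requested| = %.2g\n",
                max(dev, na.rm = TRUE)))
  if (x$standardize$kind != "none")
    cat(sprintf("  predictors standardized: %s\n", x$standardize$kind))
  invisible(x)
}

#' @export
summary.frr <- function(object, ...) {
  dev <- abs(object$achieved - object$fracs)
  out <- list(
    fit = object,
    max_dev = if (any(is.finite(dev))) max(dev, na.rm = TRUE) else NA_real_,
    norm_range = range(object$alphas[is.finite(object$alphas)]),
    coef_norms = apply(object$coefs, c(2L, 3L),
                       function(b) sqrt(sum(b^2)))
  )
  class(out) <- "summary.frr"
  out
}

#' @export
print.summary.frr <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  finite penalties span [%.3g, %.3g]\n",
              x$norm_range[1L], x$norm_range[2L]))
  cat("  coefficient L2-norms (fractions x targets):\n")
  print(signif(x$coef_norms, 4))
  invisible(x)
}

#' @export
coef.frr <- function(object, ...) object$coefs

#' Predict from a fractional ridge fit
#'
#' Returns predictions for every requested fraction and target. When the
#' model was fitted with centering or z-scoring, the new predictors are
#' passed through the stored transform and the training-target means are
#' added back, so predictions are always on the original target scale.
#'
#' @param object an \code{"frr"} fit.
#' @param newdata matrix with the training predictor count; defaults to
#'   the training design.
#' @param ... unused.
#' @return array \code{d_new x f x t} (fractions and targets as in the fit).
#' @export
predict.frr <- function(object, newdata = NULL, ...) {
  std <- object$standardize
  if (is.null(newdata)) {
    Xs <- object$X  # already standardized at fit time
  } else {
    Xs <- as.matrix(newdata)
    if (ncol(Xs) != dim(object$coefs)[1L])
      stop(sprintf("'newdata' has %d columns; the model was fit with %d",
                   ncol(Xs), dim(object$coefs)[1L]))
    Xs <- sweep(sweep(Xs, 2L, std$x_center), 2L, std$x_scale, "/")
  }
  dims <- dim(object$coefs)
  pred <- array(Xs %*% matrix(object$coefs, nrow = dims[1L]),
                dim = c(nrow(Xs), dims[2L], dims[3L]))
  sweep(pred, 3L, std$y_center, "+")
}

#' @export
fitted.frr <- function(object, ...) predict.frr(object)

#' @export
residuals.frr <- function(object, ...) {
  fit <- predict.frr(object)
  # broadcast observed targets across the fraction dimension
  obs <- aperm(array(object$Y + rep(object$standardize$y_center,
                                    each = nrow(object$Y)),
                     dim = c(dim(fit)[1L], dim(fit)[3L], dim(fit)[2L])),
               c(1L, 3L, 2L))
  obs - fit
}

#' Simulate responses from a fractional ridge fit
#'
#' Draws new target matrices from the fitted model at one chosen fraction:
#' fitted values plus Gaussian noise with each target's residual standard
#' deviation at that fraction.
#'
#' @param object an \code{"frr"} fit.
#' @param nsim number of simulated data sets.
#' @param seed optional integer seed.
#' @param frac which fitted fraction to simulate from (default: largest).
#' @param ... unused.
#' @return list of \code{nsim} matrices shaped like the training targets.
#' @export
simulate.frr <- function(object, nsim = 1, seed = NULL,
                         frac = max(object$fracs), ...) {
  if (!is.null(seed)) set.seed(seed)
  fi <- which(object$fracs == frac)[1L]
  if (is.na(fi)) stop("'frac' was not among the fitted fractions")
  fit <- predict.frr(object)[, fi, , drop = FALSE]
  d <- dim(fit)[1L]; t_n <- dim(fit)[3L]
  mu <- matrix(fit, d, t_n)
  obs <- object$Y + rep(object$standardize$y_center, each = d)
  sds <- sqrt(colMeans((obs - mu)^2))
  lapply(seq_len(nsim), function(i)
    mu + matrix(stats::rnorm(d * t_n), d, t_n) %*% diag(sds, t_n))
}

#' Coefficient-path and accuracy plot for a fractional ridge fit
#'
#' Two panels: achieved versus requested fraction (should lie on the
#' identity line), and the coefficient paths of one target as a function
#' of the requested fraction.
#'
#' @param x an \code{"frr"} fit.
#' @param target which target's paths to draw (default 1).
#' @param ... passed to \code{matplot}.
#' @export
plot.frr <- function(x, target = 1L, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$fracs, x$achieved[, target], xlab = "requested fraction",
       ylab = "achieved fraction", main = "fraction accuracy",
       xlim = c(0, 1), ylim = c(0, 1))
  graphics::abline(0, 1, col = "grey")
  graphics::matplot(x$fracs, t(x$coefs[, , target]), type = "l", lty = 1,
                    xlab = "requested fraction", ylab = "coefficient",
                    main = sprintf("coefficient paths (target %d)", target),
                    ...)
  invisible(x)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}. Can be
#' negative when the predictions are worse than the mean of the observed
#' values. A zero-variance \code{y_true} makes the score undefined
#' (\code{NaN}, with a warning).
#'
#' @param y_true observed values (length >= 2).
#' @param y_pred predicted values, same length.
#' @return a single number <= 1.
#' @export
r2_score <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (length(y_true) < 2L) stop("need at least two points")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("zero-variance 'y_true': R^2 is undefined")
    return(NaN)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Cross-validated selection of the best fraction per target
#'
#' Splits the rows into a training and a testing part, fits fractional
#' ridge regression on the training rows at every requested fraction,
#' scores out-of-sample \eqn{R^2} for every fraction and target on the
#' testing rows, and selects per target the fraction with the highest test
#' \eqn{R^2}. Ties are broken toward the smallest fraction (the most
#' regularized of the tied solutions). The split is drawn from \code{seed}
#' and recorded in the result, so a rerun with the same seed reproduces
#' the result exactly.
#'
#' @param X design matrix.
#' @param Y targets (vector or \code{d x t} matrix).
#' @param fracs requested fractions (default 0 to 1 by 0.05).
#' @param split fraction of rows used for training, in (0, 1); default 0.5.
#' @param seed integer seed for the split.
#' @param standardize passed to \code{\link{frr}}.
#' @return An object of class \code{"frr_cv"}: list with
#'   \code{best_fraction} and \code{best_alpha} (per target),
#'   \code{test_r2} and \code{train_r2} (\code{f x t}), \code{fit}
#'   (the training-split \code{"frr"} fit), and \code{split}
#'   (train/test indices and the seed).
#' @export
frr_cv <- function(X, Y, fracs = seq(0, 1, by = 0.05), split = 0.5,
                   seed = 1L, standardize = "none") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.numeric(split) || split <= 0 || split >= 1)
    stop("'split' must lie in (0, 1)")
  d <- nrow(X)
  n_train <- round(split * d)
  if (n_train < 2L || d - n_train < 2L)
    stop("split leaves fewer than 2 rows on one side")

  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  train <- sort(sample.int(d, n_train))
  if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  test <- setdiff(seq_len(d), train)

  fit <- frr(X[train, , drop = FALSE], Y[train, , drop = FALSE],
             fracs = fracs, standardize = standardize)
  pred_te <- predict(fit, X[test, , drop = FALSE])
  pred_tr <- predict(fit)

  f_n <- length(fit$fracs); t_n <- ncol(Y)
  test_r2 <- matrix(NA_real_, f_n, t_n)
  train_r2 <- matrix(NA_real_, f_n, t_n)
  for (tt in seq_len(t_n)) {
    for (ff in seq_len(f_n)) {
      test_r2[ff, tt] <- r2_score(Y[test, tt], pred_te[, ff, tt])
      train_r2[ff, tt] <- r2_score(Y[train, tt], pred_tr[, ff, tt])
    }
  }

  best_idx <- apply(test_r2, 2L, function(col) {
    cand <- which(col == max(col))
    cand[which.min(fit$fracs[cand])]
  })
  structure(
    list(best_fraction = fit$fracs[best_idx],
         best_alpha = fit$alphas[cbind(best_idx, seq_len(t_n))],
         test_r2 = test_r2, train_r2 = train_r2,
         fit = fit,
         split = list(train = train, test = test, seed = seed,
                      fraction = split)),
    class = "frr_cv"
  )
}

#' @export
print.frr_cv <- function(x, ...) {
  t_n <- length(x$best_fraction)
  cat(sprintf("Cross-validated fractional ridge (%d target%s, %d/%d split, seed %d)\n",
              t_n, if (t_n == 1L) "" else "s",
              length(x$split$train), length(x$split$test), x$split$seed))
  cat("  best fraction per target: ",
      paste(format(x$best_fraction, trim = TRUE), collapse = " "), "\n")
  cat("  test R^2 at the best fraction: ",
      paste(sprintf("%.3f", x$test_r2[cbind(
        match(x$best_fraction, x$fit$fracs), seq_len(t_n))]),
        collapse = " "), "\n")
  invisible(x)
}
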