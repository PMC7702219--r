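test_that("fit and predict reproduce least squares at fraction one", {
  set.seed(1)
  X <- matrix(rnorm(60 * 4), 60, 4)
  beta <- rnorm(4)
  y <- X %*% beta
  fit <- frr(X, y, fracs = 1)
  expect_lt(max(abs(predict(fit)[, 1, 1] - y)), 1e-8)
  expect_lt(max(abs(coef(fit)[, 1, 1] - beta)), 1e-8)
})

test_that("centering reproduces a regression with an explicit intercept", {
  set.seed(2)
  X <- matrix(rnorm(50 * 3), 50, 3) + 5   # far from zero mean
  y <- X %*% c(1, -2, 0.5) + 3 + rnorm(50)
  fit <- frr(X, y, fracs = 1, standardize = "center")
  ls <- lm.fit(cbind(1, X), y)
  expect_lt(max(abs(predict(fit)[, 1, 1] - ls$fitted.values)), 1e-8)

  # fraction 0: prediction is just the training-mean offset
  fit0 <- frr(X, y, fracs = 0, standardize = "center")
  expect_equal(unname(predict(fit0)[, 1, 1]), rep(mean(y), 50),
               tolerance = 1e-12)
  expect_true(all(coef(fit0) == 0))
})

test_that("z-scoring is undone at prediction time and rejects flat columns", {
  set.seed(3)
  X <- matrix(rnorm(40 * 3), 40, 3) %*% diag(c(1, 10, 100))
  y <- X %*% c(1, 0.1, 0.01) + rnorm(40)
  fit <- frr(X, y, fracs = 1, standardize = "zscore")
  ls <- lm.fit(cbind(1, X), y)
  expect_lt(max(abs(predict(fit)[, 1, 1] - ls$fitted.values)), 1e-8)

  Xnew <- matrix(rnorm(15), 5, 3)
  expect_equal(dim(predict(fit, Xnew)), c(5L, 1L, 1L))

  Xflat <- X; Xflat[, 2] <- 7
  expect_error(frr(Xflat, y, standardize = "zscore"), "column 2")
  expect_error(predict(fit, matrix(0, 2, 5)), "columns")
})

test_that("predictions are linear in the inputs when no centering is applied", {
  set.seed(4)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- X %*% rnorm(5) + rnorm(30)
  fit <- frr(X, y, fracs = c(0.3, 0.8))
  X1 <- matrix(rnorm(20), 4, 5)
  X2 <- matrix(rnorm(20), 4, 5)
  lhs <- predict(fit, 2 * X1 - 3 * X2)
  rhs <- 2 * predict(fit, X1) - 3 * predict(fit, X2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("R^2 follows its definition, including the degenerate cases", {
  expect_equal(r2_score(1:5, 1:5), 1)
  expect_equal(r2_score(c(2, 4, 6), rep(4, 3)), 0)
  expect_equal(r2_score(c(0, 1, 2), c(0, 0, 0)), -1.5)
  expect_warning(out <- r2_score(rep(3, 4), 1:4), "zero-variance")
  expect_true(is.nan(out))
  expect_error(r2_score(1:3, 1:4), "lengths")
})

test_that("cross-validated selection is reproducible and favors no shrinkage without noise", {
  set.seed(5)
  X <- matrix(rnorm(80 * 4), 80, 4)
  Y <- X %*% matrix(rnorm(8), 4, 2)   # noiseless
  cv1 <- frr_cv(X, Y, fracs = seq(0, 1, 0.25), seed = 42)
  cv2 <- frr_cv(X, Y, fracs = seq(0, 1, 0.25), seed = 42)
  expect_identical(cv1, cv2)
  expect_equal(cv1$best_fraction, c(1, 1))
  expect_equal(unname(cv1$best_alpha), c(0, 0))
  expect_equal(length(cv1$split$train), 40L)

  expect_error(frr_cv(X, Y, split = 1.2), "split")
  expect_error(frr_cv(X[1:3, ], Y[1:3, ], split = 0.5), "fewer than 2")
})

test_that("unregularized fits overfit pure-noise targets out of sample", {
  set.seed(6)
  X <- matrix(rnorm(60 * 30), 60, 30)
  Y <- matrix(rnorm(60 * 50), 60, 50)  # no signal at all
  cv <- frr_cv(X, Y, fracs = c(0.2, 1), seed = 7)
  expect_lte(median(cv$test_r2[2, ]), 0)
})

test_that("training-split R^2 is maximal at fraction one", {
  set.seed(8)
  X <- matrix(rnorm(100 * 20), 100, 20)
  Y <- X %*% matrix(rnorm(20 * 3), 20, 3) + matrix(rnorm(300), 100, 3)
  cv <- frr_cv(X, Y, fracs = seq(0, 1, 0.1), seed = 9)
  for (tt in 1:3)
    expect_true(all(cv$train_r2[11, tt] >= cv$train_r2[, tt] - 1e-12))
})

test_that("matched noise drives the selected fraction below one when p = d", {
  below <- vapply(1:5, function(seed) {
    spec <- frr_scenario(d = 100, p = 100, seed = seed)
    X <- make_correlated_design(spec)
    sim <- simulate_targets(X, spec, t = 10)
    cv <- frr_cv(X, sim$Y, fracs = seq(0, 1, 0.05), seed = seed)
    mean(cv$best_fraction < 1)
  }, numeric(1))
  expect_true(all(below > 0.5))
})

test_that("model object methods run and are self-consistent", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Y <- X %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(80), 40, 2)
  fit <- frr(X, Y, fracs = c(0.5, 1))
  expect_output(print(fit), "Fractional ridge")
  expect_output(print(summary(fit)), "coefficient L2-norms")
  res <- residuals(fit)
  expect_equal(dim(res), c(40L, 2L, 2L))
  expect_lt(max(abs(res[, 2, 1] - (Y[, 1] - predict(fit)[, 2, 1]))), 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1, frac = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(Y))
  pdf(NULL); plot(fit); dev.off()
})
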