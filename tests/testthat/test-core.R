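test_that("penalty grid spans three decades beyond the squared spectrum", {
  dec <- frr_decompose(diag(3))  # lambda = 1
  g <- frr_alpha_grid(dec)
  expect_length(g$alphas, 31L)  # 10^-3 .. 10^3 at 0.2 steps
  expect_equal(g$alphas[1L], 1e-3)
  expect_equal(g$alphas[31L], 1e3)
  expect_lt(max(abs(diff(log10(g$alphas)) - 0.2)), 1e-12)

  dec <- frr_decompose(rbind(c(10, 0), c(0, 0.1), c(0, 0)))
  g <- frr_alpha_grid(dec)
  expect_lte(g$alphas[1L], 1e-3 * 0.1^2 * (1 + 1e-9))
  expect_gte(g$alphas[length(g$alphas)], 1e3 * 100 * (1 - 1e-9))

  expect_error(frr_alpha_grid(dec, log_spacing = 0), "positive")
})

test_that("shrinkage factors follow lambda^2 / (lambda^2 + alpha)", {
  dec <- frr_decompose(rbind(c(2, 0), c(0, 1), c(0, 0)))
  sf <- frr_shrinkage_factors(dec, c(1))
  expect_equal(drop(sf), c(4 / 5, 1 / 2))

  g <- frr_alpha_grid(dec)
  tab <- frr_shrinkage_factors(dec, g)
  expect_true(all(tab > 0 & tab < 1))
  expect_true(all(apply(tab, 1L, function(r) all(diff(r) < 0))))
  # at the top of the grid everything is shrunk below 1e-3
  expect_true(all(tab[, ncol(tab)] <= 1e-3 * (1 + 1e-9)))
})

test_that("the fraction curve is correct and strictly decreasing", {
  # flat spectrum: alpha = lambda^2 gives exactly 1/2
  dec <- frr_decompose(flat_design(20, 5, lam = 3))
  rt <- frr_rotate_target(dec, rnorm(20))
  sf <- frr_shrinkage_factors(dec, c(9))
  expect_equal(frr_gamma_curve(rt, sf), 0.5, tolerance = 1e-10)

  g <- frr_alpha_grid(dec)
  curve <- frr_gamma_curve(rt, frr_shrinkage_factors(dec, g))
  expect_true(all(diff(curve) < 0))
  expect_true(all(curve > 0 & curve < 1))

  # single component: gamma = lambda^2 / (lambda^2 + alpha)
  dec1 <- frr_decompose(matrix(c(1, 0), 2, 1))
  rt1 <- frr_rotate_target(dec1, c(2, 0))
  expect_equal(frr_gamma_curve(rt1, frr_shrinkage_factors(dec1, c(3))), 0.25)

  rt0 <- frr_rotate_target(dec, rep(0, 20))
  expect_error(frr_gamma_curve(rt0, sf), "zero-norm")
})

test_that("interpolated penalties hit requested fractions", {
  dec <- frr_decompose(flat_design(30, 4, lam = 1))
  g <- frr_alpha_grid(dec)
  rt <- frr_rotate_target(dec, rnorm(30))
  curve <- frr_gamma_curve(rt, frr_shrinkage_factors(dec, g))

  a <- frr_interpolate_alphas(curve, g, c(0, 0.5, 1))
  expect_identical(a[3L], 0)
  expect_identical(a[1L], Inf)
  expect_lt(abs(a[2L] - 1) / 1, 0.02)  # closed form: lambda^2 (1/g - 1) = 1

  expect_error(frr_interpolate_alphas(c(0.5, 0.5, 0.4), g, 0.5),
               "not strictly decreasing")
  expect_error(frr_interpolate_alphas(curve, g, 1.5), "0, 1")
})

test_that("per-target solving applies the componentwise shrinkage", {
  X <- rbind(c(2, 0), c(0, 1), c(0, 0))
  dec <- frr_decompose(X)
  y <- dec$u %*% c(4, 3)
  rt <- frr_rotate_target(dec, y)   # rotated OLS = (2, 3)
  out <- frr_solve_target(rt, dec, c(0, 1, Inf))
  expect_equal(out[, 1L], rt$beta_ols_rot)
  expect_equal(out[, 2L], c(1.6, 1.5), tolerance = 1e-12)
  expect_equal(out[, 3L], c(0, 0))
})

test_that("direct ridge matches hand calculations and the SVD route", {
  expect_equal(ridge_direct(diag(2), c(1, 1), 1), c(0.5, 0.5))

  pr <- random_problem(20, 4, seed = 5)
  expect_equal(ridge_direct(pr$X, pr$Y, 0),
               drop(solve(crossprod(pr$X), crossprod(pr$X, pr$Y))),
               tolerance = 1e-10)

  # rotated-space route computed from scratch
  pr <- random_problem(6, 3, seed = 9)
  s <- svd(pr$X)
  beta_svd <- s$v %*% ((s$d / (s$d^2 + 2)) * crossprod(s$u, pr$Y))
  expect_equal(ridge_direct(pr$X, pr$Y, 2), drop(beta_svd), tolerance = 1e-10)

  # singular at alpha = 0 falls back to the pseudoinverse
  X <- cbind(1:4, 1:4)
  expect_warning(b <- ridge_direct(X, c(1, 2, 3, 4), 0), "pseudoinverse")
  expect_equal(b, drop(pinv_ols(X, 1:4)), tolerance = 1e-10)

  expect_error(ridge_direct(diag(2), c(1, 1), -1), "'alpha'")
})

test_that("the full solver is accurate, monotone and oracle-consistent", {
  pr <- random_problem(50, 10, t = 4, seed = 2)
  fracs <- seq(0.05, 0.95, by = 0.05)
  fit <- frr_core(pr$X, pr$Y, fracs)

  expect_lt(max(abs(fit$achieved - fracs)), 0.01)

  for (tt in 1:4) {
    norms <- apply(fit$coefs[, , tt], 2L, function(b) sqrt(sum(b^2)))
    expect_true(all(diff(norms) > 0))
    for (ff in c(1L, 10L, 19L)) {
      b_oracle <- ridge_direct(pr$X, pr$Y[, tt], fit$alphas[ff, tt])
      expect_lt(rel_err(fit$coefs[, ff, tt], b_oracle), 1e-6)
    }
  }
})

test_that("components with larger singular values are shrunk less", {
  pr <- random_problem(40, 6, seed = 13)
  dec <- frr_decompose(pr$X)
  rt <- frr_rotate_target(dec, pr$Y)
  for (alpha in c(0.1, 1, 10, 100)) {
    ratio <- drop(frr_solve_target(rt, dec, alpha)) / rt$beta_ols_rot
    # lambda is sorted decreasing, so the shrinkage ratio must decrease too
    expect_true(all(diff(ratio) <= 1e-12))
  }
})

test_that("endpoints, degenerate targets and fraction bookkeeping behave", {
  pr <- random_problem(30, 5, t = 2, seed = 4)
  fit <- frr_core(pr$X, pr$Y, fracs = c(1))
  for (tt in 1:2)
    expect_lt(rel_err(fit$coefs[, 1, tt], pinv_ols(pr$X, pr$Y[, tt])), 1e-8)
  expect_equal(unname(fit$achieved[1, ]), c(1, 1), tolerance = 1e-10)

  # requested order preserved, duplicates allowed
  fit <- frr_core(pr$X, pr$Y, fracs = c(0.9, 0.3, 0.9, 0))
  expect_equal(fit$fracs, c(0.9, 0.3, 0.9, 0))
  expect_identical(fit$coefs[, 1, ], fit$coefs[, 3, ])
  expect_true(all(fit$coefs[, 4, ] == 0))
  expect_identical(unname(fit$alphas[4, ]), c(Inf, Inf))
  expect_gt(sqrt(sum(fit$coefs[, 1, 1]^2)), sqrt(sum(fit$coefs[, 2, 1]^2)))

  # zero target: zero coefficients, NaN markers
  Y <- cbind(pr$Y[, 1], 0)
  fit <- frr_core(pr$X, Y, fracs = c(0.5))
  expect_true(all(fit$coefs[, 1, 2] == 0))
  expect_true(is.nan(fit$alphas[1, 2]))
  expect_true(is.nan(fit$achieved[1, 2]))

  # no targets: empty but well-shaped
  fit <- frr_core(pr$X, pr$Y[, integer(0)], fracs = c(0.5))
  expect_equal(dim(fit$coefs), c(5L, 1L, 0L))

  expect_error(frr_core(pr$X, pr$Y[-1, ]), "rows")
  expect_error(frr_core(pr$X, pr$Y, fracs = c(0.5, 2)), "fracs")
})

test_that("solutions computed in the rotated space keep their norm in predictor space", {
  pr <- random_problem(25, 8, seed = 21)
  dec <- frr_decompose(pr$X)
  rt <- frr_rotate_target(dec, pr$Y)
  rot <- frr_solve_target(rt, dec, c(0.5, 5, 50))
  orig <- frr_unrotate(dec, rot)
  expect_equal(sqrt(colSums(orig^2)), sqrt(colSums(rot^2)), tolerance = 1e-10)
})
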