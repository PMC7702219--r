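# small random regression problems used across tests
random_problem <- function(d, p, t = 1L, seed = 1L, noise_sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(d * p), d, p)
  beta <- matrix(rnorm(p * t), p, t)
  Y <- X %*% beta + matrix(rnorm(d * t, sd = noise_sd), d, t)
  list(X = X, Y = Y, beta = beta)
}

# design with orthonormal columns scaled by a common factor, so the
# singular-value spectrum is exactly flat at `lam`
flat_design <- function(d, p, lam = 1, seed = 1L) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * p), d, p))) * lam
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# pseudoinverse OLS solution, independent of the package's SVD path
pinv_ols <- function(X, y) MASS::ginv(X) %*% as.matrix(y)
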