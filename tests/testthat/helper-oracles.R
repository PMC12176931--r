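# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# dense multivariate-normal log density via explicit inverse/determinant
dmvnorm_oracle <- function(x, mu, S) {
  x <- as.numeric(x)
  k <- length(x)
  d <- x - mu
  -0.5 * (k * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus +
            drop(t(d) %*% solve(S) %*% d))
}

# plain split-free Gelman-Rubin statistic, written from the formula
classic_rhat_oracle <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# a small, well-conditioned population used in moment/likelihood tests
tiny_params <- function(grid = time_grid()) {
  pgm_parameters(alpha = c(10, 2, -1),
                 omega_eta = matrix(c(4, 0.5, 0.2,
                                      0.5, 1, 0.1,
                                      0.2, 0.1, 0.8), 3, 3),
                 sigma2_eps = c(1, 1.5, 2, 1, 0.5, 1, 2),
                 gamma = 2.5,
                 grid = grid)
}

# random positive-semidefinite 3x3 matrix
random_psd3 <- function() {
  A <- matrix(rnorm(9), 3, 3)
  crossprod(A)
}
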