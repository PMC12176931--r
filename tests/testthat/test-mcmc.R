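# --- R-hat ------------------------------------------------------------

test_that("R-hat stays near 1 for chains from a common distribution", {
  set.seed(101)
  ok <- vapply(1:100, function(i) {
    m <- matrix(rnorm(4000), 1000, 4)
    compute_rhat(m) < 1.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("R-hat matches a hand-coded formula oracle and flags separation", {
  c1 <- rep(c(0, 1), 500)
  m <- cbind(c1, c1 + 10)
  # oracle: split each chain in half, then the plain Gelman-Rubin formula
  half <- 500
  split <- cbind(m[1:half, ], m[half + (1:half), ])
  expect_equal(compute_rhat(m, method = "classic"),
               classic_rhat_oracle(split), tolerance = 1e-10)
  expect_gt(compute_rhat(m, method = "classic"), 1.1)
  expect_gt(compute_rhat(m, method = "rank"), 1.1)
})

test_that("rank-normalized R-hat detects scale-only divergence", {
  set.seed(5)
  m <- cbind(rnorm(1000, 0, 1), rnorm(1000, 0, 8))
  expect_gt(compute_rhat(m, method = "rank"), 1.1)
})

test_that("degenerate draws return R-hat 1 with a warning", {
  expect_warning(r <- compute_rhat(matrix(5, 100, 4)), "zero total variance")
  expect_equal(r, 1)
})

test_that("convergence check uses a strict inequality at the threshold", {
  fake <- structure(list(rhat = c(a = 1.0, b = 1.0)), class = "pgm_fit")
  expect_true(check_convergence(fake, 1.1))
  fake$rhat["b"] <- 1.1
  expect_false(check_convergence(fake, 1.1))
  fake$rhat["b"] <- 1.2
  expect_false(check_convergence(fake, 1.1))
})

# --- conjugate full conditionals against analytic posteriors ----------

test_that("growth-factor mean update matches its analytic normal", {
  set.seed(201)
  n <- 30
  eta <- matrix(rnorm(n * 3, mean = c(2, -1, 4)), n, 3, byrow = TRUE)
  omega <- diag(c(2, 1, 0.5))
  mu_a <- 1; s2_a <- 10
  # analytic conditional: precision n*Omega^-1 + I/s2_a (diagonal here)
  prec <- n / diag(omega) + 1 / s2_a
  mean_a <- (colSums(eta) / diag(omega) + mu_a / s2_a) / prec
  draws <- t(replicate(5000, as.numeric(
    pgmknot:::cpp_update_alpha(eta, omega, mu_a, s2_a))))
  for (k in 1:3) {
    ks <- ks.test(draws[, k], pnorm, mean = mean_a[k],
                  sd = sqrt(1 / prec[k]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("residual-variance update matches its inverse-gamma", {
  set.seed(202)
  resid <- matrix(rnorm(50 * 2, sd = 3), 50, 2)
  a <- 0.001; b <- 0.001
  draws <- t(replicate(5000, as.numeric(
    pgmknot:::cpp_update_sigma2(resid, a, b))))
  for (j in 1:2) {
    shape <- a + 25
    rate <- b + sum(resid[, j]^2) / 2
    # X ~ IG(shape, rate)  <=>  1/X ~ Gamma(shape, rate)
    ks <- ks.test(draws[, j], function(q) {
      pgamma(1 / q, shape, rate = rate, lower.tail = FALSE)
    })
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("factor-covariance update matches its inverse-Wishart marginal", {
  set.seed(203)
  n <- 40
  eta <- matrix(rnorm(n * 3), n, 3)
  alpha <- colMeans(eta)
  Psi <- diag(3)
  nu <- 3
  Sstar <- Psi + crossprod(sweep(eta, 2, alpha))
  df <- nu + n
  draws <- replicate(4000, pgmknot:::cpp_update_omega(eta, alpha, Psi, nu))
  # scalar upper-left block of IW_3(Sstar, df) is IG((df-2)/2, Sstar11/2)
  ks <- ks.test(draws[1, 1, ], function(q) {
    pgamma(1 / q, (df - 2) / 2, rate = Sstar[1, 1] / 2, lower.tail = FALSE)
  })
  expect_gt(ks$p.value, 0.01)
  # and the posterior mean of the full matrix: Sstar / (df - p - 1)
  expect_equal(apply(draws, 1:2, mean), Sstar / (df - 4), tolerance = 0.1)
})

test_that("factor-score update matches its analytic conditional", {
  set.seed(204)
  grid <- time_grid()
  L <- build_loading_matrix(grid, 2.5)
  omega <- diag(c(4, 1, 1))
  alpha <- c(10, 2, 1)
  sigma2 <- rep(2, 7)
  y <- matrix(drop(L %*% alpha) + rnorm(7), 1, 7)
  OmInv <- solve(omega)
  prec <- OmInv + t(L) %*% diag(1 / sigma2) %*% L
  V <- solve(prec)
  m <- drop(V %*% (OmInv %*% alpha + t(L) %*% (y[1, ] / sigma2)))
  draws <- t(replicate(5000, as.numeric(
    pgmknot:::cpp_update_eta(y, L, omega, alpha, sigma2))))
  for (k in 1:3) {
    ks <- ks.test(draws[, k], pnorm, mean = m[k], sd = sqrt(V[k, k]))
    expect_gt(ks$p.value, 0.01)
  }
  expect_equal(cov(draws), V, tolerance = 0.05)
})

# --- the full sampler --------------------------------------------------

test_that("with no data the knot posterior reproduces its prior", {
  d0 <- longitudinal_dataset(matrix(numeric(0), 0, 7))
  pr <- default_nuisance_priors(knot_prior_preset("I-ATK"))
  fit <- fit_pgm(d0, pr, mcmc_config_reduced(n_iter = 8000, seed = 303))
  g <- do.call(rbind, fit$chains)[, "gamma"]
  # truncation at (0, 6) is negligible for N(3, 0.146)
  expect_lt(abs(mean(g) - 3), 0.03)
  expect_lt(abs(sd(g) - sqrt(0.146)), 0.03)
  expect_true(all(g > 0 & g < 6))
})

test_that("fits are deterministic under a fixed seed", {
  d <- generate_complete(default_population(), 40, seed = 41)
  pr <- default_nuisance_priors(knot_prior_preset("WI-ATK"))
  cfg <- mcmc_config_reduced(n_iter = 500, burn_in = 200, seed = 99)
  f1 <- fit_pgm(d, pr, cfg)
  f2 <- fit_pgm(d, pr, cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$summaries, f2$summaries)
})

test_that("augmentation path with zero missingness equals the complete path", {
  d <- generate_complete(default_population(), 40, seed = 43)
  dm <- apply_mar(d, missingness_spec("complete"))
  pr <- default_nuisance_priors(knot_prior_preset("WI-ATK"))
  cfg <- mcmc_config_reduced(n_iter = 600, burn_in = 200, seed = 7)
  f1 <- fit_pgm(d, pr, cfg)
  f2 <- fit_pgm(dm, pr, cfg)
  expect_identical(f1$summaries, f2$summaries)
})

test_that("knot draws never leave the truncated support", {
  d <- generate_complete(default_population(), 30, seed = 45)
  dm <- apply_mar(d, missing_level_spec("Constant-70%"), seed = 46)
  pr <- default_nuisance_priors(knot_prior_preset("I-PSK"))
  fit <- fit_pgm(dm, pr, mcmc_config_reduced(n_iter = 2000, seed = 47))
  g <- do.call(rbind, fit$chains)[, "gamma"]
  expect_true(all(g > 0 & g < 6))
  expect_true(fit$knot_acceptance > 0 && fit$knot_acceptance < 1)
})

test_that("the knot is recovered at n = 500 under a diffuse prior", {
  pr <- default_nuisance_priors(knot_prior_preset("DIF"))
  bias <- rep(NA_real_, 20)
  conv <- logical(20)
  # longer chains than the small-n preset: the knot mixes more slowly at
  # n = 500 because its conditional given the factor scores tightens
  cfg <- mcmc_config(n_chains = 2, n_iter = 8000, burn_in = 2000, thin = 4)
  for (r in 1:20) {
    set.seed(5000 + r)
    d <- generate_complete(default_population(), 500)
    fit <- fit_pgm(d, pr, cfg)
    conv[r] <- fit$converged
    bias[r] <- fit$summaries$mean[fit$summaries$parameter == "gamma"] - 3
  }
  expect_gte(mean(conv), 0.5)
  expect_lt(abs(mean(bias)), 0.1)
})

test_that("posterior summaries agree with a sorting-based oracle", {
  d <- generate_complete(default_population(), 30, seed = 51)
  fit <- fit_pgm(d, default_nuisance_priors(knot_prior_preset("WI-ATK")),
                 mcmc_config_reduced(n_iter = 800, burn_in = 200, seed = 52))
  pooled <- do.call(rbind, fit$chains)[, "gamma"]
  s <- summary(fit)
  g <- s[s$parameter == "gamma", ]
  expect_equal(g$mean, mean(pooled))
  expect_equal(g$median, median(pooled))
  # manual type-7 interpolation quantile
  manual_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(g$ci_lower, manual_q(pooled, 0.025))
  expect_equal(g$ci_upper, manual_q(pooled, 0.975))
  expect_true(g$ci_lower <= g$median && g$median <= g$ci_upper)
})

test_that("tidy draw export is long-format and complete", {
  d <- generate_complete(default_population(), 20, seed = 61)
  fit <- fit_pgm(d, default_nuisance_priors(),
                 mcmc_config_reduced(n_iter = 100, burn_in = 50, seed = 62))
  td <- as.data.frame(fit)
  expect_named(td, c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(td), 2 * 100 * 17)
  expect_setequal(unique(td$parameter), pgmknot:::param_names(7))
})
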