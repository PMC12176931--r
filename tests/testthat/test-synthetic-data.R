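test_that("missingness schedules evaluate the printed formulas", {
  expect_equal(missing_schedule("constant", 0.30),
               c(0, .05, .10, .15, .20, .25, .30))
  s <- missing_schedule("concen_s", 0.30)
  expect_equal(s[1], 0)
  expect_equal(s[7], 0.30)
  # accelerated 70% pattern at t = 3: (35/18) * 9 = 17.5%
  expect_equal(missing_schedule("concen_e", 0.70)[4], 0.175)
  expect_equal(missing_schedule("constant", 0.70),
               (35 / 3) * (0:6) / 100)
  expect_equal(missing_schedule("concen_s", 0.70),
               (-(35 / 18) * ((0:6) - 6)^2 + 70) / 100)
})

test_that("schedules outside the default grid require an explicit schedule", {
  g <- time_grid(c(0, 0.5, 1, 1.5, 3.5, 5.5, 8.5))
  expect_error(missing_schedule("constant", 0.3, g), "default 0..6")
  sp <- missingness_spec("constant", schedule = c(0, .1, .2, .3, .4, .5, .6),
                         grid = g)
  expect_equal(sp$terminal_prop, 0.6)
  expect_error(missingness_spec("constant",
                                schedule = c(.1, .1, .2, .3, .4, .5, .6),
                                grid = g),
               "fully observed")
})

test_that("logit intercepts hit the target marginal missingness", {
  expect_equal(solve_logit_intercepts(0.5, b1 = 0), 0, tolerance = 1e-7)
  # symmetry of the standard-normal predictor: p = 0.5 gives b0 = 0 for any b1
  expect_equal(solve_logit_intercepts(0.5, b1 = 1.48), 0, tolerance = 1e-7)
  expect_true(is.na(solve_logit_intercepts(0, b1 = 1.48)))
  # Monte Carlo oracle for the quadrature
  b0 <- solve_logit_intercepts(0.30, b1 = 1.48)
  set.seed(123)
  z <- rnorm(1e6)
  expect_equal(mean(plogis(b0 + 1.48 * z)), 0.30, tolerance = 0.002)
  expect_error(solve_logit_intercepts(1.2), "\\[0, 1\\)")
})

test_that("complete-data generation matches the implied moments", {
  p <- default_population()
  mom <- implied_moments(p)
  d <- generate_complete(p, 1e5, seed = 17)
  expect_true(all(d$mask))
  se <- sqrt(diag(mom$cov) / 1e5)
  expect_true(all(abs(colMeans(d$values) - mom$mean) < 4 * se))
})

test_that("degenerate populations produce deterministic trajectories", {
  grid <- time_grid()
  p <- pgm_parameters(c(5, 1, 2), matrix(0, 3, 3), 1e-18, 3, grid)
  d <- generate_complete(p, 10, seed = 2)
  mu <- drop(build_loading_matrix(grid, 3) %*% c(5, 1, 2))
  expect_equal(unname(d$values), matrix(mu, 10, 7, byrow = TRUE),
               tolerance = 1e-6)
})

test_that("generation is reproducible under a fixed seed", {
  p <- default_population()
  d1 <- generate_complete(p, 100, seed = 31)
  d2 <- generate_complete(p, 100, seed = 31)
  expect_identical(d1$values, d2$values)
  m1 <- apply_mar(d1, missing_level_spec("Constant-70%"), seed = 8)
  m2 <- apply_mar(d2, missing_level_spec("Constant-70%"), seed = 8)
  expect_identical(m1$mask, m2$mask)
})

test_that("a complete spec leaves the data untouched", {
  d <- generate_complete(default_population(), 50, seed = 4)
  expect_identical(apply_mar(d, missingness_spec("complete"), seed = 1), d)
})

test_that("MAR generator calibrates to the schedule at every occasion", {
  d <- generate_complete(default_population(), 1e5, seed = 55)
  dm <- apply_mar(d, missing_level_spec("Constant-30%"), seed = 56)
  achieved <- colMeans(!dm$mask)
  target <- missing_schedule("constant", 0.30)
  expect_equal(achieved[1], 0)
  expect_true(all(abs(achieved - target) < 0.006))
  expect_lt(abs(achieved[7] - 0.30), 0.005)
})

test_that("dropout regression recovers the generating slope b1 = 1.48", {
  d <- generate_complete(default_population(), 1e5, seed = 77)
  dm <- apply_mar(d, missing_level_spec("Constant-30%"), seed = 78)
  z <- scale(d$values[, 1])[, 1]
  miss7 <- as.integer(!dm$mask[, 7])
  fit <- glm(miss7 ~ z, family = binomial())
  est <- coef(summary(fit))["z", ]
  expect_lt(abs(est["Estimate"] - 1.48), 2 * est["Std. Error"])
})

test_that("missingness indicators depend only on the first occasion (MAR)", {
  d <- generate_complete(default_population(), 2000, seed = 91)
  spec <- missing_level_spec("Concen-E-70%")
  m1 <- apply_mar(d, spec, seed = 92)
  # perturbing later-occasion values cannot change who goes missing
  d2 <- d
  d2$values[, 2:7] <- d2$values[, 2:7] + rnorm(2000 * 6, 0, 50)
  m2 <- apply_mar(d2, spec, seed = 92)
  expect_identical(m1$mask, m2$mask)
})

test_that("the monotone flag produces staircase dropout", {
  d <- generate_complete(default_population(), 5000, seed = 13)
  spec <- missingness_spec("constant", 0.70, monotone = TRUE)
  dm <- apply_mar(d, spec, seed = 14)
  # once missing, always missing: the observed indicator never rises again
  for (j in 3:7) {
    expect_true(all(dm$mask[, j] <= dm$mask[, j - 1] |
                      dm$mask[, j] == FALSE |
                      dm$mask[, j - 1] == TRUE))
    expect_false(any(dm$mask[, j] & !dm$mask[, j - 1]))
  }
})

test_that("documented population defaults describe a detectable knot", {
  p <- default_population()
  expect_equal(p$gamma, 3)
  expect_false(p$alpha[2] == p$alpha[3])
  # standardized slope-change effect (change over SD of the slope difference)
  eff <- (p$alpha[3] - p$alpha[2]) /
    sqrt(p$omega_eta[2, 2] + p$omega_eta[3, 3] - 2 * p$omega_eta[2, 3])
  expect_gte(eff, 0.8)
})

test_that("wide CSV round-trips values, mask and grid", {
  d <- generate_complete(default_population(), 30, seed = 6)
  dm <- apply_mar(d, missing_level_spec("Concen-S-30%"), seed = 7)
  path <- tempfile(fileext = ".csv")
  write_longitudinal_csv(dm, path)
  back <- read_longitudinal_csv(path)
  expect_equal(back$grid$codes, dm$grid$codes)
  expect_identical(back$mask, unname(dm$mask))
  expect_equal(unname(back$values[back$mask]), unname(dm$values[dm$mask]),
               tolerance = 1e-12)
  unlink(path)
})
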