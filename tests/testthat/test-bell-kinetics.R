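# High-precision reference values below were computed independently with
# 30-digit arithmetic (mpmath) from the printed formulas.

test_that("membrane off-rate follows Bell's model exactly", {
  # force-independent bond
  expect_identical(membrane_off_rate(1, 0, 50), 1)
  # direct evaluation oracle: exp(6/4.2797)
  expect_equal(membrane_off_rate(1, 0.4, 15, temp = 4.2797),
               4.06318613280369, tolerance = 1e-9)
  # zero-force identity holds exactly for arbitrary parameters
  set.seed(1)
  for (i in 1:25) {
    k0 <- 10^runif(1, -2, 2); xb <- runif(1, -1, 1)
    expect_identical(membrane_off_rate(k0, xb, 0), k0)
  }
  expect_equal(membrane_off_rate(0.29, 0.37, 0), 0.29)
})

test_that("off-rate is monotone in force with the sign of x_beta", {
  f <- seq(0, 120, by = 5)
  set.seed(2)
  for (i in 1:20) {
    k0 <- 10^runif(1, -2, 1); xb <- runif(1, 0.05, 1)
    expect_true(all(diff(membrane_off_rate(k0, xb, f)) > 0))
    expect_true(all(diff(membrane_off_rate(k0, -xb, f)) < 0))
  }
})

test_that("membrane off-rate rejects invalid parameters", {
  expect_error(membrane_off_rate(-1, 0.3, 10), "k0_off")
  expect_error(membrane_off_rate(1, 0.3, NaN), "force")
  expect_error(membrane_off_rate(1, 0.3, -5), "force")
  expect_error(membrane_off_rate(1, Inf, 5), "x_beta")
})

test_that("fold-change calculus reproduces the discrimination examples", {
  rel_pos <- xbeta_relation(0.3, argument = "k_off")
  rel_neg <- xbeta_relation(-0.3, argument = "k_off")
  # ~820-fold amplification / ~12-fold damping of a 100-fold k_off difference
  expect_equal(fold_change_under_force(0.1, 10, rel_pos, 15, temp = 4.2797),
               819.030503051986, tolerance = 1e-9)
  expect_equal(fold_change_under_force(0.1, 10, rel_neg, 15, temp = 4.2797),
               12.2095574740337, tolerance = 1e-9)
  # without force the ratio is preserved
  expect_equal(fold_change_under_force(0.03, 3, rel_pos, 0), 100)
})

test_that("fold-change under force depends only on the rate ratio", {
  # algebraic identity when the relation multiplies log10
  set.seed(3)
  for (i in 1:15) {
    rel <- xbeta_relation(runif(1, -0.5, 0.5), runif(1, -0.2, 0.2), "k_off")
    a <- 10^runif(1, -2, 0)
    b <- 10^runif(1, -2, 0)
    f1 <- fold_change_under_force(a, a * 100, rel, 15, temp = 4.2797)
    f2 <- fold_change_under_force(b, b * 100, rel, 15, temp = 4.2797)
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("fit_bell inverts noiseless forward simulation", {
  f <- c(0, 10, 20, 30)
  k <- membrane_off_rate(1, 0.4, f)
  fit <- suppressWarnings(fit_bell(f, k))
  # two-point closed-form oracle
  kbt <- temp_context()$k_B_T
  xb_oracle <- kbt * (log(k[4]) - log(k[1])) / (f[4] - f[1])
  expect_equal(fit$x_beta, xb_oracle, tolerance = 1e-9)
  expect_equal(fit$k0_off, 1, tolerance = 1e-9)
  expect_equal(fit$x_beta, 0.4, tolerance = 1e-9)
  # nonlinear refit agrees on noiseless data
  fit_nls <- suppressWarnings(fit_bell(f, k, method = "nls"))
  expect_equal(coef(fit_nls), coef(fit), tolerance = 1e-6)
  # and the nonlinear route stays close under multiplicative noise
  set.seed(55)
  kn <- k * exp(rnorm(4, 0, 0.05))
  fit_n1 <- fit_bell(f, kn)
  fit_n2 <- fit_bell(f, kn, method = "nls")
  expect_identical(fit_n2$method, "nls")
  expect_equal(coef(fit_n2), coef(fit_n1), tolerance = 0.1)
  # constant rates: force-independent bond
  fit0 <- suppressWarnings(fit_bell(f, rep(2, 4)))
  expect_equal(fit0$x_beta, 0, tolerance = 1e-12)
})

test_that("fit_bell is unbiased under multiplicative noise", {
  f <- c(5, 15, 30, 45, 60, 80)
  truth <- membrane_off_rate(0.3, 0.3, f)
  set.seed(11)
  est <- t(replicate(200, {
    k <- truth * exp(rnorm(6, 0, 0.05))
    coef(fit_bell(f, k))
  }))
  # Monte-Carlo oracle: means within 2 MC standard errors of the truth
  for (j in 1:2) {
    truth_j <- c(0.3, 0.3)[j]
    expect_lt(abs(mean(est[, j]) - truth_j),
              2 * sd(est[, j]) / sqrt(nrow(est)) + 1e-12)
  }
})

test_that("fit_bell validates its inputs", {
  expect_error(fit_bell(c(0, 10), c(1, 2)), "3 distinct")
  expect_error(fit_bell(c(0, 10, 20), c(1, -1, 2)), "positive")
})

test_that("Bell-Evans force matches direct evaluation and its identities", {
  # log(1) = 0: force vanishes at the crossover speed
  expect_equal(bell_evans_force(1 * 1e-5 / (5 * 0.12), 1e-5, 5, 0.12), 0)
  expect_equal(bell_evans_force(0.005, 1e-5, 5, 0.12, k_B_T = 1),
               1.14075649493124, tolerance = 1e-9)
  # doubling the speed adds (kBT/x_beta) ln 2
  f1 <- bell_evans_force(0.002, 1e-5, 5, 0.12)
  f2 <- bell_evans_force(0.004, 1e-5, 5, 0.12)
  expect_equal(f2 - f1, log(2) / 5, tolerance = 1e-12)
  # below the crossover the force is clamped at zero with a warning
  expect_warning(f0 <- bell_evans_force(1e-9, 1e-5, 5, 0.12), "clamped")
  expect_identical(f0, 0)
})

test_that("fit_bell_evans inverts noiseless Bell-Evans data", {
  v <- c(0.0005, 0.001, 0.002, 0.005)
  fm <- bell_evans_force(v, 1e-5, 5, 0.12)
  fit <- fit_bell_evans(v, fm, kappa = 0.12)
  expect_equal(fit$x_beta, 5, tolerance = 1e-8)
  expect_equal(fit$k_off_tau, 1e-5, tolerance = 1e-8)
  # slope equals kBT/x_beta: two-point closed-form oracle
  slope_oracle <- (fm[4] - fm[1]) / (log(v[4]) - log(v[1]))
  expect_equal(1 / fit$x_beta, slope_oracle, tolerance = 1e-9)
})

test_that("fit_bell_evans flags non-identifiable (flat) data", {
  fit <- suppressWarnings(fit_bell_evans(c(0.001, 0.002, 0.004),
                                         rep(2, 3), kappa = 0.12))
  expect_false(fit$identifiable)
  expect_identical(fit$x_beta, Inf)
  expect_error(fit_bell_evans(rep(0.001, 3), c(1, 2, 3), kappa = 0.12),
               "distinct")
})

test_that("fit_bell_evans standard errors are calibrated", {
  v <- c(0.0005, 0.001, 0.002, 0.005)
  truth <- bell_evans_force(v, 1e-5, 5, 0.12)
  set.seed(21)
  covered <- replicate(100, {
    fm <- truth + rnorm(4, 0, 0.05 * truth)
    fit <- suppressWarnings(fit_bell_evans(v, fm, f_sem = 0.05 * truth,
                                           kappa = 0.12))
    abs(fit$x_beta - 5) < fit$se_x_beta
  })
  # nominal 68% coverage of the 1-SE interval, +/- 10 points
  expect_gt(mean(covered), 0.58)
  expect_lt(mean(covered), 0.78)
})

test_that("x_beta vs log10 abscissa regression recovers planted lines", {
  x <- 10^seq(-6, -3, length.out = 6)
  xb <- -0.05 * log10(x) + 0.2
  fit <- fit_xbeta_relation(x, xb, argument = "k_off")
  expect_equal(fit$slope, -0.05, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-9)
  # constant x_beta: zero slope
  fit0 <- fit_xbeta_relation(x, rep(0.3, 6), argument = "K_D")
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_error(fit_xbeta_relation(rep(1, 3), c(1, 2, 3)), "distinct")
})

test_that("a planted -0.043 slope is detected as negative in >= 95% of replicates", {
  koff <- 10^seq(-7, -4, length.out = 5)
  truth <- -0.043 * log10(koff) + 0.1
  set.seed(31)
  neg <- replicate(200, {
    fit_xbeta_relation(koff, truth + rnorm(5, 0, 0.03), argument = "k_off")$slope < 0
  })
  expect_gte(mean(neg), 0.95)
})

test_that("relation evaluation and printing are consistent", {
  rel <- xbeta_relation(-0.029, -0.11, "K_D")
  expect_equal(xbeta(rel, 1), -0.11)
  expect_equal(xbeta(rel, 100), -0.029 * 2 - 0.11)
  expect_error(xbeta(rel, -1), "positive")
})
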