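test_that("arrest detection recovers planted stops", {
  fps <- 50
  # constant-velocity track: no arrests
  x <- cumsum(rep(1, 200)) / fps  # 1 um/s... speed = 1 um/s per frame scale
  expect_identical(nrow(detect_arrests(x * 50, velocity_threshold = 10)), 0L)
  # one 50-frame stop
  x <- c(seq(0, 2, length.out = 100), rep(2, 50), seq(2, 4, length.out = 100))
  arr <- detect_arrests(x * 25, velocity_threshold = 5, fps = fps)
  expect_identical(nrow(arr), 1L)
  expect_equal(arr$duration_s, 1.0, tolerance = 0.03)
  # three planted stops with sub-threshold jitter
  set.seed(5)
  v <- 40 / fps  # 40 um/s
  seg <- function(n_move, n_stop) c(rep(v, n_move), rep(0, n_stop))
  steps <- c(seg(100, 15), seg(100, 60), seg(100, 200), rep(v, 100))
  x <- cumsum(steps) + rnorm(length(steps), 0, 0.02)
  arr <- detect_arrests(x, velocity_threshold = 10, fps = fps)
  expect_identical(nrow(arr), 3L)
  expect_equal(arr$duration_s, c(0.3, 1.2, 4.0), tolerance = 1 / fps + 1e-9)
  expect_equal(arr$bead_velocity[1], 40, tolerance = 0.15 * 40)
  # degenerate input
  expect_identical(nrow(detect_arrests(numeric(1), 5)), 0L)
})

test_that("binding linear density uses geometric statistics", {
  expect_equal(binding_linear_density(50, 250)$bld, 0.2)
  g <- binding_linear_density(c(10, 40), c(100, 100))
  expect_equal(g$geo_mean, 0.2)  # sqrt(0.1 * 0.4)
  expect_error(binding_linear_density(5, 0), "positive")
  # seeded lognormal replicates: geo-mean within 2 geo-SEM factors of truth
  set.seed(6)
  bld_true <- 0.3
  n <- stats::rpois(20, bld_true * 500)
  g <- binding_linear_density(n, rep(500, 20))
  expect_lt(g$geo_mean / g$geo_sem_factor^2, bld_true * 1.0001)
  expect_gt(g$geo_mean * g$geo_sem_factor^2, bld_true * 0.9999)
})

test_that("specificity filter drops bins indistinguishable from control", {
  # strong specific signal retained: geo-mean 3, modest spread
  sf <- specificity_filter(sample_bld = c(3.0, 3.1, 2.9, 3.0) * 0.1,
                           control_bld = rep(0.1, 4), bin = rep(1, 4))
  expect_true(sf$retained)
  # fold-change barely above 1 with wide error: excluded
  sf2 <- specificity_filter(sample_bld = c(0.4, 3.6, 0.5, 2.9) * 0.1,
                            control_bld = rep(0.1, 4), bin = rep(2, 4))
  expect_false(sf2$retained)
  # null data: most bins excluded
  set.seed(7)
  n_bin <- 20
  s <- rlnorm(4 * n_bin, 0, 0.4); ctl <- rlnorm(4 * n_bin, 0, 0.4)
  sf3 <- specificity_filter(s, ctl, rep(seq_len(n_bin), each = 4))
  expect_lt(mean(sf3$retained), 0.4)
  # missing control: bin dropped with warning
  expect_warning(
    sf4 <- specificity_filter(c(1, 1), c(NA, NA), c(1, 1)), "dropped")
  expect_null(sf4)
})

test_that("empirical survival is the P(duration >= t) step function", {
  sc <- empirical_survival(c(0.5, 1.5, 2.5, 3.5))
  expect_equal(sc$times, c(0.5, 1.5, 2.5, 3.5))
  expect_equal(sc$survival, c(1, 0.75, 0.5, 0.25))
  expect_equal(survival_at(sc, 0), 1)
  expect_equal(survival_at(sc, 1.0), 0.75)
  expect_equal(survival_at(sc, 10), 0)
  # all durations equal: single step from 1
  sc1 <- empirical_survival(rep(2, 5))
  expect_equal(sc1$survival, 1)
  expect_equal(survival_at(sc1, 2.1), 0)
  expect_error(empirical_survival(numeric(0)))
  # bounded, non-increasing (property over random draws)
  set.seed(8)
  for (i in 1:10) {
    sc <- empirical_survival(rexp(50, runif(1, 0.5, 3)))
    expect_true(all(diff(sc$survival) <= 0))
    expect_true(all(sc$survival >= 0 & sc$survival <= 1))
  }
})

test_that("empirical survival converges to the true survival (DKW)", {
  set.seed(9)
  d <- rexp(1e4, 2)
  sc <- empirical_survival(d)
  expect_lt(max(abs(sc$survival - exp(-2 * sc$times))), 0.02)
})

test_that("non-specific correction is count-weighted mixture subtraction", {
  set.seed(10)
  # sample = 80% rate-1 specific + 20% control-like rate-5
  n <- 2e4
  spec <- rexp(0.8 * n, 1); ns <- rexp(0.2 * n, 5)
  samp <- empirical_survival(c(spec, ns))
  ctl <- empirical_survival(rexp(1e4, 5))
  corr <- correct_nonspecific(samp, ctl, w_sample = n, w_control = 0.2 * n)
  keep <- corr$times <= 3
  expect_lt(max(abs(corr$survival[keep] - exp(-corr$times[keep]))), 0.03)
  expect_true(corr$corrected)
  # zero-weight control leaves the sample curve untouched
  same <- correct_nonspecific(samp, ctl, w_sample = n, w_control = 0)
  expect_equal(same$survival, samp$survival)
  # fully non-specific bin is refused
  expect_error(correct_nonspecific(samp, ctl, w_sample = 1, w_control = 2),
               "refused")
  # unweighted mode subtracts pointwise and clips
  un <- correct_nonspecific(samp, ctl, mode = "unweighted")
  expect_true(all(un$survival >= 0 & un$survival <= 1))
})

test_that("minimum-events QC uses the half-open (1, 2] interval", {
  curve_with <- function(d) empirical_survival(d)
  d14 <- c(seq(1.1, 1.9, length.out = 14), 0.2, 3)
  expect_false(qc_min_events(curve_with(d14)))
  d15 <- c(seq(1.1, 1.9, length.out = 15), 0.2, 3)
  expect_true(qc_min_events(curve_with(d15)))
  # exactly 1.0 s does not count; exactly 2.0 s counts
  d_edge <- c(rep(1.0, 14), 2.0, seq(1.1, 1.9, length.out = 14))
  expect_true(qc_min_events(curve_with(d_edge)))
  d_edge2 <- c(rep(1.0, 20), seq(1.1, 1.9, length.out = 14))
  expect_false(qc_min_events(curve_with(d_edge2)))
})

test_that("off-rate from the survival fraction at a fixed time", {
  # s(1) = 0.5 -> ln 2
  sc <- empirical_survival(c(rep(0.5, 5), rep(1.0, 5)))
  expect_equal(off_rate_at_time(sc, 1)$value, 0.693147180559945,
               tolerance = 1e-9)
  # s(2) = 0.1 -> -ln(0.1)/2
  sc2 <- empirical_survival(c(rep(0.5, 9), 2.0))
  expect_equal(off_rate_at_time(sc2, 2)$value, 1.15129254649702,
               tolerance = 1e-9)
  # no event at exactly 1 s: the next event's survival is used, t stays 1
  sc3 <- empirical_survival(c(rep(0.3, 6), rep(1.04, 4)))
  est <- off_rate_at_time(sc3, 1)
  expect_equal(est$t_used, 1.04)
  expect_equal(est$value, 0.916290731874155, tolerance = 1e-9)
  # all beads detached before t: undefined
  expect_error(off_rate_at_time(empirical_survival(c(0.1, 0.2)), 1),
               "no event")
})

test_that("exponential-plateau fit recovers its parameters", {
  t <- seq(0.05, 5, length.out = 50)
  s <- 0.8 * exp(-0.8 * t) + 0.2
  curve <- structure(list(times = t, survival = s, n_events = 50,
                          durations = t, corrected = TRUE),
                     class = "survival_curve")
  est <- fit_exponential_plateau(curve)
  expect_equal(est$value, 0.8, tolerance = 1e-6)
  expect_equal(est$amplitude, 1.0, tolerance = 1e-6)
  expect_equal(est$plateau, 0.2, tolerance = 1e-6)
  expect_false(est$flagged)
  # pure exponential agrees with a log-linear regression oracle
  s2 <- exp(-1.3 * t)
  curve2 <- structure(list(times = t, survival = s2, n_events = 50,
                           durations = t, corrected = TRUE),
                      class = "survival_curve")
  est2 <- fit_exponential_plateau(curve2)
  k_oracle <- -coef(lm(log(s2) ~ t))[[2]]
  expect_equal(est2$value, k_oracle, tolerance = 1e-6)
  # flat curve: boundary rate, flagged
  curve3 <- structure(list(times = t, survival = rep(1, 50), n_events = 50,
                           durations = t, corrected = FALSE),
                      class = "survival_curve")
  est3 <- fit_exponential_plateau(curve3)
  expect_true(est3$flagged || est3$value < 1e-4)
  expect_error(fit_exponential_plateau(empirical_survival(c(1, 2))), "5 distinct")
})

test_that("the three off-rate estimators agree with the exponential MLE", {
  set.seed(12)
  k_true <- 1.5
  d <- rexp(2000, k_true)
  sc <- empirical_survival(d)
  mle <- 1 / mean(d)
  se_mle <- mle / sqrt(length(d))
  e1 <- off_rate_at_time(sc, 1)
  e2 <- off_rate_at_time(sc, 2)
  e3 <- fit_exponential_plateau(sc)
  expect_lt(abs(e1$value - mle), 3 * sqrt(e1$se^2 + se_mle^2))
  expect_lt(abs(e2$value - mle), 3 * sqrt(e2$se^2 + se_mle^2))
  expect_lt(abs(e3$value - mle), 3 * sqrt(e3$se^2 + se_mle^2))
})
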