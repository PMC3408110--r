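null_coefs <- list(delta_x = c(0, 0), delta_y = c(0, 0), delta_r = c(0, 0))

test_that("continuous fit is deterministic and invariant to z location/scale", {
  d <- sample_continuous_scenario(120, null_coefs, seed = 4)
  f1 <- fit_continuous(d)
  f2 <- fit_continuous(d)
  expect_lt(max(abs(f1$coef - f2$coef)), 1e-10)

  # centering z shifts intercepts only
  dc <- d; dc$z <- dc$z - mean(dc$z)
  fc <- fit_continuous(dc)
  slopes <- function(f) unname(f$coef[c(6, 8, 10)])
  expect_lt(max(abs(slopes(fc) - slopes(f1))), 1e-6)
  expect_lt(abs(theta1_test(fc)$statistic - theta1_test(f1)$statistic), 1e-6)
  expect_lt(abs(deltar1_test(fc)$statistic - deltar1_test(f1)$statistic), 1e-6)

  # rescaling z divides slopes by the factor, Wald statistics unchanged
  ds <- d; ds$z <- ds$z * 2.5
  fs <- fit_continuous(ds)
  expect_lt(max(abs(slopes(fs) - slopes(f1) / 2.5)), 1e-6)
  expect_lt(abs(theta1_test(fs)$statistic - theta1_test(f1)$statistic), 1e-6)
  expect_lt(abs(deltar1_test(fs)$statistic - deltar1_test(f1)$statistic), 1e-6)
})

test_that("null coefficients are recovered within Wald bands at N = 280", {
  reps <- 150
  ok <- logical(reps)
  for (i in seq_len(reps)) {
    d <- sample_continuous_scenario(280, null_coefs, seed = 4000 + i)
    f <- fit_continuous(d)
    est <- f$coef[c(6, 8, 10)]
    se <- sqrt(diag(f$vcov)[c(6, 8, 10)])
    ok[i] <- all(abs(est) < 3 * se)
  }
  expect_gte(mean(ok), 0.95)
})

test_that("moderated correlation is recovered on the link scale", {
  cf <- list(delta_x = c(0, 0), delta_y = c(0, 0), delta_r = c(0, 1.0986))
  d <- sample_continuous_scenario(20000, cf, seed = 17)
  f <- fit_continuous(d)
  rho_at_1 <- fisher_inverse(f$params$delta_r[1] + f$params$delta_r[2])
  expect_within(rho_at_1, 0.5, 0.02)
})

test_that("theta_1 recovery and antisymmetry under x/y swap", {
  cf <- list(delta_x = c(0, 0), delta_y = c(0, 0.6931), delta_r = c(0, 0))
  cover <- logical(60)
  for (i in seq_along(cover)) {
    d <- sample_continuous_scenario(280, cf, seed = 6000 + i)
    tt <- theta1_test(fit_continuous(d))
    cover[i] <- abs(tt$estimate - 0.6931) < 3 * tt$se
  }
  expect_gte(mean(cover), 0.9)

  d <- sample_continuous_scenario(280, cf, seed = 6001)
  swapped <- data.frame(x = d$y, y = d$x, z = d$z)
  t_fwd <- theta1_test(fit_continuous(d))
  t_swp <- theta1_test(fit_continuous(swapped))
  expect_equal(t_swp$estimate, -t_fwd$estimate, tolerance = 1e-6)
})

test_that("deltar1 estimate reproduces link arithmetic on population values", {
  # difference of link values between z = 1 and z = 0 is delta_r1 itself
  expect_equal(fisher_link(0.7) - fisher_link(0), 1.7346, tolerance = 1e-4)
  cf <- list(delta_x = c(0, 0), delta_y = c(0, 0), delta_r = c(0, 1.7346))
  d <- sample_continuous_scenario(5000, cf, seed = 23)
  f <- fit_continuous(d)
  rt <- deltar1_test(f)
  expect_within(rt$estimate, 1.7346, 4 * rt$se)
  expect_lt(rt$p_value, 1e-10)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(x = rnorm(30), y = rnorm(30), z = 1)
  expect_error(fit_continuous(d), "zero variance")
  d2 <- data.frame(x = rnorm(10), y = rnorm(10), z = rnorm(10))
  expect_error(fit_continuous(d2), "at least 20")
  d3 <- sample_continuous_scenario(50, null_coefs, seed = 1)
  f3 <- fit_continuous(d3, vcov = FALSE)
  expect_error(theta1_test(f3), "covariance")
})
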