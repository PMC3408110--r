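test_that("bivariate normal sampler: determinism, boundary guard, moments", {
  a <- sample_bivariate_normal(500, 2, 2, 1, seed = 5)
  b <- sample_bivariate_normal(500, 2, 2, 1, seed = 5)
  expect_identical(a, b)
  expect_error(
    sample_bivariate_normal(10, 1, 4, sqrt(4) * (1 - 1e-12)), "singular")

  d <- sample_bivariate_normal(100000, 2, 2, 1, seed = 6)
  r <- cor(d$x, d$y)
  expect_within(r, 0.5, 3 * (1 - 0.25) / sqrt(100000))
})

test_that("skew-normal sampler: normal reduction, margins, determinism", {
  s0 <- sample_bivariate_skew_normal(100000, lambda = 0, rho = 0.5,
                                     sd_x = sqrt(2), sd_y = sqrt(2), seed = 7)
  expect_within(sd(s0$x), sqrt(2), 0.02)
  expect_within(cor(s0$x, s0$y), 0.5, 0.01)

  s4 <- sample_bivariate_skew_normal(100000, lambda = 4, rho = 1 / sqrt(2),
                                     seed = 8)
  delta <- 4 / sqrt(17)
  mu <- delta * sqrt(2 / pi)
  g1 <- (4 - pi) / 2 * mu^3 / (1 - mu^2)^1.5  # closed-form SN skewness
  emp_skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_within(emp_skew(s4$x) / g1, 1, 0.1)
  expect_within(emp_skew(s4$y) / g1, 1, 0.1)
  expect_within(cor(s4$x, s4$y), 1 / sqrt(2), 0.01)

  a <- sample_bivariate_skew_normal(50, 2, 0.3, seed = 9)
  b <- sample_bivariate_skew_normal(50, 2, 0.3, seed = 9)
  expect_identical(a, b)

  # unreachable target correlation under the shared-latent construction
  expect_error(sample_bivariate_skew_normal(10, 4, 0.2), "not reachable")
})

test_that("skew margins match the skew-normal density (KS-style)", {
  s <- sample_bivariate_skew_normal(20000, lambda = 2, rho = 0.3, seed = 10)
  sn <- evrtest:::sn_moments(2)
  raw <- s$x * sn$sd + sn$mean  # undo the standardization
  cdf <- function(q) vapply(q, function(qi)
    integrate(skew_normal_pdf, -10, qi, lambda = 2)$value, numeric(1))
  qs <- quantile(raw, c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_lt(max(abs(cdf(qs) - c(0.1, 0.25, 0.5, 0.75, 0.9))), 0.015)
})

test_that("published-table scenarios reproduce the printed derived headers", {
  # table 1: constant variance ratio 2, rho = 1/sqrt(2), beta_y = 1
  for (cond in 1:3) {
    sc <- build_scenario(1, cond)
    expect_equal(sc$groups$var_y / sc$groups$var_x, c(2, 2))
    expect_equal(sc$groups$rho, rep(1 / sqrt(2), 2), tolerance = 1e-12)
    expect_equal(sc$groups$beta_y, c(1, 1), tolerance = 1e-12)
  }
  # table 2: rho = 0.5 everywhere; printed beta and error variances
  beta2 <- list(c(0.5, sqrt(3 / 8)), c(0.5, sqrt(2) / 2), c(0.5, 1))
  se2 <- list(c(1.5, 2.25), c(1.5, 3), c(1.5, 6))
  for (cond in 1:3) {
    sc <- build_scenario(2, cond)
    expect_equal(sc$groups$rho, c(0.5, 0.5), tolerance = 1e-9)
    expect_equal(sc$groups$beta_y, beta2[[cond]], tolerance = 1e-9)
    expect_equal(sc$groups$sigma_e2, se2[[cond]], tolerance = 1e-9)
  }
  # table 3: beta_y = 0.5 everywhere; printed correlations
  rho3 <- c(1 / sqrt(6), 1 / sqrt(8), 0.25)
  for (cond in 1:3) {
    sc <- build_scenario(3, cond)
    expect_equal(sc$groups$beta_y, c(0.5, 0.5), tolerance = 1e-9)
    expect_equal(sc$groups$rho[2], rho3[cond], tolerance = 1e-9)
  }
  # tables 4 and 5: slopes/correlations as printed
  expect_equal(build_scenario(4, 3)$groups$beta_y, c(0.5, 1), tolerance = 1e-9)
  expect_equal(build_scenario(4, 3)$groups$rho, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(build_scenario(5, 4)$groups$rho, c(0.5, 0.17), tolerance = 1e-9)
  expect_equal(build_scenario(5, 4)$groups$beta_y, c(0.5, 0.5),
               tolerance = 1e-9)
  # polarization experiment population
  sem <- sem_example_scenario()
  expect_equal(sem$groups$rho, c(0.45, 0.45))
  expect_equal(sqrt(sem$groups$var_y), c(2, 1))
  expect_error(build_scenario(9, 1), "unknown table")
})

test_that("continuous scenario sampler matches its conditional model", {
  cf <- list(delta_x = c(0, 0), delta_y = c(0, 0), delta_r = c(0, 1.0986))
  d <- sample_continuous_scenario(200000, cf, seed = 11)
  win <- abs(d$z - 1) < 0.1
  expect_within(cor(d$x[win], d$y[win]), 0.5, 0.03)

  # all slopes zero: constant moments, bivariate normal margins
  d0 <- sample_continuous_scenario(50000, list(
    delta_x = c(log(2), 0), delta_y = c(0, 0), delta_r = c(0.5, 0)),
    seed = 12)
  expect_within(sd(d0$x), 2, 0.03)
  expect_within(cor(d0$x, d0$y), fisher_inverse(0.5), 0.01)

  a <- sample_continuous_scenario(40, cf, seed = 3)
  b <- sample_continuous_scenario(40, cf, seed = 3)
  expect_identical(a, b)
})
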