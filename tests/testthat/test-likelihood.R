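test_that("log-likelihood closed forms: single point, independence", {
  # one observation at its own mean with unit SDs and rho = 0
  d <- data.frame(x = 1.7, y = -0.3, z = 0)
  spec <- evr_model_spec(d$z, "continuous")
  p <- list(gamma_x = c(1.7, 0), gamma_y = c(-0.3, 0),
            delta_x = c(0, 0), delta_y = c(0, 0), delta_r = c(0, 0))
  expect_equal(bvn_loglik(p, spec, d), -log(2 * pi))

  # rho = 0 factorizes into two univariate normal log-likelihoods
  set.seed(7)
  d2 <- data.frame(x = rnorm(40, 1, 2), y = rnorm(40, -1, 0.5), z = rnorm(40))
  spec2 <- evr_model_spec(d2$z, "continuous")
  p2 <- list(gamma_x = c(0.8, 0.1), gamma_y = c(-1, 0),
             delta_x = c(log(2), 0), delta_y = c(log(0.5), 0),
             delta_r = c(0, 0))
  ll <- bvn_loglik(p2, spec2, d2)
  ll_uni <- sum(dnorm(d2$x, 0.8 + 0.1 * d2$z, 2, log = TRUE)) +
    sum(dnorm(d2$y, -1, 0.5, log = TRUE))
  expect_equal(ll, ll_uni, tolerance = 1e-10)
})

test_that("analytic gradient matches central differences", {
  d <- sample_continuous_scenario(
    60, coefs = list(delta_x = c(0.1, 0.3), delta_y = c(0.2, -0.2),
                     delta_r = c(0.3, 0.5)), seed = 2)
  spec <- evr_model_spec(d$z, "continuous")
  par <- c(0.1, -0.2, 0.05, 0.1, 0.2, 0.1, -0.1, 0.2, 0.4, 0.3)
  fn <- evrtest:::nll_fn(spec, d)
  gr <- evrtest:::nll_gr(spec, d)
  num <- vapply(seq_along(par), function(j) {
    h <- 1e-6
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    (fn(up) - fn(dn)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - gr(par))), 1e-6)
})

test_that("saturated closed form agrees with the row-wise likelihood and its
           numerical optimum", {
  dd <- draw_groups(build_scenario(2, 2, n = c(60, 80)), seed = 3)
  mom <- group_moments(dd)
  fit <- fit_saturated(mom)
  spec <- evr_model_spec(dd$z, "categorical")
  expect_equal(fit$loglik, bvn_loglik(unlist(fit$params), spec, dd),
               tolerance = 1e-10)

  # optimizer oracle: maximize numerically from a perturbed start
  start <- unlist(fit$params) * 1.15 + 0.05
  opt <- optim(start, evrtest:::nll_fn(spec, dd), evrtest:::nll_gr(spec, dd),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_within(-opt$value, fit$loglik, 1e-6)
})

test_that("observed-information covariance matches asymptotic oracles", {
  sc <- scenario_categorical(c(10000, 10000), var_x = c(1, 1),
                             var_y = c(1, 1), cov_xy = c(0, 0))
  dd <- draw_groups(sc, seed = 9)
  fit <- fit_saturated(dd)
  n <- 10000
  # classical variance of a log-SD is 1/(2n)
  expect_within(fit$vcov["delta_x.(base)", "delta_x.(base)"] / (1 / (2 * n)),
                1, 0.1)
  # rho = 0: log-SD estimates of x and y are asymptotically uncorrelated
  expect_lt(abs(fit$vcov["delta_x.(base)", "delta_y.(base)"]), 1 / n)

  sc2 <- scenario_categorical(c(10000, 10000), var_x = c(1, 1),
                              var_y = c(1, 1), cov_xy = c(0.6, 0.6))
  dd2 <- draw_groups(sc2, seed = 10)
  fit2 <- fit_saturated(dd2)
  r2 <- fit2$moments$r[1]
  expect_within(fit2$vcov["delta_x.(base)", "delta_y.(base)"] /
                  (r2^2 / (2 * n)), 1, 0.1)
})

test_that("analytic saturated covariance equals the numeric Hessian inverse", {
  dd <- draw_groups(build_scenario(3, 2, n = c(70, 90)), seed = 5)
  fit <- fit_saturated(dd)
  spec <- evr_model_spec(dd$z, "categorical")
  V_num <- coefficient_covariance(unlist(fit$params), spec, dd)
  expect_lt(max(abs(V_num - fit$vcov) / (abs(fit$vcov) + 1e-8)), 1e-3)
})

test_that("delta-method SE oracle: var(theta) = sum of (1 - r^2)/n", {
  sc <- build_scenario(2, 2, n = c(1000, 1000))
  dd <- draw_groups(sc, seed = 21)
  mom <- group_moments(dd)
  tt <- evr_test(mom)
  oracle <- sqrt((1 - mom$r[1]^2) / 1000 + (1 - mom$r[2]^2) / 1000)
  expect_equal(tt$se, oracle, tolerance = 1e-12)
  # and the same SE falls out of the numeric observed information
  fit <- fit_saturated(mom)
  i <- c("delta_x.2", "delta_y.2")
  se_v <- sqrt(fit$vcov["delta_y.2", "delta_y.2"] +
                 fit$vcov["delta_x.2", "delta_x.2"] -
                 2 * fit$vcov["delta_y.2", "delta_x.2"])
  expect_equal(tt$se, se_v, tolerance = 1e-10)
})

test_that("singular designs are reported as errors", {
  d <- sample_continuous_scenario(
    50, coefs = list(delta_x = c(0, 0), delta_y = c(0, 0),
                     delta_r = c(0, 0)), seed = 1)
  spec <- evr_model_spec(d$z, "continuous")
  spec$Zx <- cbind(spec$Zx, spec$Zx[, 2])  # duplicated column
  p <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_error(coefficient_covariance(p, spec, d), "singular|collinear")
})
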