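test_that("saturated fit recovers per-group moments in indicator coding", {
  m_same <- make_moments(sd_x = c(1.3, 1.3), sd_y = c(0.7, 0.7),
                         r = c(0.4, 0.4))
  fit <- fit_saturated(m_same)
  expect_equal(fit$params$delta_x[2], 0)
  expect_equal(fit$params$delta_y[2], 0)
  expect_equal(fit$params$delta_r[2], 0)

  m_dbl <- make_moments(sd_x = c(1, 1), sd_y = c(1, 2), r = c(0.2, 0.2))
  fit2 <- fit_saturated(m_dbl)
  expect_equal(fit2$params$delta_y[2], log(2))
  expect_equal(fit2$params$delta_x[2], 0)
  expect_error(fit_saturated(m_dbl[1, ]), "2 groups")
})

test_that("evr_test: identity, link arithmetic, errors", {
  m <- make_moments(sd_x = c(1.1, 1.1), sd_y = c(0.9, 0.9), r = c(0.5, 0.5))
  tt <- evr_test(m)
  expect_equal(tt$theta_hat, 0)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  m2 <- make_moments(sd_x = c(1, 1), sd_y = c(1, 2), r = c(0.3, 0.3))
  t2 <- evr_test(m2)
  expect_within(t2$theta_hat, log(2), 1e-12)  # variance ratio 4 <-> 0.6931
  expect_equal(t2$exp_ci_lo, exp(t2$ci_lo))
  expect_equal(t2$exp_ci_hi, exp(t2$ci_hi))
  expect_error(evr_test(m2, base = "1", target = "1"), "differ")
  expect_error(evr_test(m2, base = "zz"), "group labels")
})

test_that("exp(theta) equals the slope-ratio over correlation-ratio exactly", {
  for (seed in 1:5) {
    dd <- draw_groups(build_scenario(3, 3, n = c(50, 60)), seed = seed)
    mom <- group_moments(dd)
    tt <- evr_test(mom)
    beta <- slope_from_correlation(mom$r, mom$sd_y, mom$sd_x)
    oracle <- (beta[2] / beta[1]) / (mom$r[2] / mom$r[1])
    expect_equal(tt$exp_theta, oracle, tolerance = 1e-12)
  }
})

test_that("theta is antisymmetric and scale-equivariant", {
  dd <- draw_groups(build_scenario(2, 1, n = c(40, 55)), seed = 8)
  mom <- group_moments(dd)
  tt <- evr_test(mom, base = "1", target = "2")
  rev <- evr_test(mom, base = "2", target = "1")
  expect_equal(rev$theta_hat, -tt$theta_hat)
  expect_equal(rev$exp_ci_lo, 1 / tt$exp_ci_hi, tolerance = 1e-12)
  expect_equal(rev$exp_ci_hi, 1 / tt$exp_ci_lo, tolerance = 1e-12)

  # multiplying y in the target group by c shifts theta by log(c)
  d2 <- dd
  d2$y[d2$z == "2"] <- d2$y[d2$z == "2"] * 3
  t2 <- evr_test(group_moments(d2))
  expect_equal(t2$theta_hat, tt$theta_hat + log(3), tolerance = 1e-12)
  expect_equal(t2$se, tt$se)

  # shared rescaling of all x and y leaves theta untouched
  d3 <- dd
  d3$x <- d3$x * 0.2; d3$y <- d3$y * 7
  t3 <- evr_test(group_moments(d3))
  expect_equal(t3$theta_hat, tt$theta_hat, tolerance = 1e-12)
})

test_that("constrained fits: inactive constraints and parameter recovery", {
  # identical x moments in both groups: hov_x costs nothing
  set.seed(31)
  x <- rnorm(80)
  d <- data.frame(x = c(x, x), y = c(rnorm(80, 0, 1), rnorm(80, 0, 2)),
                  z = rep(c("a", "b"), each = 80))
  mom <- group_moments(d)
  sat <- fit_saturated(mom)
  hx <- fit_constrained(mom, "hov_x")
  expect_within(hx$loglik, sat$loglik, 1e-6)

  # evr constraint on data generated under a common variance ratio
  sc <- build_scenario(1, 2, n = c(5000, 5000))
  dd <- draw_groups(sc, seed = 12)
  mm <- group_moments(dd)
  fe <- fit_constrained(mm, "evr")
  ratio_true <- 0.5 * log(2)  # common log sd-ratio sqrt(2)
  common_d <- fe$params$b[1] - fe$params$a[1]
  expect_within(common_d, ratio_true, 3 * sqrt((1 - 0.5) / 10000))
  expect_equal(fe$params$b[2] - fe$params$a[2], common_d, tolerance = 1e-8)

  # equal_rho recovery on the polarization population (rho = 0.45 both)
  dd2 <- draw_groups(sem_example_scenario(5000), seed = 13)
  fr <- fit_constrained(group_moments(dd2), "equal_rho")
  expect_within(fr$params$rho[1], 0.45, 3 * (1 - 0.45^2) / sqrt(10000))
  expect_lt(fr$loglik, fit_saturated(group_moments(dd2))$loglik + 1e-9)
})

test_that("constraint combinations are validated", {
  m <- make_moments()
  expect_error(fit_constrained(m, c("equal_rho", "equal_slope")), "jointly")
  expect_error(fit_constrained(m, "not_a_constraint"), "unknown")
  # hov_x + hov_y + equal_rho + evr is satisfiable and nests everything
  f <- fit_constrained(m, c("hov_x", "hov_y", "evr", "equal_rho"))
  expect_true(f$converged)
})

test_that("profile likelihoods agree with the general constrained fits", {
  dd <- draw_groups(build_scenario(3, 2, n = c(90, 110)), seed = 11)
  mom <- group_moments(dd)
  st <- evrtest:::moments_stats(mom)
  expect_equal(evrtest:::profile_ll_equal_rho(st)$loglik,
               fit_constrained(mom, "equal_rho")$loglik, tolerance = 1e-7)
  expect_equal(evrtest:::profile_ll_equal_slope(st)$loglik,
               fit_constrained(mom, "equal_slope")$loglik, tolerance = 1e-7)
})

test_that("likelihood-ratio comparisons: nesting, df counting, Wald-LR
           agreement", {
  dd <- draw_groups(build_scenario(2, 2, n = c(10000, 10000)), seed = 14)
  mom <- group_moments(dd)
  sat <- fit_saturated(mom)
  fe <- fit_constrained(mom, "evr")
  lr <- lr_compare(fe, sat)
  expect_equal(lr$df, 1)
  wald <- evr_test(mom)$statistic^2
  expect_lt(abs(lr$chi2 - wald) / lr$chi2, 0.05)

  expect_error(lr_compare(sat, fe), "nest")
  same <- lr_compare(sat, sat)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  # three groups: evr adds one constraint per non-base group
  m3 <- make_moments(n = c(50, 60, 70), sd_x = c(1, 1, 1),
                     sd_y = c(1, 1.2, 1.5), r = c(0.3, 0.3, 0.3))
  lr3 <- lr_compare(fit_constrained(m3, "evr"), fit_saturated(m3))
  expect_equal(lr3$df, 2)
})

test_that("moderation report reproduces the polarization-experiment pattern", {
  # population: rho = 0.45 in both conditions, sd_y doubles; slopes are
  # moderated (in opposite directions by regression direction), but the
  # correlations are not
  reps <- 120
  evr_reject <- rho_retain <- sign_flip <- logical(reps)
  for (i in seq_len(reps)) {
    dd <- draw_groups(sem_example_scenario(300), seed = 1000 + i)
    rep <- moderation_report(dd)
    lr <- rep$lr_ladder
    evr_reject[i] <- lr$p_value[lr$step == "evr vs baseline"] < 0.001
    rho_retain[i] <- lr$p_value[lr$step == "equal_rho vs baseline"] > 0.05
    s <- rep$slopes
    sign_flip[i] <- (s$beta_y_on_x[1] - s$beta_y_on_x[2]) *
      (s$beta_x_on_y[1] - s$beta_x_on_y[2]) < 0
  }
  expect_gte(mean(evr_reject & rho_retain), 0.95)
  expect_gte(mean(sign_flip), 0.95)
})

test_that("joint Wald extension collapses to the pairwise test for k = 2", {
  m <- make_moments(sd_x = c(1, 1), sd_y = c(1, 1.4), r = c(0.3, 0.5))
  tw <- evrtest:::theta_joint_wald(m, base = "1")
  tt <- evr_test(m)
  expect_equal(tw$chi2, tt$statistic^2, tolerance = 1e-12)
  expect_equal(tw$df, 1)
})
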