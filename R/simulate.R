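# Monte-Carlo harness. Replicate r of a run uses substream seed
# `seed + r - 1`, so any single replicate is reproducible in isolation and
# aggregates are independent of execution order. Sweep cells get substream
# bases `seed + 100000 * (cell - 1)`.

fast_moments <- function(xg, yg) {
  n <- length(xg)
  dx <- xg - mean(xg); dy <- yg - mean(yg)
  S20 <- mean(dx^2); S02 <- mean(dy^2); S11 <- mean(dx * dy)
  list(n = n, S20 = S20, S02 = S02, S11 = S11, r = S11 / sqrt(S20 * S02))
}

# closed-form saturated log-likelihood from stacked fast moments
ll_sat_stats <- function(st) {
  -sum(st$n * (log(2 * pi) + 1 + 0.5 * log(st$S20 * st$S02) +
                 0.5 * log(1 - st$r^2)))
}

sim_tests_categorical <- c("theta", "delta_r", "lr_equal_slope",
                           "lr_equal_rho")

#' Run a Monte-Carlo simulation for one scenario
#'
#' Draws `reps` datasets from the scenario population and applies the
#' requested tests at level `alpha`, reporting rejection rates with their
#' Monte-Carlo standard errors. Available tests: for categorical scenarios
#' `"theta"` (Wald test of equal variance ratios), `"delta_r"` (Wald test
#' of equal Fisher-linked correlations), `"lr_equal_slope"` and
#' `"lr_equal_rho"` (likelihood-ratio comparisons of the constrained fit
#' against the saturated one, df = 1 for two groups); for continuous
#' scenarios `"theta"` and `"delta_r"` (Wald tests of `theta_1` and
#' `delta_r1`), for which the mean bias of both estimators is also
#' recorded. Non-converged replicates are counted and excluded from the
#' rates; the run fails if they reach 5 percent.
#'
#' @param scenario An `evr_scenario`.
#' @param reps Number of replicates (>= 1; published runs use 20,000).
#' @param tests Character subset of the tests above; default `"theta"`.
#' @param alpha Test size.
#' @param seed Integer master seed; replicate r uses `seed + r - 1`.
#' @param config Optional [evr_config()] overriding `alpha`.
#' @return An object of class `evr_sim`: rejection rates, Monte-Carlo SEs,
#'   bias (continuous scenarios), failure count, and the resolved
#'   configuration.
#' @examples
#' run_simulation(build_scenario(1, 1), reps = 200, seed = 1)
#' @export
run_simulation <- function(scenario, reps, tests = "theta", alpha = 0.05,
                           seed = 1, config = NULL) {
  stopifnot(inherits(scenario, "evr_scenario"))
  if (!is.numeric(reps) || reps < 1) abort("`reps` must be a positive count.")
  reps <- as.integer(reps)
  config <- config %||% evr_config(alpha = alpha)
  ok_tests <- if (scenario$kind == "categorical") sim_tests_categorical else
    c("theta", "delta_r")
  bad <- setdiff(tests, ok_tests)
  if (length(bad)) abort(paste0("unsupported test(s) for this scenario kind: ",
                                paste(bad, collapse = ", ")))

  if (scenario$kind == "categorical") {
    res <- sim_categorical(scenario, reps, tests, config, seed)
  } else {
    res <- sim_continuous(scenario, reps, tests, config, seed)
  }
  fail_rate <- res$failures / reps
  if (fail_rate >= 0.05) {
    abort(sprintf("%.1f%% of replicates failed to converge.", 100 * fail_rate))
  }
  used <- reps - res$failures
  structure(list(scenario = scenario, reps = reps, used = used,
                 alpha = config$alpha, seed = seed, tests = tests,
                 rejection_rates = res$rates,
                 mc_se = mc_se(res$rates, used),
                 bias = res$bias, failures = res$failures),
            class = "evr_sim")
}

sim_categorical <- function(scenario, reps, tests, config, seed) {
  g <- scenario$groups
  stopifnot(nrow(g) == 2)
  rej <- setNames(numeric(length(tests)), tests)
  failures <- 0L
  zcrit <- crit_q(config, g$n[1], g$n[2])
  chicrit <- stats::qchisq(1 - config$alpha, df = 1)
  need_lr <- intersect(tests, c("lr_equal_slope", "lr_equal_rho"))
  for (i in seq_len(reps)) {
    set.seed(seed + i - 1L)
    ms <- vector("list", 2)
    for (j in 1:2) {
      d <- if (scenario$lambda == 0) {
        gen_bvn(g$n[j], g$var_x[j], g$var_y[j], g$cov_xy[j])
      } else {
        gen_bsn(g$n[j], scenario$lambda, g$rho[j],
                sd_x = sqrt(g$var_x[j]), sd_y = sqrt(g$var_y[j]))
      }
      ms[[j]] <- fast_moments(d$x, d$y)
    }
    m1 <- ms[[1]]; m2 <- ms[[2]]
    rep_ok <- TRUE
    this <- setNames(logical(length(tests)), tests)
    if ("theta" %in% tests) {
      th <- 0.5 * (log(m2$S02 / m2$S20) - log(m1$S02 / m1$S20))
      se <- sqrt((1 - m1$r^2) / m1$n + (1 - m2$r^2) / m2$n)
      this[["theta"]] <- abs(th / se) > zcrit
    }
    if ("delta_r" %in% tests) {
      dr <- fisher_link(m2$r) - fisher_link(m1$r)
      se <- sqrt(4 / m1$n + 4 / m2$n)
      this[["delta_r"]] <- abs(dr / se) > zcrit
    }
    if (length(need_lr)) {
      st <- list(n = c(m1$n, m2$n), S20 = c(m1$S20, m2$S20),
                 S02 = c(m1$S02, m2$S02), S11 = c(m1$S11, m2$S11),
                 r = c(m1$r, m2$r))
      ll_sat <- ll_sat_stats(st)
      for (tn in need_lr) {
        fit <- if (tn == "lr_equal_slope") profile_ll_equal_slope(st) else
          profile_ll_equal_rho(st)
        if (!fit$converged) { rep_ok <- FALSE; break }
        chi2 <- max(0, 2 * (ll_sat - fit$loglik))
        this[[tn]] <- chi2 > chicrit
      }
    }
    if (rep_ok) rej <- rej + this else failures <- failures + 1L
  }
  list(rates = rej / (reps - failures), failures = failures, bias = NULL)
}

sim_continuous <- function(scenario, reps, tests, config, seed) {
  rej <- setNames(numeric(length(tests)), tests)
  failures <- 0L
  sum_th1 <- 0; sum_dr1 <- 0
  zcrit <- qnorm(1 - config$alpha / 2)
  for (i in seq_len(reps)) {
    set.seed(seed + i - 1L)
    d <- gen_cont(scenario$N, scenario$coefs, lambda = scenario$lambda)
    fit <- tryCatch(fit_cont_impl(d$x, d$y, d$z, vcov = TRUE),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || is.null(fit$vcov)) {
      failures <- failures + 1L
      next
    }
    ct <- cont_contrasts(fit$par, fit$vcov)
    if ("theta" %in% tests) {
      rej[["theta"]] <- rej[["theta"]] +
        (abs(ct$theta_1[["est"]] / ct$theta_1[["se"]]) > zcrit)
      sum_th1 <- sum_th1 + ct$theta_1[["est"]]
    }
    if ("delta_r" %in% tests) {
      rej[["delta_r"]] <- rej[["delta_r"]] +
        (abs(ct$delta_r1[["est"]] / ct$delta_r1[["se"]]) > zcrit)
      sum_dr1 <- sum_dr1 + ct$delta_r1[["est"]]
    }
  }
  used <- reps - failures
  truth_th1 <- scenario$coefs$delta_y[2] - scenario$coefs$delta_x[2]
  bias <- c(
    if ("theta" %in% tests) c(theta_1 = sum_th1 / used - truth_th1),
    if ("delta_r" %in% tests)
      c(delta_r1 = sum_dr1 / used - scenario$coefs$delta_r[2])
  )
  list(rates = rej / used, failures = failures, bias = bias)
}

#' @export
print.evr_sim <- function(x, ...) {
  cat("Monte-Carlo run: ", x$scenario$label %||% x$scenario$kind,
      "\n  reps = ", x$reps, " (", x$failures, " non-converged, excluded)",
      ", alpha = ", x$alpha, ", seed = ", x$seed, "\n", sep = "")
  out <- tibble(test = names(x$rejection_rates),
                rejection_rate = unname(x$rejection_rates),
                mc_se = unname(x$mc_se))
  print(as.data.frame(out), row.names = FALSE)
  if (!is.null(x$bias)) {
    cat("  mean bias:", paste(names(x$bias), signif(x$bias, 4),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bias sweep over the continuous-moderator effect grid
#'
#' For every combination of sample size, correlation-moderation coefficient
#' `delta_r1` and variance-ratio moderation `theta_1` (imposed as
#' `delta_x1 = 0`, `delta_y1 = theta_1`, intercepts 0, `delta_r0 = 0`),
#' fits the continuous model to `reps` replicate datasets and records the
#' mean bias of the `delta_r1` and `theta_1` estimates. The bias of the
#' correlation moderation is reported on two scales: the link-scale
#' coefficient itself (`bias_delta_r1`) and the implied correlation
#' difference between `z = 1` and `z = 0`,
#' `tanh((delta_r0 + delta_r1)/2) - tanh(delta_r0/2)`
#' (`bias_rho_diff`), the scale on which the effect grid is defined.
#'
#' @param sizes Vector of sample sizes.
#' @param delta_r1_grid,theta1_grid Effect grids.
#' @param reps Replicates per cell.
#' @param seed Master seed; cell c uses substream base
#'   `seed + 100000 * (c - 1)` (cells in row-major order).
#' @return A tibble with one row per cell: `N`, `delta_r1`, `theta_1`, the
#'   three biases (`bias_delta_r1`, `bias_theta_1`, `bias_rho_diff`) with
#'   the Monte-Carlo standard errors of the cell means (`se_*`),
#'   `reps_used` and `failures`; the grid maxima are attached as
#'   attributes `max_abs_bias_delta_r1`, `max_abs_bias_theta_1`,
#'   `max_abs_bias_rho_diff`.
#' @export
bias_sweep <- function(sizes = c(70, 140, 280),
                       delta_r1_grid = c(0, 0.2007, 0.6190, 1.0986, 1.7346),
                       theta1_grid = c(0.1116, 0.2027, 0.3466, 0.5493,
                                       0.6931, 0.8047),
                       reps = 2000, seed = 1) {
  if (!length(sizes) || !length(delta_r1_grid) || !length(theta1_grid)) {
    abort("all grids must be nonempty.")
  }
  grid <- tidyr::expand_grid(N = sizes, delta_r1 = delta_r1_grid,
                             theta_1 = theta1_grid)
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    N <- grid$N[cell]; delta_r1 <- grid$delta_r1[cell]
    theta_1 <- grid$theta_1[cell]
    base_seed <- seed + 100000L * (cell - 1L)
    coefs <- list(delta_x = c(0, 0), delta_y = c(0, theta_1),
                  delta_r = c(0, delta_r1))
    est <- matrix(NA_real_, reps, 3)  # delta_r1, theta_1, rho difference
    fail <- 0L
    for (i in seq_len(reps)) {
      set.seed(base_seed + i - 1L)
      d <- gen_cont(N, coefs)
      fit <- tryCatch(fit_cont_impl(d$x, d$y, d$z, vcov = FALSE),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { fail <- fail + 1L; next }
      est[i, ] <- c(fit$par[10], fit$par[8] - fit$par[6],
                    tanh((fit$par[9] + fit$par[10]) / 2) -
                      tanh(fit$par[9] / 2))
    }
    used <- reps - fail
    mu <- colMeans(est, na.rm = TRUE)
    se <- apply(est, 2, stats::sd, na.rm = TRUE) / sqrt(used)
    tibble(N = N, delta_r1 = delta_r1, theta_1 = theta_1,
           bias_delta_r1 = mu[1] - delta_r1,
           bias_theta_1 = mu[2] - theta_1,
           bias_rho_diff = mu[3] - tanh(delta_r1 / 2),
           se_delta_r1 = se[1], se_theta_1 = se[2], se_rho_diff = se[3],
           reps_used = used, failures = fail)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "max_abs_bias_delta_r1") <- max(abs(out$bias_delta_r1))
  attr(out, "max_abs_bias_theta_1") <- max(abs(out$bias_theta_1))
  attr(out, "max_abs_bias_rho_diff") <- max(abs(out$bias_rho_diff))
  out
}
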