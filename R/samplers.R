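# Seeded generators for bivariate normal and bivariate skew-normal data,
# and declarative builders for the simulation-study populations.

#' Sample from a bivariate normal population
#'
#' @param n Number of paired draws.
#' @param var_x,var_y Variances (positive).
#' @param cov_xy Covariance; the covariance matrix must be numerically
#'   positive definite (`cov_xy^2 < var_x * var_y * (1 - 1e-10)`).
#' @param mean_x,mean_y Means.
#' @param seed Optional integer seed (draws are then reproducible).
#' @return A tibble with columns `x`, `y`.
#' @examples
#' sample_bivariate_normal(5, var_x = 2, var_y = 8, cov_xy = 2, seed = 1)
#' @export
sample_bivariate_normal <- function(n, var_x, var_y, cov_xy,
                                    mean_x = 0, mean_y = 0, seed = NULL) {
  if (var_x <= 0 || var_y <= 0) abort("variances must be positive.")
  if (cov_xy^2 >= var_x * var_y * (1 - 1e-10)) {
    abort("covariance matrix is (numerically) singular: |cov_xy| too close to sqrt(var_x * var_y).")
  }
  if (!is.null(seed)) set.seed(seed)
  as_tibble(gen_bvn(n, var_x, var_y, cov_xy, mean_x, mean_y))
}

# unvalidated generator on the current RNG stream (hot simulation path)
gen_bvn <- function(n, var_x, var_y, cov_xy, mean_x = 0, mean_y = 0) {
  rho <- cov_xy / sqrt(var_x * var_y)
  u <- rnorm(n); v <- rnorm(n)
  list(x = mean_x + sqrt(var_x) * u,
       y = mean_y + sqrt(var_y) * (rho * u + sqrt(1 - rho^2) * v))
}

# latent correlation for the shared-|W| skew construction hitting a target
# correlation of (X, Y); errors when the target is unreachable
skew_latent_corr <- function(lambda, rho) {
  delta <- lambda / sqrt(1 + lambda^2)
  vfrac <- delta^2 * (1 - 2 / pi)      # variance contributed by |W|
  vmarg <- 1 - delta^2 * 2 / pi        # marginal variance of the SN margin
  if (lambda == 0) return(rho)
  tau <- (rho * vmarg - vfrac) / (1 - delta^2)
  if (abs(tau) > 1 - 1e-10) {
    abort(paste0("target correlation ", signif(rho, 4),
                 " is not reachable by the shared-latent construction at ",
                 "lambda = ", lambda, "."))
  }
  tau
}

#' Sample from a bivariate skew-normal population
#'
#' Both margins are exactly standard Azzalini skew-normal with shape
#' `lambda`, generated by the shared-latent construction
#' `X = delta|W| + sqrt(1 - delta^2) U`, `Y = delta|W| + sqrt(1 - delta^2) V`
#' with `W` standard normal and `(U, V)` bivariate normal whose correlation
#' is solved so that `cor(X, Y)` equals `rho`. Margins are then centered
#' and rescaled to the requested standard deviations (an affine map, so the
#' correlation and marginal shape are untouched). `lambda = 0` reduces
#' exactly to the bivariate normal sampler.
#'
#' @param n Number of paired draws.
#' @param lambda Skew-normal shape parameter (both margins).
#' @param rho Target correlation of `(x, y)`, |rho| < 1; must be reachable
#'   by the construction (an error states when it is not).
#' @param sd_x,sd_y Target marginal standard deviations.
#' @param mean_x,mean_y Target marginal means.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x`, `y`.
#' @export
sample_bivariate_skew_normal <- function(n, lambda, rho, sd_x = 1, sd_y = 1,
                                         mean_x = 0, mean_y = 0, seed = NULL) {
  if (abs(rho) >= 1) abort("|rho| must be < 1.")
  if (sd_x <= 0 || sd_y <= 0) abort("target SDs must be positive.")
  skew_latent_corr(lambda, rho)  # errors early when unreachable
  if (!is.null(seed)) set.seed(seed)
  as_tibble(gen_bsn(n, lambda, rho, sd_x, sd_y, mean_x, mean_y))
}

gen_bsn <- function(n, lambda, rho, sd_x = 1, sd_y = 1,
                    mean_x = 0, mean_y = 0) {
  tau <- skew_latent_corr(lambda, rho)
  sn <- sn_moments(lambda)
  w <- abs(rnorm(n))
  e1 <- rnorm(n); e2 <- rnorm(n)
  x0 <- sn$delta * w + sqrt(1 - sn$delta^2) * e1
  y0 <- sn$delta * w +
    sqrt(1 - sn$delta^2) * (tau * e1 + sqrt(1 - tau^2) * e2)
  list(x = mean_x + (x0 - sn$mean) / sn$sd * sd_x,
       y = mean_y + (y0 - sn$mean) / sn$sd * sd_y)
}

#' Sample from the continuous-moderator population
#'
#' Draws `z ~ N(0, 1)` and then `(x, y) | z` bivariate normal with
#' `sd_x(z) = exp(delta_x0 + delta_x1 z)`, `sd_y(z)` likewise, and
#' `rho(z) = fisher_inverse(delta_r0 + delta_r1 z)`. Means are
#' `gamma_0 + gamma_1 z` (zero by default). With `lambda > 0` the
#' conditional pair is replaced by the shared-latent skew-normal pair with
#' marginal shape `lambda`, standardized and rescaled row-wise to the same
#' conditional moments.
#'
#' @param N Number of observations.
#' @param coefs Named list with numeric length-2 vectors `delta_x`,
#'   `delta_y`, `delta_r` and optionally `gamma_x`, `gamma_y` (defaults
#'   `c(0, 0)`).
#' @param lambda Skew-normal shape of the conditional margins (0 = normal).
#' @param seed Optional integer seed.
#' @return A tibble with columns `x`, `y`, `z`.
#' @examples
#' sample_continuous_scenario(
#'   5, coefs = list(delta_x = c(0, 0.5), delta_y = c(0, 0.5),
#'                   delta_r = c(0, 1.0986)), seed = 1)
#' @export
sample_continuous_scenario <- function(N, coefs, lambda = 0, seed = NULL) {
  need <- c("delta_x", "delta_y", "delta_r")
  if (!all(need %in% names(coefs))) {
    abort("`coefs` needs delta_x, delta_y, delta_r (each length 2).")
  }
  if (!is.null(seed)) set.seed(seed)
  as_tibble(gen_cont(N, coefs, lambda))
}

gen_cont <- function(N, coefs, lambda = 0) {
  gx <- coefs$gamma_x %||% c(0, 0)
  gy <- coefs$gamma_y %||% c(0, 0)
  z <- rnorm(N)
  sx <- exp(coefs$delta_x[1] + coefs$delta_x[2] * z)
  sy <- exp(coefs$delta_y[1] + coefs$delta_y[2] * z)
  rho <- fisher_inverse(coefs$delta_r[1] + coefs$delta_r[2] * z)
  if (lambda == 0) {
    u <- rnorm(N); e <- rnorm(N)
    v <- rho * u + sqrt(1 - rho^2) * e
  } else {
    sn <- sn_moments(lambda)
    tau <- vapply(rho, function(r) skew_latent_corr(lambda, r), numeric(1))
    w <- abs(rnorm(N)); e1 <- rnorm(N); e2 <- rnorm(N)
    u0 <- sn$delta * w + sqrt(1 - sn$delta^2) * e1
    v0 <- sn$delta * w +
      sqrt(1 - sn$delta^2) * (tau * e1 + sqrt(1 - tau^2) * e2)
    u <- (u0 - sn$mean) / sn$sd
    v <- (v0 - sn$mean) / sn$sd
  }
  list(x = gx[1] + gx[2] * z + sx * u,
       y = gy[1] + gy[2] * z + sy * v,
       z = z)
}

new_scenario <- function(kind, groups = NULL, coefs = NULL, N = NULL,
                         lambda = 0, label = NULL, seed = NULL) {
  structure(list(kind = kind, groups = groups, coefs = coefs, N = N,
                 lambda = lambda, label = label, seed = seed),
            class = "evr_scenario")
}

#' Define a two-group (categorical) simulation population
#'
#' @param n Integer vector of group sizes.
#' @param var_x,var_y,cov_xy Numeric vectors (one entry per group) of
#'   population variances and covariance.
#' @param lambda Skew-normal shape of both margins (0 = normal).
#' @param label Optional description.
#' @param seed Optional default master seed carried with the scenario.
#' @return An `evr_scenario`. Derived per-group quantities (`rho`,
#'   `beta_y`, `sigma_e2`) are included for cross-checking.
#' @export
scenario_categorical <- function(n, var_x, var_y, cov_xy, lambda = 0,
                                 label = NULL, seed = NULL) {
  k <- length(n)
  stopifnot(length(var_x) == k, length(var_y) == k, length(cov_xy) == k)
  if (any(cov_xy^2 >= var_x * var_y)) abort("covariance matrix not positive definite.")
  if (any(n < 4)) abort("need n >= 4 per group.")
  rho <- cov_xy / sqrt(var_x * var_y)
  groups <- tibble(group = as.character(seq_len(k)), n = as.integer(n),
                   var_x = var_x, var_y = var_y, cov_xy = cov_xy, rho = rho,
                   beta_y = slope_from_correlation(rho, sqrt(var_y), sqrt(var_x)),
                   sigma_e2 = var_y * (1 - rho^2))
  new_scenario("categorical", groups = groups, lambda = lambda,
               label = label, seed = seed)
}

#' Define a continuous-moderator simulation population
#'
#' @inheritParams sample_continuous_scenario
#' @param label Optional description.
#' @param seed Optional default master seed carried with the scenario.
#' @return An `evr_scenario`.
#' @export
scenario_continuous <- function(N, coefs, lambda = 0, label = NULL,
                                seed = NULL) {
  if (N < 20) abort("need N >= 20.")
  new_scenario("continuous", coefs = coefs, N = as.integer(N),
               lambda = lambda, seed = seed, label = label)
}

#' Populations of the published simulation studies, by table
#'
#' Reconstructs the exact population behind a cell of the simulation
#' studies shipped with the package:
#' \describe{
#'   \item{table 1}{Type I error, two groups with a constant variance
#'     ratio of 2, `rho = 1/sqrt(2)`, `beta_y = 1`; `condition` selects
#'     `var_x` = c(1, 1), c(1, 2) or c(1, 4), with `var_y` always double
#'     `var_x`; `lambda` sets the skew.}
#'   \item{table 2}{power against moderated slopes with unmoderated
#'     correlations (`rho = 0.5` everywhere); group 1 is always
#'     (2, 2, 1); `condition` picks group 2 from (2, 3, sqrt(1.5)),
#'     (2, 4, sqrt(2)), (2, 8, 2).}
#'   \item{table 3}{power against moderated correlations with unmoderated
#'     slopes (`beta_y = 0.5` everywhere); group 2 from (2, 3, 1),
#'     (2, 4, 1), (2, 8, 1).}
#'   \item{table 4}{moderated slopes 0.50 vs \{0.61, 0.71, 1.00\} with
#'     `rho = 0.5` in both groups, `sd_x = 1`, `sd_y = beta / rho`.}
#'   \item{table 5}{moderated correlations 0.50 vs \{0.41, 0.35, 0.25,
#'     0.17\} with `beta_y = 0.5` in both groups, `sd_x = 1`,
#'     `sd_y = beta / rho`.}
#'   \item{tables 6, 7}{continuous moderator, `delta_r0` in \{0, 0.5, 1\}
#'     selected by `condition`, `delta_x1 = delta_y1 = 0.5`,
#'     `delta_r1 = 0`; table 7 is the same with skew `lambda = 2`.}
#' }
#' Each categorical scenario carries the derived `rho`, `beta_y` and
#' `sigma_e2` so the declared population can be checked against the
#' published condition headers.
#'
#' @param table Integer 1..7.
#' @param condition Column index within the table (see above).
#' @param n Group sizes (categorical tables; default `c(70, 70)`).
#' @param N Sample size (continuous tables; default 280).
#' @param lambda Skew shape for table 1 (0, 2 or 4); fixed at 0 for tables
#'   2-6 and 2 for table 7.
#' @return An `evr_scenario`.
#' @examples
#' build_scenario(2, 3, n = c(140, 140))
#' @export
build_scenario <- function(table, condition, n = c(70, 70), N = 280,
                           lambda = 0) {
  if (!table %in% 1:7) abort("unknown table id.")
  rho_t1 <- 1 / sqrt(2)
  if (table == 1) {
    vx <- list(c(1, 1), c(1, 2), c(1, 4))[[condition]]
    vy <- 2 * vx
    scenario_categorical(n, vx, vy, rho_t1 * sqrt(vx * vy), lambda = lambda,
                         label = sprintf("table 1, condition %d", condition))
  } else if (table == 2) {
    g2 <- list(c(2, 3, sqrt(1.5)), c(2, 4, sqrt(2)), c(2, 8, 2))[[condition]]
    scenario_categorical(n, c(2, g2[1]), c(2, g2[2]), c(1, g2[3]),
                         label = sprintf("table 2, condition %d", condition))
  } else if (table == 3) {
    g2 <- list(c(2, 3, 1), c(2, 4, 1), c(2, 8, 1))[[condition]]
    scenario_categorical(n, c(2, g2[1]), c(2, g2[2]), c(1, g2[3]),
                         label = sprintf("table 3, condition %d", condition))
  } else if (table == 4) {
    beta2 <- c(0.61, 0.71, 1.00)[condition]
    sy <- c(1, beta2 / 0.5)
    scenario_categorical(n, c(1, 1), sy^2, 0.5 * sy,
                         label = sprintf("table 4, condition %d", condition))
  } else if (table == 5) {
    rho2 <- c(0.41, 0.35, 0.25, 0.17)[condition]
    rho <- c(0.5, rho2)
    sy <- 0.5 / rho
    scenario_categorical(n, c(1, 1), sy^2, rho * sy,
                         label = sprintf("table 5, condition %d", condition))
  } else {
    dr0 <- c(0, 0.5, 1)[condition]
    scenario_continuous(
      N, coefs = list(delta_x = c(0, 0.5), delta_y = c(0, 0.5),
                      delta_r = c(dr0, 0)),
      lambda = if (table == 7) 2 else 0,
      label = sprintf("table %d, condition %d", table, condition))
  }
}

#' Population of the two-condition polarization experiment
#'
#' Two groups with `sd_x = 1` and `rho = 0.45` in both, and `sd_y` equal to
#' 2 in the exposed condition versus 1 in the control: correlations are
#' unmoderated while slopes are moderated in opposite directions depending
#' on the regression direction.
#'
#' @param n Per-group sample size (default 300).
#' @return An `evr_scenario`.
#' @export
sem_example_scenario <- function(n = 300) {
  scenario_categorical(c(n, n), var_x = c(1, 1), var_y = c(4, 1),
                       cov_xy = 0.45 * c(2, 1),
                       label = "two-condition polarization experiment")
}

#' Draw one dataset from a scenario
#'
#' @param scenario An `evr_scenario`.
#' @param seed Optional integer seed (falls back to the scenario's own).
#' @return A tibble with columns `x`, `y`, `z` (`z` is the group label for
#'   categorical scenarios, numeric for continuous ones).
#' @export
sample_scenario <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "evr_scenario"))
  seed <- seed %||% scenario$seed
  if (!is.null(seed)) set.seed(seed)
  if (scenario$kind == "continuous") {
    return(sample_continuous_scenario(scenario$N, scenario$coefs,
                                      lambda = scenario$lambda))
  }
  g <- scenario$groups
  dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    d <- if (scenario$lambda == 0) {
      sample_bivariate_normal(g$n[i], g$var_x[i], g$var_y[i], g$cov_xy[i])
    } else {
      sample_bivariate_skew_normal(g$n[i], scenario$lambda, g$rho[i],
                                   sd_x = sqrt(g$var_x[i]),
                                   sd_y = sqrt(g$var_y[i]))
    }
    d$z <- g$group[i]
    d
  }))
}
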