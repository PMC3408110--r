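# Multi-group bivariate-normal fits for a categorical moderator.
#
# All fitting here runs on per-group sufficient statistics (see
# group_moments()): the likelihood depends on the raw data only through
# them, and the mean estimates profile out exactly at the sample means for
# every supported constraint, since constraints never involve the means.
# The saturated fit is closed form; constrained fits are quasi-Newton with
# analytic gradients.

#' Control object for EVR hypothesis tests
#'
#' @param alpha Two-sided test size, in (0, 1).
#' @param critical `"normal"` for standard-normal critical values
#'   (large-sample ML default) or `"t"` for Student t with
#'   `n_base + n_target - 4` degrees of freedom.
#' @return A list of class `evr_config`.
#' @export
evr_config <- function(alpha = 0.05, critical = c("normal", "t")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  structure(list(alpha = alpha, critical = match.arg(critical)),
            class = "evr_config")
}

as_moments <- function(groups, moderator = "z") {
  if (all(c("n", "sd_x", "sd_y", "r") %in% names(groups))) {
    return(groups)
  }
  group_moments(groups, moderator = moderator)
}

# closed-form saturated log-likelihood from moments
loglik_saturated <- function(mom) {
  -sum(mom$n * (log(2 * pi) + 1 + log(mom$sd_x) + log(mom$sd_y) +
                  0.5 * log(1 - mom$r^2)))
}

# Observed information of one group's saturated fit in the parameters
# (mu_x, mu_y, a = log sd_x, b = log sd_y, eta = fisher_link(r)), evaluated
# at the MLE. Means are orthogonal to the scale/correlation block there.
sat_group_vcov <- function(n, sd_x, sd_y, r) {
  cc <- 1 - r^2
  V <- matrix(0, 5, 5)
  V[1:2, 1:2] <- matrix(c(sd_x^2, r * sd_x * sd_y,
                          r * sd_x * sd_y, sd_y^2), 2) / n
  info <- n * matrix(c((2 - r^2) / cc, -r^2 / cc,      -r / 2,
                       -r^2 / cc,      (2 - r^2) / cc, -r / 2,
                       -r / 2,         -r / 2,          (1 + r^2) / 4),
                     3, 3)
  V[3:5, 3:5] <- solve(info)
  V
}

#' Saturated multi-group fit
#'
#' Fits the unrestricted model in which every group has its own means,
#' standard deviations, and correlation. The solution is closed form: the
#' ML estimates are the per-group sample moments, mapped to
#' intercept-plus-indicator coding for the log-SD and Fisher-link
#' submodels. The coefficient covariance is the inverse observed
#' information at the optimum.
#'
#' @param groups Either a raw data frame with columns `x`, `y` and a
#'   moderator column, or a moments tibble from [group_moments()].
#' @param base Base category; defaults to the first group.
#' @param moderator Moderator column name when `groups` is raw data.
#' @return An object of class `evr_fit`.
#' @examples
#' d <- sample_scenario(build_scenario(2, 3, n = c(140, 140)), seed = 1)
#' fit_saturated(d)
#' @export
fit_saturated <- function(groups, base = NULL, moderator = "z") {
  mom <- as_moments(groups, moderator)
  if (nrow(mom) < 2) abort("need at least 2 groups.")
  base <- base %||% mom$group[1]
  if (!base %in% mom$group) abort(paste0("base category '", base, "' absent."))
  mom <- mom[order(mom$group != base), , drop = FALSE]
  k <- nrow(mom)

  a <- log(mom$sd_x); b <- log(mom$sd_y); eta <- fisher_link(mom$r)
  coded <- function(v) c(v[1], v[-1] - v[1])
  params <- list(gamma_x = coded(mom$mean_x), gamma_y = coded(mom$mean_y),
                 delta_x = coded(a), delta_y = coded(b),
                 delta_r = coded(eta))

  # family-major per-group covariance, then map to indicator coding
  V <- matrix(0, 5 * k, 5 * k)
  idx <- function(f, g) (f - 1) * k + g
  for (g in seq_len(k)) {
    Vg <- sat_group_vcov(mom$n[g], mom$sd_x[g], mom$sd_y[g], mom$r[g])
    ii <- idx(1:5, g)
    V[ii, ii] <- Vg
  }
  A <- diag(k); A[-1, 1] <- -1   # coded = A %*% pergroup
  M <- kronecker(diag(5), A)
  V <- M %*% V %*% t(M)

  nm <- paste0(rep(c("gamma_x", "gamma_y", "delta_x", "delta_y", "delta_r"),
                   each = k),
               ".", rep(c("(base)", mom$group[-1]), 5))
  dimnames(V) <- list(nm, nm)

  new_evr_fit(moments = mom, params = params, loglik = loglik_saturated(mom),
              vcov = V, n_free = 5 * k, converged = TRUE,
              constraints = character(), base = base)
}

new_evr_fit <- function(moments, params, loglik, vcov, n_free, converged,
                        constraints, base, optim_info = NULL) {
  structure(list(moments = moments, params = params, loglik = loglik,
                 vcov = vcov, n_free = n_free, converged = converged,
                 constraints = constraints, base = base,
                 optim_info = optim_info),
            class = "evr_fit")
}

supported_constraints <- c("hov_x", "hov_y", "evr", "equal_rho", "equal_slope")

# ---- constrained parameterization over sufficient statistics ----------------

# Free parameter layout for a constraint set over k groups:
#   a: log sd_x (scalar if x common, else k)
#   y part: d (scalar, evr: b_g = a_g + d) | b (scalar if hov_y, else k)
#   rho part: eta (scalar if equal_rho) | beta (scalar if equal_slope)
#             | eta (k) if free
constraint_layout <- function(constraints, k) {
  cons <- unique(constraints)
  bad <- setdiff(cons, supported_constraints)
  if (length(bad)) abort(paste0("unknown constraint(s): ",
                                paste(bad, collapse = ", ")))
  if (all(c("equal_rho", "equal_slope") %in% cons)) {
    abort("equal_rho and equal_slope cannot be imposed jointly.")
  }
  x_common <- "hov_x" %in% cons ||
    (all(c("evr", "hov_y") %in% cons))  # evr + hov_y forces common sd_x too
  y_mode <- if ("evr" %in% cons) "evr" else if ("hov_y" %in% cons)
    "common" else "free"
  r_mode <- if ("equal_rho" %in% cons) "common" else
    if ("equal_slope" %in% cons) "slope" else "free"
  na <- if (x_common) 1L else k
  nb <- if (y_mode == "evr") 1L else if (y_mode == "common") 1L else k
  nr <- if (r_mode == "free") k else 1L
  list(cons = cons, k = k, x_common = x_common, y_mode = y_mode,
       r_mode = r_mode, na = na, nb = nb, nr = nr, n_free = na + nb + nr)
}

RHO_CAP <- 1 - 1e-10

layout_expand <- function(par, lay) {
  k <- lay$k
  a <- par[seq_len(lay$na)]
  if (lay$x_common) a <- rep(a, k)
  bp <- par[lay$na + seq_len(lay$nb)]
  b <- switch(lay$y_mode, evr = a + bp, common = rep(bp, k), free = bp)
  rp <- par[lay$na + lay$nb + seq_len(lay$nr)]
  clamped <- rep(FALSE, k)
  if (lay$r_mode == "slope") {
    rho <- rp * exp(a - b)
    clamped <- abs(rho) >= RHO_CAP
    rho <- pmin(pmax(rho, -RHO_CAP), RHO_CAP)
  } else {
    rho <- fisher_inverse(if (lay$r_mode == "common") rep(rp, k) else rp)
  }
  list(a = a, b = b, rho = rho, beta = if (lay$r_mode == "slope") rp else NULL,
       clamped = clamped)
}

# negative log-likelihood (means profiled out) and its gradient
nll_constrained <- function(par, lay, st) {
  g <- layout_expand(par, lay)
  cc <- 1 - g$rho^2
  p <- st$S20 * exp(-2 * g$a)
  q <- st$S02 * exp(-2 * g$b)
  m <- st$S11 * exp(-g$a - g$b)
  sum(st$n * (log(2 * pi) + g$a + g$b + 0.5 * log(cc) +
                (p + q - 2 * g$rho * m) / (2 * cc)))
}

grad_constrained <- function(par, lay, st) {
  g <- layout_expand(par, lay)
  cc <- 1 - g$rho^2
  p <- st$S20 * exp(-2 * g$a)
  q <- st$S02 * exp(-2 * g$b)
  m <- st$S11 * exp(-g$a - g$b)
  da <- st$n * (1 - (p - g$rho * m) / cc)
  db <- st$n * (1 - (q - g$rho * m) / cc)
  drho <- -st$n * (g$rho / cc + m / cc -
                     g$rho * (p + q - 2 * g$rho * m) / cc^2)
  drho[g$clamped] <- 0
  if (lay$r_mode == "slope") {
    # rho_g = beta * exp(a_g - b_g): chain rule into a, b, beta
    da <- da + drho * g$rho
    db <- db - drho * g$rho
    gr_r <- sum(drho * exp(g$a - g$b))
  } else if (lay$r_mode == "common") {
    gr_r <- sum(drho) * (1 - fisher_inverse(par[lay$na + lay$nb + 1])^2) / 2
  } else {
    gr_r <- drho * cc / 2   # d rho / d eta = (1 - rho^2) / 2
  }
  if (lay$y_mode == "evr") {
    gr_a <- da + db
    gr_b <- sum(db)
  } else if (lay$y_mode == "common") {
    gr_a <- da
    gr_b <- sum(db)
  } else {
    gr_a <- da
    gr_b <- db
  }
  if (lay$x_common) gr_a <- sum(gr_a)
  c(gr_a, gr_b, gr_r)
}

constrained_start <- function(lay, mom) {
  a0 <- log(mom$sd_x); b0 <- log(mom$sd_y)
  w <- mom$n / sum(mom$n)
  a <- if (lay$x_common) sum(w * a0) else a0
  bp <- switch(lay$y_mode,
               evr = sum(w * (b0 - a0)),
               common = sum(w * b0),
               free = b0)
  rp <- switch(lay$r_mode,
               common = fisher_link(sum(w * mom$r)),
               slope = sum(w * mom$r * mom$sd_y / mom$sd_x),
               free = fisher_link(mom$r))
  c(a, bp, rp)
}

# ---- fast profile likelihoods (two of the constraints admit profiling) -----

# Equal correlations: for fixed rho the per-group scales solve in closed
# form (exp(-2a) S20 = (1 - rho^2)/(1 - rho r)), leaving a 1-D profile.
profile_ll_equal_rho <- function(st) {
  const <- sum(st$n * (log(2 * pi) + 1 + 0.5 * log(st$S20 * st$S02)))
  f <- function(rho) sum(st$n * (-0.5 * log(1 - rho^2) +
                                   log(1 - rho * st$r)))
  opt <- optimize(f, c(-RHO_CAP, RHO_CAP))
  list(loglik = -(const + opt$objective), converged = TRUE, df_drop = 1L)
}

# Equal slopes: with rho_g = beta * exp(-t_g), t_g = log(sd_y/sd_x)_g, the
# overall scale a_g solves in closed form, leaving (beta, t_1..t_k).
profile_ll_equal_slope <- function(st) {
  k <- length(st$n)
  h <- function(par) {
    beta <- par[1]; t <- par[-1]
    rho <- pmin(pmax(beta * exp(-t), -RHO_CAP), RHO_CAP)
    cc <- 1 - rho^2
    K <- st$S20 + st$S02 * exp(-2 * t) - 2 * rho * st$S11 * exp(-t)
    sum(st$n * (log(2 * pi) + 1 - log(2) + t + log(K) - 0.5 * log(cc)))
  }
  t0 <- 0.5 * log(st$S02 / st$S20)
  w <- st$n / sum(st$n)
  beta0 <- sum(w * st$r * sqrt(st$S02 / st$S20))
  opt <- optim(c(beta0, t0), h, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14,
                              ndeps = rep(1e-6, k + 1)))
  list(loglik = -opt$value, converged = opt$convergence == 0, df_drop = k - 1L)
}

#' Constrained multi-group fit
#'
#' Maximum-likelihood fit of the multi-group bivariate-normal model under
#' equality constraints, the engine behind the likelihood-ratio model
#' comparisons. Supported constraints:
#' \describe{
#'   \item{`hov_x`, `hov_y`}{homogeneous sd of x (resp. y) across groups;}
#'   \item{`evr`}{equal variance ratios: the log sd ratio
#'     `log(sd_y/sd_x)` is the same in every group;}
#'   \item{`equal_rho`}{one common correlation;}
#'   \item{`equal_slope`}{one common regression slope of y on x, imposed by
#'     parameterizing each group's correlation as
#'     `rho_g = beta * sd_x_g / sd_y_g` (clamped inside (-1, 1)), so that
#'     every comparison shares a single likelihood.}
#' }
#' Combinations are allowed except `equal_rho` with `equal_slope`. Means are
#' always estimated freely per group (they profile out at the sample means).
#'
#' @inheritParams fit_saturated
#' @param constraints Character vector from the supported set above.
#' @return An `evr_fit`; `loglik` never exceeds the saturated fit's.
#' @export
fit_constrained <- function(groups, constraints, base = NULL,
                            moderator = "z") {
  mom <- as_moments(groups, moderator)
  if (nrow(mom) < 2) abort("need at least 2 groups.")
  base <- base %||% mom$group[1]
  mom <- mom[order(mom$group != base), , drop = FALSE]
  if (length(constraints) == 0) {
    return(fit_saturated(mom, base = base))
  }
  lay <- constraint_layout(constraints, nrow(mom))
  st <- moments_stats(mom)
  start <- constrained_start(lay, mom)
  opt <- optim(start, nll_constrained, grad_constrained, lay = lay, st = st,
               method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0 ||
      max(abs(grad_constrained(opt$par, lay, st))) > 1e-4 * (1 + abs(opt$value))) {
    jitter <- start * (1 + 0.05) + 0.01
    opt2 <- optim(jitter, nll_constrained, grad_constrained, lay = lay,
                  st = st, method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-14))
    if (opt2$value < opt$value) opt <- opt2
  }
  gnorm <- max(abs(grad_constrained(opt$par, lay, st)))
  converged <- opt$convergence == 0 && gnorm < 1e-4 * (1 + abs(opt$value))
  if (!converged) {
    abort(paste0("constrained fit did not converge (optim code ",
                 opt$convergence, ", max |gradient| ", signif(gnorm, 3), ")."))
  }
  H <- fd_hessian(function(p) grad_constrained(p, lay, st), opt$par)
  V <- tryCatch((solve(H) + t(solve(H))) / 2, error = function(e) NULL)
  gpar <- layout_expand(opt$par, lay)
  params <- list(gamma_x = mom$mean_x, gamma_y = mom$mean_y,
                 a = gpar$a, b = gpar$b, rho = gpar$rho, beta = gpar$beta)
  new_evr_fit(moments = mom, params = params, loglik = -opt$value,
              vcov = V, n_free = lay$n_free + 2 * nrow(mom),
              converged = converged, constraints = sort(lay$cons),
              base = base,
              optim_info = list(par = opt$par, layout = lay,
                                counts = opt$counts, gradient_norm = gnorm))
}

#' Likelihood-ratio comparison of two nested fits
#'
#' @param restricted,full Two `evr_fit` objects on the same data, the first
#'   imposing a superset of the second's constraints.
#' @return A tibble with `chi2`, `df`, `p_value` plus the two log-likelihoods.
#' @export
lr_compare <- function(restricted, full) {
  stopifnot(inherits(restricted, "evr_fit"), inherits(full, "evr_fit"))
  if (!identical(dim(restricted$moments), dim(full$moments)) ||
      !isTRUE(all.equal(restricted$moments$n, full$moments$n))) {
    abort("fits are not on the same data.")
  }
  if (!all(full$constraints %in% restricted$constraints) ||
      restricted$n_free > full$n_free) {
    abort("`restricted` must nest inside `full` (no more free coefficients, superset of constraints).")
  }
  chi2 <- 2 * (full$loglik - restricted$loglik)
  if (chi2 < -1e-8) {
    abort("restricted fit has higher likelihood than the full fit; refit.")
  }
  chi2 <- max(chi2, 0)
  df <- full$n_free - restricted$n_free
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  tibble(chi2 = chi2, df = df, p_value = p,
         loglik_restricted = restricted$loglik, loglik_full = full$loglik,
         constraints = paste(setdiff(restricted$constraints,
                                     full$constraints), collapse = "+"))
}

# ---- Wald EVR test ----------------------------------------------------------

crit_q <- function(config, n1, n2) {
  if (config$critical == "t") {
    qt(1 - config$alpha / 2, df = (n1 - 2) + (n2 - 2))
  } else {
    qnorm(1 - config$alpha / 2)
  }
}

p_two_sided <- function(stat, config, n1, n2) {
  if (config$critical == "t") {
    2 * pt(abs(stat), df = (n1 - 2) + (n2 - 2), lower.tail = FALSE)
  } else {
    2 * pnorm(abs(stat), lower.tail = FALSE)
  }
}

#' Wald test of equal variance ratios between two moderator categories
#'
#' Tests `theta = log(sd_y/sd_x)[target] - log(sd_y/sd_x)[base] = 0`. Under
#' equal variance ratios `theta = 0`, and `exp(theta)` equals the ratio of
#' the slope ratio to the correlation ratio between the two categories, so
#' the exponentiated confidence interval bounds that ratio comparison.
#' The standard error comes from the observed-information covariance of the
#' saturated fit: `var(theta) = (1 - r_base^2)/n_base +
#' (1 - r_target^2)/n_target` exactly.
#'
#' @inheritParams fit_saturated
#' @param target Category to compare against `base`; defaults to the second
#'   group. With more than two groups, every non-base category can be tested
#'   by calling once per target (no multiplicity correction is applied).
#' @param config An [evr_config()].
#' @return A one-row tibble: `base`, `target`, `theta_hat`, `se`,
#'   `statistic`, `p_value`, `ci_lo`, `ci_hi`, `exp_theta`, `exp_ci_lo`,
#'   `exp_ci_hi`, `alpha`.
#' @examples
#' d <- sample_scenario(build_scenario(2, 3, n = c(140, 140)), seed = 1)
#' evr_test(d)
#' @export
evr_test <- function(groups, base = NULL, target = NULL,
                     config = evr_config(), moderator = "z") {
  mom <- as_moments(groups, moderator)
  base <- base %||% mom$group[1]
  target <- target %||% setdiff(mom$group, base)[1]
  if (identical(base, target)) abort("`base` and `target` must differ.")
  if (!all(c(base, target) %in% mom$group)) {
    abort("`base` or `target` not among the group labels.")
  }
  mb <- mom[mom$group == base, ]; mt <- mom[mom$group == target, ]
  theta <- log(mt$sd_y / mt$sd_x) - log(mb$sd_y / mb$sd_x)
  se <- sqrt((1 - mb$r^2) / mb$n + (1 - mt$r^2) / mt$n)
  stat <- theta / se
  q <- crit_q(config, mb$n, mt$n)
  ci <- theta + c(-1, 1) * q * se
  tibble(base = base, target = target, theta_hat = theta, se = se,
         statistic = stat,
         p_value = p_two_sided(stat, config, mb$n, mt$n),
         ci_lo = ci[1], ci_hi = ci[2],
         exp_theta = exp(theta), exp_ci_lo = exp(ci[1]), exp_ci_hi = exp(ci[2]),
         alpha = config$alpha)
}

# Wald test of equal correlations (Fisher-link contrast); var(eta_hat) = 4/n
# exactly under the observed information of the saturated fit.
deltar_test_categorical <- function(mom, base, target, config = evr_config()) {
  mb <- mom[mom$group == base, ]; mt <- mom[mom$group == target, ]
  est <- fisher_link(mt$r) - fisher_link(mb$r)
  se <- sqrt(4 / mb$n + 4 / mt$n)
  stat <- est / se
  tibble(base = base, target = target, estimate = est, se = se,
         statistic = stat, p_value = p_two_sided(stat, config, mb$n, mt$n))
}

# Joint Wald chi-square over all theta contrasts vs the base category.
# This is an extension beyond the pairwise tests: covariances between
# contrasts sharing the base group are (1 - r_base^2)/n_base.
theta_joint_wald <- function(mom, base) {
  mb <- mom[mom$group == base, ]
  others <- mom[mom$group != base, ]
  th <- log(others$sd_y / others$sd_x) - log(mb$sd_y / mb$sd_x)
  k <- nrow(others)
  V <- matrix((1 - mb$r^2) / mb$n, k, k) +
    diag((1 - others$r^2) / others$n, k)
  chi2 <- drop(th %*% solve(V, th))
  tibble(chi2 = chi2, df = k,
         p_value = pchisq(chi2, k, lower.tail = FALSE),
         note = "joint Wald test over all theta contrasts (extension)")
}
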