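# Continuous-moderator model: means, log standard deviations and the
# Fisher-linked correlation are each intercept + linear in z, and all ten
# coefficients are estimated simultaneously by maximum likelihood.

# Lean fitting core shared by fit_continuous() and the simulation loops:
# plain vectors in, plain list out, no validation or tibble overhead.
fit_cont_impl <- function(x, y, z, vcov = TRUE, spec = NULL) {
  spec <- spec %||% evr_model_spec(z, "continuous")
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  r0 <- max(min(stats::cor(x, y), 0.99), -0.99)
  d <- spec_dims(spec)
  start <- c(mean(x), numeric(d[["pm"]] - 1),
             mean(y), numeric(d[["pm"]] - 1),
             log(sx), numeric(d[["px"]] - 1),
             log(sy), numeric(d[["py"]] - 1),
             fisher_link(r0), numeric(d[["pr"]] - 1))
  bfgs <- function(s, maxit) {
    cpp_bvn_fit(s, spec$Zm, spec$Zx, spec$Zy, spec$Zr, x, y,
                maxit = maxit, reltol = 1e-14)
  }
  ok <- function(o) o$convergence == 0 &&
    o$gradient_norm < 1e-4 * (1 + abs(o$value))
  opt <- bfgs(start, 300L)
  if (!ok(opt)) {
    opt2 <- bfgs(start * 1.05 + 0.01, 600L)
    if (opt2$value < opt$value) opt <- opt2
  }
  par <- drop(opt$par)
  V <- NULL
  if (vcov) {
    gr <- function(p) cpp_bvn_nll_grad(p, spec$Zm, spec$Zx, spec$Zy, spec$Zr,
                                       x, y)
    H <- fd_hessian(gr, par)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) V <- (V + t(V)) / 2
  }
  list(par = par, loglik = -opt$value, vcov = V, spec = spec,
       converged = ok(opt), gradient_norm = opt$gradient_norm,
       counts = c(fn = opt$fncount, gr = opt$grcount),
       code = opt$convergence)
}

#' Maximum-likelihood fit of the continuous-moderator model
#'
#' Fits, by quasi-Newton maximization of the exact bivariate-normal
#' likelihood, the model in which for each observation
#' `log sd_x = delta_x0 + delta_x1 * z`, `log sd_y = delta_y0 +
#' delta_y1 * z`, `fisher_link(rho) = delta_r0 + delta_r1 * z`, and the
#' means are intercept + linear in `z`. Starting values put the intercepts
#' at the global moment estimates and all slopes at zero; on a poor
#' convergence diagnosis the fit restarts once from jittered values. The
#' coefficient covariance is the inverse observed information at the
#' optimum.
#'
#' @param data Data frame with numeric columns `x`, `y`, `z`; at least 20
#'   rows, `z` non-degenerate.
#' @param spec Optional [evr_model_spec()]; defaults to intercept + `z` for
#'   all submodels.
#' @param vcov Compute the observed-information covariance (default TRUE;
#'   skipping it saves time in tight simulation loops).
#' @return An object of class `evr_cfit` (also `evr_fit`): coefficient
#'   vector, log-likelihood, covariance, convergence record.
#' @examples
#' d <- sample_continuous_scenario(
#'   200, coefs = list(delta_x = c(0, 0.5), delta_y = c(0, 0.5),
#'                     delta_r = c(0, 0)), seed = 1)
#' fit <- fit_continuous(d)
#' theta1_test(fit)
#' @export
fit_continuous <- function(data, spec = NULL, vcov = TRUE) {
  check_sample(data, "z", continuous = TRUE)
  if (nrow(data) < 20) abort("need at least 20 observations.")
  f <- fit_cont_impl(data$x, data$y, data$z, vcov = vcov, spec = spec)
  par <- setNames(f$par, par_names(f$spec))
  if (!is.null(f$vcov)) dimnames(f$vcov) <- list(names(par), names(par))
  structure(list(params = unpack_params(par, f$spec), coef = par,
                 loglik = f$loglik, vcov = f$vcov,
                 n_free = length(par), converged = f$converged,
                 spec = f$spec, n = nrow(data),
                 optim_info = list(counts = f$counts,
                                   gradient_norm = f$gradient_norm,
                                   code = f$code)),
            class = c("evr_cfit", "evr_fit"))
}

wald_row <- function(name, est, se, config) {
  stat <- est / se
  tibble(term = name, estimate = est, se = se, statistic = stat,
         p_value = 2 * pnorm(abs(stat), lower.tail = FALSE),
         ci_lo = est - qnorm(1 - config$alpha / 2) * se,
         ci_hi = est + qnorm(1 - config$alpha / 2) * se,
         alpha = config$alpha)
}

# (estimate, se) pairs for theta_1 and delta_r1 from a lean fit; indices
# follow the par order c(gx0, gx1, gy0, gy1, dx0, dx1, dy0, dy1, dr0, dr1)
cont_contrasts <- function(par, V) {
  th <- par[8] - par[6]
  se_th <- sqrt(V[8, 8] + V[6, 6] - 2 * V[8, 6])
  list(theta_1 = c(est = th, se = se_th),
       delta_r1 = c(est = par[10], se = sqrt(V[10, 10])))
}

#' Wald test of variance-ratio moderation by a continuous moderator
#'
#' Tests `theta_1 = delta_y1 - delta_x1 = 0`: whether the log of the
#' sd-ratio `sd_y/sd_x` changes with `z`. `exp(2 * theta_1)` is the factor
#' by which the variance ratio is multiplied per unit of `z`.
#'
#' @param fit An `evr_cfit` from [fit_continuous()] (with covariance).
#' @param config An [evr_config()]. Critical values are standard normal.
#' @return A one-row tibble with estimate, `se`, `statistic`, `p_value`
#'   and confidence limits.
#' @export
theta1_test <- function(fit, config = evr_config()) {
  stopifnot(inherits(fit, "evr_cfit"))
  if (!fit$converged) abort("fit did not converge; no test available.")
  if (is.null(fit$vcov)) abort("fit was computed without a covariance matrix.")
  ct <- cont_contrasts(unname(fit$coef), fit$vcov)
  wald_row("theta_1", ct$theta_1[["est"]], ct$theta_1[["se"]], config)
}

#' Wald test of correlation moderation by a continuous moderator
#'
#' Tests `delta_r1 = 0`: whether the Fisher-linked correlation changes
#' with `z`.
#'
#' @inheritParams theta1_test
#' @return A one-row tibble as in [theta1_test()].
#' @export
deltar1_test <- function(fit, config = evr_config()) {
  stopifnot(inherits(fit, "evr_cfit"))
  if (!fit$converged) abort("fit did not converge; no test available.")
  if (is.null(fit$vcov)) abort("fit was computed without a covariance matrix.")
  ct <- cont_contrasts(unname(fit$coef), fit$vcov)
  wald_row("delta_r1", ct$delta_r1[["est"]], ct$delta_r1[["se"]], config)
}
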