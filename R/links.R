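#' Fisher link for correlations
#'
#' The Fisher link maps a correlation to the whole real line,
#' `fisher_link(rho) = log((1 + rho) / (1 - rho)) = 2 * atanh(rho)`, and is the
#' link function used by the correlation submodel: on the link scale the
#' moderated correlation is linear in the moderator codes. `fisher_inverse()`
#' is its exact inverse, `tanh(eta / 2)`.
#'
#' Note this is twice the classical Fisher z transform `atanh(rho)`.
#'
#' @param rho Numeric vector of correlations, each strictly inside (-1, 1).
#' @param eta Numeric vector on the link (real) scale.
#' @return A numeric vector of the same length.
#' @examples
#' fisher_link(0.5)
#' fisher_inverse(1.0986) # ~ 0.5
#' @export
fisher_link <- function(rho) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    abort("`rho` must be numeric with |rho| < 1.")
  }
  2 * atanh(rho)
}

#' @rdname fisher_link
#' @export
fisher_inverse <- function(eta) {
  if (!is.numeric(eta) || any(!is.finite(eta))) {
    abort("`eta` must be finite numeric.")
  }
  tanh(eta / 2)
}

#' Regression slope implied by a correlation and two standard deviations
#'
#' For a bivariate normal pair the slope of the regression of y on x is
#' `beta_y = rho * sd_y / sd_x`. Swapping the two standard deviations gives
#' the slope of x on y.
#'
#' @param rho Correlation(s).
#' @param sd_y,sd_x Positive standard deviations.
#' @return Numeric vector of slopes.
#' @examples
#' slope_from_correlation(0.5, sqrt(8), sqrt(2)) # = 1
#' @export
slope_from_correlation <- function(rho, sd_y, sd_x) {
  if (any(!is.finite(sd_x)) || any(sd_x <= 0) ||
      any(!is.finite(sd_y)) || any(sd_y <= 0)) {
    abort("standard deviations must be positive and finite.")
  }
  rho * sd_y / sd_x
}

#' Check the heterogeneous-error-variance (HeEV) balance condition
#'
#' Residual variance in the regression of y on x is equal across two groups
#' i and j exactly when `var_yi / var_yj = (1 - rho_j^2) / (1 - rho_i^2)`.
#' This condition is logically independent of equality of variance ratios:
#' either can hold while the other fails.
#'
#' @param rho_i,rho_j Group correlations, |rho| < 1.
#' @param var_yi,var_yj Positive y-variances of the two groups.
#' @param tol Relative tolerance for declaring the two sides equal.
#' @return A tibble with columns `lhs`, `rhs`, `satisfied`.
#' @examples
#' heev_ratio(0.8, 0, 1, 0.36) # both sides 2.77..., satisfied
#' @export
heev_ratio <- function(rho_i, rho_j, var_yi, var_yj, tol = 1e-9) {
  if (abs(rho_i) >= 1 || abs(rho_j) >= 1) abort("|rho| must be < 1.")
  if (var_yi <= 0 || var_yj <= 0) abort("variances must be positive.")
  lhs <- var_yi / var_yj
  rhs <- (1 - rho_j^2) / (1 - rho_i^2)
  tibble(lhs = lhs, rhs = rhs,
         satisfied = abs(lhs - rhs) <= tol * max(abs(lhs), abs(rhs)))
}

#' Azzalini skew-normal density
#'
#' Density `2 * dnorm(x) * pnorm(lambda * x)` of the standard skew-normal
#' distribution with shape `lambda`; `lambda = 0` recovers the standard
#' normal.
#'
#' @param x Numeric vector of evaluation points.
#' @param lambda Shape parameter (scalar).
#' @return Numeric vector of densities.
#' @examples
#' skew_normal_pdf(0, 2)
#' @export
skew_normal_pdf <- function(x, lambda) {
  stopifnot(is.numeric(x), length(lambda) == 1, is.finite(lambda))
  2 * dnorm(x) * pnorm(lambda * x)
}

# mean/sd of the standard skew-normal with shape lambda
sn_moments <- function(lambda) {
  delta <- lambda / sqrt(1 + lambda^2)
  m <- delta * sqrt(2 / pi)
  list(delta = delta, mean = m, sd = sqrt(1 - m^2))
}
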