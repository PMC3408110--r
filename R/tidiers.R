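# broom-style tidiers, print methods and plots for fitted objects.

#' @export
print.evr_fit <- function(x, digits = 4, ...) {
  cons <- if (length(x$constraints)) paste(x$constraints, collapse = " + ")
  else "none (saturated)"
  cat("Multi-group bivariate-normal fit\n")
  cat("  groups:", nrow(x$moments), " constraints:", cons, "\n")
  cat("  loglik:", format(x$loglik, digits = digits + 2),
      " free coefficients:", x$n_free,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
print.evr_cfit <- function(x, digits = 4, ...) {
  cat("Continuous-moderator bivariate-normal fit (n =", x$n, ")\n")
  cat("  loglik:", format(x$loglik, digits = digits + 2),
      " converged:", x$converged, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a multi-group or continuous fit
#'
#' @param x An `evr_fit` or `evr_cfit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and, when a
#'   coefficient covariance is available, `std.error`.
#' @export
tidy.evr_fit <- function(x, ...) {
  if (length(x$constraints) == 0 && !is.null(x$vcov)) {
    est <- unlist(x$params[c("gamma_x", "gamma_y", "delta_x", "delta_y",
                             "delta_r")])
    return(tibble(term = rownames(x$vcov), estimate = unname(est),
                  std.error = sqrt(diag(x$vcov))))
  }
  p <- x$params
  tibble(
    term = c(paste0("mean_x.", x$moments$group),
             paste0("mean_y.", x$moments$group),
             paste0("log_sd_x.", x$moments$group),
             paste0("log_sd_y.", x$moments$group),
             paste0("rho.", x$moments$group),
             if (!is.null(p$beta)) "beta_common"),
    estimate = c(p$gamma_x, p$gamma_y, p$a, p$b, p$rho, p$beta)
  )
}

#' @export
tidy.evr_cfit <- function(x, ...) {
  out <- tibble(term = names(x$coef), estimate = unname(x$coef))
  if (!is.null(x$vcov)) out$std.error <- sqrt(diag(x$vcov))
  out
}

#' One-row summary of a fit
#'
#' @inheritParams tidy.evr_fit
#' @return A tibble with `logLik`, `n_free`, `df.residual` analogue `nobs`,
#'   and `converged`.
#' @export
glance.evr_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_free = x$n_free,
         nobs = sum(x$moments$n), converged = x$converged)
}

#' @export
glance.evr_cfit <- function(x, ...) {
  tibble(logLik = x$loglik, n_free = x$n_free, nobs = x$n,
         converged = x$converged)
}

#' Plot rejection rates of a simulation run
#'
#' @param object An `evr_sim`.
#' @param ... Unused.
#' @return A ggplot: one bar per test with +-3 Monte-Carlo-SE error bars
#'   and the nominal level marked.
#' @export
autoplot.evr_sim <- function(object, ...) {
  d <- tibble(test = names(object$rejection_rates),
              rate = unname(object$rejection_rates),
              se = unname(object$mc_se))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - 3 * .data$se,
                                        ymax = .data$rate + 3 * .data$se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::labs(y = "rejection rate", x = NULL,
                  title = object$scenario$label %||% "simulation") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a two-group moderation analysis
#'
#' @param object An `evr_report`.
#' @param data Original data frame with `x`, `y`, `z` (the report keeps
#'   only the sufficient statistics, so the raw data must be supplied for
#'   plotting).
#' @param ... Unused.
#' @return A ggplot faceted by moderator category with per-group least
#'   squares lines in both regression directions.
#' @export
autoplot.evr_report <- function(object, data, ...) {
  check_sample(data, "z")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black") +
    ggplot2::facet_wrap(~z) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "y on x by moderator category")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
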