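#' Full moderation report for a categorical moderator
#'
#' Bundles the complete analysis workflow: per-group moments, regression
#' slopes in both directions, Wald tests of equal variance ratios against
#' the base category with exponentiated confidence intervals, Fisher-link
#' correlation contrasts, and the likelihood-ratio ladder. The ladder
#' starts from the saturated model, imposes homogeneity of sd(x) first when
#' the sample x scales are compatible (LR p-value above `alpha`), and then
#' adds one constraint at a time: equal variance ratios, equal slopes,
#' equal correlations. Raw p-values are reported throughout; no
#' multiple-testing correction is applied.
#'
#' @inheritParams evr_test
#' @return An object of class `evr_report` with elements `groups`,
#'   `slopes`, `theta_tests`, `theta_joint`, `correlations`, `lr_ladder`,
#'   `baseline`, `config`.
#' @examples
#' d <- sample_scenario(sem_example_scenario(n = 300), seed = 7)
#' moderation_report(d)
#' @export
moderation_report <- function(groups, base = NULL, config = evr_config(),
                              moderator = "z") {
  mom <- as_moments(groups, moderator)
  if (nrow(mom) < 2) abort("need at least 2 groups.")
  base <- base %||% mom$group[1]
  mom <- mom[order(mom$group != base), , drop = FALSE]

  slopes <- dplyr::mutate(
    mom[, c("group", "n", "sd_x", "sd_y", "r")],
    beta_y_on_x = slope_from_correlation(.data$r, .data$sd_y, .data$sd_x),
    beta_x_on_y = slope_from_correlation(.data$r, .data$sd_x, .data$sd_y),
    variance_ratio = .data$sd_y^2 / .data$sd_x^2
  )

  targets <- setdiff(mom$group, base)
  theta_tests <- dplyr::bind_rows(
    lapply(targets, function(tg) evr_test(mom, base, tg, config))
  )
  correlations <- dplyr::bind_rows(
    lapply(targets, function(tg) deltar_test_categorical(mom, base, tg, config))
  )
  theta_joint <- if (length(targets) > 1) theta_joint_wald(mom, base) else NULL

  sat <- fit_saturated(mom, base = base)
  hov_x <- fit_constrained(mom, "hov_x", base = base)
  hov_x_test <- lr_compare(hov_x, sat)
  use_hov_x <- hov_x_test$p_value > config$alpha
  baseline <- if (use_hov_x) hov_x else sat
  base_cons <- if (use_hov_x) "hov_x" else character()

  step <- function(extra) {
    fit <- fit_constrained(mom, c(base_cons, extra), base = base)
    lr_compare(fit, baseline)
  }
  lr_ladder <- dplyr::bind_rows(
    dplyr::mutate(hov_x_test, constraints = "hov_x", step = "hov_x vs saturated"),
    dplyr::mutate(step("evr"), step = "evr vs baseline"),
    dplyr::mutate(step("equal_slope"), step = "equal_slope vs baseline"),
    dplyr::mutate(step("equal_rho"), step = "equal_rho vs baseline")
  )

  structure(list(groups = mom, slopes = slopes, theta_tests = theta_tests,
                 theta_joint = theta_joint, correlations = correlations,
                 lr_ladder = lr_ladder,
                 baseline = if (use_hov_x) "hov_x" else "saturated",
                 base = base, config = config),
            class = "evr_report")
}

#' @export
print.evr_report <- function(x, digits = 4, ...) {
  cat("Moderation report (base category: ", x$base, ")\n\n", sep = "")
  cat("Per-group moments:\n")
  print(as.data.frame(x$groups), digits = digits, row.names = FALSE)
  cat("\nSlopes and variance ratios:\n")
  print(as.data.frame(x$slopes), digits = digits, row.names = FALSE)
  cat("\nEqual-variance-ratio (theta) tests vs base:\n")
  print(as.data.frame(x$theta_tests), digits = digits, row.names = FALSE)
  if (!is.null(x$theta_joint)) {
    cat("\nJoint Wald test over all theta contrasts (extension):\n")
    print(as.data.frame(x$theta_joint), digits = digits, row.names = FALSE)
  }
  cat("\nCorrelation contrasts (Fisher link) vs base:\n")
  print(as.data.frame(x$correlations), digits = digits, row.names = FALSE)
  cat("\nLikelihood-ratio ladder (baseline: ", x$baseline, "):\n", sep = "")
  print(as.data.frame(x$lr_ladder[, c("step", "chi2", "df", "p_value")]),
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Serialize a moderation report to JSON
#'
#' @param report An `evr_report`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param seed,version Optional reproducibility metadata embedded verbatim.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL, seed = NULL, version = NULL) {
  payload <- list(
    groups = report$groups, slopes = report$slopes,
    theta_tests = report$theta_tests, correlations = report$correlations,
    lr_ladder = report$lr_ladder, baseline = report$baseline,
    config = unclass(report$config),
    seed = seed,
    package_version = version %||%
      as.character(utils::packageVersion("evrtest"))
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
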