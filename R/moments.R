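# Per-group sufficient statistics. The multi-group bivariate-normal
# likelihood depends on the data only through (n, mean_x, mean_y, sd_x,
# sd_y, r) per group, with SDs on the maximum-likelihood (divisor n)
# convention so that moment and ML estimates coincide exactly.

#' Per-group moments of a paired bivariate sample
#'
#' Computes, for each level of the moderator, the group size, means,
#' maximum-likelihood standard deviations (divisor `n`, not `n - 1`) and the
#' Pearson correlation. These are the sufficient statistics of the
#' multi-group bivariate-normal model: every categorical fit in this package
#' is a function of them alone.
#'
#' @param data A data frame with numeric columns `x` and `y` and a moderator
#'   column (default `z`) with at least two observations per level.
#' @param moderator Name of the moderator column (string).
#' @return A tibble with one row per group: `group`, `n`, `mean_x`, `mean_y`,
#'   `sd_x`, `sd_y`, `r`.
#' @examples
#' d <- data.frame(x = rnorm(20), y = rnorm(20), z = rep(c("a", "b"), 10))
#' group_moments(d)
#' @export
group_moments <- function(data, moderator = "z") {
  check_sample(data, moderator)
  out <- dplyr::group_by(data, group = .data[[moderator]])
  out <- dplyr::summarise(
    out,
    n = dplyr::n(),
    mean_x = mean(.data$x), mean_y = mean(.data$y),
    sd_x = sqrt(mean((.data$x - mean(.data$x))^2)),
    sd_y = sqrt(mean((.data$y - mean(.data$y))^2)),
    r = mean((.data$x - mean(.data$x)) * (.data$y - mean(.data$y))),
    .groups = "drop"
  )
  out$group <- as.character(out$group)
  if (any(out$n < 4)) {
    abort(paste0("group(s) ", paste(out$group[out$n < 4], collapse = ", "),
                 " have fewer than 4 observations."))
  }
  for (v in c("sd_x", "sd_y")) {
    bad <- out[[v]] <= 0
    if (any(bad)) {
      abort(paste0("degenerate data: zero variance in ",
                   sub("sd_", "", v), " for group(s) ",
                   paste(out$group[bad], collapse = ", "), "."))
    }
  }
  out$r <- out$r / (out$sd_x * out$sd_y)
  if (any(abs(out$r) >= 1 - 1e-12)) {
    abort("degenerate data: |r| = 1 (collinear x and y) in at least one group.")
  }
  out
}

check_sample <- function(data, moderator = "z", continuous = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("x", "y", moderator)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("`data` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(data) < 1) abort("`data` has no rows.")
  for (v in c("x", "y")) {
    if (!is.numeric(data[[v]])) abort(paste0("column `", v, "` must be numeric."))
  }
  na_row <- which(!complete.cases(data[, need]))
  if (length(na_row)) {
    abort(paste0("missing values in row(s) ",
                 paste(utils::head(na_row, 5), collapse = ", "),
                 "; remove or impute them explicitly."))
  }
  if (continuous) {
    if (!is.numeric(data[[moderator]])) {
      abort("continuous moderator column must be numeric.")
    }
    if (var(data[[moderator]]) == 0) abort("moderator has zero variance.")
  }
  invisible(data)
}

# moments tibble -> list of vectors used by the likelihood internals
moments_stats <- function(mom) {
  list(n = mom$n, mx = mom$mean_x, my = mom$mean_y,
       S20 = mom$sd_x^2, S02 = mom$sd_y^2,
       S11 = mom$r * mom$sd_x * mom$sd_y, r = mom$r,
       group = mom$group)
}

#' Monte-Carlo standard error of an estimated proportion
#'
#' @param p Estimated proportion(s) in \[0, 1\].
#' @param reps Number of Monte-Carlo replicates (>= 1).
#' @return `sqrt(p * (1 - p) / reps)`.
#' @examples
#' mc_se(0.05, 20000)
#' @export
mc_se <- function(p, reps) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  if (any(reps < 1)) abort("`reps` must be >= 1.")
  sqrt(p * (1 - p) / reps)
}
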