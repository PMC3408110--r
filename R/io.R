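#' Read a paired-sample dataset from CSV
#'
#' Expects a comma-delimited UTF-8 file with header columns `x`, `y`, `z`.
#' `x` and `y` must be numeric; `z` is kept as a character label for a
#' categorical moderator or parsed as numeric for a continuous one.
#' Missing values are an explicit error (nothing is dropped silently).
#'
#' @param path File path.
#' @param kind `"categorical"` or `"continuous"`.
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
read_dataset <- function(path, kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(raw) == 0) abort("empty dataset.")
  miss <- setdiff(c("x", "y", "z"), names(raw))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (v in c("x", "y")) {
    if (!is.numeric(raw[[v]])) {
      abort(paste0("column `", v, "` is not numeric."))
    }
  }
  if (kind == "continuous") {
    z <- suppressWarnings(as.numeric(raw$z))
    if (any(is.na(z) & !is.na(raw$z))) abort("column `z` is not numeric.")
    raw$z <- z
  } else {
    raw$z <- as.character(raw$z)
  }
  d <- as_tibble(raw[, c("x", "y", "z")])
  check_sample(d, "z", continuous = kind == "continuous")
  d
}

#' Read or write a simulation scenario file
#'
#' Scenario files are JSON or YAML (by file extension) with keys `kind`
#' (`"categorical"` or `"continuous"`), `groups` (categorical: lists `n`,
#' `var_x`, `var_y`, `cov_xy`) or `coefs` and `N` (continuous: lists
#' `delta_x`, `delta_y`, `delta_r`, optionally `gamma_x`, `gamma_y`),
#' plus optional `skew` (lambda), `seed` and `label`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return [read_scenario()] returns an `evr_scenario`;
#'   [write_scenario()] returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(raw$kind)) abort("scenario file lacks a `kind` key.")
  lambda <- raw$skew %||% 0
  if (raw$kind == "categorical") {
    g <- raw$groups
    scenario_categorical(n = as.numeric(g$n), var_x = as.numeric(g$var_x),
                         var_y = as.numeric(g$var_y),
                         cov_xy = as.numeric(g$cov_xy),
                         lambda = lambda, label = raw$label,
                         seed = raw$seed)
  } else if (raw$kind == "continuous") {
    scenario_continuous(N = raw$N, coefs = lapply(raw$coefs, as.numeric),
                        lambda = lambda, label = raw$label, seed = raw$seed)
  } else {
    abort(paste0("unknown scenario kind: ", raw$kind))
  }
}

#' @rdname read_scenario
#' @param scenario An `evr_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "evr_scenario"))
  payload <- list(kind = scenario$kind, skew = scenario$lambda,
                  seed = scenario$seed, label = scenario$label)
  if (scenario$kind == "categorical") {
    g <- scenario$groups
    payload$groups <- list(n = g$n, var_x = g$var_x, var_y = g$var_y,
                           cov_xy = g$cov_xy)
  } else {
    payload$coefs <- scenario$coefs
    payload$N <- scenario$N
  }
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path, precision = 15)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Write a dataset to CSV
#'
#' @param data Data frame with columns `x`, `y`, `z`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data[, c("x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}
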