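# Row-wise bivariate-normal likelihood with link submodels. The categorical
# fitting code works from sufficient statistics (see fit-categorical.R); this
# general engine backs the continuous-moderator fit and serves as the exact
# reference the sufficient-statistic path is tested against.

#' Build design matrices for the three submodels
#'
#' Constructs the model specification shared by the mean, log-SD and
#' Fisher-link correlation submodels. For a categorical moderator the design
#' is an intercept plus one indicator column per non-base level; for a
#' continuous moderator it is an intercept plus the moderator itself.
#'
#' @param moderator Vector of moderator values (labels or numeric).
#' @param kind `"categorical"` or `"continuous"`.
#' @param base Base category label (categorical only; defaults to the first
#'   level in order of appearance).
#' @return An object of class `evr_model_spec`: a list with design matrices
#'   `Zm`, `Zx`, `Zy`, `Zr` (all identical by default, per-submodel
#'   overrides allowed downstream), the coefficient names, and the coding.
#' @export
evr_model_spec <- function(moderator, kind = c("categorical", "continuous"),
                           base = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    lev <- unique(as.character(moderator))
    base <- base %||% lev[1]
    if (!base %in% lev) abort(paste0("base category '", base, "' not present."))
    lev <- c(base, setdiff(lev, base))
    Z <- cbind(1, vapply(lev[-1], function(l) as.numeric(moderator == l),
                         numeric(length(moderator))))
    colnames(Z) <- c("(base)", lev[-1])
  } else {
    if (!is.numeric(moderator)) abort("continuous moderator must be numeric.")
    Z <- cbind(1, moderator)
    colnames(Z) <- c("(intercept)", "z")
  }
  structure(list(Zm = Z, Zx = Z, Zy = Z, Zr = Z,
                 kind = kind, base = if (kind == "categorical") base else NULL,
                 levels = if (kind == "categorical") lev else NULL),
            class = "evr_model_spec")
}

spec_dims <- function(spec) {
  c(pm = ncol(spec$Zm), px = ncol(spec$Zx),
    py = ncol(spec$Zy), pr = ncol(spec$Zr))
}

par_names <- function(spec) {
  d <- spec_dims(spec)
  c(paste0("gamma_x.", colnames(spec$Zm)),
    paste0("gamma_y.", colnames(spec$Zm)),
    paste0("delta_x.", colnames(spec$Zx)),
    paste0("delta_y.", colnames(spec$Zy)),
    paste0("delta_r.", colnames(spec$Zr)))
}

pack_params <- function(params, spec) {
  if (is.numeric(params)) return(as.numeric(params))
  with(params, c(gamma_x, gamma_y, delta_x, delta_y, delta_r))
}

unpack_params <- function(par, spec) {
  d <- spec_dims(spec)
  i <- cumsum(c(d[["pm"]], d[["pm"]], d[["px"]], d[["py"]], d[["pr"]]))
  list(gamma_x = par[1:i[1]],
       gamma_y = par[(i[1] + 1):i[2]],
       delta_x = par[(i[2] + 1):i[3]],
       delta_y = par[(i[3] + 1):i[4]],
       delta_r = par[(i[4] + 1):i[5]])
}

#' Bivariate-normal log-likelihood under the link submodels
#'
#' Evaluates the exact log-likelihood of paired observations whose per-row
#' means, log standard deviations and Fisher-linked correlation are linear
#' in the design matrices of `spec`. Inside the likelihood the correlation
#' is clamped to |rho| <= 1 - 1e-10 to guard the boundary.
#'
#' @param params Either a flat numeric vector `c(gamma_x, gamma_y, delta_x,
#'   delta_y, delta_r)` or a named list with those elements.
#' @param spec An [evr_model_spec()].
#' @param data Data frame with columns `x` and `y` (rows matching the design).
#' @return The log-likelihood (a scalar).
#' @export
bvn_loglik <- function(params, spec, data) {
  par <- pack_params(params, spec)
  if (any(!is.finite(par))) abort("non-finite parameters.")
  ll <- -cpp_bvn_nll(par, spec$Zm, spec$Zx, spec$Zy, spec$Zr, data$x, data$y)
  if (!is.finite(ll) || ll <= -1e10) {
    abort("log-likelihood is not finite at these parameters.")
  }
  ll
}

nll_fn <- function(spec, data) {
  function(par) cpp_bvn_nll(par, spec$Zm, spec$Zx, spec$Zy, spec$Zr,
                            data$x, data$y)
}

nll_gr <- function(spec, data) {
  function(par) cpp_bvn_nll_grad(par, spec$Zm, spec$Zx, spec$Zy, spec$Zr,
                                 data$x, data$y)
}

# Hessian of a function via central differences of its gradient.
fd_hessian <- function(gr, par, eps = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- eps * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (gr(up) - gr(dn)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Observed-information covariance of the coefficient estimates
#'
#' Inverts the negative Hessian (observed information) of the
#' log-likelihood at a fitted parameter vector. The Hessian is obtained by
#' central differences of the analytic gradient.
#'
#' @inheritParams bvn_loglik
#' @return A symmetric covariance matrix over all free coefficients, with
#'   dimnames from the design columns.
#' @export
coefficient_covariance <- function(params, spec, data) {
  par <- pack_params(params, spec)
  H <- fd_hessian(nll_gr(spec, data), par)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) {
    abort(paste0("information matrix is singular; check for collinear design ",
                 "columns or a boundary estimate (|rho| near 1)."))
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(par_names(spec), par_names(spec))
  V
}
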