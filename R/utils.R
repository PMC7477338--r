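#' @importFrom rlang .data %||%
#' @importFrom stats optim median sd quantile rpois runif rlnorm setNames
#' @importFrom utils head tail
NULL

# Multi-start Nelder-Mead minimization.
#
# `starts` is a list of numeric start vectors; each is polished with
# stats::optim(method = "Nelder-Mead").  The best final objective wins,
# ties broken by first-found.  Tolerances mirror fminsearch-like defaults.
multistart_nm <- function(objective, starts, maxit = 2000, reltol = 1e-10,
                          polish = 5) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  # Nelder-Mead restarts from the incumbent: rebuilding the simplex at the
  # current optimum escapes premature shrinkage in higher dimensions
  for (k in seq_len(polish)) {
    fit <- tryCatch(
      stats::optim(best$par, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) break
    improved <- fit$value < best$value - 1e-12
    if (fit$value < best$value) best <- fit
    if (!improved) break
  }
  best
}

# Fraction of variance in `observed` explained by `fitted`:
# 1 - SSE / total sum of squares about the mean.  Can be negative; NA when
# the observations carry no variance.
ev_fraction <- function(fitted, observed) {
  stopifnot(length(fitted) == length(observed), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((fitted - observed)^2) / ss_tot
}

# Small-sample adjustment of explained variance for p free parameters on
# N observations (same algebra as adjusted R^2).
adjust_ev <- function(ev, n_obs, n_par) {
  if (is.na(ev)) return(NA_real_)
  1 - (1 - ev) * (n_obs - 1) / (n_obs - n_par - 1)
}
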