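#' Naka-Rushton contrast-response function
#'
#' `R(c) = r_max * c^n / (sigma^n + c^n)`: a saturating response that is 0
#' at zero contrast, reaches half of `r_max` at `c = sigma` (the
#' semisaturation constant), and approaches `r_max` at high contrast.
#' Monotone increasing in `c` whenever `r_max > 0`.
#'
#' @param c Michelson contrast, percent (vectorised, >= 0).
#' @param r_max Response ceiling, spikes/s.
#' @param sigma Semisaturation constant, percent contrast (> 0).
#' @param n Exponent (> 0).
#' @return Response in spikes/s.
#' @export
naka_rushton_value <- function(c, r_max, sigma, n) {
  cn <- c^n
  r_max * cn / (sigma^n + cn)
}

#' Fit a Naka-Rushton contrast-response function
#'
#' Minimizes the summed squared error plus a very small penalty
#' `penalty_weight * ((sigma/100)^2 + (n - 2)^2)` that breaks the
#' degeneracy of nearly linear data (where `sigma` and `r_max` can grow
#' without bound at fixed ratio).  Sigma is normalized by 100% contrast
#' inside the penalty so both terms are order 1; the weight is relative
#' to an SSE measured in (spikes/s)^2.  Multi-start Nelder-Mead over the
#' grid `n in {1, 2, 4}` x `sigma in {20, 50, 80}` with `r_max` started at
#' the largest observed rate.
#'
#' @param mean_rates Mean evoked rates, spikes/s, one per contrast.
#' @param contrasts Contrasts, percent (>= 3 values).
#' @param penalty_weight Degeneracy-penalty weight (default 1e-4; 0
#'   disables the penalty).
#' @return An `nr_fit` object with parameters, `sse`,
#'   `explained_variance`, `c50` and `dynamic_range` (both `NA` when the
#'   fitted curve is not usable for root-finding, e.g. `r_max <= 0`).
#' @export
fit_naka_rushton <- function(mean_rates, contrasts, penalty_weight = 1e-4) {
  stopifnot(length(mean_rates) == length(contrasts), length(contrasts) >= 3,
            all(contrasts >= 0), penalty_weight >= 0)
  r <- as.numeric(mean_rates)
  cc <- as.numeric(contrasts)
  objective <- function(p) {
    rm <- p[1]; sg <- abs(p[2]); en <- abs(p[3])
    if (sg < 1e-8 || en < 1e-8) return(1e12)
    pred <- naka_rushton_value(cc, rm, sg, en)
    if (any(!is.finite(pred))) return(1e12)
    sum((pred - r)^2) + penalty_weight * ((sg / 100)^2 + (en - 2)^2)
  }
  r0 <- max(r, 0.5)
  starts <- list()
  for (en in c(1, 2, 4)) for (sg in c(20, 50, 80)) {
    starts[[length(starts) + 1]] <- c(r_max = r0, sigma = sg, n = en)
  }
  best <- multistart_nm(objective, starts)
  fit <- list(
    r_max = best$par[[1]], sigma = abs(best$par[[2]]), n = abs(best$par[[3]]),
    sse = best$value, penalty_weight = penalty_weight,
    contrasts = cc, observed = r
  )
  fit$fitted <- naka_rushton_value(cc, fit$r_max, fit$sigma, fit$n)
  fit$explained_variance <- ev_fraction(fit$fitted, r)
  fit$degenerate <- fit$r_max <= 0 ||
    naka_rushton_value(100, fit$r_max, fit$sigma, fit$n) <= 0
  class(fit) <- "nr_fit"
  fit$c50 <- c50(fit)
  fit$dynamic_range <- dynamic_range(fit)
  fit
}

#' @export
print.nr_fit <- function(x, ...) {
  cat(sprintf("Naka-Rushton fit: r_max %.3g spikes/s, sigma %.3g%%, n %.3g\n",
              x$r_max, x$sigma, x$n))
  cat(sprintf("  EV %.3f, C50 %s%%, dynamic range %s%%\n",
              x$explained_variance, formatC(x$c50, digits = 4),
              formatC(x$dynamic_range, digits = 4)))
  invisible(x)
}

# Contrast at which the fitted curve reaches fraction q of its
# (extrapolated) 100%-contrast response, by bisection root-finding.
# Extrapolation beyond the measured maximum up to `search_max` is allowed;
# NA when the target is unreachable or the fit is degenerate.
quartile_contrast <- function(fit, q, search_max = 1000) {
  if (isTRUE(fit$degenerate)) return(NA_real_)
  r100 <- naka_rushton_value(100, fit$r_max, fit$sigma, fit$n)
  if (!is.finite(r100) || r100 <= 0) return(NA_real_)
  target <- q * r100
  g <- function(c) naka_rushton_value(c, fit$r_max, fit$sigma, fit$n) - target
  lo <- 1e-9
  if (g(lo) > 0 || g(search_max) < 0) return(NA_real_)
  stats::uniroot(g, lower = lo, upper = search_max, tol = 1e-9)$root
}

#' C50 of a Naka-Rushton fit
#'
#' The interpolated contrast at which the fitted response is half the
#' response at 100% contrast, found by root-finding on the fitted curve;
#' the search extends beyond the measured contrast range (the 100%
#' reference itself is an extrapolation when the protocol stops at 90%).
#'
#' @param fit An `nr_fit` object.
#' @param search_max Upper bound of the root search, percent contrast.
#' @return C50 in percent contrast, or `NA` for degenerate fits.
#' @export
c50 <- function(fit, search_max = 1000) {
  quartile_contrast(fit, 0.5, search_max)
}

#' Dynamic range of a Naka-Rushton fit
#'
#' The difference between the contrasts that evoke three quarters and one
#' quarter of the fitted 100%-contrast response.  A response linear in
#' contrast has a dynamic range of 50%; a steep sigmoid has a much
#' smaller one.
#'
#' @inheritParams c50
#' @return Dynamic range in percent contrast, or `NA` when either
#'   quartile is unreachable within `search_max`.
#' @export
dynamic_range <- function(fit, search_max = 1000) {
  hi <- quartile_contrast(fit, 0.75, search_max)
  lo <- quartile_contrast(fit, 0.25, search_max)
  if (is.na(hi) || is.na(lo)) return(NA_real_)
  hi - lo
}

#' Fit contrast-response functions for every unit and temporal frequency
#'
#' Runs [fit_naka_rushton()] independently per unit and per temporal
#' frequency on a condition-response table.
#'
#' @param responses A `condition_response` tibble.
#' @param tf_hz Frequencies to fit (default: all present).
#' @param penalty_weight Passed to [fit_naka_rushton()].
#' @return A tibble: `unit_id`, `tf_hz`, `r_max`, `sigma`, `n`,
#'   `explained_variance`, `c50`, `dynamic_range`.
#' @export
fit_contrast_tuning <- function(responses, tf_hz = NULL,
                                penalty_weight = 1e-4) {
  tfs <- tf_hz %||% sort(unique(responses$tf_hz))
  sub <- dplyr::filter(tibble::as_tibble(responses), .data$tf_hz %in% tfs)
  sub |>
    dplyr::group_by(.data$unit_id, .data$tf_hz) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_naka_rushton(d$mean_rate, d$contrast_pct,
                              penalty_weight = penalty_weight)
      tibble::tibble(
        r_max = fit$r_max, sigma = fit$sigma, n = fit$n,
        explained_variance = fit$explained_variance,
        c50 = fit$c50, dynamic_range = fit$dynamic_range
      )
    }) |>
    dplyr::ungroup()
}
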