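#' Population response surface
#'
#' Averages the condition-response matrices of all units into one
#' population surface per (temporal frequency, contrast) cell: cell-wise
#' mean across units with the standard error across units.  The mean is
#' used rather than the raw sum of unit responses; the two differ by the
#' constant unit count, which the models absorb into their amplitude.
#'
#' @param responses A `condition_response` tibble covering a common grid.
#' @return A tibble of class `population_surface` with columns `tf_hz`,
#'   `contrast_pct`, `mean_rate`, `sem`; the unit count is in attribute
#'   `n_units`.
#' @export
population_surface <- function(responses) {
  r <- tibble::as_tibble(responses)
  per_unit <- r |> dplyr::count(.data$unit_id)
  if (length(unique(per_unit$n)) != 1)
    stop("units do not share a common (frequency, contrast) grid",
         call. = FALSE)
  out <- r |>
    dplyr::group_by(.data$tf_hz, .data$contrast_pct) |>
    dplyr::summarise(
      mean_rate = mean(.data$mean_rate),
      sem = if (dplyr::n() > 1) sd(.data$mean_rate) / sqrt(dplyr::n()) else 0,
      n_units = dplyr::n(),
      .groups = "drop"
    )
  if (length(unique(out$n_units)) != 1)
    stop("units do not share a common (frequency, contrast) grid",
         call. = FALSE)
  attr(out, "n_units") <- out$n_units[1]
  out$n_units <- NULL
  class(out) <- c("population_surface", class(out))
  out
}

# Evaluate the drive tuning T(f) of a normalization parameter set:
# difference-of-Gaussians parameters (t_gain_e fixed at 1 in fits) or a
# free per-frequency table `t_values` named by frequency.
eval_drive_t <- function(params, f) {
  if (!is.null(params$t_values)) {
    key <- match(round(f, 9), round(as.numeric(names(params$t_values)), 9))
    if (anyNA(key))
      stop("free-T drive is only defined on the fitted frequency grid",
           call. = FALSE)
    unname(params$t_values[key])
  } else {
    dog_value(f, params$t_gain_e %||% 1, params$t_width_e,
              params$t_gain_i, params$t_width_i)
  }
}

#' Evaluate a normalization-model response surface
#'
#' Three variants of the population model built on a drive tuning `T(f)`:
#' \describe{
#'   \item{static}{`R_m c^n / (sigma^n / T(f) + c^n)` — a Naka-Rushton
#'     function of contrast whose shape depends on frequency only through
#'     `T(f)`.}
#'   \item{shunting}{the static form with `sigma` replaced by
#'     `sigma + tau f`, letting the saturation constant grow with stimulus
#'     frequency.}
#'   \item{linear}{`R_m c T(f)` — no contrast saturation at all.}
#' }
#'
#' @param variant `"static"`, `"shunting"` or `"linear"`.
#' @param params Named list: `r_max`, `sigma`, `n`, `tau` (shunting), and
#'   either d.o.G. drive parameters (`t_gain_e`, `t_width_e`, `t_gain_i`,
#'   `t_width_i`) or a named `t_values` vector for a free per-frequency
#'   drive.
#' @param f Temporal frequency, Hz.
#' @param c Michelson contrast, percent.
#' @return Response in spikes/s (vectorised over `f` and `c` jointly).
#' @export
model_surface <- function(variant = c("static", "shunting", "linear"),
                          params, f, c) {
  variant <- match.arg(variant)
  tt <- eval_drive_t(params, f)
  if (variant == "linear") return(params$r_max * c * tt)
  sg <- if (variant == "shunting") params$sigma + params$tau * f else params$sigma
  cn <- c^params$n
  params$r_max * cn / (sg^params$n / tt + cn)
}

n_free_params <- function(variant, t_mode) {
  if (t_mode == "dog") {
    switch(variant, static = 7, shunting = 8, linear = 5)
  } else {
    switch(variant, static = 8, shunting = 9,
           stop("free-T mode supports static and shunting variants only",
                call. = FALSE))
  }
}

# Internal engine shared by fit_population() and fit_unit(): fit one
# normalization variant to a 30-cell (f, c) surface by multi-start
# Nelder-Mead in log space.
fit_norm_engine <- function(tf_hz, contrast_pct, rate, variant, t_mode,
                            label = "population") {
  freqs <- sort(unique(tf_hz))
  f <- tf_hz; cc <- contrast_pct; y <- rate
  big <- 1e12

  if (t_mode == "dog") {
    unpack <- switch(variant,
      static = function(p) list(
        n = exp(p[1]), sigma = exp(p[2]), r_max = exp(p[3]),
        t_gain_e = 1, t_gain_i = exp(p[4]),
        t_width_e = exp(p[5]), t_width_i = exp(p[6])),
      shunting = function(p) list(
        n = exp(p[1]), sigma = exp(p[2]), r_max = exp(p[3]),
        t_gain_e = 1, t_gain_i = exp(p[4]),
        t_width_e = exp(p[5]), t_width_i = exp(p[6]), tau = abs(p[7])),
      linear = function(p) list(
        r_max = exp(p[1]), t_gain_e = 1, t_gain_i = exp(p[2]),
        t_width_e = exp(p[3]), t_width_i = exp(p[4]))
    )
  } else {
    # free T: sigma is not identifiable separately from the scale of T
    # and is pinned at 1; T is one positive value per grid frequency
    unpack <- switch(variant,
      static = function(p) list(
        n = exp(p[1]), sigma = 1, r_max = exp(p[2]),
        t_values = setNames(exp(p[2 + seq_along(freqs)]), freqs)),
      shunting = function(p) list(
        n = exp(p[1]), sigma = exp(p[2]), r_max = exp(p[3]), tau = abs(p[4]),
        t_values = setNames(exp(p[4 + seq_along(freqs)]), freqs))
    )
  }

  objective <- function(p) {
    params <- unpack(p)
    if (t_mode == "dog") {
      tt <- eval_drive_t(params, freqs)
      if (any(!is.finite(tt)) || any(tt <= 1e-12)) return(big)
    }
    pred <- tryCatch(model_surface(variant, params, f, cc),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(big)
    sum((pred - y)^2)
  }

  # informed drive-shape start: d.o.G. fit to the top-contrast frequency
  # profile, normalized to unit peak
  top <- max(cc)
  prof <- vapply(freqs, function(fr) mean(y[f == fr & cc == top]), double(1))
  shape <- tryCatch(fit_dog(prof, freqs, n_starts = 4), error = function(e) NULL)
  if (!is.null(shape) && shape$r_max > 0) {
    t0 <- list(gi = max(shape$gain_i / max(shape$gain_e, 1e-6), 1e-3),
               we = shape$width_e, wi = min(shape$width_i, 0.9 * shape$width_e))
  } else {
    t0 <- list(gi = 0.6, we = 5, wi = 1.3)
  }
  rm0 <- max(max(y), 0.5)

  starts <- list()
  if (t_mode == "dog") {
    if (variant == "linear") {
      for (sc in c(1, 0.3)) {
        starts[[length(starts) + 1]] <-
          c(log(rm0 / (top * sc)), log(t0$gi), log(t0$we), log(t0$wi))
      }
    } else {
      for (n0 in c(1, 1.8)) for (sg0 in c(5, 30)) {
        s <- c(log(n0), log(sg0), log(1.5 * rm0), log(t0$gi),
               log(t0$we), log(t0$wi))
        if (variant == "shunting") s <- c(s, 0.05)
        starts[[length(starts) + 1]] <- s
      }
    }
  } else {
    tv0 <- pmax(prof / max(prof), 1e-3)
    for (n0 in c(1, 1.8)) for (a0 in c(3, 20)) {
      # A_j = sigma^n / T_j ~ a0 / shape
      if (variant == "static") {
        starts[[length(starts) + 1]] <-
          c(log(n0), log(1.5 * rm0), log(tv0 / a0))
      } else {
        starts[[length(starts) + 1]] <-
          c(log(n0), log(1), log(1.5 * rm0), 0.01, log(tv0 / a0))
      }
    }
    if (variant == "static") {
      # cross-start: the d.o.G.-constrained optimum mapped into free T
      sd <- fit_norm_engine(tf_hz, contrast_pct, rate, "static", "dog", label)
      tmap <- pmax(eval_drive_t(sd$params, freqs), 1e-8) /
        sd$params$sigma^sd$params$n
      starts[[length(starts) + 1]] <-
        c(log(sd$params$n), log(sd$params$r_max), log(tmap))
    } else {
      # nested start: the static free-T optimum with tau = 0
      st <- fit_norm_engine(tf_hz, contrast_pct, rate, "static", "free", label)
      starts[[length(starts) + 1]] <-
        c(log(st$params$n), log(1), log(st$params$r_max), 0,
          log(st$params$t_values))
    }
  }
  if (variant == "shunting" && t_mode == "dog") {
    st <- fit_norm_engine(tf_hz, contrast_pct, rate, "static", "dog", label)
    starts[[length(starts) + 1]] <- c(
      log(st$params$n), log(st$params$sigma), log(st$params$r_max),
      log(st$params$t_gain_i), log(st$params$t_width_e),
      log(st$params$t_width_i), 0)
  }

  best <- multistart_nm(objective, starts, maxit = 4000)
  params <- unpack(best$par)
  fitted <- model_surface(variant, params, f, cc)
  ev <- ev_fraction(fitted, y)
  p_count <- n_free_params(variant, t_mode)
  fit <- list(
    variant = variant, t_mode = t_mode, label = label,
    params = params, sse = best$value,
    explained_variance = ev,
    adjusted_explained_variance = adjust_ev(ev, length(y), p_count),
    n_obs = length(y), n_par = p_count,
    surface = tibble::tibble(tf_hz = f, contrast_pct = cc,
                             observed = y, fitted = fitted),
    converged = best$value < big
  )
  class(fit) <- "norm_fit"
  fit
}

#' Fit the normalization model to a population surface
#'
#' Fits one model variant (see [model_surface()]) to the full
#' (frequency, contrast) population surface by minimizing the summed
#' squared difference between measured and model values over all cells,
#' with multi-start Nelder-Mead in log-parameter space.  The drive `T(f)`
#' is a difference of Gaussians by default (`t_mode = "dog"`, excitatory
#' gain fixed at 1 to remove the amplitude degeneracy with `r_max` and
#' `sigma`); `t_mode = "free"` instead fits one positive drive value per
#' grid frequency, the parameterisation in which the shunting and static
#' variants are exactly equivalent.
#'
#' @param surface A `population_surface` tibble (complete grid).
#' @param variant `"static"`, `"shunting"` or `"linear"`.
#' @param t_mode `"dog"` or `"free"` (free supports static/shunting only).
#' @return A `norm_fit` object: `params`, `sse`, `explained_variance`,
#'   `adjusted_explained_variance`, and a `surface` tibble of observed
#'   and fitted values.
#' @export
fit_population <- function(surface,
                           variant = c("static", "shunting", "linear"),
                           t_mode = c("dog", "free")) {
  variant <- match.arg(variant)
  t_mode <- match.arg(t_mode)
  stopifnot(all(c("tf_hz", "contrast_pct", "mean_rate") %in% names(surface)))
  fit_norm_engine(surface$tf_hz, surface$contrast_pct, surface$mean_rate,
                  variant, t_mode, label = "population")
}

#' Fit the normalization model to a single unit
#'
#' Same machinery as [fit_population()], applied to one unit's
#' condition-response matrix; the drive `T(f)` is refit per unit.  The
#' adjusted explained variance applies the standard small-sample
#' correction with N grid cells and the variant's free-parameter count.
#'
#' @param unit_responses The rows of a `condition_response` tibble for a
#'   single unit.
#' @inheritParams fit_population
#' @return A `norm_fit` object.
#' @export
fit_unit <- function(unit_responses,
                     variant = c("static", "shunting", "linear"),
                     t_mode = c("dog", "free")) {
  variant <- match.arg(variant)
  t_mode <- match.arg(t_mode)
  stopifnot(length(unique(unit_responses$unit_id)) == 1)
  fit_norm_engine(unit_responses$tf_hz, unit_responses$contrast_pct,
                  unit_responses$mean_rate, variant, t_mode,
                  label = paste0("unit ", unit_responses$unit_id[1]))
}

#' @export
print.norm_fit <- function(x, ...) {
  cat(sprintf("normalization fit (%s, T %s, %s)\n", x$variant, x$t_mode,
              x$label))
  if (!is.null(x$params$sigma))
    cat(sprintf("  sigma %.3g%%  n %.3g", x$params$sigma, x$params$n))
  if (!is.null(x$params$tau)) cat(sprintf("  tau %.3g /Hz", x$params$tau))
  cat(sprintf("  r_max %.3g spikes/s\n", x$params$r_max))
  cat(sprintf("  EV %.4f (adjusted %.4f, %d cells, %d parameters)\n",
              x$explained_variance, x$adjusted_explained_variance,
              x$n_obs, x$n_par))
  invisible(x)
}

#' Compare normalization-model variants across units
#'
#' Fits the requested variants independently to every unit and tabulates
#' explained variance and its parameter-adjusted form, the basis of the
#' linear-vs-normalization and static-vs-shunting model comparisons.
#'
#' @param responses A `condition_response` tibble.
#' @param variants Character vector of variants to fit.
#' @param t_mode Drive parameterisation, as in [fit_population()].
#' @return A tibble: `unit_id`, `variant`, `sigma`, `n`, `tau`,
#'   `explained_variance`, `adjusted_explained_variance`.
#' @export
compare_unit_models <- function(responses,
                                variants = c("linear", "static", "shunting"),
                                t_mode = "dog") {
  r <- tibble::as_tibble(responses)
  purrr::map_dfr(sort(unique(r$unit_id)), function(u) {
    d <- dplyr::filter(r, .data$unit_id == u)
    purrr::map_dfr(variants, function(v) {
      fit <- fit_unit(d, v, t_mode)
      tibble::tibble(
        unit_id = u, variant = v,
        sigma = fit$params$sigma %||% NA_real_,
        n = fit$params$n %||% NA_real_,
        tau = fit$params$tau %||% NA_real_,
        explained_variance = fit$explained_variance,
        adjusted_explained_variance = fit$adjusted_explained_variance
      )
    })
  })
}

#' Contrast invariance of the response optimum of a static fit
#'
#' For the static normalization model the frequency of peak response is
#' the peak of the drive `T(f)` at every contrast: the model's response
#' derivative in frequency is proportional to `dT/df` through the
#' strictly positive factor `sigma^n c^n / (sigma^n + c^n T(f))^2`.  This
#' check finds the argmax of the fitted surface on a dense frequency grid
#' at each contrast and reports the spread, and compares the numerical
#' frequency derivative of the surface with that closed form.
#'
#' @param fit A static `norm_fit` with d.o.G. drive.
#' @param contrasts Contrasts to probe (default: the fitted ones).
#' @param f_range,resolution Dense argmax grid (default 0.05--32 Hz at
#'   1e-2 Hz).
#' @return A list: `argmax` tibble (contrast, f_peak), `max_deviation`
#'   (Hz, max pairwise argmax spread), `derivative` tibble comparing
#'   numeric and closed-form dP/df, `max_derivative_relerr`.
#' @export
opt_invariance_check <- function(fit, contrasts = NULL,
                                 f_range = DOG_F_RANGE, resolution = 1e-2) {
  stopifnot(inherits(fit, "norm_fit"), fit$variant == "static",
            fit$t_mode == "dog")
  contrasts <- contrasts %||% sort(unique(fit$surface$contrast_pct))
  fs <- seq(f_range[1], f_range[2], by = resolution)
  argmax <- purrr::map_dbl(contrasts, function(cc) {
    fs[which.max(model_surface("static", fit$params, fs, cc))]
  })
  p <- fit$params
  dT <- function(f) {
    -f / p$t_width_e^2 * (p$t_gain_e %||% 1) * exp(-0.5 * f^2 / p$t_width_e^2) +
      f / p$t_width_i^2 * p$t_gain_i * exp(-0.5 * f^2 / p$t_width_i^2)
  }
  h <- 1e-5
  deriv <- purrr::map_dfr(contrasts, function(cc) {
    f0 <- seq(0.5, 16, length.out = 7)
    numeric_d <- (model_surface("static", p, f0 + h, cc) -
                    model_surface("static", p, f0 - h, cc)) / (2 * h)
    tt <- eval_drive_t(p, f0)
    closed <- p$r_max * p$sigma^p$n * cc^p$n /
      (p$sigma^p$n + cc^p$n * tt)^2 * dT(f0)
    tibble::tibble(contrast_pct = cc, tf_hz = f0,
                   numeric = numeric_d, closed_form = closed)
  })
  relerr <- abs(deriv$numeric - deriv$closed_form) /
    pmax(abs(deriv$closed_form), 1e-12)
  list(
    argmax = tibble::tibble(contrast_pct = contrasts, f_peak = argmax),
    max_deviation = max(argmax) - min(argmax),
    derivative = deriv,
    max_derivative_relerr = max(relerr)
  )
}

#' High/low frequency response ratio across contrast
#'
#' The ratio of the response at a high frequency over the response at a
#' low frequency, per contrast, with the slope of its linear regression
#' on contrast.  For a model linear in contrast the ratio is exactly
#' constant; for the static normalization model it is near-constant when
#' `sigma^n / T(f)` dominates `c^n`.  A strongly contrast-dependent ratio
#' in data that the fitted model cannot produce is the signature
#' diagnostic of normalization-model failure at low frequencies.
#'
#' @param x A `population_surface` / `condition_response`-like tibble
#'   with `tf_hz`, `contrast_pct`, `mean_rate`, or a `norm_fit` (whose
#'   fitted surface is then used).
#' @param f_hi,f_lo The two frequencies, Hz (defaults 8 and 0.5); both
#'   must be on the grid.
#' @return A tibble (`contrast_pct`, `ratio`) with attributes `slope`
#'   (per percent contrast) and `slope_test` (the non-zero slope test).
#' @export
ratio_diagnostic <- function(x, f_hi = 8, f_lo = 0.5) {
  if (inherits(x, "norm_fit")) {
    d <- x$surface
    d$mean_rate <- d$fitted
  } else {
    d <- tibble::as_tibble(x)
  }
  stopifnot(f_hi %in% d$tf_hz, f_lo %in% d$tf_hz)
  hi <- d[d$tf_hz == f_hi, c("contrast_pct", "mean_rate")]
  lo <- d[d$tf_hz == f_lo, c("contrast_pct", "mean_rate")]
  m <- dplyr::inner_join(hi, lo, by = "contrast_pct",
                         suffix = c("_hi", "_lo")) |>
    dplyr::arrange(.data$contrast_pct)
  if (any(m$mean_rate_lo == 0))
    stop("zero response at the low frequency; ratio undefined", call. = FALSE)
  out <- tibble::tibble(contrast_pct = m$contrast_pct,
                        ratio = m$mean_rate_hi / m$mean_rate_lo)
  st <- nonzero_slope_test(out$contrast_pct, out$ratio)
  attr(out, "slope") <- st$estimate
  attr(out, "slope_test") <- st
  out
}

#' Relative response at one frequency across contrast
#'
#' The response at frequency `f` divided by the maximum response over all
#' frequencies, separately at each contrast.  Under the static
#' normalization model this fraction is constantly 1 at the optimal
#' frequency and strictly increases with contrast at any suboptimal
#' frequency.
#'
#' @inheritParams ratio_diagnostic
#' @param f Frequency on the grid, Hz.
#' @return A tibble: `contrast_pct`, `relative` (fraction of the
#'   per-contrast maximum).
#' @export
relative_response <- function(x, f) {
  if (inherits(x, "norm_fit")) {
    d <- x$surface
    d$mean_rate <- d$fitted
  } else {
    d <- tibble::as_tibble(x)
  }
  stopifnot(f %in% d$tf_hz)
  out <- d |>
    dplyr::group_by(.data$contrast_pct) |>
    dplyr::summarise(
      relative = {
        mx <- max(.data$mean_rate)
        if (mx <= 0) NA_real_ else .data$mean_rate[.data$tf_hz == f][1] / mx
      },
      .groups = "drop"
    )
  out
}
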