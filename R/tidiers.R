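#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per fitted parameter (`term`, `estimate`);
#' `glance()` returns a one-row goodness-of-fit summary.
#'
#' @param x A `dog_fit`, `nr_fit` or `norm_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tfnorm_tidiers
NULL

#' @rdname tfnorm_tidiers
#' @method tidy dog_fit
#' @export
tidy.dog_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gain_e", "width_e", "gain_i", "width_i"),
    estimate = c(x$gain_e, x$width_e, x$gain_i, x$width_i)
  )
}

#' @rdname tfnorm_tidiers
#' @method glance dog_fit
#' @export
glance.dog_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse %||% x$residual, accepted = x$accepted,
    explained_variance = x$explained_variance %||% NA_real_,
    f_opt = x$f_opt, f_low_half = x$f_low_half, f_high_half = x$f_high_half,
    pass_class = x$pass_class %||% NA_character_
  )
}

#' @rdname tfnorm_tidiers
#' @method tidy nr_fit
#' @export
tidy.nr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r_max", "sigma", "n"),
    estimate = c(x$r_max, x$sigma, x$n)
  )
}

#' @rdname tfnorm_tidiers
#' @method glance nr_fit
#' @export
glance.nr_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse, explained_variance = x$explained_variance,
    c50 = x$c50, dynamic_range = x$dynamic_range,
    degenerate = x$degenerate
  )
}

#' @rdname tfnorm_tidiers
#' @method tidy norm_fit
#' @export
tidy.norm_fit <- function(x, ...) {
  p <- x$params
  if (!is.null(p$t_values)) {
    drive <- tibble::tibble(
      term = paste0("T_", names(p$t_values)),
      estimate = unname(p$t_values)
    )
  } else {
    drive <- tibble::tibble(
      term = c("t_gain_e", "t_width_e", "t_gain_i", "t_width_i"),
      estimate = c(p$t_gain_e %||% 1, p$t_width_e, p$t_gain_i, p$t_width_i)
    )
  }
  head_terms <- c(r_max = p$r_max, sigma = p$sigma %||% NA_real_,
                  n = p$n %||% NA_real_, tau = p$tau %||% NA_real_)
  head_terms <- head_terms[!is.na(head_terms)]
  dplyr::bind_rows(
    tibble::tibble(term = names(head_terms), estimate = unname(head_terms)),
    drive
  )
}

#' @rdname tfnorm_tidiers
#' @method glance norm_fit
#' @export
glance.norm_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, t_mode = x$t_mode, sse = x$sse,
    explained_variance = x$explained_variance,
    adjusted_explained_variance = x$adjusted_explained_variance,
    n_obs = x$n_obs, n_par = x$n_par, converged = x$converged
  )
}
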