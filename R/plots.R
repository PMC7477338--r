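#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' measured points with the fitted curve for single fits, and a
#' per-contrast family of temporal-frequency curves for surfaces and
#' normalization fits.
#'
#' @param object A fitted object or surface tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @name tfnorm_plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tfnorm_plots
#' @method autoplot dog_fit
#' @export
autoplot.dog_fit <- function(object, ...) {
  fs <- exp(seq(log(0.05), log(32), length.out = 300))
  curve <- tibble::tibble(
    tf_hz = fs,
    rate = dog_value(fs, object$gain_e, object$width_e,
                     object$gain_i, object$width_i)
  )
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$tf_hz, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "temporal frequency (Hz)", y = "evoked rate (spikes/s)",
                  title = "difference-of-Gaussians tuning fit")
  if (!is.null(object$frequencies)) {
    pts <- tibble::tibble(tf_hz = object$frequencies, rate = object$observed)
    p <- p + ggplot2::geom_point(data = pts)
  }
  if (is.finite(object$f_opt %||% NA))
    p <- p + ggplot2::geom_vline(xintercept = object$f_opt, linetype = 2)
  p
}

#' @rdname tfnorm_plots
#' @method autoplot nr_fit
#' @export
autoplot.nr_fit <- function(object, ...) {
  cs <- seq(0, 100, length.out = 300)
  curve <- tibble::tibble(
    contrast_pct = cs,
    rate = naka_rushton_value(cs, object$r_max, object$sigma, object$n)
  )
  pts <- tibble::tibble(contrast_pct = object$contrasts, rate = object$observed)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$contrast_pct, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts) +
    ggplot2::labs(x = "contrast (%)", y = "evoked rate (spikes/s)",
                  title = "Naka-Rushton contrast-response fit")
}

#' @rdname tfnorm_plots
#' @method autoplot population_surface
#' @export
autoplot.population_surface <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf_hz, y = .data$mean_rate,
                                  colour = factor(.data$contrast_pct))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_rate - .data$sem,
                                          ymax = .data$mean_rate + .data$sem)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "temporal frequency (Hz)",
                  y = "population mean evoked rate (spikes/s)",
                  colour = "contrast (%)")
}

#' @rdname tfnorm_plots
#' @method autoplot norm_fit
#' @export
autoplot.norm_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$surface, c("observed", "fitted"),
                           names_to = "source", values_to = "rate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf_hz, y = .data$rate,
                                  colour = factor(.data$contrast_pct),
                                  linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d[d$source == "observed", ]) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "temporal frequency (Hz)", y = "rate (spikes/s)",
                  colour = "contrast (%)",
                  title = sprintf("%s normalization fit (EV %.3f)",
                                  object$variant, object$explained_variance))
}
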