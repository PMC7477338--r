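#' Run the full analysis on a trial table
#'
#' Chains the pipeline stages: condition aggregation, the minimum-response
#' inclusion filter, per-unit temporal-frequency (d.o.G.) and contrast
#' (Naka-Rushton) fits, the population surface, and the normalization
#' population fits in the requested variants.  Per-unit normalization
#' model comparison is optional because it is the slowest stage.
#'
#' @param trials A trial table from [simulate_trials()] / [read_trials()].
#' @param protocol A [stimulus_protocol()]; defaults to the one attached
#'   to the trial table.
#' @param threshold Inclusion threshold in spikes/s (default 1).
#' @param variants Normalization variants to fit to the population
#'   surface.
#' @param fit_units If `TRUE`, also fit the linear and static models to
#'   every unit ([compare_unit_models()]).
#' @return A list of class `study_analysis`: `responses` (included units
#'   only), `n_recorded`, `n_included`, `tf_fits`, `contrast_fits`,
#'   `surface`, `pop_fits` (named list of `norm_fit`), `unit_models`
#'   (tibble or `NULL`), `ratio` (the 8 Hz / 0.5 Hz ratio diagnostic of
#'   the measured surface).
#' @export
analyze_study <- function(trials, protocol = NULL, threshold = 1,
                          variants = c("static", "shunting", "linear"),
                          fit_units = FALSE) {
  responses <- aggregate_conditions(trials, protocol)
  n_recorded <- length(unique(responses$unit_id))
  included <- inclusion_filter(responses, threshold)
  if (length(attr(included, "included_units")) == 0)
    stop("no unit passes the inclusion filter", call. = FALSE)
  surface <- population_surface(included)
  out <- list(
    responses = included,
    n_recorded = n_recorded,
    n_included = length(attr(included, "included_units")),
    tf_fits = fit_tf_tuning(included),
    contrast_fits = fit_contrast_tuning(included),
    surface = surface,
    pop_fits = setNames(
      lapply(variants, function(v) fit_population(surface, v)),
      variants
    ),
    unit_models = if (fit_units) {
      compare_unit_models(included, variants = c("linear", "static"))
    },
    ratio = ratio_diagnostic(surface)
  )
  class(out) <- "study_analysis"
  out
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("study analysis: %d/%d units included\n",
              x$n_included, x$n_recorded))
  for (v in names(x$pop_fits)) {
    f <- x$pop_fits[[v]]
    cat(sprintf("  population %-8s EV %.3f (adjusted %.3f)\n",
                v, f$explained_variance, f$adjusted_explained_variance))
  }
  invisible(x)
}

#' Summary tables of a study analysis
#'
#' Produces the numeric report of a study: per-contrast medians (with
#' bootstrapped standard errors) of the optimal and high half-maximum
#' temporal frequencies and the band-pass fraction; per-frequency medians
#' of C50 and dynamic range; the population model-comparison table; the
#' high/low frequency ratio diagnostic; and the dLGN proxy comparison of
#' the static fit's inferred drive.
#'
#' @param analysis A `study_analysis` from [analyze_study()].
#' @param seed Integer seed for the bootstrap and the dLGN proxy search.
#' @param lgn_target Characteristic triple for the dLGN proxy
#'   (optimal, low half-maximum, high half-maximum, Hz).
#' @param n_boot Bootstrap resamples per median.
#' @return A list of class `tuning_report` with tibbles `tf_by_contrast`,
#'   `contrast_by_tf`, `model_comparison`, `ratio`, `lgn`.
#' @export
tuning_report <- function(analysis, seed, lgn_target = c(3.2, 1.5, 6.0),
                          n_boot = 1000) {
  stopifnot(inherits(analysis, "study_analysis"))
  if (missing(seed) || length(seed) != 1 || !is.finite(seed))
    stop("a single integer seed is required", call. = FALSE)

  boot_row <- function(v, s) {
    v <- v[is.finite(v)]
    if (length(v) < 2) {
      return(tibble::tibble(median = ifelse(length(v), v, NA_real_),
                            sem = NA_real_, n = length(v), n_boot = n_boot))
    }
    bootstrap_median_sem(v, n_boot = n_boot, seed = s)
  }

  tf_ok <- dplyr::filter(analysis$tf_fits, .data$accepted)
  tf_by_contrast <- tf_ok |>
    dplyr::group_by(.data$contrast_pct) |>
    dplyr::group_modify(function(d, key) {
      fo <- boot_row(d$f_opt, seed)
      fh <- boot_row(d$f_high_half, seed + 1)
      tibble::tibble(
        n_fits = nrow(d),
        f_opt_median = fo$median, f_opt_sem = fo$sem,
        f_high_median = fh$median, f_high_sem = fh$sem,
        band_fraction = mean(d$pass_class == "band", na.rm = TRUE)
      )
    }) |>
    dplyr::ungroup()

  contrast_by_tf <- analysis$contrast_fits |>
    dplyr::group_by(.data$tf_hz) |>
    dplyr::group_modify(function(d, key) {
      c5 <- boot_row(d$c50, seed + 2)
      dr <- boot_row(d$dynamic_range, seed + 3)
      tibble::tibble(
        n_fits = nrow(d),
        c50_median = c5$median, c50_sem = c5$sem,
        dynamic_range_median = dr$median, dynamic_range_sem = dr$sem
      )
    }) |>
    dplyr::ungroup()

  model_comparison <- purrr::map_dfr(analysis$pop_fits, glance)
  if (!is.null(analysis$unit_models)) {
    unit_medians <- analysis$unit_models |>
      dplyr::group_by(.data$variant) |>
      dplyr::summarise(
        unit_median_ev = median(.data$explained_variance, na.rm = TRUE),
        unit_median_adj_ev = median(.data$adjusted_explained_variance,
                                    na.rm = TRUE),
        .groups = "drop"
      )
    model_comparison <- dplyr::left_join(model_comparison, unit_medians,
                                         by = "variant")
  }

  lgn_fit <- fit_dog_to_characteristics(lgn_target, seed = seed + 4)
  static_fit <- analysis$pop_fits[["static"]] %||%
    fit_population(analysis$surface, "static")
  lgn <- lgn_comparison(static_fit, lgn_fit,
                        f_grid = sort(unique(analysis$surface$tf_hz)))

  out <- list(
    tf_by_contrast = tf_by_contrast,
    contrast_by_tf = contrast_by_tf,
    model_comparison = model_comparison,
    ratio = analysis$ratio,
    lgn = lgn
  )
  class(out) <- "tuning_report"
  out
}

#' @export
print.tuning_report <- function(x, ...) {
  cat("Temporal-frequency tuning by contrast:\n")
  print(x$tf_by_contrast)
  cat("\nContrast tuning by temporal frequency:\n")
  print(x$contrast_by_tf)
  cat("\nModel comparison:\n")
  print(x$model_comparison)
  cat("\n8 Hz / 0.5 Hz response ratio by contrast (slope",
      format(attr(x$ratio, "slope"), digits = 3), "per % contrast):\n")
  print(x$ratio)
  cat("\nInferred drive vs dLGN proxy:\n")
  print(x$lgn)
  invisible(x)
}
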