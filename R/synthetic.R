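#' Sampling distributions for synthetic-population parameters
#'
#' Each per-unit generative parameter is drawn from either a uniform or a
#' log-normal distribution.  `r_uniform(lo, hi)` collapses to a point when
#' `lo == hi`, which pins the parameter exactly; `r_lognormal(med, sdlog)`
#' is parameterised by its median so the centre is readable in natural
#' units.
#'
#' @param lo,hi Uniform bounds, `lo <= hi`.
#' @param median Median of the log-normal, > 0.
#' @param sdlog Standard deviation on the log scale, >= 0.
#' @return A distribution spec used by [parameter_ranges()].
#' @export
r_uniform <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || is.na(lo) || is.na(hi) || lo > hi)
    stop("invalid uniform range: need numeric lo <= hi", call. = FALSE)
  structure(list(dist = "uniform", lo = lo, hi = hi), class = "param_dist")
}

#' @rdname r_uniform
#' @export
r_lognormal <- function(median, sdlog) {
  if (!is.numeric(median) || median <= 0 || !is.numeric(sdlog) || sdlog < 0)
    stop("invalid log-normal spec: need median > 0, sdlog >= 0", call. = FALSE)
  structure(list(dist = "lognormal", meanlog = log(median), sdlog = sdlog),
            class = "param_dist")
}

draw_param <- function(spec, n) {
  switch(spec$dist,
    uniform = runif(n, spec$lo, spec$hi),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog)
  )
}

#' Default parameter ranges for the synthetic population
#'
#' The drive of each unit is a difference of Gaussians
#' `d(f) = g_e exp(-f^2 / 2 w_e^2) - g_i exp(-f^2 / 2 w_i^2)` and its
#' contrast coupling follows the divisive-normalization surface (see
#' [simulate_trials()]).  The default ranges are calibrated so that the
#' population's drive optima have a median near 2.8 Hz and roughly half
#' the units are band-pass: `w_e` log-normal around 5.5 Hz, `w_i`
#' log-normal around 1.2 Hz (capped at `0.9 w_e` so the drive stays
#' positive), inhibitory gain uniform on (0.5, 0.9) with `g_e = 1`.
#'
#' @param drive_gain_e,drive_width_e,drive_gain_i,drive_width_i Drive
#'   d.o.G. parameter distributions (gains dimensionless, widths Hz).
#' @param sat_constant Semisaturation constant, percent contrast.
#' @param exponent Naka-Rushton exponent (dimensionless).
#' @param response_scale Peak evoked-rate scale, spikes/s.
#' @param spontaneous_rate Spontaneous firing rate, spikes/s.
#' @param direction_modulation_depth Cosine direction-tuning depth in
#'   \[0, 1\]; the default 0 makes all directions equivalent, matching an
#'   analysis that averages over directions.
#' @return A named list of `param_dist` specs.
#' @export
parameter_ranges <- function(drive_gain_e = r_uniform(1, 1),
                             drive_width_e = r_lognormal(5.5, 0.3),
                             drive_gain_i = r_uniform(0.5, 0.9),
                             drive_width_i = r_lognormal(1.2, 0.3),
                             sat_constant = r_uniform(15, 45),
                             exponent = r_uniform(0.9, 1.8),
                             response_scale = r_uniform(8, 30),
                             spontaneous_rate = r_uniform(0.5, 4),
                             direction_modulation_depth = r_uniform(0, 0)) {
  ranges <- list(
    drive_gain_e = drive_gain_e, drive_width_e = drive_width_e,
    drive_gain_i = drive_gain_i, drive_width_i = drive_width_i,
    sat_constant = sat_constant, exponent = exponent,
    response_scale = response_scale, spontaneous_rate = spontaneous_rate,
    direction_modulation_depth = direction_modulation_depth
  )
  bad <- names(ranges)[!vapply(ranges, inherits, logical(1), "param_dist")]
  if (length(bad))
    stop("not distribution specs: ", paste(bad, collapse = ", "), call. = FALSE)
  ranges
}

#' Sample a synthetic population's ground-truth parameters
#'
#' Draws per-unit generative parameters: the d.o.G. temporal-frequency
#' drive, the per-unit semisaturation constant and exponent that couple
#' drive to contrast, the response scale and the spontaneous rate.  The
#' returned tibble is the ground truth retained for parameter-recovery
#' tests; `drive_f_opt` is each unit's drive optimum found by dense-grid
#' argmax.
#'
#' @param n_units Number of units, >= 1.
#' @param protocol A [stimulus_protocol()] (used for validation only).
#' @param ranges Parameter distributions from [parameter_ranges()].
#' @param seed Integer seed; identical seeds give identical populations.
#' @return A tibble with one row per unit, class `ground_truth`.
#' @export
sample_population <- function(n_units, protocol = stimulus_protocol(),
                              ranges = parameter_ranges(), seed) {
  stopifnot(n_units >= 1, inherits(protocol, "stim_protocol"))
  if (missing(seed) || length(seed) != 1 || !is.finite(seed))
    stop("a single integer seed is required", call. = FALSE)
  bad <- names(ranges)[!vapply(ranges, inherits, logical(1), "param_dist")]
  if (length(bad))
    stop("invalid parameter ranges: ", paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  truth <- tibble::as_tibble(lapply(ranges, draw_param, n = n_units))
  # keep the negative Gaussian narrower than the positive one so the
  # drive is strictly positive (g_i < g_e is then sufficient)
  truth$drive_width_i <- pmin(truth$drive_width_i, 0.9 * truth$drive_width_e)
  truth <- tibble::add_column(truth, unit_id = seq_len(n_units), .before = 1)
  truth$drive_f_opt <- purrr::pmap_dbl(
    truth[c("drive_gain_e", "drive_width_e", "drive_gain_i", "drive_width_i")],
    function(drive_gain_e, drive_width_e, drive_gain_i, drive_width_i) {
      f <- exp(seq(log(0.05), log(32), length.out = 4001))
      f[which.max(dog_value(f, drive_gain_e, drive_width_e,
                            drive_gain_i, drive_width_i))]
    }
  )
  class(truth) <- c("ground_truth", class(truth))
  truth
}

#' Mean evoked-rate surface of a synthetic unit
#'
#' The generative surface couples the d.o.G. drive `d(f)` to contrast via
#' the divisive-normalization form
#' `rate(f, c) = scale * c^n d(f) / (sigma^n + c^n d(f))`,
#' which is a Naka-Rushton function of contrast whose shape depends on
#' temporal frequency.
#'
#' @param unit One row of a `ground_truth` tibble (or an equivalent list).
#' @param tf_hz Temporal frequency, Hz.
#' @param contrast_pct Michelson contrast, percent.
#' @return Mean evoked rate in spikes/s (same length as the inputs).
#' @export
mean_rate_surface <- function(unit, tf_hz, contrast_pct) {
  d <- dog_value(tf_hz, unit$drive_gain_e, unit$drive_width_e,
                 unit$drive_gain_i, unit$drive_width_i)
  cn <- contrast_pct^unit$exponent
  unit$response_scale * cn * d / (unit$sat_constant^unit$exponent + cn * d)
}

#' Simulate trial-level spike data for a synthetic population
#'
#' For every unit the full factorial of temporal frequency, contrast and
#' direction is presented once per repeat block, shuffled within each
#' block.  Spike counts in the stimulus window are Poisson with mean
#' `(spontaneous + evoked) * duration`, where the evoked rate comes from
#' [mean_rate_surface()] (optionally modulated by cosine direction
#' tuning); the preceding gap window carries Poisson spontaneous spikes.
#' Spike times are reported relative to stimulus onset, so gap spikes are
#' negative down to `-gap_duration`.
#'
#' @param truth A `ground_truth` tibble from [sample_population()].
#' @param protocol A [stimulus_protocol()].
#' @param seed Integer seed; identical seed and inputs give an identical
#'   trial table.
#' @return A tibble with one row per trial: `unit_id`, `trial_index`,
#'   `tf_hz`, `contrast_pct`, `direction_deg`, `onset_s`, and a
#'   `spike_times` list-column of ascending spike times in seconds.
#' @export
simulate_trials <- function(truth, protocol = stimulus_protocol(), seed) {
  stopifnot(inherits(protocol, "stim_protocol"), nrow(truth) >= 1)
  if (missing(seed) || length(seed) != 1 || !is.finite(seed))
    stop("a single integer seed is required", call. = FALSE)
  set.seed(seed)
  dur <- protocol$stimulus_duration
  gap <- protocol$gap_duration
  block <- tidyr::expand_grid(
    tf_hz = protocol$temporal_frequencies,
    contrast_pct = protocol$contrasts,
    direction_deg = protocol$directions
  )
  n_block <- nrow(block)

  per_unit <- lapply(seq_len(nrow(truth)), function(i) {
    unit <- truth[i, ]
    trials <- dplyr::bind_rows(lapply(seq_len(protocol$repeats), function(b) {
      block[sample.int(n_block), ]
    }))
    trials$trial_index <- seq_len(nrow(trials))
    trials$onset_s <- gap + (trials$trial_index - 1) * (dur + gap)
    evoked <- mean_rate_surface(unit, trials$tf_hz, trials$contrast_pct)
    if (unit$direction_modulation_depth > 0) {
      evoked <- evoked *
        (1 + unit$direction_modulation_depth * cos(trials$direction_deg * pi / 180))
    }
    stim_rate <- pmax(unit$spontaneous_rate + evoked, 0)
    n_stim <- rpois(nrow(trials), stim_rate * dur)
    n_gap <- rpois(nrow(trials), unit$spontaneous_rate * gap)
    trials$spike_times <- purrr::map2(n_stim, n_gap, function(ns, ng) {
      sort(c(runif(ns, 0, dur), runif(ng, -gap, 0)))
    })
    trials$unit_id <- unit$unit_id
    trials
  })
  out <- dplyr::bind_rows(per_unit)
  out <- out[, c("unit_id", "trial_index", "tf_hz", "contrast_pct",
                 "direction_deg", "onset_s", "spike_times")]
  attr(out, "protocol") <- protocol
  out
}

#' Convenience wrapper: sample a population and simulate its trials
#'
#' @inheritParams sample_population
#' @return A list with elements `truth` (the ground-truth tibble),
#'   `trials` (the simulated trial table) and `protocol`.
#' @export
simulate_study <- function(n_units, protocol = stimulus_protocol(),
                           ranges = parameter_ranges(), seed) {
  truth <- sample_population(n_units, protocol, ranges, seed = seed)
  trials <- simulate_trials(truth, protocol, seed = seed + 1L)
  list(truth = truth, trials = trials, protocol = protocol)
}
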