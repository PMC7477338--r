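#' Evoked firing rate of a single trial
#'
#' The evoked rate is the mean firing rate over the stimulus window minus
#' the spontaneous rate, where the spontaneous rate is the mean rate in
#' the last `baseline_window` seconds before stimulus onset.  Spike times
#' are relative to onset, so baseline spikes are negative.  The result can
#' be negative: baseline subtraction is not clipped.
#'
#' @param spike_times Numeric vector of spike times in seconds relative to
#'   stimulus onset (an empty vector is a valid silent trial).
#' @param stimulus_duration Stimulus window length, seconds (> 0).
#' @param baseline_window Pre-onset window used for the spontaneous rate,
#'   seconds (> 0, default 0.5).
#' @return Evoked rate in spikes/s.
#' @export
evoked_rate <- function(spike_times, stimulus_duration, baseline_window = 0.5) {
  stopifnot(stimulus_duration > 0, baseline_window > 0)
  n_stim <- sum(spike_times >= 0 & spike_times < stimulus_duration)
  n_base <- sum(spike_times >= -baseline_window & spike_times < 0)
  n_stim / stimulus_duration - n_base / baseline_window
}

#' Aggregate trials into per-unit condition responses
#'
#' Computes, for every unit and every (temporal frequency, contrast)
#' condition, the mean evoked rate over all directions and repeats, its
#' standard error across those pooled trials, and the trial count.  The
#' spontaneous rate can be subtracted per trial (each trial's own pre-onset
#' baseline, the default) or pooled per unit (the unit's mean baseline
#' rate subtracted from every stimulus-window rate).
#'
#' @param trials A trial table from [simulate_trials()] or [read_trials()].
#' @param protocol The [stimulus_protocol()] the trials follow; defaults to
#'   the protocol attached to the trial table.
#' @param spontaneous Baseline convention, `"per_trial"` or `"pooled"`.
#' @param baseline_window Pre-onset baseline window, seconds.
#' @return A tibble of class `condition_response` with columns `unit_id`,
#'   `tf_hz`, `contrast_pct`, `mean_rate`, `sem`, `n_trials`, plus a
#'   per-unit `spontaneous` attribute table (unit_id, spont_rate).
#' @export
aggregate_conditions <- function(trials, protocol = NULL,
                                 spontaneous = c("per_trial", "pooled"),
                                 baseline_window = 0.5) {
  spontaneous <- match.arg(spontaneous)
  protocol <- protocol %||% attr(trials, "protocol")
  if (is.null(protocol))
    stop("no protocol supplied and none attached to the trial table",
         call. = FALSE)
  dur <- protocol$stimulus_duration
  bw <- baseline_window
  t <- tibble::as_tibble(trials)
  t$stim_rate <- vapply(t$spike_times, function(s) {
    sum(s >= 0 & s < dur) / dur
  }, double(1))
  t$base_rate <- vapply(t$spike_times, function(s) {
    sum(s >= -bw & s < 0) / bw
  }, double(1))

  spont <- t |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(spont_rate = mean(.data$base_rate), .groups = "drop")

  if (spontaneous == "per_trial") {
    t$evoked <- t$stim_rate - t$base_rate
  } else {
    t <- dplyr::left_join(t, spont, by = "unit_id")
    t$evoked <- t$stim_rate - t$spont_rate
  }

  out <- t |>
    dplyr::group_by(.data$unit_id, .data$tf_hz, .data$contrast_pct) |>
    dplyr::summarise(
      mean_rate = mean(.data$evoked),
      sem = if (dplyr::n() > 1) sd(.data$evoked) / sqrt(dplyr::n()) else 0,
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$unit_id, .data$tf_hz, .data$contrast_pct)

  # every unit must cover the full protocol grid
  grid <- tidyr::expand_grid(
    unit_id = unique(out$unit_id),
    tf_hz = protocol$temporal_frequencies,
    contrast_pct = protocol$contrasts
  )
  missing <- dplyr::anti_join(grid, out, by = c("unit_id", "tf_hz", "contrast_pct"))
  if (nrow(missing) > 0) {
    gaps <- paste(sprintf("unit %s: %g Hz @ %g%%", missing$unit_id,
                          missing$tf_hz, missing$contrast_pct),
                  collapse = "; ")
    stop("missing condition cells: ", gaps, call. = FALSE)
  }
  attr(out, "spontaneous") <- spont
  attr(out, "protocol") <- protocol
  class(out) <- c("condition_response", class(out))
  out
}

#' Filter units by minimum evoked response
#'
#' A unit is retained if and only if its maximum mean evoked rate over all
#' (temporal frequency, contrast) cells is at least `threshold` ("minimum
#' response" read as an inclusive bound).
#'
#' @param responses A `condition_response` tibble.
#' @param threshold Minimum peak evoked rate, spikes/s (default 1).
#' @return The filtered `condition_response` tibble; the ids of retained
#'   units are in attribute `included_units`.
#' @export
inclusion_filter <- function(responses, threshold = 1) {
  stopifnot(threshold >= 0)
  keep <- responses |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(peak = max(.data$mean_rate), .groups = "drop") |>
    dplyr::filter(.data$peak >= threshold)
  out <- dplyr::semi_join(tibble::as_tibble(responses), keep, by = "unit_id")
  for (a in c("spontaneous", "protocol")) attr(out, a) <- attr(responses, a)
  attr(out, "included_units") <- keep$unit_id
  class(out) <- c("condition_response", class(out))
  out
}
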