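#' Drifting-grating stimulus protocol
#'
#' Describes the factorial drifting-grating protocol used throughout the
#' package: temporal frequencies crossed with Michelson contrasts and drift
#' directions, each combination repeated a fixed number of times, with a
#' gray gap between presentations.
#'
#' @param temporal_frequencies Grating temporal frequencies in Hz.
#'   Default: six octave-spaced frequencies 0.5--16 Hz.
#' @param contrasts Michelson contrasts in percent, each in (0, 100].
#' @param directions Drift directions in degrees.  Default: the eight
#'   cardinal and oblique directions.
#' @param repeats Number of repeats of each condition. Must be >= 1.
#' @param stimulus_duration Stimulus presentation length in seconds.
#' @param gap_duration Gray-screen gap between presentations in seconds.
#' @param spatial_frequency Grating spatial frequency in cycles/degree.
#'
#' @return An object of class `stim_protocol`: a named list of the
#'   validated protocol settings.
#'
#' @examples
#' p <- stimulus_protocol()
#' drift_speeds(p)
#' @export
stimulus_protocol <- function(temporal_frequencies = c(0.5, 1, 2, 4, 8, 16),
                              contrasts = c(10, 30, 50, 70, 90),
                              directions = seq(0, 315, by = 45),
                              repeats = 5,
                              stimulus_duration = 2,
                              gap_duration = 1.5,
                              spatial_frequency = 0.05) {
  stopifnot(
    length(temporal_frequencies) >= 1, all(temporal_frequencies > 0),
    length(contrasts) >= 1, all(contrasts > 0), all(contrasts <= 100),
    length(directions) >= 1,
    length(repeats) == 1, repeats >= 1, repeats == as.integer(repeats),
    stimulus_duration > 0, gap_duration > 0, spatial_frequency > 0
  )
  structure(
    list(
      temporal_frequencies = sort(unname(temporal_frequencies)),
      contrasts = sort(unname(contrasts)),
      directions = unname(directions),
      repeats = as.integer(repeats),
      stimulus_duration = stimulus_duration,
      gap_duration = gap_duration,
      spatial_frequency = spatial_frequency
    ),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Drifting-grating protocol\n")
  cat("  temporal frequencies:", paste(x$temporal_frequencies, collapse = ", "), "Hz\n")
  cat("  contrasts:           ", paste(x$contrasts, collapse = ", "), "%\n")
  cat("  directions:          ", paste(x$directions, collapse = ", "), "deg\n")
  cat("  repeats:             ", x$repeats, "\n")
  cat("  stimulus / gap:      ", x$stimulus_duration, "s /", x$gap_duration, "s\n")
  cat("  spatial frequency:   ", x$spatial_frequency, "cyc/deg\n")
  invisible(x)
}

#' Drift speeds implied by a protocol
#'
#' A grating of temporal frequency `f` (Hz) and spatial frequency `sf`
#' (cycles/degree) drifts at `f / sf` degrees of visual angle per second.
#'
#' @param protocol A [stimulus_protocol()].
#' @return A tibble with columns `tf_hz` and `speed_deg_s`.
#' @export
drift_speeds <- function(protocol = stimulus_protocol()) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tibble::tibble(
    tf_hz = protocol$temporal_frequencies,
    speed_deg_s = protocol$temporal_frequencies / protocol$spatial_frequency
  )
}

n_conditions <- function(protocol) {
  length(protocol$temporal_frequencies) * length(protocol$contrasts) *
    length(protocol$directions)
}
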