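#' Read and write trial tables
#'
#' Trial tables are stored as plain CSV with one row per trial and the
#' spike times of that trial semicolon-joined in a single column.  Floats
#' are written with 17 significant digits so a write/read round trip is
#' exact.
#'
#' @param trials A trial table as produced by [simulate_trials()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial tibble.
#' @export
write_trials <- function(trials, path) {
  cols <- c("unit_id", "trial_index", "tf_hz", "contrast_pct",
            "direction_deg", "onset_s", "spike_times")
  stopifnot(all(cols %in% names(trials)))
  fmt <- function(x) {
    vapply(x, function(v) sprintf("%.17g", v), character(1))
  }
  spikes <- vapply(trials$spike_times, function(s) {
    paste(sprintf("%.17g", s), collapse = ";")
  }, character(1))
  flat <- data.frame(
    unit_id = trials$unit_id,
    trial_index = trials$trial_index,
    tf_hz = fmt(trials$tf_hz),
    contrast_pct = fmt(trials$contrast_pct),
    direction_deg = fmt(trials$direction_deg),
    onset_s = fmt(trials$onset_s),
    spike_times = spikes,
    check.names = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = 7)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  header <- gsub('"', "", strsplit(lines[[1]], ",", fixed = TRUE)[[1]],
                 fixed = TRUE)
  expected <- c("unit_id", "trial_index", "tf_hz", "contrast_pct",
                "direction_deg", "onset_s", "spike_times")
  if (!identical(header, expected))
    stop("line 1: unexpected header", call. = FALSE)
  if (length(lines) == 1) {
    out <- tibble::tibble(
      unit_id = integer(), trial_index = integer(), tf_hz = double(),
      contrast_pct = double(), direction_deg = double(), onset_s = double(),
      spike_times = list()
    )
    return(out)
  }
  body <- lines[-1]
  parse_row <- function(line, lineno) {
    # spike_times is the quoted final field; strip it first
    m <- regmatches(line, regexec('^([^"]*),"([^"]*)"$', line))[[1]]
    if (length(m) == 3) {
      lead <- m[2]; spikes_str <- m[3]
    } else {
      parts <- strsplit(line, ",", fixed = TRUE)[[1]]
      if (length(parts) == 6) {
        lead <- line; spikes_str <- ""
      } else if (length(parts) == 7) {
        lead <- paste(parts[1:6], collapse = ","); spikes_str <- parts[7]
      } else {
        stop("line ", lineno, ": expected 7 fields, found ", length(parts),
             call. = FALSE)
      }
    }
    fields <- strsplit(lead, ",", fixed = TRUE)[[1]]
    if (length(fields) != 6)
      stop("line ", lineno, ": expected 7 fields, found ", length(fields) + 1,
           call. = FALSE)
    num <- suppressWarnings(as.numeric(fields))
    if (anyNA(num))
      stop("line ", lineno, ": non-numeric value in column ",
           expected[which(is.na(num))[1]], call. = FALSE)
    spikes <- if (nzchar(spikes_str)) {
      s <- suppressWarnings(as.numeric(strsplit(spikes_str, ";", fixed = TRUE)[[1]]))
      if (anyNA(s))
        stop("line ", lineno, ": malformed spike_times", call. = FALSE)
      s
    } else numeric(0)
    list(num = num, spikes = spikes)
  }
  rows <- Map(parse_row, body, seq_along(body) + 1L)
  num <- unname(do.call(rbind, lapply(rows, `[[`, "num")))
  tibble::tibble(
    unit_id = as.integer(num[, 1]),
    trial_index = as.integer(num[, 2]),
    tf_hz = num[, 3],
    contrast_pct = num[, 4],
    direction_deg = num[, 5],
    onset_s = num[, 6],
    spike_times = unname(lapply(rows, `[[`, "spikes"))
  )
}

#' Write a condition-response table as tidy CSV
#'
#' @param responses A condition-response tibble from
#'   [aggregate_conditions()].
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
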