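#' Trough-to-peak width of a mean spike waveform
#'
#' The width is the time from the waveform's global trough (most negative
#' sample) to the subsequent positive peak (maximum after the trough) — the
#' standard wave-shape feature separating putative interneurons (narrow)
#' from putative pyramidal neurons (wide).
#'
#' @param waveform Numeric vector of voltage samples.
#' @param sampling_rate Waveform sampling rate in Hz.
#' @return Width in milliseconds.
#' @examples
#' w <- simulate_waveform(0.6, seed = 1)
#' peak_to_valley_width(w, 30000)
#' @export
peak_to_valley_width <- function(waveform, sampling_rate) {
  if (!is.numeric(waveform) || length(waveform) < 3) {
    abort("`waveform` must be a numeric vector with at least 3 samples.")
  }
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  trough <- which.min(waveform)
  if (trough >= length(waveform)) {
    abort("Waveform is not spike-like: no samples after the trough.")
  }
  after <- waveform[(trough + 1):length(waveform)]
  peak <- trough + which.max(after)
  if (waveform[peak] <= waveform[trough]) {
    abort("Waveform is not spike-like: no rise after the trough.")
  }
  (peak - trough) / sampling_rate * 1000
}

#' Classify a sorted spike unit
#'
#' Applies the post-sorting rules: units firing below `min_rate` (default
#' 0.5 Hz) over the session are excluded; among the rest, a trough-to-peak
#' width under `width_threshold_ms` (default 0.5 ms) marks a putative
#' interneuron, a wider waveform a putative pyramidal neuron. A width exactly
#' at the threshold is classed pyramidal ("narrow" being the marked
#' category).
#'
#' @param unit A list with elements `spike_times` (seconds, sorted),
#'   `waveform` (numeric) and `waveform_sampling_rate` (Hz); extra elements
#'   are ignored. Units from [simulate_session()] rows qualify.
#' @param session_duration Recording duration in seconds (> 0).
#' @param width_threshold_ms Width separating the two classes (ms).
#' @param min_rate Exclusion threshold on mean firing rate (Hz).
#' @return A one-row tibble with `label` (one of `putative_interneuron`,
#'   `putative_pyramidal`, `excluded_low_rate`), `peak_to_valley_ms`,
#'   `mean_rate_hz`.
#' @examples
#' u <- list(spike_times = seq(0, 99, by = 0.5),
#'           waveform = simulate_waveform(0.8, seed = 1),
#'           waveform_sampling_rate = 30000)
#' classify_unit(u, session_duration = 100)
#' @export
classify_unit <- function(unit, session_duration, width_threshold_ms = 0.5,
                          min_rate = 0.5) {
  assert_scalar_num(session_duration, "session_duration", 0, strict = TRUE)
  if (is.null(unit$waveform) || length(unit$waveform) == 0) {
    abort("Unit has an empty waveform; width cannot be measured.")
  }
  fs <- unit$waveform_sampling_rate %||% 30000
  width <- peak_to_valley_width(unit$waveform, fs)
  rate <- length(unit$spike_times) / session_duration
  label <- if (rate < min_rate) {
    "excluded_low_rate"
  } else if (width < width_threshold_ms) {
    "putative_interneuron"
  } else {
    "putative_pyramidal"
  }
  tibble(label = label, peak_to_valley_ms = width, mean_rate_hz = rate)
}

#' Classify every unit of a session
#'
#' Tidy wrapper over [classify_unit()]: takes the `units` tibble of an
#' [simulate_session()] session (or any tibble with `spike_times` and
#' `waveform` list-columns) and appends the classification columns.
#'
#' @param units An `ephys_session` or its `units` tibble.
#' @param session_duration Recording duration (s); taken from the session
#'   config when a session is supplied.
#' @param waveform_sampling_rate Waveform sampling rate (Hz).
#' @inheritParams classify_unit
#' @return The units tibble with `label`, `peak_to_valley_ms`,
#'   `mean_rate_hz` columns added.
#' @export
classify_units <- function(units, session_duration = NULL,
                           waveform_sampling_rate = 30000,
                           width_threshold_ms = 0.5, min_rate = 0.5) {
  if (inherits(units, "ephys_session")) {
    session_duration <- session_duration %||% units$config$session_duration
    units <- units$units
  }
  if (is.null(session_duration)) abort("`session_duration` is required.")
  res <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    classify_unit(
      list(
        spike_times = units$spike_times[[i]],
        waveform = units$waveform[[i]],
        waveform_sampling_rate = waveform_sampling_rate
      ),
      session_duration, width_threshold_ms, min_rate
    )
  })
  dplyr::bind_cols(units, res)
}
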