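#' Simulate an inhomogeneous Poisson spike train
#'
#' Samples spike times from an inhomogeneous Poisson process with a
#' piecewise-constant intensity, using thinning (rejection of a homogeneous
#' dominating process), which is exact for piecewise-constant rates.
#'
#' @param rate Either a single non-negative rate in Hz (homogeneous process)
#'   or a data frame with columns `start`, `end`, `rate` describing a
#'   piecewise-constant intensity in Hz. Time outside the listed intervals has
#'   rate 0. Intervals must not overlap.
#' @param duration Duration of the simulated recording in seconds.
#' @param seed Optional integer seed; a fixed seed gives an identical train.
#'
#' @return Sorted numeric vector of spike times in `[0, duration)`, in seconds.
#' @examples
#' simulate_spike_train(5, duration = 2, seed = 1)
#' prof <- data.frame(start = c(0, 1), end = c(1, 2), rate = c(2, 20))
#' simulate_spike_train(prof, duration = 2, seed = 1)
#' @export
simulate_spike_train <- function(rate, duration, seed = NULL) {
  assert_scalar_num(duration, "duration", lower = 0)
  prof <- as_rate_profile(rate, duration)
  bad <- prof$rate < 0
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Negative rate %g Hz on interval [%g, %g) s; rates must be >= 0.",
      prof$rate[i], prof$start[i], prof$end[i]
    ))
  }
  rmax <- max(prof$rate, 0)
  if (rmax == 0 || duration == 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- stats::rpois(1, rmax * duration)
    if (n_cand == 0) return(numeric(0))
    cand <- sort(runif(n_cand, 0, duration))
    lambda <- rate_at(prof, cand)
    keep <- runif(n_cand) < lambda / rmax
    unique(cand[keep])
  })
}

# Normalise the two accepted rate descriptions into a start/end/rate frame.
as_rate_profile <- function(rate, duration) {
  if (is.numeric(rate) && length(rate) == 1L) {
    return(tibble(start = 0, end = duration, rate = as.numeric(rate)))
  }
  if (is.data.frame(rate)) {
    need <- c("start", "end", "rate")
    if (!all(need %in% names(rate))) {
      abort("A piecewise rate profile needs columns `start`, `end`, `rate`.")
    }
    prof <- as_tibble(rate[need])
    if (any(prof$end <= prof$start)) abort("Profile intervals need end > start.")
    prof <- prof[order(prof$start), ]
    if (nrow(prof) > 1 && any(prof$start[-1] < prof$end[-nrow(prof)] - 1e-12)) {
      abort("Profile intervals must not overlap.")
    }
    return(prof)
  }
  abort("`rate` must be a single number or a start/end/rate data frame.")
}

rate_at <- function(prof, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(prof))) {
    inside <- t >= prof$start[i] & t < prof$end[i]
    out[inside] <- prof$rate[i]
  }
  out
}

#' Build the stimulus-locked rate profile of a simulated unit
#'
#' Constructs the piecewise-constant intensity of a unit firing at a constant
#' baseline rate, multiplied by `gain` inside a fixed window after each
#' stimulus: gain > 1 models an excitatory response, gain < 1 an inhibitory
#' one, gain = 1 no response.
#'
#' @param duration Session duration (s).
#' @param baseline_rate Baseline firing rate (Hz).
#' @param events Stimulus onset times (s), sorted.
#' @param gain Multiplicative rate factor inside the response window.
#' @param window Numeric length-2 `(offset, duration)` of the response window
#'   in seconds relative to each stimulus onset.
#' @return A start/end/rate tibble suitable for [simulate_spike_train()].
#' @export
stimulus_rate_profile <- function(duration, baseline_rate, events = numeric(0),
                                  gain = 1, window = c(0, 0.5)) {
  assert_scalar_num(baseline_rate, "baseline_rate", lower = 0)
  assert_scalar_num(gain, "gain", lower = 0)
  stopifnot(length(window) == 2, window[2] > 0)
  cuts <- c(0, duration)
  for (ev in events) {
    cuts <- c(cuts, max(0, min(duration, ev + window[1])),
              max(0, min(duration, ev + window[1] + window[2])))
  }
  cuts <- sort(unique(cuts))
  start <- cuts[-length(cuts)]
  end <- cuts[-1]
  mid <- (start + end) / 2
  in_resp <- vapply(mid, function(m) {
    any(m >= events + window[1] & m < events + window[1] + window[2])
  }, logical(1))
  tibble(start = start, end = end,
         rate = baseline_rate * ifelse(in_resp, gain, 1))
}

#' Simulate an average spike waveform of given trough-to-peak width
#'
#' Produces a stereotyped extracellular spike shape: a sharp negative trough
#' followed by a slower positive after-peak, with the trough-to-peak interval
#' equal to `width_ms`. A small seeded jitter is added so repeated units are
#' not byte-identical, scaled to never displace the extrema.
#'
#' @param width_ms Trough-to-peak width in milliseconds (> 0).
#' @param n_samples Number of samples in the returned waveform.
#' @param sampling_rate Waveform sampling rate in Hz (default 30 kHz, typical
#'   for tetrode acquisition).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_samples` (arbitrary voltage units,
#'   trough normalised to -1).
#' @examples
#' w <- simulate_waveform(0.4, seed = 1)
#' peak_to_valley_width(w, 30000)
#' @export
simulate_waveform <- function(width_ms, n_samples = 64, sampling_rate = 30000,
                              seed = NULL) {
  assert_scalar_num(width_ms, "width_ms", lower = 0, strict = TRUE)
  dt_ms <- 1000 / sampling_rate
  width_samp <- round(width_ms / dt_ms)
  if (width_samp < 1) {
    abort(sprintf(
      "width %g ms is below one sample period (%g ms) at %g Hz.",
      width_ms, dt_ms, sampling_rate
    ))
  }
  trough <- max(2L, round(n_samples / 4))
  peak <- trough + width_samp
  if (peak > n_samples - 1L) {
    abort(sprintf(
      "width %g ms does not fit in %d samples at %g Hz; increase `n_samples`.",
      width_ms, n_samples, sampling_rate
    ))
  }
  i <- seq_len(n_samples)
  s_tr <- max(1, width_samp / 4)
  s_pk <- max(1.5, width_samp / 2.5)
  w <- -exp(-(i - trough)^2 / (2 * s_tr^2)) +
    0.55 * exp(-(i - peak)^2 / (2 * s_pk^2))
  # jitter kept at 0.2% of trough amplitude: visible in overlays, far too
  # small to displace the measured extrema by more than one sample
  with_seed(seed, w + rnorm(n_samples, sd = 0.002))
}
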