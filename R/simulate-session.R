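#' Configuration for a synthetic recording session
#'
#' Bundles every ground-truth parameter of a simulated two-region session.
#' Defaults mirror the recording protocol the pipeline targets: 20 stimulus
#' trials at least 60 s apart, LFPs at 1250 Hz, and a bivariate VAR LFP model
#' with directional coupling from the second channel (IL) into the first (PL).
#'
#' @param seed Integer seed; a fixed seed makes the whole session reproducible.
#' @param session_duration Session length in seconds (default 1320 s, enough
#'   for 20 trials with a 60 s minimum inter-stimulus interval).
#' @param lfp_sampling_rate LFP sampling rate in Hz.
#' @param n_trials Number of stimulus events.
#' @param min_event_gap Minimum inter-stimulus interval (s).
#' @param units A tibble (one row per unit) with columns `baseline_rate` (Hz),
#'   `response_gain` (rate multiplier in the response window; > 1 excitatory,
#'   < 1 inhibitory, 1 neutral), `width_ms` (waveform trough-to-peak width)
#'   and `region`. Default: three PL units, one of each response class.
#' @param response_window `(offset, duration)` in seconds of the evoked-rate
#'   window relative to stimulus onset.
#' @param var_model An [mvar_model] generating the two LFP channels; must be
#'   stable. Default: stable bivariate VAR(2) with coupling channel 2 -> 1.
#' @param lfp_regions Region labels for the LFP channels.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       session_duration = 1320,
                       lfp_sampling_rate = 1250,
                       n_trials = 20,
                       min_event_gap = 60,
                       units = default_sim_units(),
                       response_window = c(0, 0.5),
                       var_model = default_var_model(lfp_sampling_rate),
                       lfp_regions = c("PL", "IL")) {
  assert_scalar_num(session_duration, "session_duration", 0, strict = TRUE)
  assert_scalar_num(lfp_sampling_rate, "lfp_sampling_rate", 0, strict = TRUE)
  assert_scalar_num(n_trials, "n_trials", lower = 0)
  units <- as_tibble(units)
  need <- c("baseline_rate", "response_gain", "width_ms", "region")
  if (!all(need %in% names(units))) {
    abort(sprintf("`units` needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(units$baseline_rate < 0) || any(units$response_gain < 0)) {
    abort("Unit rates and gains must be >= 0.")
  }
  stopifnot(inherits(var_model, "mvar_model"))
  if (!is_stable(var_model)) abort("`var_model` must be stable.")
  if (length(lfp_regions) != var_model$n_channels) {
    abort("`lfp_regions` must name one region per VAR channel.")
  }
  structure(
    list(
      seed = as.integer(seed),
      session_duration = session_duration,
      lfp_sampling_rate = lfp_sampling_rate,
      n_trials = as.integer(n_trials),
      min_event_gap = min_event_gap,
      units = units,
      response_window = response_window,
      var_model = var_model,
      lfp_regions = as.character(lfp_regions)
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_sim_units <- function() {
  tibble(
    baseline_rate = c(5, 8, 5),
    response_gain = c(3, 0, 1),
    width_ms = c(0.8, 0.3, 0.8),
    region = c("PL", "PL", "PL")
  )
}

#' @rdname sim_config
#' @param sampling_rate Sampling rate for the default LFP model.
#' @export
default_var_model <- function(sampling_rate = 1250) {
  mvar_model(
    list(
      matrix(c(0.5, 0.3,
               0.0, 0.5), 2, 2, byrow = TRUE),
      matrix(c(-0.1, 0.0,
               0.0, -0.1), 2, 2, byrow = TRUE)
    ),
    residual_sd = c(1, 1),
    sampling_rate = sampling_rate,
    channel_names = c("PL", "IL")
  )
}

# Place n events in (lead, duration - tail] with a minimum gap. Events start
# after 2 s (the PSTH baseline window) and leave 2 s at the end.
place_events <- function(n, duration, min_gap, lead = 2.5, tail = 2.5) {
  if (n == 0) return(numeric(0))
  span <- duration - lead - tail - (n - 1) * min_gap
  if (span < 0) {
    abort(sprintf(
      "Cannot place %d events with %g s minimum gap in %g s.", n, min_gap,
      duration
    ))
  }
  jitter <- sort(runif(n, 0, span))
  lead + jitter + (seq_len(n) - 1) * min_gap
}

#' Simulate a full recording session with known ground truth
#'
#' Generates stimulus events, one inhomogeneous-Poisson spike train and mean
#' waveform per configured unit, and the multichannel VAR LFPs — all from the
#' config seed, so the whole session is reproducible.
#'
#' @param config A [sim_config].
#' @return An object of class `ephys_session`: a list with `units` (tibble
#'   with list-columns `spike_times` and `waveform` plus the true class
#'   labels), `events`, `lfps` (named list of [lfp_record]), and `config`.
#' @examples
#' s <- simulate_session(sim_config(seed = 1, session_duration = 120,
#'                                  n_trials = 5, min_event_gap = 10))
#' s$units$true_response
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    events <- place_events(config$n_trials, config$session_duration,
                           config$min_event_gap)
    n_units <- nrow(config$units)
    units <- config$units
    units$unit_id <- sprintf("u%02d", seq_len(n_units))
    units$true_response <- dplyr::case_when(
      units$response_gain > 1 ~ "excitatory",
      units$response_gain < 1 ~ "inhibitory",
      TRUE ~ "neutral"
    )
    units$true_width_class <- ifelse(units$width_ms < 0.5,
                                     "putative_interneuron",
                                     "putative_pyramidal")
    units$spike_times <- lapply(seq_len(n_units), function(i) {
      prof <- stimulus_rate_profile(
        config$session_duration, units$baseline_rate[i], events,
        units$response_gain[i], config$response_window
      )
      simulate_spike_train(prof, config$session_duration)
    })
    units$waveform <- lapply(seq_len(n_units), function(i) {
      simulate_waveform(units$width_ms[i])
    })
    n_lfp <- round(config$session_duration * config$lfp_sampling_rate)
    x <- simulate_var_lfp(config$var_model, n_lfp)
    lfps <- lapply(seq_len(ncol(x)), function(j) {
      lfp_record(x[, j], config$lfp_sampling_rate,
                 channel_id = config$var_model$channel_names[j],
                 region_label = config$lfp_regions[j])
    })
    names(lfps) <- config$lfp_regions
    structure(
      list(
        units = dplyr::relocate(units, "unit_id"),
        events = events,
        lfps = lfps,
        config = config
      ),
      class = "ephys_session"
    )
  })
}

#' @export
print.ephys_session <- function(x, ...) {
  cat(sprintf(
    "<ephys_session> %d units, %d events, %d LFP channel(s), %.0f s (seed %d)\n",
    nrow(x$units), length(x$events), length(x$lfps),
    x$config$session_duration, x$config$seed
  ))
  invisible(x)
}
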