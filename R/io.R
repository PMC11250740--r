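# Session serialization.
#
# Timestamps (events, spikes) go to one-column delimited text in seconds with
# 6 decimals; waveforms and LFPs to flat little-endian float32 binaries with
# a JSON sidecar (sampling rate, channel, region, units); ground truth to
# JSON.

write_timestamps <- function(x, path) {
  writeLines(sprintf("%.6f", x), path)
}

read_timestamps <- function(path) {
  if (!file.exists(path)) abort(sprintf("Missing timestamp file: %s", path))
  x <- suppressWarnings(as.numeric(readLines(path)))
  if (anyNA(x)) abort(sprintf("Non-numeric line in timestamp file: %s", path))
  x
}

write_float32 <- function(x, path, sidecar) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  jsonlite::write_json(sidecar, sub("\\.bin$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
}

read_float32 <- function(path) {
  side_path <- sub("\\.bin$", ".json", path)
  if (!file.exists(path)) abort(sprintf("Missing binary file: %s", path))
  if (!file.exists(side_path)) {
    abort(sprintf("Missing JSON sidecar for %s", path))
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  n <- file.info(path)$size / 4
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  list(samples = x, sidecar = side)
}

#' Write a simulated session to a directory
#'
#' Lays out one directory per session: `events.txt`, per-unit
#' `spikes_<id>.txt` and `waveform_<id>.bin/.json`, per-channel
#' `lfp_<region>.bin/.json`, and `truth.json` echoing the generating
#' parameters and true labels.
#'
#' @param session An `ephys_session` from [simulate_session()].
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ephys_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_timestamps(session$events, file.path(dir, "events.txt"))
  u <- session$units
  for (i in seq_len(nrow(u))) {
    write_timestamps(u$spike_times[[i]],
                     file.path(dir, sprintf("spikes_%s.txt", u$unit_id[i])))
    write_float32(
      u$waveform[[i]],
      file.path(dir, sprintf("waveform_%s.bin", u$unit_id[i])),
      list(sampling_rate = 30000, unit_id = u$unit_id[i],
           region = u$region[i], units = "a.u.")
    )
  }
  for (nm in names(session$lfps)) {
    l <- session$lfps[[nm]]
    write_float32(
      l$samples, file.path(dir, sprintf("lfp_%s.bin", nm)),
      list(sampling_rate = l$sampling_rate, channel = l$channel_id,
           region = l$region_label, units = "uV")
    )
  }
  cfg <- session$config
  truth <- list(
    seed = cfg$seed,
    session_duration = cfg$session_duration,
    lfp_sampling_rate = cfg$lfp_sampling_rate,
    n_trials = cfg$n_trials,
    min_event_gap = cfg$min_event_gap,
    response_window = cfg$response_window,
    units = u[, c("unit_id", "region", "baseline_rate", "response_gain",
                  "width_ms", "true_response", "true_width_class")],
    var_order = cfg$var_model$order,
    var_coefficients = cfg$var_model$coefficients,
    residual_sd = cfg$var_model$residual_sd,
    lfp_regions = cfg$lfp_regions
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a session directory back into analysis objects
#'
#' @param dir A directory written by [write_session()] (or following the
#'   same layout).
#' @return A list with `events`, `units` (tibble with `unit_id`, `region`,
#'   `spike_times`, `waveform`, `waveform_sampling_rate`), `lfps` (named
#'   list of [lfp_record]), and `truth` (parsed `truth.json`, or `NULL`).
#' @export
read_session <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("Session directory not found: %s", dir))
  events <- read_timestamps(file.path(dir, "events.txt"))
  spike_files <- sort(list.files(dir, pattern = "^spikes_.*\\.txt$"))
  unit_ids <- sub("^spikes_(.*)\\.txt$", "\\1", spike_files)
  units <- purrr::map_dfr(seq_along(unit_ids), function(i) {
    wf <- read_float32(file.path(dir, sprintf("waveform_%s.bin", unit_ids[i])))
    tibble(
      unit_id = unit_ids[i],
      region = wf$sidecar$region %||% NA_character_,
      spike_times = list(read_timestamps(file.path(dir, spike_files[i]))),
      waveform = list(wf$samples),
      waveform_sampling_rate = wf$sidecar$sampling_rate %||% 30000
    )
  })
  lfp_files <- sort(list.files(dir, pattern = "^lfp_.*\\.bin$"))
  lfps <- lapply(lfp_files, function(f) {
    r <- read_float32(file.path(dir, f))
    lfp_record(r$samples, r$sidecar$sampling_rate,
               channel_id = r$sidecar$channel %||% sub("^lfp_(.*)\\.bin$", "\\1", f),
               region_label = r$sidecar$region %||% NA_character_)
  })
  names(lfps) <- sub("^lfp_(.*)\\.bin$", "\\1", lfp_files)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  list(events = events, units = units, lfps = lfps, truth = truth)
}
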