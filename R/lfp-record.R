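#' Local field potential record
#'
#' Container for a uniformly sampled extracellular voltage trace. All spectral
#' and connectivity functions in the package accept these records.
#'
#' @param samples Numeric vector of voltage samples (conventionally in uV).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_id Channel identifier.
#' @param region_label Anatomical region the channel was recorded from
#'   (e.g. `"PL"`, `"IL"`).
#'
#' @return An object of class `lfp_record`.
#' @examples
#' lfp <- lfp_record(sin(2 * pi * 7 * seq(0, 1, by = 1 / 1250)), 1250)
#' lfp
#' @export
lfp_record <- function(samples, sampling_rate, channel_id = "ch1",
                       region_label = NA_character_) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty numeric vector.")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite (no NA/Inf).")
  }
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 0, strict = TRUE)
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate = as.numeric(sampling_rate),
      channel_id = as.character(channel_id),
      region_label = as.character(region_label)
    ),
    class = "lfp_record"
  )
}

#' @export
print.lfp_record <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf(
    "<lfp_record> channel %s (%s): %d samples @ %g Hz (%.2f s)\n",
    x$channel_id, x$region_label, length(x$samples), x$sampling_rate, dur
  ))
  invisible(x)
}

#' @export
length.lfp_record <- function(x) length(x$samples)

#' Tidy an LFP record into a time/voltage tibble
#'
#' @param x An [lfp_record].
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `voltage`, `channel_id`,
#'   `region_label`.
#' @export
tidy.lfp_record <- function(x, ...) {
  tibble(
    time = (seq_along(x$samples) - 1) / x$sampling_rate,
    voltage = x$samples,
    channel_id = x$channel_id,
    region_label = x$region_label
  )
}
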