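#' Standard LFP preprocessing: down-sample, band-pass, notch
#'
#' Brings a raw trace to the analysis rate (default 1250 Hz) with an
#' anti-alias low-pass before decimation, band-pass filters 1-100 Hz and
#' notch filters 48-52 Hz (mains). All filtering is zero-phase
#' (forward-backward Butterworth), so stimulus alignment is preserved; the
#' band-pass is realised as a high-pass/low-pass cascade, which is
#' numerically safer than a single narrow-band transfer function at these
#' relative frequencies.
#'
#' @param lfp An [lfp_record] with sampling rate >= `target_rate`; the input
#'   rate must be an integer multiple of `target_rate`.
#' @param target_rate Output sampling rate in Hz (default 1250).
#' @param bandpass Length-2 pass band in Hz (default `c(1, 100)`).
#' @param notch Length-2 stop band in Hz (default `c(48, 52)`); `NULL` skips
#'   the notch.
#' @return A new [lfp_record] at `target_rate`.
#' @export
preprocess_lfp <- function(lfp, target_rate = 1250, bandpass = c(1, 100),
                           notch = c(48, 52)) {
  stopifnot(inherits(lfp, "lfp_record"))
  fs <- lfp$sampling_rate
  if (fs < target_rate) {
    abort(sprintf(
      "Sampling rate %g Hz is below the target %g Hz; cannot down-sample.",
      fs, target_rate
    ))
  }
  x <- lfp$samples
  if (fs > target_rate) {
    q <- fs / target_rate
    if (abs(q - round(q)) > 1e-9) {
      abort(sprintf(
        "Sampling rate %g Hz is not an integer multiple of %g Hz.",
        fs, target_rate
      ))
    }
    q <- as.integer(round(q))
    aa <- signal::butter(4, (0.45 * target_rate) / (fs / 2), type = "low")
    x <- signal::filtfilt(aa, x)
    x <- x[seq(1, length(x), by = q)]
    fs <- target_rate
  }
  x <- bandpass_filtfilt(x, fs, bandpass)
  if (!is.null(notch)) {
    bs <- signal::butter(2, notch / (fs / 2), type = "stop")
    x <- signal::filtfilt(bs, x)
  }
  lfp_record(x, fs, lfp$channel_id, lfp$region_label)
}

# Zero-phase band-pass as high-pass then low-pass 4th-order Butterworth.
# The mean is removed first: a DC offset would otherwise excite large edge
# transients in the high-pass (and is rejected by the 1 Hz corner anyway).
bandpass_filtfilt <- function(x, fs, band) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  nyq <- fs / 2
  if (band[2] >= nyq) abort("Band-pass upper edge must be below Nyquist.")
  x <- x - mean(x)
  hp <- signal::butter(4, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Fragment an LFP into equal non-overlapping segments, band-passed 1-46 Hz
#'
#' Splits the record into consecutive `seg_len`-second segments (any trailing
#' remainder is dropped) after a 1-46 Hz zero-phase band-pass — the
#' spectral-analysis band that avoids motor and mains contamination.
#'
#' @param lfp An [lfp_record] at the analysis rate.
#' @param seg_len Segment length in seconds (default 10).
#' @param bandpass Band in Hz applied before segmentation (default
#'   `c(1, 46)`); `NULL` skips filtering.
#' @return A samples x segments numeric matrix of class `lfp_segments` with
#'   attributes `sampling_rate` and `seg_len`.
#' @export
segment_lfp <- function(lfp, seg_len = 10, bandpass = c(1, 46)) {
  stopifnot(inherits(lfp, "lfp_record"))
  assert_scalar_num(seg_len, "seg_len", 0, strict = TRUE)
  n_seg_samp <- round(seg_len * lfp$sampling_rate)
  n <- length(lfp$samples)
  if (n < n_seg_samp) {
    abort(sprintf(
      "Record (%.2f s) is shorter than one %g-s segment.",
      n / lfp$sampling_rate, seg_len
    ))
  }
  x <- lfp$samples
  if (!is.null(bandpass)) x <- bandpass_filtfilt(x, lfp$sampling_rate, bandpass)
  n_segs <- floor(n / n_seg_samp)
  m <- matrix(x[seq_len(n_segs * n_seg_samp)], nrow = n_seg_samp)
  structure(m, sampling_rate = lfp$sampling_rate, seg_len = seg_len,
            class = c("lfp_segments", "matrix", "array"))
}
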