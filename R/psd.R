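#' Multitaper power spectral density, absolute and relative
#'
#' Per segment, direct spectral estimates with the first `k` Slepian tapers
#' (time-bandwidth product `nw`) are averaged over tapers, then over
#' segments. The result is restricted to the analysis grid (default 1-46 Hz
#' at the segment's natural resolution, 0.1 Hz for 10-s segments) and the
#' relative PSD is each frequency's fraction of the total power on that
#' grid, so it sums to 1.
#'
#' @param segments An [segment_lfp()] result, or a numeric matrix
#'   (samples x segments) with `sampling_rate` passed explicitly. A plain
#'   vector is treated as one segment.
#' @param sampling_rate Sampling rate in Hz (taken from `segments` when
#'   available).
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5).
#' @param fmin,fmax Analysis band edges in Hz (default 1 and 46, both grid
#'   points included).
#' @return An object of class `psd_result`: list with `spectrum` (tibble
#'   `freq`, `absolute`, `relative`), `n_segments`, `nw`, `k`,
#'   `sampling_rate`.
#' @examples
#' lfp <- lfp_record(rnorm(12500), 1250)
#' psd <- multitaper_psd(segment_lfp(lfp))
#' sum(psd$spectrum$relative)
#' @export
multitaper_psd <- function(segments, sampling_rate = NULL, nw = 3, k = 5,
                           fmin = 1, fmax = 46) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    segments <- matrix(segments, ncol = 1)
  }
  sampling_rate <- sampling_rate %||% attr(segments, "sampling_rate")
  if (is.null(sampling_rate)) abort("`sampling_rate` is required.")
  n <- nrow(segments)
  n_segs <- ncol(segments)
  if (n_segs < 1) abort("Need at least one segment.")
  tapers <- dpss_tapers(n, nw, k)
  df <- sampling_rate / n
  n_keep <- floor(n / 2) + 1
  psd_acc <- numeric(n_keep)
  for (s in seq_len(n_segs)) {
    x <- segments[, s]
    tap_spec <- matrix(0, n_keep, k)
    for (j in seq_len(k)) {
      X <- fft(x * tapers[, j])[seq_len(n_keep)]
      tap_spec[, j] <- Mod(X)^2 / sampling_rate
    }
    psd_acc <- psd_acc + rowMeans(tap_spec)
  }
  psd_all <- psd_acc / n_segs
  freqs <- (seq_len(n_keep) - 1) * df
  keep <- freqs >= fmin - 1e-9 & freqs <= fmax + 1e-9
  freq <- freqs[keep]
  absolute <- psd_all[keep]
  relative <- absolute / sum(absolute)
  structure(
    list(
      spectrum = tibble(freq = freq, absolute = absolute, relative = relative),
      n_segments = n_segs,
      nw = nw,
      k = k,
      sampling_rate = sampling_rate
    ),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %d frequencies [%g, %g] Hz, %d segment(s), nw = %g, %d tapers\n",
    nrow(x$spectrum), min(x$spectrum$freq), max(x$spectrum$freq),
    x$n_segments, x$nw, x$k
  ))
  invisible(x)
}

#' @export
tidy.psd_result <- function(x, ...) x$spectrum

#' @export
glance.psd_result <- function(x, ...) {
  tibble(
    n_freq = nrow(x$spectrum),
    fmin = min(x$spectrum$freq),
    fmax = max(x$spectrum$freq),
    n_segments = x$n_segments,
    nw = x$nw,
    k = x$k,
    total_power = sum(x$spectrum$absolute)
  )
}

#' Canonical frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-46 Hz. Bands are
#' half-open `[lo, hi)` — a shared boundary frequency belongs to the upper
#' band — except the top band, which includes its upper edge.
#'
#' @return Tibble with `band`, `lo`, `hi`.
#' @export
canonical_bands <- function() {
  tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                  levels = c("delta", "theta", "alpha", "beta", "gamma")),
    lo = c(1, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 46)
  )
}

#' Band power summary of a PSD
#'
#' Sums relative PSD (so relative band powers add to 1 exactly) and
#' integrates absolute PSD (rectangle rule on the grid) over each band;
#' the mean absolute PSD per band is also reported.
#'
#' @param psd A [multitaper_psd()] result.
#' @param bands Band definition tibble (`band`, `lo`, `hi`); default
#'   [canonical_bands()].
#' @return Tibble with one row per band: `band`, `lo`, `hi`, `relative`,
#'   `absolute_integral`, `absolute_mean`.
#' @export
band_power <- function(psd, bands = canonical_bands()) {
  stopifnot(inherits(psd, "psd_result"))
  sp <- psd$spectrum
  df <- stats::median(diff(sp$freq))
  top <- max(bands$hi)
  purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    lo <- bands$lo[i]
    hi <- bands$hi[i]
    inb <- sp$freq >= lo - 1e-9 &
      (if (hi >= top) sp$freq <= hi + 1e-9 else sp$freq < hi - 1e-9)
    tibble(
      band = bands$band[i], lo = lo, hi = hi,
      relative = sum(sp$relative[inb]),
      absolute_integral = sum(sp$absolute[inb]) * df,
      absolute_mean = mean(sp$absolute[inb])
    )
  })
}

#' LFP record straight to PSD
#'
#' Convenience chain: [segment_lfp()] then [multitaper_psd()].
#'
#' @param lfp An [lfp_record] at the analysis rate.
#' @inheritParams segment_lfp
#' @inheritParams multitaper_psd
#' @return A `psd_result`.
#' @export
lfp_psd <- function(lfp, seg_len = 10, bandpass = c(1, 46), nw = 3, k = 5,
                    fmin = 1, fmax = 46) {
  multitaper_psd(segment_lfp(lfp, seg_len, bandpass), nw = nw, k = k,
                 fmin = fmin, fmax = fmax)
}
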