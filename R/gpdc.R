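#' Spectral coefficient matrix of an MVAR model
#'
#' Evaluates \eqn{\bar{A}(f) = I - \sum_{r=1}^{p} A_r e^{-i 2\pi f r / fs}}
#' on a frequency grid — the Fourier-domain transform of the coefficient
#' matrices from which partial directed coherence is built. With all
#' coefficients zero it is the identity at every frequency, and at f = 0 it
#' reduces to the real matrix \eqn{I - \sum_r A_r}.
#'
#' @param model An [mvar_model].
#' @param freqs Frequencies in Hz, all below Nyquist.
#' @return Complex array k x k x length(freqs).
#' @export
mvar_transfer <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"))
  if (any(freqs >= model$sampling_rate / 2)) {
    abort("All frequencies must be below Nyquist.")
  }
  k <- model$n_channels
  p <- model$order
  out <- array(0 + 0i, dim = c(k, k, length(freqs)))
  I <- diag(k)
  for (fi in seq_along(freqs)) {
    ph <- exp(-2i * pi * freqs[fi] * seq_len(p) / model$sampling_rate)
    A <- I
    for (r in seq_len(p)) A <- A - model$coefficients[[r]] * ph[r]
    out[, , fi] <- A
  }
  out
}

#' Generalized partial directed coherence
#'
#' For every ordered channel pair and frequency,
#' \deqn{|C_{i \leftarrow j}(f)| = \frac{|\bar{A}_{ij}(f)| / \sigma_i}
#'   {\sqrt{\sum_k |\bar{A}_{kj}(f)|^2 / \sigma_k^2}}}
#' with \eqn{\sigma_k} the residual standard deviation of channel k. The
#' residual-variance weighting in the numerator makes the measure invariant
#' to channel scale and gives the structural normalization
#' \eqn{\sum_i |C_{i \leftarrow j}(f)|^2 = 1} for every source column j, so
#' all values lie in `[0, 1]`: 0 means no influence of source j on target i
#' at that frequency, 1 a linearly predictable target. Off-diagonal values
#' are exactly 0 for diagonal (uncoupled) coefficient matrices.
#'
#' @param model An [mvar_model] with positive residual SDs.
#' @param freqs Frequency grid in Hz (default `seq(1, 46, by = 0.1)`,
#'   matching the spectral pipeline's grid).
#' @return An object of class `gpdc_spectrum`: list with `table` (tibble
#'   `freq`, `target`, `source`, `direction` ("target<-source"), `gpdc`),
#'   `freqs`, `channel_names`, and the generating `model`.
#' @examples
#' g <- gpdc(default_var_model())
#' max(g$table$gpdc)
#' @export
gpdc <- function(model, freqs = seq(1, 46, by = 0.1)) {
  stopifnot(inherits(model, "mvar_model"))
  if (any(model$residual_sd <= 0)) abort("All residual SDs must be > 0.")
  if (any(freqs <= 0) || any(freqs >= model$sampling_rate / 2)) {
    abort("Frequencies must lie in (0, Nyquist).")
  }
  k <- model$n_channels
  Abar <- mvar_transfer(model, freqs)
  w <- 1 / model$residual_sd          # per-target weight
  nf <- length(freqs)
  val <- array(0, dim = c(k, k, nf))
  for (fi in seq_len(nf)) {
    num <- Mod(Abar[, , fi]) * w      # |A_ij| / sigma_i
    denom <- sqrt(colSums(num^2))     # per source column j
    val[, , fi] <- sweep(num, 2, denom, "/")
  }
  nms <- model$channel_names
  tbl <- tibble(
    freq = rep(freqs, each = k * k),
    target = rep(rep(nms, times = k), times = nf),
    source = rep(rep(nms, each = k), times = nf),
    gpdc = as.vector(val)
  )
  tbl$direction <- paste0(tbl$target, "<-", tbl$source)
  structure(
    list(table = tbl, freqs = freqs, channel_names = nms, model = model),
    class = "gpdc_spectrum"
  )
}

#' @export
print.gpdc_spectrum <- function(x, ...) {
  cat(sprintf(
    "<gpdc_spectrum> %d channels, %d frequencies [%g, %g] Hz\n",
    length(x$channel_names), length(x$freqs), min(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

#' @export
tidy.gpdc_spectrum <- function(x, ...) x$table

#' @export
glance.gpdc_spectrum <- function(x, ...) {
  off <- x$table[x$table$target != x$table$source, ]
  tibble(
    n_channels = length(x$channel_names),
    n_freq = length(x$freqs),
    max_gpdc = max(x$table$gpdc),
    max_offdiag_gpdc = if (nrow(off)) max(off$gpdc) else NA_real_
  )
}

#' Band-mean gPDC per ordered channel pair
#'
#' Mean gPDC magnitude over a frequency band for each ordered (target,
#' source) pair — the scalar used to compare directed coupling between, say,
#' beta-gamma band influence in the two directions.
#'
#' @param spectrum A [gpdc()] result.
#' @param band Length-2 Hz interval (closed); must intersect the grid.
#' @return Tibble with `target`, `source`, `direction`, `band_lo`, `band_hi`,
#'   `mean_gpdc`.
#' @examples
#' directional_band_gpdc(gpdc(default_var_model()), band = c(20, 46))
#' @export
directional_band_gpdc <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "gpdc_spectrum"), length(band) == 2)
  tbl <- spectrum$table
  inb <- tbl$freq >= band[1] - 1e-9 & tbl$freq <= band[2] + 1e-9
  if (!any(inb)) abort("Band does not intersect the frequency grid.")
  tbl[inb, ] |>
    dplyr::group_by(.data$target, .data$source, .data$direction) |>
    dplyr::summarise(mean_gpdc = mean(.data$gpdc), .groups = "drop") |>
    dplyr::mutate(band_lo = band[1], band_hi = band[2]) |>
    dplyr::relocate("target", "source", "direction", "band_lo", "band_hi")
}

#' Point-by-point FDR-corrected comparison of gPDC spectra
#'
#' For one ordered direction, per-frequency unpaired two-sided t-tests
#' between two groups of gPDC spectra with Benjamini-Hochberg adjustment
#' across the grid; maximal runs of adjacent significant frequencies are
#' reported as intervals.
#'
#' @param group_a,group_b Lists of [gpdc()] results (>= 2 each) on identical
#'   grids.
#' @param target,source Channel names (or indices) selecting the direction
#'   target <- source.
#' @param q FDR level (default 0.05).
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return A `pointwise_test` object.
#' @export
pointwise_gpdc_test <- function(group_a, group_b, target, source, q = 0.05,
                                var_equal = TRUE) {
  extract <- function(g) {
    stopifnot(all(vapply(g, inherits, logical(1), "gpdc_spectrum")))
    freqs <- g[[1]]$freqs
    mat <- do.call(rbind, lapply(g, function(s) {
      if (length(s$freqs) != length(freqs) ||
          max(abs(s$freqs - freqs)) > 1e-9) {
        abort("All gPDC spectra must share one frequency grid.")
      }
      nms <- s$channel_names
      tg <- if (is.numeric(target)) nms[target] else target
      sr <- if (is.numeric(source)) nms[source] else source
      rows <- s$table$target == tg & s$table$source == sr
      if (!any(rows)) abort("Requested direction not present in spectrum.")
      s$table$gpdc[rows]
    }))
    list(freqs = freqs, mat = mat)
  }
  a <- extract(group_a)
  b <- extract(group_b)
  if (length(a$freqs) != length(b$freqs) ||
      max(abs(a$freqs - b$freqs)) > 1e-9) {
    abort("Frequency grids differ between groups.")
  }
  pointwise_core(a$mat, b$mat, a$freqs, q, var_equal)
}

#' Segment-averaged gPDC of a two-region recording
#'
#' Mirrors the segment-based spectral pipeline: the multichannel series is
#' cut into segments, one MVAR model is fitted per segment, and the gPDC
#' spectra are averaged across segments.
#'
#' @param signals Samples x channels matrix or list of [lfp_record]s.
#' @param sampling_rate Hz (taken from records when given).
#' @param seg_len Segment length in seconds (default 10); `NULL` fits one
#'   model to the whole record.
#' @param freqs Frequency grid (Hz).
#' @inheritParams fit_mvar
#' @return A `gpdc_spectrum` whose table is the across-segment mean; the
#'   `model` element is the last segment's fit and `n_segments` records the
#'   averaging count.
#' @export
segment_gpdc <- function(signals, sampling_rate = NULL, seg_len = 10,
                         freqs = seq(1, 46, by = 0.1), max_order = 12,
                         criterion = "bic") {
  if (is.list(signals) && all(vapply(signals, inherits, logical(1), "lfp_record"))) {
    rates <- vapply(signals, function(l) l$sampling_rate, numeric(1))
    sampling_rate <- sampling_rate %||% rates[1]
    nms <- vapply(signals, function(l) l$channel_id, character(1))
    signals <- do.call(cbind, lapply(signals, function(l) l$samples))
    colnames(signals) <- nms
  }
  x <- as.matrix(signals)
  if (is.null(sampling_rate)) abort("`sampling_rate` is required.")
  n <- nrow(x)
  if (is.null(seg_len)) {
    starts <- 1
    seg_n <- n
  } else {
    seg_n <- round(seg_len * sampling_rate)
    if (n < seg_n) abort("Record shorter than one segment.")
    starts <- seq(1, n - seg_n + 1, by = seg_n)
  }
  specs <- lapply(starts, function(s0) {
    fit <- fit_mvar(x[s0:(s0 + seg_n - 1), , drop = FALSE],
                    max_order = max_order, criterion = criterion,
                    sampling_rate = sampling_rate)
    gpdc(fit, freqs)
  })
  avg <- specs[[1]]
  if (length(specs) > 1) {
    acc <- Reduce(`+`, lapply(specs, function(s) s$table$gpdc))
    avg$table$gpdc <- acc / length(specs)
  }
  avg$n_segments <- length(specs)
  avg
}
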