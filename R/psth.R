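#' Trial-aligned spike-count tensor
#'
#' Bins a unit's spikes around each stimulus onset into a trials x bins count
#' matrix — the substrate for response classification and Z-scored PSTHs.
#' Bins are half-open `[lo, hi)` in time relative to onset, so a spike
#' exactly at onset falls in the first post-onset bin.
#'
#' @param spike_times Sorted spike times (s). A unit row or list with a
#'   `spike_times` element is also accepted.
#' @param events Sorted stimulus onset times (s).
#' @param bin_width Bin width in seconds (default 0.1 s).
#' @param window Length-2 window around onset in seconds (default `c(-2, 2)`);
#'   must span the onset and be an exact multiple of `bin_width`.
#' @return An object of class `trial_tensor`: integer matrix (trials x bins)
#'   with attributes `bin_width`, `window`, `bin_lo` (left edges, s relative
#'   to onset) and `events`. A warning is raised when trial windows overlap.
#' @examples
#' tt <- build_trial_tensor(c(0.95, 1.05), events = 1)
#' which(tt == 1)
#' @export
build_trial_tensor <- function(spike_times, events, bin_width = 0.1,
                               window = c(-2, 2)) {
  if (is.list(spike_times) && !is.null(spike_times$spike_times)) {
    spike_times <- spike_times$spike_times
  }
  spike_times <- as.numeric(spike_times)
  events <- as.numeric(events)
  if (length(events) == 0) abort("`events` must contain at least one onset.")
  if (is.unsorted(events)) abort("`events` must be sorted.")
  assert_scalar_num(bin_width, "bin_width", 0, strict = TRUE)
  stopifnot(length(window) == 2, window[1] < 0, window[2] > 0)
  n_bins <- (window[2] - window[1]) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort("`window` must span an integer number of bins.")
  }
  n_bins <- as.integer(round(n_bins))
  if (length(events) > 1 &&
      any(diff(events) < (window[2] - window[1]) - 1e-12)) {
    warn("Trial windows overlap; spikes may be counted in multiple trials.")
  }
  edges <- window[1] + bin_width * (0:n_bins)
  counts <- matrix(0L, length(events), n_bins)
  for (t in seq_along(events)) {
    rel <- spike_times - events[t]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      idx <- findInterval(rel, edges, rightmost.closed = FALSE)
      tab <- tabulate(idx, nbins = n_bins)
      counts[t, ] <- as.integer(tab)
    }
  }
  structure(
    counts,
    bin_width = bin_width,
    window = window,
    bin_lo = edges[-length(edges)],
    events = events,
    class = c("trial_tensor", "matrix", "array")
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf(
    "<trial_tensor> %d trials x %d bins (%g s bins, window [%g, %g] s)\n",
    nrow(x), ncol(x), attr(x, "bin_width"), attr(x, "window")[1],
    attr(x, "window")[2]
  ))
  invisible(x)
}

#' Tidy a trial tensor into long form
#'
#' @param x A [build_trial_tensor()] result.
#' @param ... Unused.
#' @return Tibble with `trial`, `bin`, `bin_start` (s relative to onset),
#'   `count`, `rate` (Hz).
#' @export
tidy.trial_tensor <- function(x, ...) {
  bw <- attr(x, "bin_width")
  tibble(
    trial = rep(seq_len(nrow(x)), times = ncol(x)),
    bin = rep(seq_len(ncol(x)), each = nrow(x)),
    bin_start = rep(attr(x, "bin_lo"), each = nrow(x)),
    count = as.integer(x),
    rate = as.numeric(x) / bw
  )
}

post_onset_bins <- function(tensor) which(attr(tensor, "bin_lo") >= 0)
pre_onset_bins <- function(tensor) which(attr(tensor, "bin_lo") < 0)

#' Classify a unit's evoked response from its trial tensor
#'
#' Per trial, the baseline is the mean rate over the pre-onset bins. Each
#' post-onset bin's per-trial rate is compared to the per-trial baseline with
#' a paired two-sided t-test. The unit is excitatory if any significant bin
#' lies above baseline, inhibitory if below; when both directions reach
#' significance the earliest significant bin decides. Bins whose paired
#' differences have zero variance are non-significant by convention, so
#' deterministic flat tensors come out neutral.
#'
#' @param tensor A [build_trial_tensor()] result with at least 2 trials.
#' @param alpha Two-sided significance level per bin (default 0.05). No
#'   correction is applied across post-onset bins; the resulting family-wise
#'   rate is a measured property, not an assumption.
#' @return An object of class `response_label`: list with `label`
#'   (`excitatory` / `inhibitory` / `neutral`), `per_bin_p` (one p per
#'   post-onset bin), `per_bin_delta` (mean rate minus baseline, Hz),
#'   `first_significant_bin` (index among post-onset bins, or `NA`).
#' @export
classify_response <- function(tensor, alpha = 0.05) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (nrow(tensor) < 2) abort("Response classification needs >= 2 trials.")
  bw <- attr(tensor, "bin_width")
  pre <- pre_onset_bins(tensor)
  post <- post_onset_bins(tensor)
  if (!length(pre) || !length(post)) {
    abort("Window must include pre- and post-onset bins.")
  }
  baseline <- rowMeans(tensor[, pre, drop = FALSE]) / bw  # Hz, per trial
  rates <- tensor[, post, drop = FALSE] / bw
  stats_per_bin <- purrr::map(seq_along(post), function(b) {
    d <- rates[, b] - baseline
    if (sd(d) == 0) {
      list(p = 1, delta = mean(d))
    } else {
      list(p = t.test(d)$p.value, delta = mean(d))
    }
  })
  p <- vapply(stats_per_bin, `[[`, numeric(1), "p")
  delta <- vapply(stats_per_bin, `[[`, numeric(1), "delta")
  sig <- which(p < alpha)
  mixed <- FALSE
  if (!length(sig)) {
    label <- "neutral"
    first <- NA_integer_
  } else {
    first <- sig[1]
    dirs <- sign(delta[sig])
    mixed <- length(unique(dirs[dirs != 0])) > 1
    if (mixed) {
      warn("Both excitatory and inhibitory bins significant; labelling by earliest.")
    }
    label <- if (delta[first] > 0) "excitatory" else "inhibitory"
  }
  structure(
    list(
      label = label,
      per_bin_p = p,
      per_bin_delta = delta,
      first_significant_bin = first,
      mixed_directions = mixed,
      alpha = alpha
    ),
    class = "response_label"
  )
}

#' @export
print.response_label <- function(x, ...) {
  cat(sprintf(
    "<response_label> %s (first significant post-onset bin: %s)\n", x$label,
    ifelse(is.na(x$first_significant_bin), "none", x$first_significant_bin)
  ))
  invisible(x)
}

#' @export
tidy.response_label <- function(x, ...) {
  tibble(
    post_bin = seq_along(x$per_bin_p),
    p_value = x$per_bin_p,
    delta_rate = x$per_bin_delta,
    significant = x$per_bin_p < x$alpha
  )
}

#' @export
glance.response_label <- function(x, ...) {
  tibble(
    label = x$label,
    first_significant_bin = x$first_significant_bin,
    n_significant = sum(x$per_bin_p < x$alpha),
    alpha = x$alpha
  )
}

#' Z-score-transformed average PSTH
#'
#' The trial-averaged PSTH is standardised against its own pre-onset bins:
#' each bin's Z is its distance from the mean of the baseline bins in units
#' of their standard deviation. Units whose baseline bins have zero spread
#' are unscorable and yield all-NaN with a warning.
#'
#' @param tensor A [build_trial_tensor()] result.
#' @return Tibble with `bin_start` (s relative to onset), `mean_rate` (Hz)
#'   and `z`.
#' @export
zscore_psth <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  bw <- attr(tensor, "bin_width")
  m <- colMeans(tensor) / bw
  pre <- pre_onset_bins(tensor)
  mu <- mean(m[pre])
  s <- sd(m[pre])
  if (s == 0) {
    warn("Baseline bins of the mean PSTH have zero SD; unit is unscorable (all NaN).")
    z <- rep(NaN, length(m))
  } else {
    z <- (m - mu) / s
  }
  tibble(bin_start = attr(tensor, "bin_lo"), mean_rate = m, z = z)
}

#' Firing-rate modulation index
#'
#' `|f_after - f_before| / (f_after + f_before)`: a bounded, dimensionless
#' measure of evoked rate change, 0 for no change and 1 for one-sided firing.
#' Vectorised over its arguments.
#'
#' @param f_before Mean firing rate over the 2 s before onset (Hz).
#' @param f_after Mean firing rate over the 2 s after onset (Hz).
#' @return Numeric in `[0, 1]`; `NA` (with a warning) where both rates are 0.
#' @examples
#' modulation_index(1, 3)  # 0.5
#' @export
modulation_index <- function(f_before, f_after) {
  if (any(f_before < 0) || any(f_after < 0)) abort("Rates must be >= 0.")
  denom <- f_before + f_after
  out <- ifelse(denom > 0, abs(f_after - f_before) / denom, NA_real_)
  if (anyNA(out)) {
    warn("Modulation index undefined where both rates are 0; returned NA.")
  }
  out
}

#' Mean rates before/after onset and the modulation index for a tensor
#'
#' @param tensor A [build_trial_tensor()] result.
#' @return One-row tibble with `f_before`, `f_after` (Hz) and `index`.
#' @export
modulation_from_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  bw <- attr(tensor, "bin_width")
  pre <- pre_onset_bins(tensor)
  post <- post_onset_bins(tensor)
  f_before <- mean(tensor[, pre, drop = FALSE]) / bw
  f_after <- mean(tensor[, post, drop = FALSE]) / bw
  tibble(f_before = f_before, f_after = f_after,
         index = modulation_index(f_before, f_after))
}
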