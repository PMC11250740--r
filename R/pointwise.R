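# Point-by-point group comparison on a frequency grid, shared by the
# spectral (relative PSD) and connectivity (gPDC) pipelines.

# Vectorised two-sample t-tests per column of a (members x freq) matrix pair.
# Classic pooled-variance (Student) two-sided test; columns where both groups
# are constant and equal get p = 1 (no evidence of difference, no variance).
columnwise_t <- function(a, b, var_equal = TRUE) {
  na <- nrow(a)
  nb <- nrow(b)
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- apply(a, 2, var)
  vb <- apply(b, 2, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- !is.finite(tstat)
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  list(t = tstat, p = p, mean_a = ma, mean_b = mb)
}

# Maximal runs of adjacent significant grid points -> (lo, hi) Hz intervals.
significant_intervals <- function(freqs, mask) {
  if (!any(mask)) {
    return(tibble(lo = numeric(0), hi = numeric(0), n_points = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble(
    lo = freqs[starts[keep]],
    hi = freqs[ends[keep]],
    n_points = r$lengths[keep]
  )
}

pointwise_core <- function(mat_a, mat_b, freqs, q, var_equal = TRUE) {
  if (nrow(mat_a) < 2 || nrow(mat_b) < 2) {
    abort("Each group needs at least 2 members.")
  }
  if (ncol(mat_a) != ncol(mat_b)) abort("Frequency grids differ between groups.")
  ts <- columnwise_t(mat_a, mat_b, var_equal)
  adj <- fdr_bh(ts$p, q)
  res <- tibble(
    freq = freqs,
    mean_a = ts$mean_a,
    mean_b = ts$mean_b,
    statistic = ts$t,
    p_value = ts$p,
    p_adjusted = adj$p_adjusted,
    significant = adj$reject
  )
  structure(
    list(
      table = res,
      intervals = significant_intervals(freqs, res$significant),
      q = q,
      n_a = nrow(mat_a),
      n_b = nrow(mat_b)
    ),
    class = "pointwise_test"
  )
}

#' @export
print.pointwise_test <- function(x, ...) {
  cat(sprintf(
    "<pointwise_test> %d frequencies, n = %d vs %d, q = %g; %d significant point(s) in %d interval(s)\n",
    nrow(x$table), x$n_a, x$n_b, x$q, sum(x$table$significant),
    nrow(x$intervals)
  ))
  if (nrow(x$intervals)) {
    for (i in seq_len(nrow(x$intervals))) {
      cat(sprintf("  %g-%g Hz (%d points)\n", x$intervals$lo[i],
                  x$intervals$hi[i], x$intervals$n_points[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.pointwise_test <- function(x, ...) x$table

#' @export
glance.pointwise_test <- function(x, ...) {
  tibble(
    n_freq = nrow(x$table),
    n_significant = sum(x$table$significant),
    n_intervals = nrow(x$intervals),
    min_p_adjusted = min(x$table$p_adjusted),
    q = x$q,
    n_a = x$n_a,
    n_b = x$n_b
  )
}

#' Point-by-point FDR-corrected comparison of relative PSDs
#'
#' At each frequency of the common grid, the two groups' relative PSD values
#' are compared with an unpaired two-sided t-test; p-values are
#' Benjamini-Hochberg adjusted across the whole grid, and maximal runs of
#' adjacent significant frequencies are reported as intervals — the
#' frequency-interval readout used to contrast experimental groups.
#'
#' @param group_a,group_b Lists of [multitaper_psd()] results (>= 2 each) on
#'   identical frequency grids.
#' @param q FDR level (default 0.05).
#' @param measure Which PSD column to compare, `"relative"` (default) or
#'   `"absolute"`.
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return A `pointwise_test` object; `tidy()` gives the per-frequency table,
#'   `x$intervals` the significant intervals.
#' @export
pointwise_group_test <- function(group_a, group_b, q = 0.05,
                                 measure = c("relative", "absolute"),
                                 var_equal = TRUE) {
  measure <- match.arg(measure)
  grab <- function(g) {
    stopifnot(all(vapply(g, inherits, logical(1), "psd_result")))
    freqs <- g[[1]]$spectrum$freq
    for (p in g) {
      if (length(p$spectrum$freq) != length(freqs) ||
          max(abs(p$spectrum$freq - freqs)) > 1e-9) {
        abort("All PSDs must share one frequency grid.")
      }
    }
    list(freqs = freqs,
         mat = do.call(rbind, lapply(g, function(p) p$spectrum[[measure]])))
  }
  a <- grab(group_a)
  b <- grab(group_b)
  if (length(a$freqs) != length(b$freqs) ||
      max(abs(a$freqs - b$freqs)) > 1e-9) {
    abort("Frequency grids differ between groups.")
  }
  pointwise_core(a$mat, b$mat, a$freqs, q, var_equal)
}
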