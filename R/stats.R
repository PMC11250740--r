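#' Benjamini-Hochberg false discovery rate adjustment
#'
#' The step-up procedure: with m p-values sorted ascending, the adjusted
#' value at rank i is `min over j >= i of m * p_(j) / j`, capped at 1 and
#' mapped back to input order; hypotheses with adjusted p below `q` are
#' rejected. This is the FDR step shared by the spectral and connectivity
#' point-by-point comparisons.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A list with `p_adjusted` (same order as input) and `reject`
#'   (logical mask, `p_adjusted < q`).
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))$reject
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!is.numeric(p) || length(p) == 0) abort("`p` must be a numeric vector.")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1] with no NA.")
  }
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- rev(cummin(rev(m * ranked / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  list(p_adjusted = out, reject = out < q)
}

#' Two-group comparison with the field's standard tests
#'
#' Thin, uniform wrapper over the base tests used on pipeline outputs
#' (firing rates, band powers, gPDC summaries): Mann-Whitney, unpaired or
#' paired Student's t, and Wilcoxon signed-rank, all two-sided. Rank tests
#' use exact small-sample p-values when no ties permit it (the default of
#' [stats::wilcox.test()]), normal approximation otherwise; the mode used is
#' recorded.
#'
#' @param values_a,values_b Numeric samples; paired tests require equal
#'   lengths.
#' @param test One of `"mann_whitney"`, `"t_unpaired"`, `"t_paired"`,
#'   `"wilcoxon_signed_rank"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `direction` (sign of a-location minus b-location), `mode`
#'   (`exact` / `approximate` / `degenerate`).
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6), "mann_whitney")
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("mann_whitney", "t_unpaired", "t_paired",
                                    "wilcoxon_signed_rank")) {
  test <- match.arg(test)
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  paired <- test %in% c("t_paired", "wilcoxon_signed_rank")
  if (paired && length(a) != length(b)) {
    abort("Paired tests require equal-length samples.")
  }
  direction <- sign(stats::median(a) - stats::median(b))
  mode <- "exact"
  res <- switch(
    test,
    mann_whitney = {
      h <- suppressWarnings(wilcox.test(a, b, exact = NULL))
      ties <- any(duplicated(c(a, b)))
      mode <- if (!ties && length(a) < 50 && length(b) < 50) "exact" else "approximate"
      h
    },
    t_unpaired = {
      if (sd(a) == 0 && sd(b) == 0) NULL else t.test(a, b)
    },
    t_paired = {
      if (sd(a - b) == 0) NULL else t.test(a, b, paired = TRUE)
    },
    wilcoxon_signed_rank = {
      if (all(a == b)) NULL else {
        h <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = NULL))
        ties <- any(duplicated(abs(a - b)[a != b])) || any(a == b)
        mode <- if (!ties && length(a) < 50) "exact" else "approximate"
        h
      }
    }
  )
  if (is.null(res)) {
    warn(sprintf("`%s`: zero-variance (degenerate) comparison; p reported as NA.", test))
    return(tibble(test = test, statistic = NA_real_, p_value = NA_real_,
                  n_a = length(a), n_b = length(b), direction = direction,
                  mode = "degenerate"))
  }
  tibble(
    test = test,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_a = length(a),
    n_b = length(b),
    direction = direction,
    mode = mode
  )
}

#' Compare proportions with chi-squared or Fisher's exact test
#'
#' Uses the chi-squared test when every expected count is at least 5;
#' otherwise falls back to Fisher's exact test (2 x 2 tables only) — the
#' standard decision rule for response-class proportion tables. The choice
#' made is recorded.
#'
#' @param counts A 2 x k matrix of non-negative integer counts.
#' @param force One of `"auto"` (default), `"chisq"`, `"fisher"`.
#' @return One-row tibble: `test`, `statistic` (chi-squared statistic or NA
#'   for Fisher), `p_value`, `df`, `mode`.
#' @examples
#' proportion_test(matrix(c(5, 0, 0, 5), 2, 2))
#' @export
proportion_test <- function(counts, force = c("auto", "chisq", "fisher")) {
  force <- match.arg(force)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (nrow(counts) != 2) abort("`counts` must have exactly 2 rows.")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  use_fisher <- switch(force,
    auto = any(expected < 5),
    chisq = FALSE,
    fisher = TRUE
  )
  if (use_fisher && ncol(counts) > 2) {
    abort("Fisher's exact test is only applied to 2 x 2 tables here; use `force = \"chisq\"` for wider tables.")
  }
  if (use_fisher) {
    res <- fisher.test(counts)
    tibble(test = "fisher_exact", statistic = NA_real_, p_value = res$p.value,
           df = NA_integer_, mode = "exact")
  } else {
    res <- suppressWarnings(chisq.test(counts, correct = FALSE))
    tibble(test = "chi_squared", statistic = unname(res$statistic),
           p_value = res$p.value, df = unname(res$parameter),
           mode = "asymptotic")
  }
}

#' Pearson correlation with R-squared
#'
#' Correlates a pipeline readout (e.g. band-integrated absolute PSD) against
#' a user-supplied covariate such as a behavioural recovery measure.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return One-row tibble: `r`, `r_squared`, `statistic` (t), `p_value`, `n`.
#' @examples
#' correlate(1:5, c(2, 4, 5, 8, 11))
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Correlation needs at least 3 pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  res <- cor.test(x, y)
  r <- unname(res$estimate)
  tibble(r = r, r_squared = r^2, statistic = unname(res$statistic),
         p_value = res$p.value, n = length(x))
}
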