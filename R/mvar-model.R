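#' Multivariate autoregressive (MVAR) model
#'
#' A VAR(p) model \eqn{x(t) = \sum_{r=1}^{p} A_r x(t-r) + u(t)} with white
#' Gaussian residuals \eqn{u(t)}. The same object serves generatively (in
#' [simulate_var_lfp()]) and as the result of [fit_mvar()]; generalized
#' partial directed coherence is computed from it by [gpdc()].
#'
#' @param coefficients List of p square (k x k) coefficient matrices
#'   \eqn{A_1 \dots A_p}; entry `[i, j]` couples lagged channel j into
#'   channel i.
#' @param residual_sd Numeric vector of k per-channel residual standard
#'   deviations (non-negative; [gpdc()] additionally requires them strictly
#'   positive), or a full k x k residual covariance matrix via
#'   `residual_cov`.
#' @param sampling_rate Sampling rate in Hz of the modelled series.
#' @param residual_cov Optional residual covariance matrix; when supplied,
#'   `residual_sd` is taken from its diagonal.
#' @param channel_names Optional character vector of channel names.
#'
#' @return An object of class `mvar_model` with elements `coefficients`,
#'   `order`, `n_channels`, `residual_sd`, `residual_cov`, `sampling_rate`,
#'   `channel_names`, and (for fitted models) `diagnostics`.
#' @examples
#' m <- mvar_model(list(matrix(c(0.5, 0.4, 0, 0.5), 2, 2, byrow = TRUE)),
#'                 residual_sd = c(1, 1), sampling_rate = 1250)
#' is_stable(m)
#' @export
mvar_model <- function(coefficients, residual_sd = NULL, sampling_rate = 1250,
                       residual_cov = NULL, channel_names = NULL) {
  if (is.matrix(coefficients)) coefficients <- list(coefficients)
  if (!is.list(coefficients) || length(coefficients) == 0L) {
    abort("`coefficients` must be a non-empty list of square matrices.")
  }
  k <- nrow(coefficients[[1]])
  for (A in coefficients) {
    if (!is.matrix(A) || nrow(A) != k || ncol(A) != k) {
      abort("All coefficient matrices must be square with equal dimension.")
    }
  }
  if (is.null(residual_cov)) {
    if (is.null(residual_sd)) residual_sd <- rep(1, k)
    if (length(residual_sd) != k || any(residual_sd < 0)) {
      abort("`residual_sd` must have one non-negative entry per channel.")
    }
    residual_cov <- diag(residual_sd^2, k)
  } else {
    if (!is.matrix(residual_cov) || nrow(residual_cov) != k ||
        ncol(residual_cov) != k) {
      abort("`residual_cov` must be a k x k matrix.")
    }
    residual_sd <- sqrt(diag(residual_cov))
    if (any(residual_sd < 0)) abort("Residual variances must be non-negative.")
  }
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 0, strict = TRUE)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(k))
  structure(
    list(
      coefficients = lapply(coefficients, unname),
      order = length(coefficients),
      n_channels = k,
      residual_sd = as.numeric(residual_sd),
      residual_cov = unname(residual_cov),
      sampling_rate = as.numeric(sampling_rate),
      channel_names = as.character(channel_names),
      diagnostics = NULL
    ),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf(
    "<mvar_model> VAR(%d), %d channels @ %g Hz; stable: %s\n",
    x$order, x$n_channels, x$sampling_rate, is_stable(x)
  ))
  invisible(x)
}

# Companion-form spectral radius; < 1 iff the VAR process is stable.
companion_spectral_radius <- function(model) {
  p <- model$order
  k <- model$n_channels
  C <- matrix(0, k * p, k * p)
  for (r in seq_len(p)) {
    C[seq_len(k), (r - 1) * k + seq_len(k)] <- model$coefficients[[r]]
  }
  if (p > 1) {
    C[(k + 1):(k * p), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  }
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Is an MVAR model stable (stationary)?
#'
#' @param model An [mvar_model].
#' @return `TRUE` when the companion-matrix spectral radius is below 1.
#' @export
is_stable <- function(model) {
  stopifnot(inherits(model, "mvar_model"))
  companion_spectral_radius(model) < 1
}

#' Tidy MVAR coefficients into long form
#'
#' @param x An [mvar_model].
#' @param ... Unused.
#' @return Tibble with columns `lag`, `target`, `source`, `estimate`.
#' @export
tidy.mvar_model <- function(x, ...) {
  k <- x$n_channels
  purrr::map_dfr(seq_len(x$order), function(r) {
    A <- x$coefficients[[r]]
    tibble(
      lag = r,
      target = rep(x$channel_names, times = k),
      source = rep(x$channel_names, each = k),
      estimate = as.vector(A)
    )
  })
}

#' One-row summary of an MVAR model
#'
#' @param x An [mvar_model].
#' @param ... Unused.
#' @return Tibble with order, channel count, stability, spectral radius and
#'   (for fitted models) the selected-order AIC/BIC.
#' @export
glance.mvar_model <- function(x, ...) {
  rho <- companion_spectral_radius(x)
  out <- tibble(
    order = x$order,
    n_channels = x$n_channels,
    spectral_radius = rho,
    stable = rho < 1,
    sampling_rate = x$sampling_rate
  )
  if (!is.null(x$diagnostics)) {
    sel <- x$diagnostics[x$diagnostics$order == x$order, , drop = FALSE]
    if (nrow(sel) == 1) {
      out$aic <- sel$aic
      out$bic <- sel$bic
    }
  }
  out
}
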