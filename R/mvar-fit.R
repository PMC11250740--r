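#' Fit an MVAR model by conditional least squares with order selection
#'
#' Each channel is regressed on p lags of all channels (no intercept;
#' signals are demeaned first). Candidate orders `1..max_order` are scored
#' with AIC and BIC on a common effective sample (conditioning on the first
#' `max_order` values so criteria are comparable), the order is chosen by
#' the requested criterion, and the model is refit at that order on all
#' available data.
#'
#' AIC = log det(Sigma_hat) + 2 p k^2 / N;  BIC = log det(Sigma_hat) +
#' log(N) p k^2 / N, with Sigma_hat the ML residual covariance and N the
#' effective sample size.
#'
#' @param signals Numeric matrix (samples x channels), a list of
#'   [lfp_record]s of equal length and rate, or an `lfp_segments` pair —
#'   anything coercible to a multichannel series.
#' @param max_order Largest candidate order (default 12).
#' @param criterion `"bic"` (default; the more conservative choice when the
#'   two disagree), `"aic"`, or `"min_of_both"` (the smaller of the two
#'   selected orders).
#' @param sampling_rate Sampling rate in Hz (taken from records when given).
#' @param demean Subtract channel means before fitting (default `TRUE`).
#' @return A fitted [mvar_model] with a `diagnostics` tibble (`order`,
#'   `aic`, `bic`), `selected_by`, and a `stable` flag; an unstable fit
#'   warns but is returned.
#' @examples
#' m0 <- default_var_model()
#' x <- simulate_var_lfp(m0, 5000, seed = 1)
#' fit <- fit_mvar(x, max_order = 4, sampling_rate = 1250)
#' glance(fit)
#' @export
fit_mvar <- function(signals, max_order = 12,
                     criterion = c("bic", "aic", "min_of_both"),
                     sampling_rate = NULL, demean = TRUE) {
  criterion <- match.arg(criterion)
  if (is.list(signals) && all(vapply(signals, inherits, logical(1), "lfp_record"))) {
    rates <- vapply(signals, function(l) l$sampling_rate, numeric(1))
    if (length(unique(rates)) != 1) abort("LFP records differ in sampling rate.")
    sampling_rate <- sampling_rate %||% rates[1]
    nms <- vapply(signals, function(l) l$channel_id, character(1))
    signals <- do.call(cbind, lapply(signals, function(l) l$samples))
    colnames(signals) <- nms
  }
  x <- as.matrix(signals)
  if (is.null(sampling_rate)) sampling_rate <- attr(signals, "sampling_rate")
  if (is.null(sampling_rate)) abort("`sampling_rate` is required.")
  k <- ncol(x)
  n <- nrow(x)
  if (k < 2) abort("MVAR fitting needs at least 2 channels.")
  assert_scalar_num(max_order, "max_order", lower = 1)
  if (n <= max_order * k * 10) {
    abort("Series too short for the requested maximum order.")
  }
  ch_names <- colnames(x) %||% paste0("ch", seq_len(k))
  if (demean) x <- sweep(x, 2, colMeans(x))

  ols_fit <- function(p, rows) {
    # rows: indices t for which x[t, ] is the response
    Y <- x[rows, , drop = FALSE]
    X <- do.call(cbind, lapply(seq_len(p), function(r) x[rows - r, , drop = FALSE]))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- ((qx$pivot[qx$rank + 1] - 1) %% k) + 1
      abort(sprintf(
        "Rank-deficient regressor matrix (channel %s is linearly dependent).",
        ch_names[bad]
      ))
    }
    B <- qr.coef(qx, Y)                      # (k*p) x k
    E <- Y - X %*% B
    sigma <- crossprod(E) / nrow(Y)          # ML residual covariance
    list(B = B, sigma = sigma, n_eff = nrow(Y))
  }

  rows_common <- (max_order + 1):n
  diag_tbl <- purrr::map_dfr(seq_len(max_order), function(p) {
    f <- ols_fit(p, rows_common)
    ld <- determinant(f$sigma, logarithm = TRUE)$modulus
    npar <- p * k^2
    tibble(
      order = p,
      aic = as.numeric(ld + 2 * npar / f$n_eff),
      bic = as.numeric(ld + log(f$n_eff) * npar / f$n_eff)
    )
  })
  p_aic <- diag_tbl$order[which.min(diag_tbl$aic)]
  p_bic <- diag_tbl$order[which.min(diag_tbl$bic)]
  p_sel <- switch(criterion,
    aic = p_aic,
    bic = p_bic,
    min_of_both = min(p_aic, p_bic)
  )

  f <- ols_fit(p_sel, (p_sel + 1):n)
  coefs <- lapply(seq_len(p_sel), function(r) {
    t(f$B[(r - 1) * k + seq_len(k), , drop = FALSE])
  })
  # unbiased residual covariance for inference
  sigma <- crossprod(x[(p_sel + 1):n, , drop = FALSE] -
                       do.call(cbind, lapply(seq_len(p_sel), function(r) {
                         x[(p_sel + 1):n - r, , drop = FALSE]
                       })) %*% f$B) / (f$n_eff - p_sel * k)
  model <- mvar_model(coefs, residual_cov = sigma,
                      sampling_rate = sampling_rate,
                      channel_names = ch_names)
  model$diagnostics <- diag_tbl
  model$selected_by <- criterion
  model$order_aic <- p_aic
  model$order_bic <- p_bic
  model$n_obs <- n
  if (!is_stable(model)) {
    warn("Fitted MVAR model is unstable (spectral radius >= 1).")
    model$stable <- FALSE
  } else {
    model$stable <- TRUE
  }
  model
}
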