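#' Simulate a multichannel series from a stable MVAR model
#'
#' Realizes \eqn{x(t) = \sum_r A_r x(t-r) + u(t)} with independent Gaussian
#' residuals of the model's per-channel standard deviations. A burn-in period
#' is simulated and discarded so the returned samples are (numerically)
#' stationary.
#'
#' @param model A stable [mvar_model]; unstable models are rejected before
#'   any simulation.
#' @param n_samples Number of post-burn-in samples to return.
#' @param seed Optional integer seed.
#' @param burn_in Number of initial samples to discard; default
#'   `1000 * order`, ample for the stability margins used here.
#'
#' @return Numeric matrix `n_samples` x k, one column per channel, with
#'   column names from the model.
#' @examples
#' m <- mvar_model(list(diag(0.9, 1)), residual_sd = 1, sampling_rate = 1250)
#' x <- simulate_var_lfp(m, 1000, seed = 1)
#' @export
simulate_var_lfp <- function(model, n_samples, seed = NULL, burn_in = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  assert_scalar_num(n_samples, "n_samples", lower = 1)
  rho <- companion_spectral_radius(model)
  if (rho >= 1) {
    abort(sprintf(
      "MVAR model is unstable (companion spectral radius %.4f >= 1); refusing to simulate.",
      rho
    ))
  }
  p <- model$order
  k <- model$n_channels
  if (is.null(burn_in)) burn_in <- 1000L * p
  n_tot <- n_samples + burn_in + p
  A <- model$coefficients
  sds <- model$residual_sd
  with_seed(seed, {
    u <- matrix(rnorm(n_tot * k), n_tot, k) %*% diag(sds, k)
    x <- matrix(0, n_tot, k)
    if (all(vapply(A, function(a) all(a == 0), logical(1)))) {
      x <- u
    } else {
      for (t in (p + 1):n_tot) {
        acc <- u[t, ]
        for (r in seq_len(p)) acc <- acc + A[[r]] %*% x[t - r, ]
        x[t, ] <- acc
      }
    }
    out <- x[(n_tot - n_samples + 1):n_tot, , drop = FALSE]
    colnames(out) <- model$channel_names
    attr(out, "sampling_rate") <- model$sampling_rate
    out
  })
}

#' Model-implied stationary covariance of a VAR process
#'
#' Solves the discrete Lyapunov equation of the companion form, giving the
#' covariance the simulator's output should converge to; used as the oracle
#' in generator tests.
#'
#' @param model A stable [mvar_model].
#' @return k x k stationary covariance matrix.
#' @export
stationary_cov <- function(model) {
  stopifnot(inherits(model, "mvar_model"), is_stable(model))
  p <- model$order
  k <- model$n_channels
  kp <- k * p
  C <- matrix(0, kp, kp)
  for (r in seq_len(p)) {
    C[seq_len(k), (r - 1) * k + seq_len(k)] <- model$coefficients[[r]]
  }
  if (p > 1) C[(k + 1):kp, seq_len(k * (p - 1))] <- diag(k * (p - 1))
  Q <- matrix(0, kp, kp)
  Q[seq_len(k), seq_len(k)] <- model$residual_cov
  # vec(S) = (I - C (x) C)^{-1} vec(Q)
  vecS <- solve(diag(kp * kp) - kronecker(C, C), as.vector(Q))
  S <- matrix(vecS, kp, kp)
  S[seq_len(k), seq_len(k), drop = FALSE]
}

#' Add a sinusoidal oscillation to an LFP record
#'
#' Injects a pure sinusoid of known frequency and amplitude, creating
#' ground-truth band power for spectral tests.
#'
#' @param lfp An [lfp_record].
#' @param freq_hz Oscillation frequency (Hz); must be below Nyquist.
#' @param amplitude Peak amplitude in the record's voltage units.
#' @param phase Initial phase in radians.
#' @return A new [lfp_record] with identical length and rate.
#' @export
inject_oscillation <- function(lfp, freq_hz, amplitude, phase = 0) {
  stopifnot(inherits(lfp, "lfp_record"))
  assert_scalar_num(freq_hz, "freq_hz", lower = 0)
  nyq <- lfp$sampling_rate / 2
  if (freq_hz >= nyq) {
    abort(sprintf("freq_hz (%g) must be below Nyquist (%g Hz).", freq_hz, nyq))
  }
  if (amplitude == 0) return(lfp)
  t <- (seq_along(lfp$samples) - 1) / lfp$sampling_rate
  lfp_record(
    lfp$samples + amplitude * sin(2 * pi * freq_hz * t + phase),
    lfp$sampling_rate, lfp$channel_id, lfp$region_label
  )
}
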