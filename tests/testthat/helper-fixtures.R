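# Shared desk-scale fixtures, all built in code.

# A stable bivariate VAR(1) with known one-way coupling source -> target.
coupled_var <- function(strength = 0.4, target = 1, source = 2,
                        sampling_rate = 1250) {
  A <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  A[target, source] <- strength
  mvar_model(list(A), residual_sd = c(1, 1), sampling_rate = sampling_rate)
}

# Random stable bivariate VAR(1..3) with heterogeneous residual SDs.
random_stable_var <- function(max_tries = 100, sampling_rate = 1250) {
  p <- sample(1:3, 1)
  for (try in seq_len(max_tries)) {
    A <- lapply(seq_len(p), function(r) matrix(rnorm(4, sd = 0.35), 2, 2))
    sds <- exp(runif(2, log(0.1), log(10)))
    m <- mvar_model(A, residual_sd = sds, sampling_rate = sampling_rate)
    if (is_stable(m)) return(m)
  }
  stop("Could not draw a stable model.")
}

# Spike-count tensor for one simulated unit: `n_trials` stimuli with a
# multiplicative rate `gain` in (0, resp_dur) after each onset.
simulated_tensor <- function(baseline = 5, gain = 1, n_trials = 20,
                             resp_dur = 0.5, gap = 4.5, seed = NULL) {
  events <- 2.5 + gap * (seq_len(n_trials) - 1)
  duration <- max(events) + 2.5
  prof <- stimulus_rate_profile(duration, baseline, events, gain,
                                window = c(0, resp_dur))
  spk <- simulate_spike_train(prof, duration, seed = seed)
  build_trial_tensor(spk, events)
}

# White-noise LFP of `n_seg` 10-s segments at 1250 Hz.
noise_lfp <- function(n_seg = 2, sd = 1, fs = 1250, region = "PL") {
  lfp_record(rnorm(n_seg * 10 * fs, sd = sd), fs, region_label = region)
}

# Independent brute-force BH step-up oracle (kept deliberately naive).
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  list(p_adjusted = adj, reject = adj < q)
}

# Direct complex-arithmetic gPDC for a bivariate model at one frequency,
# independent of the package's vectorised implementation.
gpdc_by_hand <- function(A_list, sds, f, fs) {
  k <- 2
  Abar <- diag(2) + 0i
  for (r in seq_along(A_list)) {
    Abar <- Abar - A_list[[r]] * exp(-2i * pi * f * r / fs)
  }
  out <- matrix(0, 2, 2)
  for (j in 1:2) {
    denom <- sqrt(sum((Mod(Abar[, j]) / sds)^2))
    for (i in 1:2) out[i, j] <- (Mod(Abar[i, j]) / sds[i]) / denom
  }
  out
}

# classify_response with the mixed-direction warning muted (it fires by
# design in Monte-Carlo loops; the label is what is under test).
quiet_response <- function(tensor, ...) {
  suppressWarnings(classify_response(tensor, ...))
}
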