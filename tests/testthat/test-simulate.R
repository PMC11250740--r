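test_that("spike train generator is an inhomogeneous Poisson sampler", {
  expect_identical(simulate_spike_train(0, duration = 100, seed = 1), numeric(0))
  expect_identical(simulate_spike_train(5, duration = 0, seed = 1), numeric(0))

  # determinism and ordering
  a <- simulate_spike_train(10, 50, seed = 42)
  b <- simulate_spike_train(10, 50, seed = 42)
  expect_identical(a, b)
  expect_false(is.unsorted(a, strictly = TRUE))
  expect_true(all(a >= 0 & a < 50))

  # Poisson tail bound: counts of a 10 Hz / 100 s train stay within
  # 1000 +/- 4*sqrt(1000) (4-sigma, miss probability ~6e-5 per seed)
  counts <- vapply(1:200, function(s) {
    length(simulate_spike_train(10, 100, seed = s))
  }, numeric(1))
  expect_true(all(abs(counts - 1000) <= 4 * sqrt(1000)))

  # negative rate rejected with the interval named
  bad <- data.frame(start = c(0, 1), end = c(1, 2), rate = c(5, -1))
  expect_error(simulate_spike_train(bad, 2), "\\[1, 2\\)")
})

test_that("stimulus-gain trains recover the configured rate ratio", {
  events <- 2.5 + 4.5 * (0:19)
  duration <- max(events) + 2.5
  ratios <- vapply(1:100, function(s) {
    prof <- stimulus_rate_profile(duration, 5, events, gain = 3,
                                  window = c(0, 0.5))
    spk <- simulate_spike_train(prof, duration, seed = s)
    in_resp <- sum(vapply(events, function(e) {
      sum(spk >= e & spk < e + 0.5)
    }, numeric(1)))
    pre <- sum(vapply(events, function(e) {
      sum(spk >= e - 0.5 & spk < e)
    }, numeric(1)))
    in_resp / pre
  }, numeric(1))
  expect_equal(mean(ratios), 3, tolerance = 0.25)
})

test_that("homogeneous inter-spike intervals look exponential (KS at 1%)", {
  pass <- vapply(1:100, function(s) {
    spk <- simulate_spike_train(8, 120, seed = s)
    isi <- diff(spk)
    suppressWarnings(stats::ks.test(isi, "pexp", rate = 1 / mean(isi))$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("waveforms carry the requested trough-to-peak width", {
  for (w in c(0.3, 0.8)) {
    wf <- simulate_waveform(w, seed = 7)
    got <- peak_to_valley_width(wf, 30000)
    expect_lte(abs(got - w), 1000 / 30000 + 1e-12)
  }
  expect_identical(simulate_waveform(0.4, seed = 3), simulate_waveform(0.4, seed = 3))
  expect_error(simulate_waveform(0.01, sampling_rate = 30000), "sample period")
  expect_error(simulate_waveform(5, n_samples = 32), "does not fit")
})

test_that("VAR generator matches closed-form AR(1) autocorrelation", {
  m <- mvar_model(list(matrix(0.9, 1, 1)), residual_sd = 1)
  x <- simulate_var_lfp(m, 100000, seed = 5)
  r1 <- stats::cor(x[-1, 1], x[-nrow(x), 1])
  expect_equal(r1, 0.9, tolerance = 0.02 / 0.9)
})

test_that("degenerate and unstable VAR inputs are handled", {
  z <- mvar_model(list(matrix(0, 2, 2)), residual_sd = c(0, 0))
  expect_true(all(simulate_var_lfp(z, 100, seed = 1) == 0))
  un <- mvar_model(list(diag(1.05, 2)), residual_sd = c(1, 1))
  expect_error(simulate_var_lfp(un, 100), "unstable")
})

test_that("cross-correlation peak side follows the coupling direction", {
  lagged_xcorr_peak <- function(model) {
    x <- simulate_var_lfp(model, 50000, seed = 11)
    # brute-force cross-correlogram of ch1 against lagged ch2
    lags <- -10:10
    cc <- vapply(lags, function(l) {
      if (l >= 0) {
        stats::cor(x[(1 + l):nrow(x), 1], x[1:(nrow(x) - l), 2])
      } else {
        stats::cor(x[1:(nrow(x) + l), 1], x[(1 - l):nrow(x), 2])
      }
    }, numeric(1))
    lags[which.max(cc)]
  }
  expect_gt(lagged_xcorr_peak(coupled_var(0.4, target = 1, source = 2)), 0)
  expect_lt(lagged_xcorr_peak(coupled_var(0.4, target = 2, source = 1)), 0)
})

test_that("sample covariance converges to the Lyapunov solution", {
  m <- default_var_model()
  x <- simulate_var_lfp(m, 100000, seed = 9)
  S_hat <- stats::cov(x)
  S <- stationary_cov(m)
  expect_lt(norm(S_hat - S, "F") / norm(S, "F"), 0.05)
})

test_that("oscillation injection adds exactly one sinusoid", {
  set.seed(21)
  lfp <- noise_lfp(2)
  expect_identical(inject_oscillation(lfp, 20, 0), lfp)
  expect_error(inject_oscillation(lfp, 700, 1), "Nyquist")

  beta_rel <- function(l) {
    bp <- band_power(lfp_psd(l))
    bp$relative[bp$band == "beta"]
  }
  delta_rel <- function(l) {
    bp <- band_power(lfp_psd(l))
    bp$relative[bp$band == "delta"]
  }
  expect_gt(beta_rel(inject_oscillation(lfp, 20, 0.5)), beta_rel(lfp))
  expect_gt(delta_rel(inject_oscillation(lfp, 2, 0.5)), delta_rel(lfp))
})

test_that("sessions are reproducible and carry their ground truth", {
  cfg <- sim_config(seed = 3, session_duration = 60, n_trials = 8,
                    min_event_gap = 6)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$units$spike_times, s2$units$spike_times)
  expect_identical(s1$lfps$PL$samples, s2$lfps$PL$samples)
  expect_setequal(s1$units$true_response,
                  c("excitatory", "inhibitory", "neutral"))
  expect_true(all(vapply(s1$units$spike_times, function(t) {
    !is.unsorted(t, strictly = TRUE) && all(t >= 0 & t <= 60)
  }, logical(1))))
  expect_equal(length(s1$events), 8)
  expect_true(all(diff(s1$events) >= 6))
})
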