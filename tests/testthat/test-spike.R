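test_that("unit classification applies the width and rate thresholds", {
  mk <- function(width, rate, dur = 100) {
    list(
      spike_times = seq(0, dur - 1e-3, length.out = max(1, round(rate * dur))),
      waveform = simulate_waveform(width, seed = 2),
      waveform_sampling_rate = 30000
    )
  }
  expect_equal(classify_unit(mk(0.3, 2), 100)$label, "putative_interneuron")
  expect_equal(classify_unit(mk(0.8, 1), 100)$label, "putative_pyramidal")
  # the rate filter wins regardless of width
  expect_equal(classify_unit(mk(0.8, 0.2), 100)$label, "excluded_low_rate")
  expect_equal(classify_unit(mk(0.3, 0.2), 100)$label, "excluded_low_rate")

  expect_error(classify_unit(list(spike_times = 1:3, waveform = numeric(0)), 100),
               "empty waveform")
  expect_error(classify_unit(mk(0.8, 1), 0), "session_duration")
})

test_that("trough-to-peak width measurement is shape-faithful", {
  wf <- simulate_waveform(0.4, seed = 5)
  w <- peak_to_valley_width(wf, 30000)
  expect_lte(abs(w - 0.4), 1000 / 30000 + 1e-12)

  # no symmetry assumption: the reversed waveform measures differently
  expect_false(isTRUE(all.equal(w, peak_to_valley_width(rev(wf), 30000))))

  # 2x upsampling leaves the width unchanged within half a coarse sample
  n <- length(wf)
  fine <- approx(seq_len(n), wf, xout = seq(1, n, by = 0.5))$y
  w2 <- peak_to_valley_width(fine, 60000)
  expect_lte(abs(w2 - w), 0.5 * 1000 / 30000 + 1e-12)

  expect_error(peak_to_valley_width(seq(1, 0, length.out = 10), 30000),
               "not spike-like")
})

test_that("trial tensors bin spikes with half-open bins around onsets", {
  tt <- build_trial_tensor(1.05, events = 1)
  expect_equal(dim(tt), c(1, 40))
  expect_equal(unname(tt[1, 21]), 1L)  # first post-onset bin
  expect_equal(sum(tt), 1L)

  # a spike exactly at onset belongs to the first post-onset bin
  tt0 <- build_trial_tensor(1, events = 1)
  expect_equal(unname(tt0[1, 21]), 1L)

  empty <- build_trial_tensor(numeric(0), events = c(10, 20, 30))
  expect_equal(dim(empty), c(3, 40))
  expect_true(all(empty == 0))

  expect_warning(build_trial_tensor(c(1, 2), events = c(5, 6)), "overlap")
})

test_that("binned counts conserve spikes and match the Poisson mean", {
  spk <- simulate_spike_train(10, 460, seed = 8)
  events <- seq(5, 450, by = 4.5)  # 100 trials
  tt <- build_trial_tensor(spk, events)
  # oracle: direct interval membership per spike
  n_in <- sum(vapply(spk, function(t) {
    any(t >= events - 2 & t < events + 2)
  }, logical(1)))
  expect_equal(sum(tt), n_in)
  # homogeneous 10 Hz, 0.1 s bins -> mean count 1.0
  expect_equal(mean(tt), 1.0, tolerance = 0.1)
})

test_that("response classification follows the bin-wise paired t-test", {
  # identical deterministic trials: zero-variance convention gives neutral
  spk <- as.vector(outer(c(0.35, -1.25, 1.15), c(10, 20, 30), "+"))
  tt <- build_trial_tensor(sort(spk), events = c(10, 20, 30))
  expect_true(all(apply(tt, 2, stats::sd) == 0))
  r <- classify_response(tt)
  expect_equal(r$label, "neutral")
  expect_true(is.na(r$first_significant_bin))
  expect_true(all(r$per_bin_p == 1))

  expect_error(classify_response(build_trial_tensor(1.05, events = 1)),
               ">= 2 trials")

  # power on strong effects, desk-scale Monte-Carlo
  exc <- vapply(1:40, function(s) {
    quiet_response(simulated_tensor(5, gain = 3, seed = s))$label
  }, character(1))
  expect_gte(mean(exc == "excitatory"), 0.95)

  inh <- vapply(1:40, function(s) {
    quiet_response(simulated_tensor(10, gain = 0, resp_dur = 1, seed = s))$label
  }, character(1))
  expect_gte(mean(inh == "inhibitory"), 0.95)
})

test_that("excitatory detection rate is monotone in response gain", {
  rate_at_gain <- function(g) {
    mean(vapply(1:30, function(s) {
      quiet_response(simulated_tensor(5, gain = g, seed = 1000 + s))$label
    }, character(1)) == "excitatory")
  }
  rates <- vapply(c(1.5, 2.5, 4), rate_at_gain, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("Z-scored PSTH standardises against its own baseline", {
  spk <- simulate_spike_train(6, 200, seed = 12)
  events <- seq(5, 190, by = 9)
  tt <- build_trial_tensor(spk, events)
  z <- zscore_psth(tt)
  pre <- z$bin_start < 0
  expect_equal(mean(z$z[pre]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z[pre]), 1, tolerance = 1e-12)
  # definition: z of any bin is (mean rate - baseline mean) / baseline SD
  m <- colMeans(tt) / 0.1
  expect_equal(z$z, (m - mean(m[pre])) / sd(m[pre]))

  # flat tensor: zero baseline SD -> unscorable
  flat <- build_trial_tensor(sort(c(10.05, 20.05)), events = c(10, 20))
  flat[] <- 1L
  expect_warning(zf <- zscore_psth(flat), "unscorable")
  expect_true(all(is.nan(zf$z)))
})

test_that("modulation index is bounded, symmetric and scale-invariant", {
  expect_equal(modulation_index(2, 2), 0)
  expect_equal(modulation_index(0, 5), 1)
  expect_equal(modulation_index(1, 3), 0.5)
  expect_error(modulation_index(-1, 2), ">= 0")
  expect_warning(mi <- modulation_index(0, 0), "undefined")
  expect_true(is.na(mi))

  set.seed(33)
  f1 <- runif(50, 0, 20)
  f2 <- runif(50, 0, 20)
  expect_equal(modulation_index(f1, f2), modulation_index(f2, f1))
  expect_equal(modulation_index(3 * f1, 3 * f2), modulation_index(f1, f2))
  expect_true(all(modulation_index(f1, f2) >= 0 & modulation_index(f1, f2) <= 1))
})
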