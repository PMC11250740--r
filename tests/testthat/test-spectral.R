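test_that("Slepian tapers match a dense-eigenproblem oracle at small n", {
  n <- 300; nw <- 3; k <- 5
  V <- dpss_tapers(n, nw, k)
  # oracle: dense symmetric tridiagonal eigendecomposition
  W <- nw / n
  i <- 0:(n - 1)
  Tm <- diag(((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W))
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  for (ii in 1:(n - 1)) Tm[ii, ii + 1] <- Tm[ii + 1, ii] <- e[ii]
  Vd <- eigen(Tm, symmetric = TRUE)$vectors[, 1:k]
  for (j in 1:k) {
    d <- min(max(abs(V[, j] - Vd[, j])), max(abs(V[, j] + Vd[, j])))
    expect_lt(d, 1e-8)
  }
  expect_equal(crossprod(V), diag(k), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(dpss_tapers(300, 3, 7), "k <= 2\\*nw")
})

test_that("LFP preprocessing notches mains and passes the analysis band", {
  fs <- 2500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  mains <- lfp_record(sin(2 * pi * 50 * t), fs)
  out50 <- preprocess_lfp(mains)
  expect_equal(out50$sampling_rate, 1250)
  expect_lte(rms(out50$samples) / rms(mains$samples), 0.10)

  beta <- lfp_record(sin(2 * pi * 20 * t), fs)
  out20 <- preprocess_lfp(beta)
  expect_gte(rms(out20$samples) / rms(beta$samples), 0.70)

  zero <- preprocess_lfp(lfp_record(rep(0, fs * 15), fs))
  expect_true(all(zero$samples == 0))

  expect_error(preprocess_lfp(lfp_record(rnorm(1000), 1000)), "below the target")
  expect_error(preprocess_lfp(lfp_record(rnorm(10000), 1875)), "integer multiple")
})

test_that("segmentation drops the remainder and enforces a minimum length", {
  fs <- 1250
  expect_equal(ncol(segment_lfp(lfp_record(rnorm(35 * fs), fs))), 3)
  one <- segment_lfp(lfp_record(rnorm(10 * fs), fs))
  expect_equal(dim(one), c(10 * fs, 1))
  expect_error(segment_lfp(lfp_record(rnorm(round(9.99 * fs)), fs)),
               "shorter than one")
})

test_that("multitaper PSD localises tones and is flat for white noise", {
  fs <- 1250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  tone <- lfp_record(sin(2 * pi * 20 * t) + 0.01 * rnorm(length(t)), fs)
  psd <- lfp_psd(tone)
  expect_equal(psd$spectrum$freq[which.max(psd$spectrum$absolute)], 20,
               tolerance = 1e-9)
  expect_equal(sum(psd$spectrum$relative), 1, tolerance = 1e-9)
  expect_equal(nrow(psd$spectrum), 451)  # 1..46 Hz at 0.1 Hz

  set.seed(14)
  wn <- noise_lfp(n_seg = 100)
  bp <- band_power(multitaper_psd(segment_lfp(wn, bandpass = NULL)))
  # flat spectrum: relative band power proportional to grid points per band
  pts <- c(delta = 30, theta = 40, alpha = 50, beta = 170, gamma = 161)
  expect_equal(bp$relative, unname(pts / 451), tolerance = 0.15)

  expect_error(multitaper_psd(matrix(rnorm(100), 50, 2), 100, nw = 2, k = 5),
               "k <= 2\\*nw")
})

test_that("band powers split the grid with boundaries in the upper band", {
  mk_psd <- function(freq, absolute) {
    structure(list(
      spectrum = tibble::tibble(freq = freq, absolute = absolute,
                                relative = absolute / sum(absolute)),
      n_segments = 1, nw = 3, k = 5, sampling_rate = 1250
    ), class = "psd_result")
  }
  grid <- seq(1, 46, by = 0.1)
  conc2 <- mk_psd(grid, as.numeric(grid == 2))
  bp2 <- band_power(conc2)
  expect_equal(bp2$relative[bp2$band == "delta"], 1)
  expect_equal(sum(bp2$relative), 1)

  conc20 <- mk_psd(grid, as.numeric(grid == 20))
  expect_equal(band_power(conc20)$relative[4], 1)  # beta

  # shared boundary goes up: all power at 13 Hz is beta, none alpha
  conc13 <- mk_psd(grid, as.numeric(abs(grid - 13) < 1e-9))
  bp13 <- band_power(conc13)
  expect_equal(bp13$relative[bp13$band == "beta"], 1)
  expect_equal(bp13$relative[bp13$band == "alpha"], 0)

  unif <- mk_psd(grid, rep(1, length(grid)))
  expect_equal(band_power(unif)$relative,
               c(30, 40, 50, 170, 161) / 451, tolerance = 1e-12)
})

test_that("total multitaper power scales linearly with input variance", {
  set.seed(40)
  sds <- c(0.5, 1, 2, 4)
  tot <- vapply(sds, function(s) {
    glance(multitaper_psd(segment_lfp(noise_lfp(4, sd = s), bandpass = NULL)))$total_power
  }, numeric(1))
  fit <- stats::lm(tot ~ I(sds^2))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("pipeline is invariant to a constant voltage offset", {
  set.seed(51)
  x <- rnorm(1250 * 25)
  p1 <- lfp_psd(preprocess_lfp(lfp_record(x, 1250)))
  p2 <- lfp_psd(preprocess_lfp(lfp_record(x + 40, 1250)))
  expect_equal(p1$spectrum$relative, p2$spectrum$relative, tolerance = 1e-6)
})

test_that("pointwise group test flags only genuine spectral differences", {
  set.seed(60)
  group_a <- replicate(8, lfp_psd(noise_lfp(2)), simplify = FALSE)
  same <- pointwise_group_test(group_a, group_a)
  expect_equal(sum(same$table$significant), 0)
  expect_equal(nrow(same$intervals), 0)

  # injected 20 Hz oscillation in group b is found around 20 Hz
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    a <- replicate(8, lfp_psd(noise_lfp(2)), simplify = FALSE)
    b <- replicate(8, lfp_psd(inject_oscillation(noise_lfp(2), 20, 0.25)),
                   simplify = FALSE)
    res <- pointwise_group_test(a, b)
    any(res$intervals$lo <= 20 & res$intervals$hi >= 20)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # grid mismatch is an error
  short <- multitaper_psd(segment_lfp(noise_lfp(2), bandpass = NULL),
                          fmin = 2, fmax = 40)
  expect_error(pointwise_group_test(group_a, list(short, short)),
               "grids differ|share one")
})

test_that("adjusted p-values equal the brute-force BH oracle", {
  set.seed(71)
  a <- matrix(rnorm(8 * 50), 8)
  b <- matrix(rnorm(8 * 50), 8)
  res <- ephysflow:::pointwise_core(a, b, freqs = seq_len(50), q = 0.05)$table
  oracle <- bh_oracle(res$p_value)
  expect_equal(res$p_adjusted, oracle$p_adjusted, tolerance = 1e-12)
  expect_identical(res$significant, oracle$reject)
})
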