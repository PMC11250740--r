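test_that("spectral coefficient matrix has the analytic endpoints", {
  fs <- 1250
  zero <- mvar_model(list(matrix(0, 2, 2)), residual_sd = c(1, 1),
                     sampling_rate = fs)
  Abar <- mvar_transfer(zero, c(1, 10, 40))
  for (fi in 1:3) expect_equal(Abar[, , fi], diag(2) + 0i, ignore_attr = TRUE)

  A1 <- matrix(c(0.4, 0.2, -0.1, 0.3), 2, 2)
  A2 <- matrix(c(0.1, 0, 0.05, -0.2), 2, 2)
  m <- mvar_model(list(A1, A2), residual_sd = c(1, 1), sampling_rate = fs)
  # at f = 0 the exponentials are all 1
  expect_equal(mvar_transfer(m, 1e-12)[, , 1], (diag(2) - A1 - A2) + 0i,
               ignore_attr = TRUE)

  dm <- mvar_model(list(diag(c(0.5, 0.3)), diag(c(-0.2, 0.1))),
                   residual_sd = c(1, 2), sampling_rate = fs)
  Ad <- mvar_transfer(dm, c(5, 25))
  expect_true(all(Ad[1, 2, ] == 0 & Ad[2, 1, ] == 0))
})

test_that("gPDC is zero off-diagonal for uncoupled models, exactly", {
  dm <- mvar_model(list(diag(c(0.5, 0.3)), diag(c(-0.2, 0.1))),
                   residual_sd = c(1, 2))
  g <- gpdc(dm)
  off <- g$table[g$table$target != g$table$source, ]
  expect_true(all(off$gpdc == 0))
  expect_equal(nrow(off), 2 * 451)
})

test_that("gPDC is bounded by 1 with unit column-square norm", {
  set.seed(81)
  for (rep in 1:50) {
    m <- random_stable_var()
    g <- gpdc(m, freqs = seq(1, 46, by = 0.5))
    expect_lte(max(g$table$gpdc), 1 + 1e-9)
    norms <- tapply(g$table$gpdc^2, list(g$table$freq, g$table$source), sum)
    expect_lt(max(abs(norms - 1)), 1e-9)
  }
  expect_error(gpdc(mvar_model(list(diag(0.5, 2)), residual_sd = c(0, 1))),
               "> 0")
})

test_that("gPDC matches a direct evaluation of the formula", {
  A1 <- matrix(c(0.5, 0, 0.4, 0.5), 2, 2, byrow = TRUE)  # coupling 1 -> 2
  m <- mvar_model(list(A1), residual_sd = c(1, 1), sampling_rate = 1250)
  freqs <- c(0.001, 10, 30)
  g <- gpdc(m, freqs)
  hand <- lapply(freqs, function(f) gpdc_by_hand(list(A1), c(1, 1), f, 1250))
  for (fi in seq_along(freqs)) {
    got <- matrix(g$table$gpdc[g$table$freq == freqs[fi]], 2, 2)
    expect_equal(got, hand[[fi]], tolerance = 1e-12)
  }
  # frozen value at f ~ 0: |(I-A1)_21| / sqrt(0.5^2 + 0.4^2)
  g21 <- g$table$gpdc[g$table$freq == 0.001 & g$table$direction == "ch2<-ch1"]
  expect_equal(g21, 0.4 / sqrt(0.25 + 0.16), tolerance = 1e-6)
})

test_that("least-squares MVAR fit recovers known coefficients", {
  m0 <- mvar_model(
    list(matrix(c(0.5, 0.3, 0, 0.5), 2, 2, byrow = TRUE),
         matrix(c(-0.2, 0, 0.1, -0.15), 2, 2, byrow = TRUE)),
    residual_sd = c(1, 1.5), sampling_rate = 1250
  )
  x <- simulate_var_lfp(m0, 50000, seed = 17)
  fit <- fit_mvar(x, max_order = 4)
  expect_equal(fit$order, 2)
  for (r in 1:2) {
    expect_lt(max(abs(fit$coefficients[[r]] - m0$coefficients[[r]])), 0.05)
  }
  expect_lt(max(abs(fit$residual_sd - c(1, 1.5))), 0.05)
  expect_true(fit$stable)
  expect_equal(nrow(fit$diagnostics), 4)

  # dual route: stats::ar.ols on the same data agrees closely
  ref <- stats::ar.ols(x, aic = FALSE, order.max = 2, demean = TRUE,
                       intercept = FALSE)
  for (r in 1:2) {
    expect_lt(max(abs(fit$coefficients[[r]] - ref$ar[r, , ])), 1e-3)
  }
})

test_that("white-noise channels fit to near-zero cross-coefficients", {
  set.seed(19)
  x <- matrix(rnorm(2 * 10000), ncol = 2)
  fit <- fit_mvar(x, max_order = 3, criterion = "bic", sampling_rate = 1250)
  se <- 1 / sqrt(nrow(x))
  for (r in seq_len(fit$order)) {
    offd <- fit$coefficients[[r]][row(diag(2)) != col(diag(2))]
    expect_true(all(abs(offd) < 3.5 * se))
  }
})

test_that("BIC selects the true order of a strong VAR(3)", {
  m3 <- mvar_model(
    list(matrix(c(0.4, 0.2, 0, 0.3), 2, 2, byrow = TRUE),
         matrix(c(-0.3, 0, 0.1, -0.3), 2, 2, byrow = TRUE),
         matrix(c(0.3, 0.1, -0.1, 0.25), 2, 2, byrow = TRUE)),
    residual_sd = c(1, 1), sampling_rate = 1250
  )
  expect_true(is_stable(m3))
  sel <- vapply(1:20, function(s) {
    x <- simulate_var_lfp(m3, 5000, seed = 100 + s)
    fit_mvar(x, max_order = 8, criterion = "bic")$order
  }, numeric(1))
  expect_gte(mean(sel == 3), 0.9)
})

test_that("order-selection modes report both criteria and honour the flag", {
  x <- simulate_var_lfp(default_var_model(), 4000, seed = 23)
  f_bic <- fit_mvar(x, max_order = 5, criterion = "bic")
  f_aic <- fit_mvar(x, max_order = 5, criterion = "aic")
  f_min <- fit_mvar(x, max_order = 5, criterion = "min_of_both")
  expect_equal(f_min$order, min(f_aic$order_aic, f_bic$order_bic))
  expect_named(f_bic$diagnostics, c("order", "aic", "bic"))
})

test_that("band-mean gPDC recovers the coupling direction", {
  g0 <- gpdc(mvar_model(list(diag(c(0.5, 0.3))), residual_sd = c(1, 2)))
  b0 <- directional_band_gpdc(g0, c(20, 46))
  expect_equal(b0$mean_gpdc[b0$target != b0$source], c(0, 0))
  expect_error(directional_band_gpdc(g0, c(100, 120)), "intersect")

  hits <- vapply(1:10, function(s) {
    x <- simulate_var_lfp(coupled_var(0.4, target = 1, source = 2), 12500,
                          seed = 200 + s)
    g <- gpdc(fit_mvar(x, max_order = 5), freqs = seq(1, 46, by = 0.5))
    b <- directional_band_gpdc(g, c(1, 46))
    b$mean_gpdc[b$direction == "ch1<-ch2"] > b$mean_gpdc[b$direction == "ch2<-ch1"]
  }, logical(1))
  expect_true(all(hits))
})

test_that("estimated null gPDC shrinks with sample size", {
  med_null <- function(n) {
    stats::median(vapply(1:5, function(s) {
      x <- ephysflow:::with_seed(300 + s, matrix(rnorm(2 * n), ncol = 2))
      g <- gpdc(fit_mvar(x, max_order = 2, sampling_rate = 1250),
                freqs = seq(1, 46, by = 1))
      off <- g$table[g$table$target != g$table$source, ]
      mean(off$gpdc)
    }, numeric(1)))
  }
  meds <- vapply(c(2000, 8000, 32000), med_null, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("pointwise gPDC comparison finds coupling-strength differences", {
  mk_group <- function(strength, seeds) {
    lapply(seeds, function(s) {
      x <- simulate_var_lfp(coupled_var(strength), 12500, seed = s)
      gpdc(fit_mvar(x, max_order = 3), freqs = seq(1, 46, by = 0.5))
    })
  }
  a <- mk_group(0.4, 401:408)
  same <- pointwise_gpdc_test(a, a, target = "ch1", source = "ch2")
  expect_equal(sum(same$table$significant), 0)

  b <- mk_group(0.2, 501:508)
  diffres <- pointwise_gpdc_test(a, b, target = "ch1", source = "ch2")
  expect_gt(sum(diffres$table$significant), 0)

  oracle <- bh_oracle(diffres$table$p_value)
  expect_equal(diffres$table$p_adjusted, oracle$p_adjusted, tolerance = 1e-12)
})
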