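test_that("zero-phase FIR bandpass: passband, stopband, no lag", {
  fs <- 1000
  t <- seq_len(20000) / fs
  x5 <- sin(2 * pi * 5 * t)
  y5 <- fir_bandpass(x5, 2, 10, sfreq = fs, order = 1000, trim = TRUE)
  core <- y5[2000:14000]
  expect_gt(max(abs(core)), 0.94)
  expect_lt(max(abs(core)), 1.06)

  x40 <- sin(2 * pi * 40 * t)
  y40 <- fir_bandpass(x40, 2, 10, sfreq = fs, order = 1000, trim = TRUE)
  expect_lt(max(abs(y40[2000:14000])), 0.01)

  # zero phase distortion: cross-correlation peak at zero lag
  cc <- stats::ccf(core, x5[2500:14500], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(fir_bandpass(x5, 2, 600, sfreq = fs), "Nyquist")
  expect_error(fir_bandpass(x5, 2, 10, sfreq = fs, order = 999), "even")
})

test_that("relative band power: line spectra, white noise, partition", {
  fs <- 1000
  t <- seq_len(60000) / fs
  s <- structure(list(s = rbind(sin(2 * pi * 10 * t)), sfreq = fs),
                 class = "source_timeseries")
  p <- relative_band_power(s)
  expect_gt(p[1, "alpha"], 0.95)
  expect_equal(sum(p[1, ]), 1, tolerance = 1e-6)

  set.seed(21)
  wn <- structure(list(s = matrix(rnorm(3 * 60000), 3), sfreq = fs),
                  class = "source_timeseries")
  pw <- relative_band_power(wn)
  bw_frac <- c(2, 4, 5, 17) / 28
  for (b in 1:4)
    expect_lt(max(abs(pw[, b] - bw_frac[b])), 0.05)
  expect_lt(max(abs(rowSums(pw) - 1)), 1e-6)
  expect_true(all(pw >= 0 & pw <= 1))
  expect_error(relative_band_power(wn, epochs = list()), "epochs")
})

test_that("phase-locking value: identity, independence, phase offsets", {
  fs <- 1000
  set.seed(33)
  base <- fir_bandpass(rnorm(8000), 8, 13, sfreq = fs, order = 500,
                       trim = TRUE)
  # identical series and a constant-phase-shifted copy both lock at 1
  an <- megsss:::analytic_signal(base)
  shifted <- Re(an * exp(1i * 1.1))
  s <- structure(list(s = rbind(base, base, shifted), sfreq = fs),
                 class = "source_timeseries")
  P <- plv(s, 8, 13, order = 500)
  expect_equal(dim(P), c(3L, 3L))
  expect_equal(P[1, 2], 1, tolerance = 1e-6)
  expect_gt(P[1, 3], 0.99)   # finite-series analytic-signal edge effects
  expect_true(isSymmetric(P))
  expect_equal(diag(P), rep(1, 3))

  # independent noise: PLV at the chance floor (few hundred effective
  # phase samples in a 5 Hz band over 30 s)
  s2 <- structure(list(s = matrix(rnorm(2 * 30000), 2), sfreq = fs),
                  class = "source_timeseries")
  P2 <- plv(s2, 8, 13, order = 500)
  expect_lt(P2[1, 2], 0.1)

  # constant channel: flagged NaN
  s3 <- structure(list(s = rbind(rnorm(4000), rep(0, 4000)), sfreq = fs),
                  class = "source_timeseries")
  P3 <- plv(s3, 8, 13, order = 500)
  expect_true(is.nan(P3[1, 2]))
})

test_that("representative VEF extracts the dominant evoked pattern", {
  fs <- 1000
  times <- seq(-0.1, 0.899, by = 1 / fs)
  w <- exp(-((times - 0.1)^2) / (2 * 0.025^2))
  set.seed(44)
  pattern <- rnorm(30)
  trials <- array(0, c(30, length(times), 8))
  for (k in 1:8)
    trials[, , k] <- outer(pattern, w) +
      matrix(rnorm(30 * length(times), sd = 0.05), 30)
  v <- representative_vef(trials, fs, t0 = -0.1)
  expect_gt(pearson_r2(v$component, w), 0.99)
  expect_gt(v$explained_variance, 0.5)
  # sign convention: global sign flip leaves the output unchanged
  v_neg <- representative_vef(-trials, fs, t0 = -0.1)
  expect_equal(v_neg$component, v$component, tolerance = 1e-10)
  # peak positivity inside the window
  win <- v$times >= 0.06 & v$times <= 0.16
  expect_gt(v$component[win][which.max(abs(v$component[win]))], 0)

  # two orthogonal patterns with 10:1 power: PC1 follows the stronger
  w2 <- exp(-((times - 0.4)^2) / (2 * 0.05^2)) * sin(2 * pi * 20 * times)
  p1 <- c(rep(1, 15), rep(0, 15)); p2 <- c(rep(0, 15), rep(1, 15))
  tr2 <- array(0, c(30, length(times), 4))
  for (k in 1:4)
    tr2[, , k] <- outer(p1, w) + outer(p2, w2 / sqrt(10) / 2)
  v2 <- representative_vef(tr2, fs, t0 = -0.1)
  expect_gt(pearson_r2(v2$component, w), 0.95)
})

test_that("activation maps measure windowed power changes", {
  fs <- 1000
  times <- seq(-0.1, 0.899, by = 1 / fs)
  active <- times >= 0.06 & times <= 0.16
  set.seed(55)
  s_tr <- array(rnorm(2 * length(times) * 6), c(2, length(times), 6))
  # source 1 doubles its amplitude in the active window: change ~ 3
  s_tr[1, active, ] <- 2 * s_tr[1, active, ]
  ch <- activation_map(s_tr, fs, t0 = -0.1)
  expect_equal(ch[1], 3, tolerance = 0.5)
  expect_lt(abs(ch[2]), 0.35)
  expect_error(activation_map(s_tr, fs, t0 = 5), "windows")
})
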