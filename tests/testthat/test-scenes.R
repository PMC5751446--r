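test_that("scenes are bit-exactly reproducible from their seed", {
  sp <- get_space()
  arr <- get_array()
  s1 <- make_resting_scene(5, 2, "low", duration = 2, space = sp)
  s2 <- make_resting_scene(5, 2, "low", duration = 2, space = sp)
  expect_identical(s1, s2)
  r1 <- render(s1[[1]], arr, leadfield = get_leadfield())
  r2 <- render(s2[[1]], arr, leadfield = get_leadfield())
  expect_identical(r1$data, r2$data)
  # the leadfield shortcut is exact, not an approximation
  r3 <- render(s1[[1]], arr)
  expect_rel_equal(r3$data, r1$data, 1e-12)
  expect_error(make_resting_scene(1, 0), "n_subjects")
})

test_that("rendering is a superposition of its components", {
  arr <- get_array()
  sc <- make_resting_scene(9, 1, "high", duration = 2,
                           space = get_space())[[1]]
  lf <- get_leadfield()
  full <- render(sc, arr, leadfield = lf)
  int <- render(sc, arr, components = "internal", leadfield = lf)
  ext <- render(sc, arr, components = "external", leadfield = lf)
  noi <- render(sc, arr, components = "noise", leadfield = lf)
  expect_rel_equal(int$data + ext$data + noi$data, full$data, 1e-12)

  # zero sources and zero noise: all-zero output
  sc0 <- make_resting_scene(9, 1, "none", duration = 1,
                            space = get_space())[[1]]
  empty <- render(sc0, arr, components = "external", leadfield = lf)
  expect_identical(max(abs(empty$data)), 0)
})

test_that("brain-only magnetometer amplitudes sit at the ~20 fT scale", {
  arr <- get_array()
  magi <- channel_indices(arr, "MAG")
  peaks <- vapply(1:2, function(s) {
    sc <- make_resting_scene(40 + s, 1, "none", duration = 4,
                             space = get_space())[[1]]
    M <- render(sc, arr, components = "internal",
                leadfield = get_leadfield())
    max(abs(M$data[magi, ]))
  }, numeric(1))
  expect_true(all(peaks > 20e-15 / 3 & peaks < 20e-15 * 3))
})

test_that("interference levels behave as designed", {
  arr <- get_array()
  magi <- channel_indices(arr, "MAG")
  # none: nothing for SSS to remove beyond noise; ratio near 1
  none <- render_subject(23, duration = 4, interference = "none")
  nr_none <- noise_ratio(none$raw, none$sss$M_in_hat, magi)
  expect_lt(abs(nr_none - 1), 0.5)
  # high: rendered magnetometer data dominated by interference
  sc <- make_resting_scene(23, 1, "high", duration = 4,
                           space = get_space())[[1]]
  lf <- get_leadfield()
  ext <- render(sc, arr, components = "external", leadfield = lf)
  int <- render(sc, arr, components = "internal", leadfield = lf)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(ext$data[magi, ]) / rms(int$data[magi, ]), 5)
})

test_that("external-only renderings live in the span of the external basis", {
  arr <- get_array()
  basis <- get_basis_raw()
  sc <- make_resting_scene(29, 1, "high", duration = 1,
                           space = get_space())[[1]]
  ext <- render(sc, arr, components = "external",
                leadfield = get_leadfield())
  w <- basis$channel_scales
  Q <- qr.Q(qr(basis$S_out / w))
  Xw <- ext$data / w
  resid <- sqrt(sum((Xw - Q %*% crossprod(Q, Xw))^2) / sum(Xw^2))
  expect_lt(resid, 0.05)
})

test_that("evoked scenes: latency, trial averaging and null response", {
  arr <- get_array()
  sp <- get_space()
  sc <- make_evoked_scene(13, n_trials = 8, space = sp, n_background = 10)
  rt <- render_trials(sc, arr, leadfield = get_leadfield())
  expect_equal(dim(rt$trials), c(306L, 1000L, 8L))

  # evoked-only rendering peaks inside 60-160 ms
  ev <- render_trials(sc, arr, components = "evoked",
                      leadfield = get_leadfield())
  avg <- apply(ev$trials, c(1, 2), mean)
  t_peak <- rt$times[which.max(colSums(avg^2))]
  expect_gte(t_peak, 0.06)
  expect_lte(t_peak, 0.16)

  # trial-average SNR grows roughly like sqrt(n)
  sc4 <- make_evoked_scene(13, n_trials = 4, space = sp, n_background = 10)
  sc64 <- make_evoked_scene(13, n_trials = 64, space = sp,
                            n_background = 10)
  snr_of <- function(scn) {
    r <- render_trials(scn, arr, leadfield = get_leadfield())
    e <- render_trials(scn, arr, components = "evoked",
                       leadfield = get_leadfield())
    sig <- apply(e$trials, c(1, 2), mean)
    noiz <- apply(r$trials, c(1, 2), mean) - sig
    sqrt(sum(sig^2) / sum(noiz^2))
  }
  g <- snr_of(sc64) / snr_of(sc4)
  expect_gt(g, sqrt(16) / 2.5)
  expect_lt(g, sqrt(16) * 2.5)

  # zero-amplitude evoked spec: activation maps are flat
  sc0 <- make_evoked_scene(13, n_trials = 6, space = sp, evoked_amp = 0,
                           n_background = 10)
  ev0 <- render_trials(sc0, arr, components = "evoked",
                       leadfield = get_leadfield())
  expect_identical(max(abs(ev0$trials)), 0)
  expect_error(make_evoked_scene(1, n_trials = 1), "n_trials")
})
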