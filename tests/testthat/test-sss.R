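test_that("basis matrices have the expected shape and conditioning", {
  basis <- get_basis_raw()
  expect_equal(dim(basis$S_in), c(306L, 80L))
  expect_equal(dim(basis$S_out), c(306L, 15L))
  expect_equal(basis$rank, 95L)
  expect_false(basis$rank_deficient)
  # normalized columns recorded with unit norm
  w <- basis$channel_scales
  Sn <- cbind(basis$S_in, basis$S_out) / w
  Sn <- sweep(Sn, 2, basis$column_scales, "/")
  expect_lt(max(abs(sqrt(colSums(Sn^2)) - 1)), 1e-12)

  # condition-limited pruning keeps the external set intact and lands in
  # the production 60-80 internal component range
  pruned <- get_basis()
  expect_lte(pruned$condition, 100)
  expect_true(length(pruned$keep_in) >= 60 &&
                length(pruned$keep_in) <= 80)
  expect_equal(ncol(pruned$S_out), 15L)
})

test_that("a single-triplet array cannot support the expansion", {
  tiny <- build_array(n_triplets = 1)
  b <- assemble_basis(tiny)
  expect_true(b$rank_deficient)
  expect_equal(dim(b$S_in), c(3L, 80L))
})

test_that("internal dipole fields project onto the joint basis, mostly S_in", {
  arr <- get_array()
  sp <- get_space()
  basis <- get_basis_raw()
  # a deep source (well below the sensors)
  v <- measure_field(arr, function(P)
    dipole_field(sp$grid[sp$probe_idx["precuneus"], ],
                 c(2e-9, 1e-9, -1e-9), P))
  w <- basis$channel_scales
  S <- cbind(basis$S_in, basis$S_out) / w
  fit <- qr.solve(qr(S), v / w)
  resid <- sqrt(sum((v / w - S %*% fit)^2) / sum((v / w)^2))
  expect_lt(resid, 1e-2)
  e_in <- sum((S[, 1:80] %*% fit[1:80])^2)
  e_all <- sum((S %*% fit)^2)
  expect_gt(e_in / e_all, 0.99)
})

test_that("separation recovers in-span coefficients exactly", {
  basis <- get_basis_raw()
  set.seed(42)
  # scale the coefficients so every component contributes comparable
  # (whitened) signal: physical column norms span ~10 orders of magnitude
  cn_in <- sqrt(colSums((basis$S_in / basis$channel_scales)^2))
  x_true <- matrix(rnorm(80 * 5), 80) / cn_in
  M <- channel_data(basis$S_in %*% x_true, 1000)
  res <- sss_separate(M, basis)
  expect_rel_equal(res$x_in * cn_in, x_true * cn_in, 1e-8)
  expect_lt(max(abs(res$x_out * basis$column_scales[81:95])) /
              max(abs(res$x_in * cn_in)), 1e-6)
  expect_rel_equal(res$M_in_hat$data, M$data, 1e-8)
})

test_that("cleaning is an idempotent linear projection", {
  dat <- render_subject(101, duration = 5)
  once <- dat$sss$M_in_hat
  twice <- sss_separate(once, get_basis())$M_in_hat
  expect_rel_equal(twice$data, once$data, 1e-10)
  # and linear
  basis <- get_basis()
  A <- matrix(rnorm(306 * 3, sd = 1e-13), 306)
  B <- matrix(rnorm(306 * 3, sd = 1e-13), 306)
  expect_rel_equal(sss_clean_matrix(A + 2 * B, basis),
                   sss_clean_matrix(A, basis) +
                     2 * sss_clean_matrix(B, basis), 1e-12)
})

test_that("external sources are shielded", {
  arr <- get_array()
  for (basis in list(get_basis_raw(), get_basis())) {
    # dipole at 3 m: backprojected amplitude under 5%
    v3 <- measure_field(arr, function(P)
      magnetic_dipole_field(c(2.1, 1.4, 1.5), c(1, 2, 3) / sqrt(14), P))
    clean3 <- sss_clean_matrix(matrix(v3), basis)
    expect_lt(sqrt(sum(clean3^2) / sum(v3^2)), 0.05)
    # dipole at 2 m: energy suppression at least 95%
    v2 <- measure_field(arr, function(P)
      magnetic_dipole_field(c(1.2, 0.9, 1.3), c(-1, 1, 2) / sqrt(6), P))
    clean2 <- sss_clean_matrix(matrix(v2), basis)
    expect_gt(1 - sum(clean2^2) / sum(v2^2), 0.95)
  }
})

test_that("backprojected data have rank at most n_in", {
  dat <- render_subject(77, duration = 3)
  X <- dat$sss$M_in_hat$data           # 306 x 3000
  sv <- svd(X, nu = 0, nv = 0)$d
  expect_lte(sum(sv > 1e-8 * sv[1]), 80L)
})

test_that("magnetometer and gradiometer rows share the internal coefficients", {
  dat <- render_subject(55, duration = 3)
  basis <- get_basis()
  arr <- get_array()
  gradi <- channel_indices(arr, "GRAD")
  rebuilt <- basis$S_in[gradi, basis$keep_in, drop = FALSE] %*%
    dat$sss$x_in[basis$keep_in, ]
  expect_rel_equal(dat$sss$M_in_hat$data[gradi, ], rebuilt, 1e-10)
})

test_that("bad channels are excluded from the fit but reconstructed", {
  arr_bad <- build_array(bad_channels = c(10L, 200L))
  sp <- get_space()
  basis_bad <- assemble_basis(arr_bad, prune_condition = 100)
  expect_false(any(c(10L, 200L) %in% basis_bad$good_channels))
  # corrupt the bad channels heavily: cleaned output must not change
  sc <- make_resting_scene(7, 1, "none", duration = 2, space = sp)[[1]]
  M <- render(sc, arr_bad)
  M_corrupt <- M
  M_corrupt$data[c(10, 200), ] <- 1e-9
  clean_a <- sss_separate(M, basis_bad)$M_in_hat$data
  clean_b <- sss_separate(M_corrupt, basis_bad)$M_in_hat$data
  expect_rel_equal(clean_b, clean_a, 1e-12)
  # and the bad rows are filled with a backprojection
  expect_true(all(abs(clean_b[c(10, 200), ]) < 1e-10))
  expect_gt(max(abs(clean_b[c(10, 200), ])), 0)
})

test_that("channel mismatch and contract errors are caught", {
  basis <- get_basis()
  expect_error(sss_separate(channel_data(matrix(0, 10, 5), 1000), basis),
               "mismatch")
  expect_error(sss_separate(matrix(0, 306, 5), basis), "channel_data")
})
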