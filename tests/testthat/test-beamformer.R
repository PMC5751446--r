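test_that("covariance estimation matches a brute-force oracle", {
  set.seed(5)
  X <- matrix(rnorm(4 * 600), 4)
  M <- channel_data(X, 100)
  eps <- list(1:200, 201:400, 401:600)
  C <- estimate_covariance(M, eps)$C
  # oracle: accumulate outer products sample by sample after epoch demean
  C_ref <- matrix(0, 4, 4)
  for (ep in eps) {
    Xd <- X[, ep] - rowMeans(X[, ep])
    for (t in seq_along(ep)) C_ref <- C_ref + Xd[, t] %*% t(Xd[, t])
  }
  C_ref <- C_ref / 600
  expect_lt(max(abs(C - C_ref)), 1e-12)

  # constant signal: zero covariance after demeaning
  Mc <- channel_data(matrix(7, 3, 50), 100)
  expect_equal(estimate_covariance(Mc)$C, matrix(0, 3, 3))

  # perfectly correlated pair: rank 1
  z <- rnorm(100)
  Mr <- channel_data(rbind(z, 2 * z), 100)
  expect_equal(qr(estimate_covariance(Mr)$C)$rank, 1L)

  expect_error(estimate_covariance(M, list()), "samples")
})

test_that("trace-scaled regularization and 1-norm condition numbers", {
  # closed form: C = I, lambda = 0.5
  m <- estimate_covariance(channel_data(matrix(rnorm(300), 3), 100))
  m$C <- diag(3)
  r <- regularize_invert(m, 0.5)
  expect_equal(r$C_reg, 1.5 * diag(3), tolerance = 1e-14)
  expect_equal(r$C_inv, diag(3) * 2 / 3, tolerance = 1e-12)
  expect_equal(r$cn, 1, tolerance = 1e-12)

  # diagonal case: cn = 1.5 x 2 = 3
  m$C <- diag(c(1, 0, 0))[1:2, 1:2]
  m2 <- m; m2$C <- diag(c(1, 0))
  r2 <- regularize_invert(m2, 1)
  expect_equal(diag(r2$C_reg), c(1.5, 0.5), tolerance = 1e-14)
  expect_equal(r2$cn, 3, tolerance = 1e-12)

  # monotonicity of cn in lambda for random PSD matrices
  set.seed(8)
  for (k in 1:5) {
    A <- matrix(rnorm(36), 6); C <- crossprod(A)
    mm <- m; mm$C <- C
    cns <- vapply(c(0.1, 0.5, 2, 10), function(l)
      regularize_invert(mm, l)$cn, numeric(1))
    expect_true(all(diff(cns) <= 1e-8 * cns[-length(cns)]))
    expect_gte(min(cns), 1 - 1e-12)
  }
  expect_error(regularize_invert(m, -0.1), "lambda")
  mz <- m; mz$C <- matrix(0, 2, 2)
  expect_error(regularize_invert(mz, 1), "degenerate")
})

test_that("LCMV filters pass unit gain on the tangential subspace", {
  lf <- get_leadfield()
  sp <- get_space()
  set.seed(3)
  A <- matrix(rnorm(306 * 320, sd = 1e-13), 306)
  cov <- estimate_covariance(channel_data(A, 100))
  cov <- regularize_invert(cov, 0)
  L <- lf$L[, , sp$probe_idx[2]]
  f <- lcmv_filter(L, cov)
  # W L acts as the identity on the tangential subspace
  V2 <- f$V_active
  expect_lt(max(abs(f$W %*% L %*% V2 - V2)), 1e-8)
  # unit-gain homogeneity: scaling L scales W inversely
  f10 <- lcmv_filter(10 * L, cov)
  expect_rel_equal(f10$W, f$W / 10, 1e-8)
  expect_error(lcmv_filter(matrix(0, 306, 3), cov), "degenerate")
})

test_that("a noiseless single dipole is localized at its true grid point", {
  arr <- get_array()
  sp <- get_space()
  lf <- get_leadfield()
  i_true <- sp$probe_idx[["somatosensory"]]
  ori <- megsss:::tangent_pair(sp$grid[i_true, ] /
                                 sqrt(sum(sp$grid[i_true, ]^2)))$t1
  set.seed(10)
  wav <- 1e-9 * sin(2 * pi * 8 * (1:400) / 1000) * rnorm(400, 1, 0.2)
  M <- channel_data(outer(as.vector(lf$L[, , i_true] %*% ori), wav), 1000)
  cov <- regularize_invert(estimate_covariance(M), 0.001)
  pow <- vapply(seq(1, dim(lf$L)[3]), function(j) {
    f <- select_orientation(lcmv_filter(lf$L[, , j], cov), cov)
    mean((f$W_eta %*% M$data)^2)
  }, numeric(1))
  expect_equal(which.max(pow), unname(i_true))
})

test_that("orientation selection recovers the generating orientation", {
  arr <- get_array()
  sp <- get_space()
  lf <- get_leadfield()
  i <- sp$probe_idx[["precuneus"]]
  u <- sp$grid[i, ] / sqrt(sum(sp$grid[i, ]^2))
  tp <- megsss:::tangent_pair(u)
  eta0 <- (tp$t1 + 0.5 * tp$t2) / sqrt(1.25)
  set.seed(12)
  wav <- 1e-9 * rnorm(500)
  noise <- matrix(rnorm(306 * 500, sd = 1e-15), 306)
  M <- channel_data(outer(as.vector(lf$L[, , i] %*% eta0), wav) + noise,
                    1000)
  cov <- regularize_invert(estimate_covariance(M), 0.01)
  f <- select_orientation(lcmv_filter(lf$L[, , i], cov), cov)
  expect_gt(abs(sum(f$eta * eta0)), 0.99)
  expect_false(f$degenerate_orientation)
  # eta invariant to positive rescaling of C
  cov2 <- cov; cov2$C <- 5 * cov$C
  f2 <- select_orientation(lcmv_filter(lf$L[, , i], cov), cov2)
  expect_equal(abs(sum(f2$eta * f$eta)), 1, tolerance = 1e-8)

  # isotropic covariance: degenerate tie flagged
  cov_iso <- cov; cov_iso$C <- diag(306)
  f_iso <- select_orientation(lcmv_filter(lf$L[, , i], cov_iso), cov_iso)
  expect_true(is.numeric(f_iso$eta))
})

test_that("source extraction is linear and null-preserving", {
  lf <- get_leadfield()
  sp <- get_space()
  set.seed(4)
  M <- channel_data(matrix(rnorm(306 * 100, sd = 1e-13), 306), 1000)
  cov <- regularize_invert(estimate_covariance(M), 0.05)
  filters <- lapply(sp$probe_idx, function(i)
    select_orientation(lcmv_filter(lf$L[, , i], cov), cov))
  s1 <- extract_sources(filters, M)
  expect_equal(dim(s1$s), c(4L, 100L))
  M0 <- channel_data(matrix(0, 306, 100), 1000)
  expect_identical(extract_sources(filters, M0)$s, matrix(0, 4, 100))
  M3 <- channel_data(3 * M$data, 1000)
  expect_rel_equal(extract_sources(filters, M3)$s, 3 * s1$s, 1e-12)
})

test_that("post-SSS covariances: rank-deficient but invertible, grad worse conditioned", {
  dat <- render_subject(31, duration = 10)
  arr <- get_array()
  cleaned <- dat$sss$M_in_hat
  magi <- channel_indices(arr, "MAG")
  gradi <- channel_indices(arr, "GRAD")
  cm <- estimate_covariance(channel_data(cleaned$data[magi, ], 1000))
  cg <- estimate_covariance(channel_data(cleaned$data[gradi, ], 1000))
  svg <- svd(cg$C, nu = 0, nv = 0)$d
  expect_lte(sum(svg > 1e-8 * svg[1]), 80L)
  for (lam in c(0.01, 0.05, 0.29)) {
    rm_ <- regularize_invert(cm, lam)
    rg_ <- regularize_invert(cg, lam)
    expect_true(all(is.finite(rg_$C_inv)))
    expect_gt(rg_$cn, rm_$cn)
  }
})
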