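# Nominal per-channel scales used to whiten the joint multipole fit so that
# magnetometers (tesla) and gradiometers (tesla/meter) contribute comparably.
# Backprojected data are invariant to these constants.
DEFAULT_MAG_SCALE <- 3e-14    # T
DEFAULT_GRAD_SCALE <- 3e-12   # T/m

channel_scales_for <- function(array, mag_scale = DEFAULT_MAG_SCALE,
                               grad_scale = DEFAULT_GRAD_SCALE) {
  ifelse(array$channel_table$type == "MAG", mag_scale, grad_scale)
}

#' Assemble the SSS multipole basis for a sensor array
#'
#' Evaluates every internal and external multipole field basis function
#' through the array's channel pickup models, producing the S_in
#' [channels x n_in] and S_out [channels x n_out] matrices of the signal
#' space separation model M = S_in x_in + S_out x_out. Channels are
#' whitened by nominal per-type noise scales and columns unit-normalized
#' before the (recorded) pseudoinverse; bad channels are excluded from the
#' fit but kept as rows so they can be reconstructed by backprojection.
#'
#' When `prune_condition` is finite, internal columns are dropped one at a
#' time (the column loading most on the weakest joint singular direction)
#' until the normalized joint basis has condition number at most
#' `prune_condition`. This mirrors production SSS implementations, which
#' back-project only the 60-80 best-conditioned internal components:
#' without it, near-collinear internal/external directions amplify sensor
#' noise enormously in the separation. External columns are never pruned.
#'
#' @param array a `sensor_array`.
#' @param origin expansion origin in meters, normally the source-sphere
#'   center.
#' @param L_in internal truncation order (default 8, giving 80 components).
#' @param L_out external truncation order (default 3, giving 15 components).
#' @param mag_scale,grad_scale channel whitening constants (T, T/m).
#' @param svd_tol relative singular-value cutoff for the pseudoinverse.
#' @param prune_condition maximum allowed condition number of the
#'   normalized joint basis; `Inf` (default) disables pruning.
#' @return object of class `multipole_basis` with `S_in`, `S_out`
#'   (physical units, all channels), `origin`, `L_in`, `L_out`,
#'   `component_index_in/out`, `keep_in` (indices of retained internal
#'   columns), `channel_scales`, `column_scales`, `pinv` (maps whitened
#'   good-channel data to normalized coefficients of the retained
#'   columns), `good_channels`, `rank`, `condition`.
#' @export
assemble_basis <- function(array, origin = c(0, 0, 0), L_in = 8L,
                           L_out = 3L, mag_scale = DEFAULT_MAG_SCALE,
                           grad_scale = DEFAULT_GRAD_SCALE,
                           svd_tol = 1e-12, prune_condition = Inf) {
  n_in <- count_components(L_in)
  n_out <- count_components(L_out)
  idx_in <- component_index(L_in)
  idx_out <- component_index(L_out)

  basis_cols <- function(idx, fn) {
    vapply(seq_len(nrow(idx)), function(k) {
      l <- idx$l[k]; m <- idx$m[k]
      measure_field(array, function(P)
        fn(l, m, sweep(P, 2, origin)))
    }, numeric(array$n_channels))
  }
  S_in <- basis_cols(idx_in, internal_basis_field)
  S_out <- basis_cols(idx_out, external_basis_field)

  w <- channel_scales_for(array, mag_scale, grad_scale)
  good <- setdiff(seq_len(array$n_channels), array$bad_channels)

  normalized <- function(keep_in) {
    S <- cbind(S_in[, keep_in, drop = FALSE], S_out)[good, , drop = FALSE] /
      w[good]
    cs <- sqrt(colSums(S^2))
    if (any(cs == 0))
      stop("ill-posed basis: zero columns ",
           paste(which(cs == 0), collapse = ", "))
    list(Sn = sweep(S, 2, cs, "/"), col_scales = cs)
  }

  keep_in <- seq_len(n_in)
  repeat {
    nb <- normalized(keep_in)
    sv <- svd(nb$Sn)
    cond <- sv$d[1] / sv$d[length(sv$d)]
    if (cond <= prune_condition || length(keep_in) == 0) break
    vmin <- sv$v[, length(sv$d)]
    in_part <- abs(vmin[seq_along(keep_in)])
    # stop rather than touch the external columns
    if (max(in_part) < max(abs(vmin)) * 0.5) break
    keep_in <- keep_in[-which.max(in_part)]
  }
  rank <- sum(sv$d > svd_tol * sv$d[1])
  n_cols <- length(keep_in) + n_out
  if (rank < n_cols && length(good) >= n_cols)
    warning("ill-posed basis: rank ", rank, " < ", n_cols, " columns")

  structure(list(
    S_in = S_in, S_out = S_out, origin = origin,
    L_in = as.integer(L_in), L_out = as.integer(L_out),
    n_in = n_in, n_out = n_out, keep_in = keep_in,
    component_index_in = idx_in, component_index_out = idx_out,
    channel_scales = w, column_scales = nb$col_scales,
    pinv = pinv_svd(nb$Sn, svd_tol), good_channels = good,
    rank = rank, condition = cond,
    rank_deficient = rank < n_cols
  ), class = "multipole_basis")
}

#' @export
print.multipole_basis <- function(x, ...) {
  cat(sprintf(
    "<multipole_basis> L_in=%d (%d/%d cols kept), L_out=%d (%d cols), %d channels, cond %.3g%s\n",
    x$L_in, length(x$keep_in), x$n_in, x$L_out, x$n_out, nrow(x$S_in),
    x$condition, if (x$rank_deficient) " [RANK DEFICIENT]" else ""))
  invisible(x)
}

#' Signal space separation of multichannel data
#'
#' Jointly estimates internal and external multipole coefficients from all
#' (good) channels per time sample, x_hat = pinv(S) M, and backprojects the
#' internal components only, M_in_hat = S_in x_in_hat, into every channel of
#' both sensor types (including bad channels). This is the SSS denoising
#' step: external interference lives in the S_out subspace and is discarded.
#' Magnetometer and gradiometer rows of the cleaned data are, by
#' construction, linear images of the same internal coefficient series.
#'
#' @param M a `channel_data` whose rows match the basis' channel order.
#' @param basis a `multipole_basis` from [assemble_basis()].
#' @return object of class `sss_result`: `M_in_hat` (a `channel_data`),
#'   `x_in` [n_in x samples] (rows of pruned components are zero), `x_out`
#'   [n_out x samples], `residual_norm` (per-sample relative residual of
#'   the joint fit over good channels).
#' @export
sss_separate <- function(M, basis) {
  if (!inherits(M, "channel_data")) stop("M must be a channel_data")
  if (nrow(M$data) != nrow(basis$S_in))
    stop("channel count mismatch between data and basis")
  good <- basis$good_channels
  w <- basis$channel_scales
  nk <- length(basis$keep_in)
  n_samp <- ncol(M$data)
  S_in_kept <- basis$S_in[, basis$keep_in, drop = FALSE]
  x <- matrix(0, nk + basis$n_out, n_samp)
  res <- numeric(n_samp)
  # sample blocks keep peak memory modest on long recordings
  block <- 20000L
  Sg_fit <- cbind(S_in_kept, basis$S_out)[good, , drop = FALSE] / w[good]
  for (b0 in seq(1L, n_samp, by = block)) {
    b1 <- min(b0 + block - 1L, n_samp)
    Mw <- M$data[good, b0:b1, drop = FALSE] / w[good]
    y <- basis$pinv %*% Mw
    x[, b0:b1] <- y / basis$column_scales
    fit <- Sg_fit %*% x[, b0:b1, drop = FALSE]
    denom <- sqrt(colSums(Mw^2))
    res[b0:b1] <- sqrt(colSums((Mw - fit)^2)) /
      ifelse(denom > 0, denom, 1)
  }
  x_in <- matrix(0, basis$n_in, n_samp)
  x_in[basis$keep_in, ] <- x[seq_len(nk), , drop = FALSE]
  x_out <- x[-seq_len(nk), , drop = FALSE]
  M_in <- S_in_kept %*% x[seq_len(nk), , drop = FALSE]
  structure(list(
    M_in_hat = channel_data(M_in, M$sfreq, M$bad_channels),
    x_in = x_in, x_out = x_out, residual_norm = res
  ), class = "sss_result")
}

#' @export
print.sss_result <- function(x, ...) {
  cat(sprintf(
    "<sss_result> %d internal + %d external components, %d samples, median residual %.3g\n",
    nrow(x$x_in), nrow(x$x_out), ncol(x$x_in), stats::median(x$residual_norm)))
  invisible(x)
}

#' Apply the SSS cleaning map to an arbitrary channel-space matrix
#'
#' The SSS denoising step is a fixed linear map; this applies it to any
#' [channels x k] matrix (for example leadfield columns), returning the
#' internal-component backprojection.
#'
#' @param X numeric matrix [channels x k].
#' @param basis a `multipole_basis`.
#' @return matrix of the same shape.
#' @export
sss_clean_matrix <- function(X, basis) {
  good <- basis$good_channels
  w <- basis$channel_scales
  x <- (basis$pinv %*% (X[good, , drop = FALSE] / w[good])) /
    basis$column_scales
  nk <- length(basis$keep_in)
  basis$S_in[, basis$keep_in, drop = FALSE] %*% x[seq_len(nk), , drop = FALSE]
}

#' Project a leadfield through the SSS cleaning map
#'
#' Beamforming SSS-cleaned data is most consistent when the forward model
#' is passed through the same linear cleaning map as the data (as is done
#' for projector-based denoising generally); otherwise the component
#' pruning inside SSS leaves a systematic forward-model mismatch.
#'
#' @param lf a `leadfield`.
#' @param basis a `multipole_basis`.
#' @return a `leadfield` with every source's [channels x 3] matrix
#'   backprojected onto the retained internal components.
#' @export
project_leadfield <- function(lf, basis) {
  for (i in seq_len(dim(lf$L)[3]))
    lf$L[, , i] <- sss_clean_matrix(lf$L[, , i], basis)
  lf$sss_projected <- TRUE
  lf
}
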