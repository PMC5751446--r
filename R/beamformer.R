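#' Sensor covariance from epoched data
#'
#' C = (1/T) sum_t m(t) m(t)', after removing the per-epoch mean of every
#' channel, pooled over all epochs. No bandpass is applied here; filtering
#' is a pipeline stage.
#'
#' @param M a `channel_data`.
#' @param epochs list of integer sample-index vectors; default one epoch
#'   spanning all samples.
#' @return object of class `covariance_model`: `C` [channels x channels],
#'   `n_samples`, with `lambda`, `C_inv`, `cn` unset until
#'   [regularize_invert()].
#' @export
estimate_covariance <- function(M, epochs = NULL) {
  if (!inherits(M, "channel_data")) stop("M must be a channel_data")
  if (is.null(epochs)) epochs <- list(seq_len(ncol(M$data)))
  if (length(epochs) == 0 || sum(lengths(epochs)) < 2)
    stop("need at least 2 samples across non-empty epochs")
  N <- nrow(M$data)
  S <- matrix(0, N, N)
  total <- 0L
  for (ep in epochs) {
    X <- M$data[, ep, drop = FALSE]
    X <- X - rowMeans(X)
    S <- S + tcrossprod(X)
    total <- total + length(ep)
  }
  C <- S / total
  C <- (C + t(C)) / 2
  structure(list(C = C, n_samples = total, lambda = NA_real_,
                 C_inv = NULL, cn = NA_real_),
            class = "covariance_model")
}

#' Regularize and (pseudo)invert a sensor covariance
#'
#' Adds the standard trace-scaled diagonal loading
#' C_reg = C + lambda * (trace(C) / N) * I, computes its pseudoinverse and
#' its 1-norm condition number cn = ||C_reg||_1 ||C_reg^-1||_1. lambda is
#' dimensionless: the fraction of the mean sensor variance added to the
#' diagonal. After SSS the covariance is rank deficient (rank <= number of
#' internal components), so any lambda > 0 is needed for a classical
#' inverse; the pseudoinverse keeps lambda = 0 usable diagnostically.
#'
#' @param model a `covariance_model`.
#' @param lambda dimensionless regularization factor >= 0.
#' @param tol relative singular-value cutoff of the pseudoinverse.
#' @return the model with `lambda`, `C_reg`, `C_inv` and `cn` filled in.
#' @export
regularize_invert <- function(model, lambda, tol = 1e-12) {
  if (!inherits(model, "covariance_model")) stop("not a covariance_model")
  if (lambda < 0) stop("lambda must be >= 0")
  N <- nrow(model$C)
  tr <- sum(diag(model$C))
  if (tr == 0 && lambda > 0)
    stop("degenerate data: zero-trace covariance cannot be regularized")
  C_reg <- model$C + diag(lambda * tr / N, N)
  C_inv <- pinv_svd(C_reg, tol)
  model$lambda <- lambda
  model$C_reg <- C_reg
  model$C_inv <- C_inv
  model$cn <- norm(C_reg, "1") * norm(C_inv, "1")
  model
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> %d x %d, %d samples", nrow(x$C), ncol(x$C),
              x$n_samples))
  if (!is.na(x$lambda))
    cat(sprintf(", lambda = %g, cn = %.3g", x$lambda, x$cn))
  cat("\n")
  invisible(x)
}

#' LCMV spatial filter for one source
#'
#' W_i = (L' C_inv L)^-1 L' C_inv with unit gain at the target source. In
#' the conducting-sphere model the radial leadfield column is silent, so the
#' 3 x 3 inversion is carried out on the well-conditioned tangential
#' subspace of L (columns with singular value >= `sv_tol` times the
#' largest); silent directions get zero filter rows.
#'
#' @param L_i numeric matrix [channels x 3], the source's leadfield.
#' @param model a `covariance_model` with `C_inv` present.
#' @param sv_tol relative leadfield singular-value cutoff separating the
#'   active subspace from silent directions (default 1e-6).
#' @return object of class `source_filter`: `W` [3 x channels], `eta`
#'   (unset), `W_eta` (unset).
#' @export
lcmv_filter <- function(L_i, model, sv_tol = 1e-6) {
  if (is.null(model$C_inv)) stop("run regularize_invert() first")
  if (all(L_i == 0)) stop("degenerate source: all-zero leadfield")
  s <- svd(L_i)
  keep <- s$d >= sv_tol * s$d[1]
  V2 <- s$v[, keep, drop = FALSE]
  L2 <- L_i %*% V2
  A <- crossprod(L2, model$C_inv %*% L2)
  W2 <- pinv_svd(A) %*% crossprod(L2, model$C_inv)
  W <- V2 %*% W2
  structure(list(W = W, eta = NULL, W_eta = NULL, V_active = V2,
                 degenerate_orientation = FALSE),
            class = "source_filter")
}

#' Select the maximum-power source orientation
#'
#' eta_i is the dominant eigenvector of the 3 x 3 projected power matrix
#' W_i C W_i', i.e. the orientation maximizing beamformer output power; the
#' oriented filter is W_eta = eta' W. Sign is fixed so the
#' largest-magnitude component of eta is positive. A degenerate power
#' matrix (top eigenvalues equal within 1e-12 relative) is flagged and
#' broken deterministically toward the first eigenvector.
#'
#' @param filter a `source_filter` from [lcmv_filter()].
#' @param model the `covariance_model` used to build it.
#' @return the filter with `eta` (unit 3-vector) and `W_eta`
#'   ([1 x channels]) set; `degenerate_orientation` flags ties.
#' @export
select_orientation <- function(filter, model) {
  P <- filter$W %*% model$C %*% t(filter$W)
  P <- (P + t(P)) / 2
  e <- eigen(P, symmetric = TRUE)
  if (length(e$values) > 1 &&
      abs(e$values[1] - e$values[2]) <= 1e-12 * max(abs(e$values[1]), 1e-300))
    filter$degenerate_orientation <- TRUE
  eta <- e$vectors[, 1]
  j <- which.max(abs(eta))
  if (eta[j] < 0) eta <- -eta
  filter$eta <- eta
  filter$W_eta <- matrix(eta, 1, 3) %*% filter$W
  filter
}

#' Extract source time series through oriented filters
#'
#' s_i(t) = W_i,eta M(t) for every filter; linear in the data.
#'
#' @param filters list of oriented `source_filter`s.
#' @param M a `channel_data` whose rows match the filters' channel sets.
#' @return object of class `source_timeseries`: `s` [sources x samples]
#'   (nominal ampere meter), `sfreq`.
#' @export
extract_sources <- function(filters, M) {
  if (!inherits(M, "channel_data")) stop("M must be a channel_data")
  W <- do.call(rbind, lapply(filters, function(f) {
    if (is.null(f$W_eta)) stop("filters must be oriented (select_orientation)")
    f$W_eta
  }))
  if (ncol(W) != nrow(M$data)) stop("channel count mismatch")
  structure(list(s = W %*% M$data, sfreq = M$sfreq),
            class = "source_timeseries")
}

#' @export
print.source_timeseries <- function(x, ...) {
  cat(sprintf("<source_timeseries> %d sources x %d samples @ %g Hz\n",
              nrow(x$s), ncol(x$s), x$sfreq))
  invisible(x)
}

#' One-call beamformer reconstruction for a sensor type
#'
#' Convenience wrapper: restricts data and leadfields to the chosen sensor
#' type, estimates (or accepts) the covariance, regularizes with `lambda`,
#' builds oriented LCMV filters for the requested sources and extracts their
#' time series.
#'
#' @param M a full-array `channel_data`.
#' @param lf a `leadfield` for the full array.
#' @param array the `sensor_array`.
#' @param sensors `"MAG"`, `"GRAD"` or `"all"`.
#' @param lambda regularization factor.
#' @param sources integer indices into the leadfield's sources (default
#'   all).
#' @param epochs epoch sample ranges for the covariance (default one
#'   epoch).
#' @param cov optional precomputed (unregularized) `covariance_model` on the
#'   restricted channel set, to reuse across lambdas.
#' @return list: `sources` (a `source_timeseries`), `cov` (the regularized
#'   model), `filters`.
#' @export
beamform_sources <- function(M, lf, array, sensors = "all", lambda = 0.05,
                             sources = NULL, epochs = NULL, cov = NULL) {
  ch <- channel_indices(array, sensors)
  if (is.null(sources)) sources <- seq_len(dim(lf$L)[3])
  Mr <- channel_data(M$data[ch, , drop = FALSE], M$sfreq)
  if (is.null(cov)) cov <- estimate_covariance(Mr, epochs)
  cov <- regularize_invert(cov, lambda)
  filters <- lapply(sources, function(i)
    select_orientation(lcmv_filter(lf$L[ch, , i], cov), cov))
  list(sources = extract_sources(filters, Mr), cov = cov, filters = filters)
}
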