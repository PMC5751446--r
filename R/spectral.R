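#' Canonical frequency band definitions
#'
#' The four classical bands partitioning 2-30 Hz: delta 2-4, theta 4-8,
#' alpha 8-13, beta 13-30 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo = c(2, 4, 8, 13), hi = c(4, 8, 13, 30))
}

# Symmetric (linear-phase) FIR bandpass kernel, Hamming window.
fir_design <- function(lo, hi, sfreq, order = 1000L) {
  if (order %% 2 != 0) stop("FIR order must be even")
  if (hi >= sfreq / 2) stop("band above Nyquist")
  if (!(0 < lo && lo < hi)) stop("need 0 < lo < hi")
  signal::fir1(order, c(lo, hi) / (sfreq / 2), type = "pass")
}

# Zero-phase FIR application to the rows of X by FFT convolution with
# group-delay compensation (kernel is symmetric). Returns same dimensions;
# the first and last order/2 samples carry edge transients and should be
# trimmed before statistics.
fir_apply_rows <- function(X, b) {
  n <- length(b) - 1L
  T_len <- ncol(X)
  nfft <- stats::nextn(T_len + n, 2)
  B <- stats::fft(c(b, rep(0, nfft - length(b))))
  out <- matrix(0, nrow(X), T_len)
  for (i in seq_len(nrow(X))) {
    Xf <- stats::fft(c(X[i, ], rep(0, nfft - T_len)))
    y <- Re(stats::fft(Xf * B, inverse = TRUE)) / nfft
    out[i, ] <- y[(n / 2 + 1):(n / 2 + T_len)]
  }
  out
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR bandpass applied with exact
#' group-delay compensation, so the output is zero-phase. Accepts a
#' `channel_data`, a `source_timeseries` or a plain [series x samples]
#' matrix and returns the same type. The first and last `order/2` samples
#' contain edge transients; trim them (see `trim`) before computing
#' statistics.
#'
#' @param x `channel_data`, `source_timeseries`, or matrix.
#' @param lo,hi band edges in Hz.
#' @param sfreq sampling rate (taken from `x` when it carries one).
#' @param order even FIR order (default 1000).
#' @param trim if TRUE, drop `order/2` samples at both ends.
#' @return filtered object of the same class as `x`.
#' @export
fir_bandpass <- function(x, lo, hi, sfreq = NULL, order = 1000L,
                         trim = FALSE) {
  if (inherits(x, "channel_data")) {
    y <- fir_bandpass(x$data, lo, hi, x$sfreq, order, trim)
    return(channel_data(y, x$sfreq, x$bad_channels))
  }
  if (inherits(x, "source_timeseries")) {
    y <- fir_bandpass(x$s, lo, hi, x$sfreq, order, trim)
    return(structure(list(s = y, sfreq = x$sfreq),
                     class = "source_timeseries"))
  }
  if (is.null(sfreq)) stop("sfreq required for matrix input")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  b <- fir_design(lo, hi, sfreq, order)
  y <- fir_apply_rows(x, b)
  if (trim) {
    h <- order / 2
    y <- y[, (h + 1):(ncol(y) - h), drop = FALSE]
  }
  if (vec) y[1, ] else y
}

# Hamming-tapered Welch power spectral density of the rows of X at ~df Hz
# resolution (segment length sfreq/df samples, 50% overlap). Returns
# list(freqs, psd [rows x freqs]).
welch_psd <- function(X, sfreq, df = 1) {
  nw <- round(sfreq / df)
  T_len <- ncol(X)
  if (T_len < nw) stop("epoch shorter than one analysis window")
  step <- max(1L, floor(nw / 2))
  starts <- seq(1L, T_len - nw + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nw) / (nw - 1))
  scale <- sum(w^2)
  nfreq <- nw %/% 2 + 1
  acc <- matrix(0, nrow(X), nfreq)
  for (s0 in starts) {
    seg <- X[, s0:(s0 + nw - 1), drop = FALSE]
    seg <- (seg - rowMeans(seg)) * rep(w, each = nrow(seg))
    Fc <- t(stats::mvfft(t(seg)))
    acc <- acc + Mod(Fc[, seq_len(nfreq), drop = FALSE])^2 / scale
  }
  list(freqs = (seq_len(nfreq) - 1) * sfreq / nw, psd = acc / length(starts))
}

band_bin_mask <- function(freqs, lo, hi, include_hi) {
  if (include_hi) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
}

#' Relative band power per source region
#'
#' Hamming-tapered segment-averaged spectra (about 1 Hz resolution) of each
#' source time series, averaged over epochs; band powers are integrals over
#' each band and are normalized to the total power in `norm_range`. With
#' the default bands, which partition 2-30 Hz, each row sums to 1.
#'
#' @param s a `source_timeseries` (or [sources x samples] matrix with
#'   `sfreq` supplied).
#' @param bands data.frame as from [default_bands()].
#' @param epochs list of sample-index vectors (default: one epoch).
#' @param norm_range normalization frequency range, Hz.
#' @param sfreq sampling rate for matrix input.
#' @return matrix [sources x bands] of relative power fractions in [0, 1].
#' @export
relative_band_power <- function(s, bands = default_bands(), epochs = NULL,
                                norm_range = c(2, 30), sfreq = NULL) {
  if (inherits(s, "source_timeseries")) {
    sfreq <- s$sfreq
    X <- s$s
  } else X <- s
  if (is.null(sfreq)) stop("sfreq required")
  if (is.null(epochs)) epochs <- list(seq_len(ncol(X)))
  if (length(epochs) == 0) stop("empty epochs")
  psd_acc <- NULL
  for (ep in epochs) {
    p <- welch_psd(X[, ep, drop = FALSE], sfreq)
    psd_acc <- if (is.null(psd_acc)) p$psd else psd_acc + p$psd
    freqs <- p$freqs
  }
  psd <- psd_acc / length(epochs)
  nb <- nrow(bands)
  out <- matrix(NA_real_, nrow(X), nb,
                dimnames = list(NULL, bands$name))
  hi_max <- max(bands$hi)
  for (k in seq_len(nb)) {
    mask <- band_bin_mask(freqs, bands$lo[k], bands$hi[k],
                          include_hi = bands$hi[k] == hi_max)
    out[, k] <- rowSums(psd[, mask, drop = FALSE])
  }
  norm_mask <- freqs >= norm_range[1] & freqs <= norm_range[2]
  out / rowSums(psd[, norm_mask, drop = FALSE])
}

# Analytic signal of a real vector via the FFT (one-sided spectrum method).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value between all pairs of sources in a band
#'
#' The series are bandpass filtered (zero-phase FIR), instantaneous phases
#' taken from the analytic signal per epoch, and
#' PLV_jk = |mean_t exp(i (phi_j - phi_k))| computed per epoch, then
#' averaged over epochs. Constant (zero-variance) series have undefined
#' phase; their entries are flagged NaN.
#'
#' @param s a `source_timeseries`.
#' @param lo,hi band edges, Hz.
#' @param epochs list of sample-index vectors into the trimmed series;
#'   default one epoch of everything after edge trimming.
#' @param order FIR order used for the band filter.
#' @return symmetric [sources x sources] matrix in [0, 1] with unit
#'   diagonal.
#' @export
plv <- function(s, lo, hi, epochs = NULL, order = 1000L) {
  if (!inherits(s, "source_timeseries")) stop("s must be a source_timeseries")
  Xf <- fir_bandpass(s$s, lo, hi, s$sfreq, order, trim = TRUE)
  n_src <- nrow(Xf)
  if (is.null(epochs)) epochs <- list(seq_len(ncol(Xf)))
  bad <- apply(Xf, 1, function(v) stats::sd(v) == 0)
  acc <- matrix(0, n_src, n_src)
  for (ep in epochs) {
    Ph <- matrix(0i, n_src, length(ep))
    for (i in seq_len(n_src)) {
      z <- analytic_signal(Xf[i, ep])
      Ph[i, ] <- exp(1i * Arg(z))
    }
    acc <- acc + Mod(Ph %*% Conj(t(Ph))) / length(ep)
  }
  out <- acc / length(epochs)
  out[bad, ] <- NaN
  out[, bad] <- NaN
  diag(out)[!bad] <- 1
  out <- (out + t(out)) / 2
  out
}

#' Representative evoked field via a principal-component summary
#'
#' Averages time-locked trials, then extracts the first principal component
#' across channels of the chosen sensor set: the dominant spatio-temporal
#' pattern of the evoked response. The component's sign is fixed so that
#' its largest-magnitude excursion inside `peak_window` is positive, making
#' the output invariant to global sign flips of the data.
#'
#' @param trials numeric array [channels x time x trials] (already
#'   restricted to one sensor type).
#' @param sfreq sampling rate, Hz.
#' @param t0 time of the first sample relative to stimulus onset, seconds.
#' @param peak_window window (s) used to fix the component sign.
#' @return list: `component` (time course, length = time points), `pattern`
#'   (channel weights), `explained_variance` (fraction in [0, 1]), `times`.
#' @export
representative_vef <- function(trials, sfreq, t0 = -0.1,
                               peak_window = c(0.06, 0.16)) {
  stopifnot(length(dim(trials)) == 3, dim(trials)[3] >= 2)
  avg <- apply(trials, c(1, 2), mean)
  nt <- ncol(avg)
  times <- t0 + (seq_len(nt) - 1) / sfreq
  if (nrow(avg) == 1) {
    comp <- avg[1, ] - mean(avg[1, ])
    ev <- 1
    pattern <- 1
  } else {
    A <- avg - rowMeans(avg)
    sv <- svd(A)
    comp <- sv$d[1] * sv$v[, 1]
    pattern <- sv$u[, 1]
    ev <- sv$d[1]^2 / sum(sv$d^2)
  }
  win <- times >= peak_window[1] & times <= peak_window[2]
  if (any(win)) {
    pk <- which.max(abs(comp[win]))
    if (comp[win][pk] < 0) {
      comp <- -comp
      pattern <- -pattern
    }
  }
  list(component = comp, pattern = pattern, explained_variance = ev,
       times = times)
}

#' Source power change between an active window and baseline
#'
#' (P_active - P_baseline) / P_baseline per source, computed per trial and
#' averaged over trials; P is the mean squared amplitude in the window.
#'
#' @param s_trials numeric array [sources x time x trials].
#' @param sfreq sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @param active,baseline windows in seconds.
#' @return numeric vector of relative power changes per source; sources
#'   with zero baseline power are NaN with a warning.
#' @export
activation_map <- function(s_trials, sfreq, t0 = -0.1,
                           active = c(0.060, 0.160),
                           baseline = c(-0.100, 0)) {
  stopifnot(length(dim(s_trials)) == 3)
  nt <- dim(s_trials)[2]
  times <- t0 + (seq_len(nt) - 1) / sfreq
  ia <- which(times >= active[1] & times <= active[2])
  ib <- which(times >= baseline[1] & times <= baseline[2])
  if (!length(ia) || !length(ib))
    stop("trial time axis does not cover the requested windows")
  n_src <- dim(s_trials)[1]
  n_tr <- dim(s_trials)[3]
  ch <- matrix(NA_real_, n_src, n_tr)
  for (k in seq_len(n_tr)) {
    Pa <- rowMeans(s_trials[, ia, k, drop = FALSE]^2)
    Pb <- rowMeans(s_trials[, ib, k, drop = FALSE]^2)
    ch[, k] <- (Pa - Pb) / Pb
  }
  out <- rowMeans(ch)
  if (any(!is.finite(out)))
    warning("zero baseline power for some sources; entries flagged NaN")
  out
}
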