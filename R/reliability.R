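#' Squared Pearson correlation
#'
#' r^2 between two equal-length series; invariant to affine maps of either
#' argument (so also to the arbitrary sign of beamformer orientations).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return r^2 in [0, 1]; NaN (with a warning) for zero-variance input.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length series of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: r^2 undefined")
    return(NaN)
  }
  stats::cor(x, y)^2
}

#' Intraclass correlation coefficient ICC(1,1)
#'
#' One-way random-effects, single-rater ICC from the one-way ANOVA
#' decomposition over targets: (MSB - MSW) / (MSB + (k - 1) MSW) with MSB
#' the between-target and MSW the within-target mean square and k the
#' number of raters. Negative values are reported as computed, not
#' clipped.
#'
#' @param table numeric matrix [targets x raters], >= 2 of each.
#' @return ICC(1,1), always <= 1; NaN (flagged by a warning) when the
#'   denominator vanishes.
#' @export
icc_1_1 <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  k <- ncol(table)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 raters")
  row_means <- rowMeans(table)
  grand <- mean(table)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((table - row_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom == 0) {
    warning("degenerate table: ICC undefined")
    return(NaN)
  }
  (msb - msw) / denom
}

#' lambda_grad maximizing r^2 for each lambda_mag
#'
#' Argmax of each row of an r^2 surface over the gradiometer-lambda axis.
#' Ties are broken toward the smaller lambda (less added noise) and
#' flagged.
#'
#' @param r2_surface matrix [lambda_mag x lambda_grad] of mean r^2.
#' @param lambda_grid numeric vector of lambda values labeling the columns
#'   (and rows).
#' @return data.frame: `lambda_mag`, `lambda_grad_max`, `r2_max`, `tie`.
#' @export
lambda_grad_max <- function(r2_surface, lambda_grid) {
  stopifnot(ncol(r2_surface) == length(lambda_grid))
  out <- data.frame(lambda_mag = lambda_grid[seq_len(nrow(r2_surface))],
                    lambda_grad_max = NA_real_, r2_max = NA_real_,
                    tie = FALSE)
  for (i in seq_len(nrow(r2_surface))) {
    row <- r2_surface[i, ]
    if (all(is.na(row))) stop("all-NaN r^2 row at lambda_mag index ", i)
    j <- which(row == max(row, na.rm = TRUE))
    out$tie[i] <- length(j) > 1
    j <- min(j)
    out$lambda_grad_max[i] <- lambda_grid[j]
    out$r2_max[i] <- row[j]
  }
  out
}

#' Least-squares fit of log10(lambda_grad_max) on log10(lambda_mag)
#'
#' Ordinary least squares in log10-log10 space, restricted (by default) to
#' lambda_mag > 0.01 where the relation is close to linear.
#'
#' @param lambda_mag,lambda_grad_max positive numeric vectors.
#' @param lambda_min lower restriction on lambda_mag (default 0.01,
#'   exclusive).
#' @return list: `a` (slope), `b` (intercept), `r2_fit` (explained
#'   variance), `n` points used.
#' @export
loglog_fit <- function(lambda_mag, lambda_grad_max, lambda_min = 0.01) {
  keep <- lambda_mag > lambda_min
  x <- log10(lambda_mag[keep])
  y <- log10(lambda_grad_max[keep])
  if (length(unique(x)) < 2)
    stop("fewer than 2 distinct lambda_mag after restriction")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       r2_fit = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n = length(x))
}

#' Interference intensity estimate from SSS attenuation
#'
#' Ratio of the maximum absolute magnetometer amplitude before and after
#' SSS: a rough estimate of how much environmental noise SSS removed.
#'
#' @param M_raw,M_sss `channel_data` objects with identical channel sets.
#' @param mag_idx indices of the magnetometer rows.
#' @return dimensionless ratio >= 0; Inf (flagged) for zero denominator.
#' @export
noise_ratio <- function(M_raw, M_sss, mag_idx) {
  stopifnot(all(dim(M_raw$data) == dim(M_sss$data)))
  num <- max(abs(M_raw$data[mag_idx, , drop = FALSE]))
  den <- max(abs(M_sss$data[mag_idx, , drop = FALSE]))
  if (den == 0) {
    warning("zero post-SSS amplitude: ratio infinite")
    return(Inf)
  }
  num / den
}
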