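#' Moore-Penrose pseudoinverse with a relative singular-value cutoff
#'
#' Thin SVD-based pseudoinverse. Singular values below `tol` times the
#' largest singular value are treated as zero.
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff (default 1e-12).
#' @return the pseudoinverse of `A`.
#' @keywords internal
pinv_svd <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' 1-norm condition number of a square matrix
#'
#' cond(A) = ||A||_1 * ||A^-1||_1, the inverse taken as a pseudoinverse so
#' that exactly singular inputs give a finite (pseudo) condition number and
#' regularized matrices give the classical value.
#'
#' @param A square numeric matrix.
#' @param tol relative cutoff passed to [pinv_svd()].
#' @return dimensionless condition number, >= 1 for invertible `A`.
#' @keywords internal
cond1 <- function(A, tol = 1e-12) {
  norm(A, "1") * norm(pinv_svd(A, tol), "1")
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(M) sqrt(rowSums(M * M))

# Normalize the rows of an n x 3 matrix to unit length.
normalize_rows <- function(M) M / row_norms(M)

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Quasi-uniform points on a spherical cap via a Fibonacci lattice
#'
#' Deterministic golden-angle lattice on the unit sphere restricted to
#' z > z_lo. The `seed` only rotates the lattice about the z axis, so two
#' calls with equal arguments are bit-identical.
#'
#' @param n number of points.
#' @param z_lo lower bound of the z coordinate on the unit sphere.
#' @param seed integer; sets the deterministic azimuthal phase.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_cap <- function(n, z_lo = -0.2, seed = 1L) {
  stopifnot(n >= 1, z_lo > -1, z_lo < 1)
  i <- seq_len(n)
  z <- 1 - (i - 0.5) * (1 - z_lo) / n
  golden <- pi * (3 - sqrt(5))
  phase <- (as.integer(seed) %% 360L) * pi / 180
  phi <- i * golden + phase
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Deterministic orthonormal tangent pair completing a unit normal u.
tangent_pair <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- vec_cross(u, a)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- vec_cross(u, t1)
  list(t1 = t1, t2 = t2)
}

#' Non-overlapping epoch index ranges
#'
#' Splits `1:n_samples` into consecutive non-overlapping epochs of `len`
#' samples; a trailing partial epoch is dropped.
#'
#' @param n_samples total number of samples.
#' @param len epoch length in samples.
#' @return list of integer index vectors.
#' @export
epoch_ranges <- function(n_samples, len) {
  n_ep <- n_samples %/% len
  if (n_ep < 1) stop("data shorter than one epoch")
  lapply(seq_len(n_ep), function(k) ((k - 1) * len + 1):(k * len))
}
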