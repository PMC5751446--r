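#' Number of multipole components up to truncation order L
#'
#' A spherical-harmonic expansion truncated at order L carries
#' (L+1)^2 - 1 components: degrees l = 1..L with 2l+1 orders each. The
#' monopole term l = 0 is excluded (no magnetic monopoles). The standard
#' MEG truncations L = 8 (internal) and L = 3 (external) give 80 and 15
#' components.
#'
#' @param L non-negative integer truncation order.
#' @return integer number of components.
#' @examples
#' count_components(8)  # 80
#' count_components(3)  # 15
#' @export
count_components <- function(L) {
  if (length(L) != 1 || is.na(L) || L < 0 || L != round(L))
    stop("L must be a single non-negative integer")
  as.integer((L + 1)^2 - 1)
}

# ---- real solid harmonic polynomials -------------------------------------
#
# S_lm(x, y, z) is the real regular solid harmonic: a homogeneous harmonic
# polynomial of degree l with S_lm = sqrt(4 pi / (2l+1)) r^l Y_lm for the
# real orthonormal spherical harmonics Y_lm (Condon-Shortley phase,
# m = -l..l; m > 0 cosine-type, m < 0 sine-type). Coefficients are built
# from the explicit expansion of the complex Racah-normalized solid
# harmonic
#   R_l^m = sum_{p+q+s=l, p-q=m} sqrt((l+m)!(l-m)!) / (p! q! s!)
#             (-(x+iy)/2)^p ((x-iy)/2)^q z^s
# and converted to the real combinations. Polynomials are stored as
# matrices [a, b, c, coef] meaning coef * x^a y^b z^c, and are cached.

.sh_cache <- new.env(parent = emptyenv())

complex_solid_harmonic_poly <- function(l, m) {
  # returns accumulation arrays for real and imaginary coefficient parts
  re <- array(0, dim = c(l + 1, l + 1, l + 1))
  im <- array(0, dim = c(l + 1, l + 1, l + 1))
  for (p in 0:l) for (q in 0:(l - p)) {
    if (p - q != m) next
    s <- l - p - q
    base <- sqrt(factorial(l + m) * factorial(l - m)) /
      (factorial(p) * factorial(q) * factorial(s)) *
      (-1)^p * 2^(-(p + q))
    for (j in 0:p) for (k in 0:q) {
      a <- p - j + q - k; b <- j + k
      # i^j * (-i)^k = i^(j-k)
      ph <- (j - k) %% 4
      cc <- base * choose(p, j) * choose(q, k)
      if (ph == 0) re[a + 1, b + 1, s + 1] <- re[a + 1, b + 1, s + 1] + cc
      if (ph == 1) im[a + 1, b + 1, s + 1] <- im[a + 1, b + 1, s + 1] + cc
      if (ph == 2) re[a + 1, b + 1, s + 1] <- re[a + 1, b + 1, s + 1] - cc
      if (ph == 3) im[a + 1, b + 1, s + 1] <- im[a + 1, b + 1, s + 1] - cc
    }
  }
  list(re = re, im = im)
}

array_to_terms <- function(A) {
  idx <- which(abs(A) > 1e-14, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(0, 0, 4))
  cbind(a = idx[, 1] - 1, b = idx[, 2] - 1, c = idx[, 3] - 1,
        coef = A[idx])
}

real_solid_harmonic_poly <- function(l, m) {
  key <- paste0("S", l, "_", m)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  cx <- complex_solid_harmonic_poly(l, abs(m))
  terms <- if (m == 0) {
    array_to_terms(cx$re)
  } else if (m > 0) {
    array_to_terms((-1)^m * sqrt(2) * cx$re)
  } else {
    array_to_terms((-1)^m * sqrt(2) * cx$im)
  }
  .sh_cache[[key]] <- terms
  terms
}

poly_deriv <- function(terms, dim) {
  if (nrow(terms) == 0) return(terms)
  keep <- terms[, dim] > 0
  out <- terms[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  out[, "coef"] <- out[, "coef"] * out[, dim]
  out[, dim] <- out[, dim] - 1
  out
}

poly_eval <- function(terms, P) {
  if (nrow(terms) == 0) return(numeric(nrow(P)))
  out <- numeric(nrow(P))
  for (t in seq_len(nrow(terms))) {
    out <- out + terms[t, "coef"] *
      P[, 1]^terms[t, "a"] * P[, 2]^terms[t, "b"] * P[, 3]^terms[t, "c"]
  }
  out
}

solid_harmonic <- function(l, m) {
  key <- paste0("G", l, "_", m)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  S <- real_solid_harmonic_poly(l, m)
  out <- list(poly = S,
              grad = list(poly_deriv(S, 1), poly_deriv(S, 2),
                          poly_deriv(S, 3)))
  .sh_cache[[key]] <- out
  out
}

check_lm <- function(l, m) {
  if (l < 1 || abs(m) > l) stop("need 1 <= l and |m| <= l")
}

#' Internal multipole basis field
#'
#' The magnetic field basis function of the internal (brain-side) expansion:
#' F_lm(r) = -grad( Y_lm(theta, phi) / r^(l+1) ), with real orthonormal
#' spherical harmonics Y_lm. F_lm is homogeneous of degree -(l+2), so
#' internal fields fall off as 1/r^(l+2) away from the expansion origin.
#'
#' @param l degree, 1 <= l.
#' @param m order, -l <= m <= l.
#' @param r n x 3 matrix (or 3-vector) of positions relative to the
#'   expansion origin, meters.
#' @return n x 3 matrix of field vectors (arbitrary basis units).
#' @export
internal_basis_field <- function(l, m, r) {
  check_lm(l, m)
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  rn <- row_norms(r)
  if (any(rn == 0)) stop("singularity: position at the expansion origin")
  sh <- solid_harmonic(l, m)
  k <- sqrt((2 * l + 1) / (4 * pi))
  S <- poly_eval(sh$poly, r)
  gS <- cbind(poly_eval(sh$grad[[1]], r), poly_eval(sh$grad[[2]], r),
              poly_eval(sh$grad[[3]], r))
  # -grad( k * S / r^(2l+1) )
  -k * (gS / rn^(2 * l + 1) - (2 * l + 1) * S / rn^(2 * l + 3) * r)
}

#' External multipole basis field
#'
#' The magnetic field basis function of the external (environment-side)
#' expansion: G_lm(r) = -grad( r^l Y_lm(theta, phi) ), homogeneous of degree
#' l - 1; the l = 1 components are spatially uniform fields.
#'
#' @inheritParams internal_basis_field
#' @return n x 3 matrix of field vectors.
#' @export
external_basis_field <- function(l, m, r) {
  check_lm(l, m)
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  if (any(row_norms(r) == 0) && l > 1) {
    # gradient of a degree-l polynomial is fine at the origin; keep going
  }
  sh <- solid_harmonic(l, m)
  k <- sqrt((2 * l + 1) / (4 * pi))
  -k * cbind(poly_eval(sh$grad[[1]], r), poly_eval(sh$grad[[2]], r),
             poly_eval(sh$grad[[3]], r))
}

# Ordered (l, m) labels for an expansion truncated at L: l-major, m = -l..l.
component_index <- function(L) {
  do.call(rbind, lapply(seq_len(L), function(l)
    data.frame(l = l, m = seq(-l, l))))
}
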