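MU0_OVER_4PI <- 1e-7  # magnetic constant / 4 pi, T m / A

#' Magnetic field of a current dipole in a homogeneous conducting sphere
#'
#' Closed-form quasistatic field (Sarvas formula) of a current dipole at
#' `r_q` with moment `q` (ampere meter), evaluated at external positions.
#' The sphere is centered at `origin`; volume currents are accounted for
#' exactly, which makes radially oriented dipoles externally silent.
#'
#' @param r_q 3-vector, dipole position in meters (inside the sphere).
#' @param q 3-vector, dipole moment in ampere meter.
#' @param r n x 3 matrix (or 3-vector) of field positions in meters,
#'   strictly outside the sphere.
#' @param origin sphere center, meters.
#' @param sphere_radius conductor radius in meters; used only to validate
#'   the geometry (`NULL` skips the check).
#' @return n x 3 matrix of magnetic field vectors in tesla.
#' @export
dipole_field <- function(r_q, q, r, origin = c(0, 0, 0),
                         sphere_radius = NULL) {
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  r0 <- sweep(r, 2, origin)
  rq <- r_q - origin
  if (!is.null(sphere_radius)) {
    if (sqrt(sum(rq^2)) >= sphere_radius)
      stop("dipole position outside the conducting sphere")
    if (any(row_norms(r0) <= sphere_radius))
      stop("field position inside the conducting sphere")
  }
  a_vec <- r0 - matrix(rq, nrow(r0), 3, byrow = TRUE)
  a <- row_norms(a_vec)
  if (any(a == 0)) stop("field position coincides with the dipole")
  rr <- row_norms(r0)
  ar <- rowSums(a_vec * r0)          # a . r
  rq_r <- as.vector(r0 %*% rq)       # r_q . r
  Fs <- a * (rr * a + rr^2 - rq_r)
  cF1 <- a^2 / rr + ar / a + 2 * a + 2 * rr
  cF2 <- a + 2 * rr + ar / a
  gradF <- cF1 * r0 - outer(cF2, rq)
  qxrq <- vec_cross(q, rq)
  t1 <- outer(Fs, qxrq)
  t2 <- as.vector(r0 %*% qxrq) * gradF
  MU0_OVER_4PI * (t1 - t2) / Fs^2
}

#' Free-space field of a distant magnetic dipole
#'
#' Vacuum point-dipole formula
#' B = (mu0 / 4 pi) (3 (m . a_hat) a_hat - m) / |a|^3, used for
#' environmental interference sources (current loops in distant equipment
#' and power installations). Away from the source this field is curl- and
#' divergence-free, i.e. it admits the harmonic-potential expansion that
#' signal space separation relies on.
#'
#' @param r_q 3-vector, dipole position in meters.
#' @param m 3-vector, magnetic dipole moment in ampere meter^2.
#' @param r n x 3 matrix (or 3-vector) of field positions in meters.
#' @return n x 3 matrix of field vectors in tesla.
#' @export
magnetic_dipole_field <- function(r_q, m, r) {
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  a_vec <- sweep(r, 2, r_q)
  a <- row_norms(a_vec)
  if (any(a == 0)) stop("field position coincides with the source")
  ah <- a_vec / a
  ma <- as.vector(ah %*% m)
  MU0_OVER_4PI * (3 * ma * ah - matrix(m, nrow(r), 3, byrow = TRUE)) / a^3
}

# MNI-like probe coordinates (mm) for the four sources of interest, mapped
# into the model sphere by a fixed affine: meters = mm / 1000 * 0.75.
PROBE_MNI_MM <- rbind(
  visual       = c(-41, -77, 3),
  somatosensory = c(-38, -27, 52),
  precuneus    = c(1, -57, 28),
  cingulate    = c(-2, 12, 40)
)
MNI_TO_SPHERE_SCALE <- 0.75e-3

#' Build a spherical source space
#'
#' A source grid of two concentric Fibonacci-lattice shells (default radii
#' 0.55 and 0.75 of the sphere radius) plus four named probe positions
#' standing in for commonly probed cortical sites (visual cortex, primary
#' somatosensory cortex, precuneus, median cingulate); their MNI-style
#' millimeter coordinates are mapped into the sphere by a fixed affine.
#' Each grid point doubles as a "region" for region-level statistics. The
#' shells are restricted to the upper hemisphere (`cap_z`), mirroring
#' cortex under a helmet: sources below the sensor rim are not part of the
#' mapped space.
#'
#' @param sphere_radius conductor sphere radius in meters (default 0.09).
#' @param origin sphere center (also the SSS expansion origin), meters.
#' @param n_per_shell grid points per shell (default 100).
#' @param shell_fracs radii of the shells as fractions of `sphere_radius`.
#' @param cap_z lower z bound of the shell lattices as a fraction of the
#'   shell radius (default 0: upper hemisphere).
#' @return object of class `source_space`: `grid` (n x 3 positions, probes
#'   are the last four rows), `probe_idx` (named indices into `grid`),
#'   `origin`, `sphere_radius`.
#' @export
build_source_space <- function(sphere_radius = 0.09, origin = c(0, 0, 0),
                               n_per_shell = 100L,
                               shell_fracs = c(0.55, 0.75), cap_z = 0) {
  shells <- lapply(seq_along(shell_fracs), function(k) {
    u <- fibonacci_cap(n_per_shell, z_lo = cap_z, seed = k)
    sphere_radius * shell_fracs[k] * u
  })
  probes <- PROBE_MNI_MM * MNI_TO_SPHERE_SCALE
  grid <- rbind(do.call(rbind, shells), probes)
  grid <- sweep(grid, 2, origin, "+")
  rn <- row_norms(sweep(grid, 2, origin))
  stopifnot(all(rn < sphere_radius))
  probe_idx <- nrow(grid) - 3:0
  names(probe_idx) <- rownames(PROBE_MNI_MM)
  rownames(grid) <- NULL
  structure(list(grid = grid, probe_idx = probe_idx, origin = origin,
                 sphere_radius = sphere_radius),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d grid points in sphere R = %g m; probes: %s\n",
              nrow(x$grid), x$sphere_radius,
              paste(names(x$probe_idx), collapse = ", ")))
  invisible(x)
}

#' Leadfield matrices for a source space
#'
#' For each source position the [channels x 3] linear map from a dipole
#' moment (ampere meter, Cartesian components) to the channel measurements
#' (tesla for magnetometers, tesla/meter for gradiometers), using the
#' conducting-sphere forward model. The radial column is numerically silent.
#'
#' @param array a `sensor_array`.
#' @param space a `source_space`.
#' @return object of class `leadfield`: `L` array
#'   [channels x 3 x n_sources], plus `positions`, `origin`.
#' @export
compute_leadfield <- function(array, space) {
  cp <- coil_points(array)
  pts <- cp$points
  n_src <- nrow(space$grid)
  n_chan <- array$n_channels
  rn <- row_norms(sweep(space$grid, 2, space$origin))
  if (any(rn >= space$sphere_radius))
    stop("source outside the conducting sphere")
  L <- array(0, dim = c(n_chan, 3, n_src))
  ct <- array$channel_table
  normals <- array$triplet_normals[ct$triplet[cp$channel], , drop = FALSE]
  first <- !duplicated(cp$channel)
  second <- duplicated(cp$channel)
  ch2 <- cp$channel[second]
  for (i in seq_len(n_src)) {
    for (d in 1:3) {
      q <- c(0, 0, 0); q[d] <- 1
      B <- dipole_field(space$grid[i, ], q, pts, origin = space$origin)
      bn <- rowSums(B * normals)
      v <- numeric(n_chan)
      v[cp$channel[first]] <- bn[first]
      v[ch2] <- (v[ch2] - bn[second]) / array$baseline
      L[, d, i] <- v
    }
  }
  structure(list(L = L, positions = space$grid, origin = space$origin),
            class = "leadfield")
}
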