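#' Build a Vectorview-like helmet sensor array
#'
#' Constructs a hemispherical helmet of sensor triplets, each holding one
#' magnetometer (measuring the field component along the outward helmet
#' normal, in tesla) and two orthogonal planar gradiometers (measuring the
#' tangential spatial derivative of that normal component, in tesla/meter).
#' Triplets are laid out on a deterministic Fibonacci lattice over the upper
#' part of the helmet sphere, so the same `(n_triplets, seed)` always yields
#' bit-identical geometry. The default of 102 triplets mirrors the
#' 306-channel layout of modern MEG systems.
#'
#' @param n_triplets number of sensor triplets (default 102).
#' @param helmet_radius helmet sphere radius in meters (default 0.12).
#' @param baseline gradiometer coil separation in meters (default 0.0168,
#'   a hardware-typical planar-gradiometer value).
#' @param center 3-vector, helmet sphere center in meters; by default
#'   0.04 m above the source-sphere origin.
#' @param coverage_z lower z bound (as a fraction of the helmet radius, in
#'   helmet-centered coordinates) of the sensor lattice. The default -0.6
#'   wraps the array around the sides of the head the way whole-head
#'   helmets do; shallower caps degrade the conditioning of the
#'   internal/external multipole separation.
#' @param seed integer controlling the deterministic lattice phase.
#' @param bad_channels integer vector of channel indices flagged bad.
#' @return an object of class `sensor_array` with elements
#'   `triplet_positions` (n x 3), `triplet_normals` (n x 3),
#'   `tangent_frames` (list of 2 x 3 matrices), `channel_table`
#'   (data.frame: channel, type, triplet, tangent), `baseline`, `center`,
#'   `helmet_radius`, `bad_channels`, and `n_channels = 3 * n_triplets`.
#'   Channel order is MAG, GRAD1, GRAD2 within each triplet.
#' @examples
#' arr <- build_array(n_triplets = 102)
#' table(arr$channel_table$type)   # 102 MAG, 204 GRAD
#' @export
build_array <- function(n_triplets = 102L, helmet_radius = 0.12,
                        baseline = 0.0168, center = c(0, 0, 0.04),
                        coverage_z = -0.6, seed = 1L,
                        bad_channels = integer()) {
  if (n_triplets < 1 || helmet_radius <= 0 || baseline <= 0)
    stop("invalid geometry: n_triplets, helmet_radius and baseline must be positive")
  if (baseline >= helmet_radius)
    stop("invalid geometry: baseline must be small compared to helmet_radius")

  u <- fibonacci_cap(n_triplets, z_lo = coverage_z, seed = seed)
  positions <- sweep(helmet_radius * u, 2, center, "+")
  frames <- lapply(seq_len(n_triplets), function(i) {
    tp <- tangent_pair(u[i, ])
    rbind(tp$t1, tp$t2)
  })

  channel_table <- data.frame(
    channel = seq_len(3L * n_triplets),
    type = rep(c("MAG", "GRAD", "GRAD"), n_triplets),
    triplet = rep(seq_len(n_triplets), each = 3L),
    tangent = rep(c(NA_integer_, 1L, 2L), n_triplets)
  )

  structure(list(
    triplet_positions = positions,
    triplet_normals = u,
    tangent_frames = frames,
    channel_table = channel_table,
    baseline = baseline,
    center = center,
    helmet_radius = helmet_radius,
    bad_channels = as.integer(bad_channels),
    n_channels = 3L * n_triplets
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "<sensor_array> %d triplets / %d channels (%d MAG + %d GRAD), helmet R = %g m, baseline = %g m\n",
    nrow(x$triplet_positions), x$n_channels,
    sum(x$channel_table$type == "MAG"), sum(x$channel_table$type == "GRAD"),
    x$helmet_radius, x$baseline))
  if (length(x$bad_channels))
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Indices of magnetometer / gradiometer channels
#'
#' @param array a `sensor_array`.
#' @param type `"MAG"`, `"GRAD"` or `"all"`.
#' @return integer vector of channel indices.
#' @export
channel_indices <- function(array, type = c("all", "MAG", "GRAD")) {
  type <- match.arg(type)
  if (type == "all") return(array$channel_table$channel)
  array$channel_table$channel[array$channel_table$type == type]
}

# Coil evaluation points for every channel together with bookkeeping to
# convert point field values into channel outputs. Magnetometers contribute
# one point; each gradiometer two points at p +/- (baseline/2) * tangent.
coil_points <- function(array) {
  ct <- array$channel_table
  n_chan <- nrow(ct)
  pts <- vector("list", n_chan)
  for (ch in seq_len(n_chan)) {
    tri <- ct$triplet[ch]
    p <- array$triplet_positions[tri, ]
    if (ct$type[ch] == "MAG") {
      pts[[ch]] <- matrix(p, 1, 3)
    } else {
      th <- array$tangent_frames[[tri]][ct$tangent[ch], ]
      h <- array$baseline / 2
      pts[[ch]] <- rbind(p + h * th, p - h * th)
    }
  }
  idx <- rep(seq_len(n_chan), vapply(pts, nrow, 1L))
  list(points = do.call(rbind, pts), channel = idx)
}

#' Evaluate a vector-field function through every channel's pickup model
#'
#' Magnetometer channels return the normal field component n.B(p) in tesla;
#' planar-gradiometer channels return the symmetric difference
#' (n.B(p + b/2 t) - n.B(p - b/2 t)) / b in tesla/meter, with b the
#' gradiometer baseline and t the channel's tangent direction. Pickup is
#' point-like (no coil-area integration).
#'
#' @param array a `sensor_array`.
#' @param field_fn function mapping an n x 3 matrix of positions (meters) to
#'   an n x 3 matrix of magnetic field vectors (tesla).
#' @return numeric vector of length `array$n_channels`.
#' @export
measure_field <- function(array, field_fn) {
  cp <- coil_points(array)
  B <- field_fn(cp$points)
  if (is.null(dim(B))) B <- matrix(B, ncol = 3)
  if (any(!is.finite(B)))
    stop("field_fn returned non-finite values at coil positions")
  ct <- array$channel_table
  normals <- array$triplet_normals[ct$triplet[cp$channel], , drop = FALSE]
  bn <- rowSums(B * normals)
  out <- numeric(nrow(ct))
  first <- !duplicated(cp$channel)
  out[cp$channel[first]] <- bn[first]
  second <- duplicated(cp$channel)
  ch2 <- cp$channel[second]
  out[ch2] <- (out[ch2] - bn[second]) / array$baseline
  out
}

#' Write a sensor-array layout to a JSON file
#'
#' @param array a `sensor_array`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_array_layout <- function(array, path) {
  n <- nrow(array$triplet_positions)
  triplets <- lapply(seq_len(n), function(i) list(
    position = array$triplet_positions[i, ],
    normal = array$triplet_normals[i, ],
    tangents = list(array$tangent_frames[[i]][1, ],
                    array$tangent_frames[[i]][2, ])
  ))
  jsonlite::write_json(
    list(triplets = triplets, baseline_m = array$baseline,
         helmet_radius_m = array$helmet_radius, center_m = array$center,
         bad_channels = array$bad_channels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sensor-array layout from a JSON file
#'
#' Validates the geometric invariants (unit normals, normal-tangent
#' orthogonality, positive baseline) on load.
#'
#' @param path JSON layout file written by [write_array_layout()].
#' @return a `sensor_array`.
#' @export
read_array_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v) if (is.list(v)) do.call(rbind, v) else
    matrix(unlist(v), ncol = 3, byrow = is.list(v))
  pos <- as_mat(x$triplets$position)
  nrm <- as_mat(x$triplets$normal)
  n <- nrow(pos)
  frames <- lapply(x$triplets$tangents, function(tt)
    if (is.list(tt)) do.call(rbind, tt) else tt)
  if (x$baseline_m <= 0) stop("invalid layout: non-positive baseline")
  if (any(abs(row_norms(nrm) - 1) > 1e-9))
    stop("invalid layout: normals are not unit vectors")
  for (i in seq_len(n)) {
    if (max(abs(frames[[i]] %*% nrm[i, ])) > 1e-9)
      stop("invalid layout: tangents not orthogonal to normal")
  }
  channel_table <- data.frame(
    channel = seq_len(3L * n),
    type = rep(c("MAG", "GRAD", "GRAD"), n),
    triplet = rep(seq_len(n), each = 3L),
    tangent = rep(c(NA_integer_, 1L, 2L), n)
  )
  center <- if (!is.null(x$center_m)) as.numeric(x$center_m) else c(0, 0, 0)
  hr <- if (!is.null(x$helmet_radius_m)) x$helmet_radius_m else NA_real_
  structure(list(
    triplet_positions = pos, triplet_normals = nrm, tangent_frames = frames,
    channel_table = channel_table, baseline = x$baseline_m,
    center = center, helmet_radius = hr,
    bad_channels = as.integer(unlist(x$bad_channels)),
    n_channels = 3L * n
  ), class = "sensor_array")
}
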