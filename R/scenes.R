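# Generator defaults — the study conditions of every synthetic experiment.
# Dipole moments were calibrated once, by rendering, so that brain sources
# alone give magnetometer peaks of order 20 fT (within a small factor), and
# the "high" interference level so that the magnetometer max-amplitude
# ratio before/after SSS is comfortably >= 5. Sensor noise floors are set
# to preserve, at this field scale, the in-band channel SNR regime of real
# recordings (see the methods vignette).
DEFAULT_PROBE_AMP <- 0.5e-9       # A m RMS, probe sources
DEFAULT_BACKGROUND_AMP <- 0.13e-9 # A m RMS, each diffuse background source
# external interference: magnetic dipole moments, A m^2
DEFAULT_INTERFERENCE_AMP <- list(none = 0, low = 1e-6, high = 1e-5)
DEFAULT_MAG_NOISE <- 0.05e-15     # T / sqrt(Hz)
DEFAULT_GRAD_NOISE <- 0.05e-13    # (T/m) / sqrt(Hz)
N_PATCHES <- 24L                  # spatially coherent background patches

# Unit vector tangential to the radius at position p (random in-plane
# angle; consumes RNG).
random_tangential <- function(p) {
  u <- p / sqrt(sum(p^2))
  tp <- tangent_pair(u)
  th <- stats::runif(1, 0, 2 * pi)
  cos(th) * tp$t1 + sin(th) * tp$t2
}

# Unit-RMS band-limited Gaussian noise: white noise spectrally shaped by a
# Gaussian bump centered at f0 with standard deviation bw/2.
narrowband_noise <- function(n, sfreq, f0, bw) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sfreq - f)                      # two-sided frequency axis
  g <- exp(-((f - f0)^2) / (2 * (bw / 2)^2))
  y <- Re(stats::fft(X * g, inverse = TRUE) / n)
  y / stats::sd(y)
}

# Unit-RMS 1/f^(expo/2)-amplitude noise, flat below f_lo to avoid the DC
# singularity.
pink_noise <- function(n, sfreq, expo = 1, f_lo = 0.5) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sfreq - f)
  g <- 1 / pmax(f, f_lo)^(expo / 2)
  g[1] <- 0
  y <- Re(stats::fft(X * g, inverse = TRUE) / n)
  y / stats::sd(y)
}

# Unit-RMS low-frequency environmental drift in [f_lo, f_hi] Hz.
drift_noise <- function(n, sfreq, f_lo = 0.5, f_hi = 8) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sfreq - f)
  g <- as.numeric(f >= f_lo & f <= f_hi)
  g[1] <- 0
  y <- Re(stats::fft(X * g, inverse = TRUE) / n)
  y / stats::sd(y)
}

# Patch membership: grid points assigned to the nearest of N_PATCHES
# centers taken from the lattice itself (half per shell).
patch_assignment <- function(space) {
  n_grid <- nrow(space$grid) - length(space$probe_idx)
  half <- n_grid %/% 2
  ctr_idx <- c(round(seq(1, half, length.out = N_PATCHES / 2)),
               half + round(seq(1, n_grid - half, length.out = N_PATCHES / 2)))
  centers <- space$grid[ctr_idx, , drop = FALSE]
  vapply(seq_len(n_grid), function(k)
    which.min(colSums((t(centers) - space$grid[k, ])^2)), integer(1))
}

external_source_set <- function(n_ext, ext_amp) {
  lapply(seq_len(n_ext), function(k) {
    d <- stats::runif(1, 2.5, 4)
    az <- stats::runif(1, 0, 2 * pi)
    el <- stats::runif(1, -0.3, 0.5)
    pos <- d * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    ori <- stats::rnorm(3)
    list(pos = pos, ori = ori / sqrt(sum(ori^2)),
         amp = ext_amp * stats::runif(1, 0.5, 1.5), line_mix = 0.3)
  })
}

#' Generate synthetic resting-state scenes
#'
#' One scene per "subject". Brain activity is diffuse: every source-grid
#' point carries a dipolar source with a tangential orientation and a
#' waveform mixing a local in-band rhythm, a higher-frequency rhythm, 1/f
#' broadband noise, and a rhythm shared across its spatial patch (cortical
#' activity is spatially correlated at the centimeter scale). The four
#' probe positions carry stronger alpha-band sources. Distant magnetic
#' dipole interferers at 2.5-4 m (slow drifts plus a 50 Hz component) load
#' magnetometers far more than gradiometers, and i.i.d. per-channel sensor
#' noise is added at rendering. Per-(subject, source) lognormal amplitude
#' jitter (sigma = 0.3) creates between-subject variance. Scenes are
#' bit-exactly reproducible from (seed, arguments).
#'
#' @param seed integer cohort seed.
#' @param n_subjects number of subjects (scenes).
#' @param interference `"none"`, `"low"` or `"high"`; `"high"` is
#'   calibrated so the magnetometer max-amplitude before/after-SSS ratio
#'   exceeds 5.
#' @param duration recording length per subject, seconds (default 120).
#' @param sfreq sampling rate, Hz.
#' @param space a `source_space` (default [build_source_space()]).
#' @param epoch_length epoch length in seconds used downstream.
#' @param probe_amp,background_amp dipole moment scales, A m RMS.
#' @param n_external number of interference dipoles.
#' @return list of `synthetic_scene` objects.
#' @export
make_resting_scene <- function(seed, n_subjects = 8L,
                               interference = c("high", "low", "none"),
                               duration = 120, sfreq = 1000,
                               space = build_source_space(),
                               epoch_length = 6,
                               probe_amp = DEFAULT_PROBE_AMP,
                               background_amp = DEFAULT_BACKGROUND_AMP,
                               n_external = 10L) {
  interference <- match.arg(interference)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  ext_amp <- DEFAULT_INTERFERENCE_AMP[[interference]]
  patch_of <- patch_assignment(space)
  n_grid <- nrow(space$grid)

  lapply(seq_len(n_subjects), function(subj) {
    set.seed(as.integer(seed) + 7919L * subj)
    jitter <- stats::rlnorm(n_grid, 0, 0.3)
    patch_f0 <- stats::runif(N_PATCHES, 3.5, 18)
    internal <- vector("list", n_grid)
    for (k in seq_len(n_grid)) {
      pos <- space$grid[k, ]
      if (k %in% space$probe_idx) {
        internal[[k]] <- list(
          pos = pos, grid_idx = k, ori = random_tangential(pos),
          amp = probe_amp * jitter[k],
          f0 = 9, bw = 2, f0b = NA_real_, bwb = NA_real_,
          patch = NA_integer_, mix = c(0.7, 0, 0.3, 0))
      } else {
        internal[[k]] <- list(
          pos = pos, grid_idx = k, ori = random_tangential(pos),
          amp = background_amp * jitter[k],
          f0 = stats::runif(1, 3.5, 9.5), bw = stats::runif(1, 1.5, 3),
          f0b = stats::runif(1, 10, 28), bwb = stats::runif(1, 2, 5),
          patch = patch_of[k], mix = c(0.45, 0.2, 0.15, 0.3))
      }
    }
    external <- external_source_set(n_external, ext_amp)
    structure(list(
      seed = as.integer(seed) + 7919L * subj + 13L,
      subject = subj, kind = "resting",
      internal_sources = internal, external_sources = external,
      patch_f0 = patch_f0,
      mag_noise = DEFAULT_MAG_NOISE, grad_noise = DEFAULT_GRAD_NOISE,
      sfreq = sfreq, duration = duration, epoch_length = epoch_length,
      interference = interference
    ), class = "synthetic_scene")
  })
}

#' Generate a synthetic evoked (visual task) scene
#'
#' Trials of -0.1 to 0.9 s around a stimulus: two occipital sources near
#' the visual-cortex probe carry a Gabor-like evoked waveform peaking near
#' 100 ms (inside 60-160 ms), on top of ongoing diffuse background
#' activity, low-level interference and sensor noise.
#'
#' @param seed integer seed.
#' @param n_trials number of trials (>= 2).
#' @param sfreq sampling rate, Hz.
#' @param space a `source_space`.
#' @param evoked_amp evoked dipole peak moment, A m (0 disables the evoked
#'   response).
#' @param n_background number of ongoing background sources (drawn from
#'   the grid).
#' @return a `synthetic_scene` with trial structure (`t0 = -0.1`,
#'   `trial_length = 1` s).
#' @export
make_evoked_scene <- function(seed, n_trials = 64L, sfreq = 1000,
                              space = build_source_space(),
                              evoked_amp = 30e-9, n_background = 40L) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  set.seed(as.integer(seed))
  vis <- space$grid[space$probe_idx["visual"], ]
  # the two responses differ in latency and carrier (as bilateral evoked
  # responses do); identical waveforms would also be mutually cancelled by
  # the minimum-variance beamformer
  evoked <- lapply(1:2, function(k) {
    pos <- vis + c(0.008 * (k == 2), 0.008 * (k == 1), 0)
    list(pos = pos, ori = random_tangential(pos), amp = evoked_amp,
         latency = 0.095 + 0.02 * (k - 1), width = 0.025,
         f_carrier = 8 + 2 * (k - 1))
  })
  n_grid <- nrow(space$grid) - length(space$probe_idx)
  bg_idx <- sample(seq_len(n_grid), n_background)
  background <- lapply(bg_idx, function(k) {
    pos <- space$grid[k, ]
    list(pos = pos, grid_idx = k, ori = random_tangential(pos),
         amp = DEFAULT_BACKGROUND_AMP,
         f0 = stats::runif(1, 3.5, 9.5), bw = stats::runif(1, 1.5, 3),
         f0b = stats::runif(1, 10, 28), bwb = stats::runif(1, 2, 5),
         patch = NA_integer_, mix = c(0.45, 0.2, 0.35, 0))
  })
  external <- external_source_set(2L, DEFAULT_INTERFERENCE_AMP$low)
  structure(list(
    seed = as.integer(seed) + 101L, kind = "evoked",
    evoked_sources = evoked, internal_sources = background,
    external_sources = external,
    mag_noise = DEFAULT_MAG_NOISE, grad_noise = DEFAULT_GRAD_NOISE,
    sfreq = sfreq, n_trials = as.integer(n_trials),
    t0 = -0.1, trial_length = 1
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  if (x$kind == "resting") {
    cat(sprintf(
      "<synthetic_scene:resting> subject %d, %d internal + %d external sources, %g s @ %g Hz, interference=%s\n",
      x$subject, length(x$internal_sources), length(x$external_sources),
      x$duration, x$sfreq, x$interference))
  } else {
    cat(sprintf(
      "<synthetic_scene:evoked> %d trials of %g s, %d evoked + %d background sources\n",
      x$n_trials, x$trial_length, length(x$evoked_sources),
      length(x$internal_sources)))
  }
  invisible(x)
}

# Channel-space spatial pattern (per unit dipole moment along ori) of an
# internal source: taken from a precomputed leadfield when the source sits
# on the grid, otherwise via the conducting-sphere forward model directly.
internal_pattern <- function(src, array, origin = c(0, 0, 0),
                             leadfield = NULL) {
  if (!is.null(leadfield) && !is.null(src$grid_idx) &&
      !is.na(src$grid_idx) && is.null(leadfield$sss_projected))
    return(as.vector(leadfield$L[, , src$grid_idx] %*% src$ori))
  measure_field(array, function(P)
    dipole_field(src$pos, src$ori, P, origin = origin))
}

external_pattern <- function(src, array) {
  measure_field(array, function(P)
    magnetic_dipole_field(src$pos, src$ori, P))
}

# One internal source waveform on n samples (unit RMS before amp scaling).
internal_waveform <- function(src, n, sfreq, patchW = NULL) {
  w <- src$mix[1] * narrowband_noise(n, sfreq, src$f0, src$bw)
  if (src$mix[2] > 0)
    w <- w + src$mix[2] * narrowband_noise(n, sfreq, src$f0b, src$bwb)
  if (src$mix[3] > 0)
    w <- w + src$mix[3] * pink_noise(n, sfreq)
  if (src$mix[4] > 0 && !is.na(src$patch))
    w <- w + src$mix[4] * patchW[src$patch, ]
  src$amp * w / stats::sd(w)
}

#' Render a synthetic resting scene into channel data
#'
#' Superposes the forward fields of all internal and external sources with
#' their waveforms and adds i.i.d. Gaussian sensor noise scaled to the
#' Nyquist bandwidth. Rendering is bit-exact given the scene; the
#' component subset never changes the realization of the included
#' components.
#'
#' @param scene a resting `synthetic_scene`.
#' @param array a `sensor_array`.
#' @param components subset of `c("internal", "external", "noise")` to
#'   include (all by default); useful for calibration and linearity checks.
#' @param leadfield optional unprojected `leadfield` matching the scene's
#'   source space, to reuse precomputed source patterns.
#' @return a `channel_data` [channels x samples].
#' @export
render <- function(scene, array,
                   components = c("internal", "external", "noise"),
                   leadfield = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"), scene$kind == "resting")
  set.seed(scene$seed)
  n <- round(scene$duration * scene$sfreq)
  patchW <- t(vapply(seq_len(N_PATCHES), function(c0)
    narrowband_noise(n, scene$sfreq, scene$patch_f0[c0], 2.5), numeric(n)))
  ns <- length(scene$internal_sources)
  W <- matrix(0, ns, n)
  for (k in seq_len(ns))
    W[k, ] <- internal_waveform(scene$internal_sources[[k]], n,
                                scene$sfreq, patchW)
  if ("internal" %in% components) {
    P <- vapply(scene$internal_sources, internal_pattern,
                numeric(array$n_channels), array = array,
                leadfield = leadfield)
    X <- P %*% W
  } else X <- matrix(0, array$n_channels, n)
  rm(W)
  for (src in scene$external_sources) {
    drift <- drift_noise(n, scene$sfreq)
    line <- sin(2 * pi * 50 * seq_len(n) / scene$sfreq +
                  stats::runif(1, 0, 2 * pi))
    w <- src$amp * ((1 - src$line_mix) * drift +
                      src$line_mix * sqrt(2) * line)
    if ("external" %in% components && src$amp > 0)
      X <- X + outer(external_pattern(src, array), w)
  }
  if ("noise" %in% components) {
    sd_chan <- ifelse(array$channel_table$type == "MAG",
                      scene$mag_noise, scene$grad_noise) *
      sqrt(scene$sfreq / 2)
    X <- X + sd_chan * matrix(stats::rnorm(length(X)), nrow(X))
  }
  channel_data(X, scene$sfreq, array$bad_channels)
}

# Gabor-like evoked waveform on the trial time axis (seconds).
evoked_waveform <- function(t, latency, width, f_carrier) {
  exp(-((t - latency)^2) / (2 * width^2)) *
    cos(2 * pi * f_carrier * (t - latency))
}

#' Render an evoked scene into time-locked trials
#'
#' @param scene an evoked `synthetic_scene`.
#' @param array a `sensor_array`.
#' @param components subset of
#'   `c("evoked", "background", "external", "noise")`.
#' @param leadfield optional unprojected `leadfield` for pattern reuse.
#' @return list: `trials` array [channels x time x trials], `sfreq`, `t0`,
#'   `times`.
#' @export
render_trials <- function(scene, array,
                          components = c("evoked", "background",
                                         "external", "noise"),
                          leadfield = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"), scene$kind == "evoked")
  set.seed(scene$seed)
  nt <- round(scene$trial_length * scene$sfreq)
  times <- scene$t0 + (seq_len(nt) - 1) / scene$sfreq
  n_tr <- scene$n_trials
  trials <- array(0, dim = c(array$n_channels, nt, n_tr))

  ev_pat <- lapply(scene$evoked_sources, internal_pattern, array = array)
  ev_wav <- lapply(scene$evoked_sources, function(src)
    src$amp * evoked_waveform(times, src$latency, src$width, src$f_carrier))
  bg_pat <- vapply(scene$internal_sources, internal_pattern,
                   numeric(array$n_channels), array = array,
                   leadfield = leadfield)
  ex_pat <- lapply(scene$external_sources, external_pattern, array = array)
  sd_chan <- ifelse(array$channel_table$type == "MAG",
                    scene$mag_noise, scene$grad_noise) *
    sqrt(scene$sfreq / 2)

  for (k in seq_len(n_tr)) {
    Xk <- matrix(0, array$n_channels, nt)
    if ("evoked" %in% components)
      for (j in seq_along(ev_pat))
        Xk <- Xk + outer(ev_pat[[j]], ev_wav[[j]])
    Wk <- t(vapply(scene$internal_sources, internal_waveform, numeric(nt),
                   n = nt, sfreq = scene$sfreq))
    if ("background" %in% components) Xk <- Xk + bg_pat %*% Wk
    for (j in seq_along(scene$external_sources)) {
      src <- scene$external_sources[[j]]
      drift <- drift_noise(nt, scene$sfreq)
      line <- sin(2 * pi * 50 * times + stats::runif(1, 0, 2 * pi))
      w <- src$amp * ((1 - src$line_mix) * drift +
                        src$line_mix * sqrt(2) * line)
      if ("external" %in% components && src$amp > 0)
        Xk <- Xk + outer(ex_pat[[j]], w)
    }
    nz <- sd_chan * matrix(stats::rnorm(array$n_channels * nt),
                           array$n_channels)
    if ("noise" %in% components) Xk <- Xk + nz
    trials[, , k] <- Xk
  }
  list(trials = trials, sfreq = scene$sfreq, t0 = scene$t0, times = times)
}
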