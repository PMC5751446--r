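#' Experiment configuration
#'
#' Collects every knob of the end-to-end experiments with the defaults
#' used throughout: SSS truncations L_in = 8 / L_out = 3 with
#' condition-limited internal-component pruning, a [2, 10] Hz FIR band of
#' order 1000, 6 s epochs, the canonical comparison pipelines
#' (mag 0.01 reference vs mag 0.02, mag 0.05, grad 0.29) and a log-spaced
#' lambda grid in [1e-4, 1].
#'
#' @param seed integer master seed.
#' @param n_subjects subjects in resting cohorts.
#' @param interference interference level for resting scenes.
#' @param duration resting recording length, seconds.
#' @param lambda_grid regularization grid (default 80 log-spaced points in
#'   [1e-4, 1]).
#' @param band analysis band (Hz) for source time-series comparisons.
#' @param fir_order FIR order for the band filter.
#' @param epoch_length epoch length, seconds.
#' @param sss_condition condition limit for SSS internal-component pruning.
#' @param lambda_map lambdas (mag, grad) for the whole-grid map.
#' @param pipelines list of comparison pipelines, each
#'   `list(sensors=, lambda=)`; the first is the reference.
#' @param n_trials evoked-scene trial count.
#' @param fast if TRUE, shrink to a quick profile (4 subjects, 30 s,
#'   20-point grid) for smoke runs.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, n_subjects = 8L,
                              interference = "high", duration = 120,
                              lambda_grid = 10^seq(-4, 0, length.out = 80),
                              band = c(2, 10), fir_order = 1000L,
                              epoch_length = 6, sss_condition = 100,
                              lambda_map = c(mag = 0.01, grad = 0.29),
                              pipelines = list(
                                list(sensors = "MAG", lambda = 0.01),
                                list(sensors = "MAG", lambda = 0.02),
                                list(sensors = "MAG", lambda = 0.05),
                                list(sensors = "GRAD", lambda = 0.29)),
                              n_trials = 64L, fast = FALSE) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              interference = interference, duration = duration,
              lambda_grid = lambda_grid, band = band,
              fir_order = as.integer(fir_order),
              epoch_length = epoch_length, sss_condition = sss_condition,
              lambda_map = lambda_map, pipelines = pipelines,
              n_trials = as.integer(n_trials))
  if (fast) {
    cfg$n_subjects <- 4L
    cfg$duration <- 30
    cfg$lambda_grid <- 10^seq(-4, 0, length.out = 20)
    cfg$n_trials <- 16L
  }
  class(cfg) <- "experiment_config"
  cfg
}

#' Build the shared geometry and operators of an experiment
#'
#' Constructs the sensor array, source space, SSS basis, leadfields and
#' their SSS-projected counterpart once, for reuse across experiment
#' drivers.
#'
#' @param config an `experiment_config`.
#' @return list: `array`, `space`, `basis`, `lf`, `lf_proj`.
#' @export
setup_experiment <- function(config = experiment_config()) {
  array <- build_array()
  space <- build_source_space()
  basis <- assemble_basis(array, origin = space$origin,
                          prune_condition = config$sss_condition)
  lf <- compute_leadfield(array, space)
  list(array = array, space = space, basis = basis, lf = lf,
       lf_proj = project_leadfield(lf, basis))
}

# Band-filter, trim edges and epoch one recording.
prep_filtered <- function(M, config) {
  Mf <- fir_bandpass(M, config$band[1], config$band[2],
                     order = config$fir_order, trim = TRUE)
  eps <- epoch_ranges(ncol(Mf$data), round(config$epoch_length * Mf$sfreq))
  list(M = Mf, epochs = eps)
}

# Oriented source series for a set of sources at each lambda of a grid.
# Returns list of [n_sources x samples] matrices, one per lambda, plus the
# cn per lambda.
series_over_lambdas <- function(Mf, lf_use, array, sensors, lambdas,
                                sources, epochs) {
  ch <- channel_indices(array, sensors)
  Mr <- channel_data(Mf$data[ch, , drop = FALSE], Mf$sfreq)
  cov0 <- estimate_covariance(Mr, epochs)
  out <- vector("list", length(lambdas))
  cns <- numeric(length(lambdas))
  for (j in seq_along(lambdas)) {
    cv <- regularize_invert(cov0, lambdas[j])
    cns[j] <- cv$cn
    filters <- lapply(sources, function(i)
      select_orientation(lcmv_filter(lf_use$L[ch, , i], cv), cv))
    out[[j]] <- extract_sources(filters, Mr)$s
  }
  list(series = out, cn = cns)
}

# Mean-over-epochs squared correlation between two source series matrices,
# per source.
epoch_r2 <- function(Sa, Sb, epochs) {
  vapply(seq_len(nrow(Sa)), function(i)
    mean(vapply(epochs, function(ep)
      pearson_r2(Sa[i, ep], Sb[i, ep]), numeric(1))), numeric(1))
}

#' Regularization-sweep equivalence experiment
#'
#' For each synthetic subject: render, optionally SSS-clean, bandpass,
#' then reconstruct the four probe sources with magnetometer-only and
#' gradiometer-only LCMV beamformers for every lambda pair of the grid,
#' and correlate the resulting source time series (per epoch, then
#' averaged). Also fits log10(lambda_grad_max) against log10(lambda_mag)
#' on the subject-mean surfaces and records the SSS noise ratio.
#'
#' @param config an `experiment_config`.
#' @param setup optional result of [setup_experiment()] to reuse.
#' @param sss apply SSS before beamforming (default TRUE).
#' @param lambda_mag,lambda_grad optional lambda sub-grids (default: the
#'   config grid for both).
#' @return list: `r2` [n_lambda_mag x n_lambda_grad x probes x subjects],
#'   `r2_mean` (over probes and subjects), `noise_ratio` per subject,
#'   `cn_mag`, `cn_grad` [lambdas x subjects], `grad_max` (per-subject
#'   argmax curves on probe-averaged surfaces), `fits` (per-subject
#'   log-log fits, when the grid allows), `lambda_mag`, `lambda_grad`.
#' @export
run_equivalence <- function(config = experiment_config(), setup = NULL,
                            sss = TRUE, lambda_mag = NULL,
                            lambda_grad = NULL) {
  if (is.null(setup)) setup <- setup_experiment(config)
  if (is.null(lambda_mag)) lambda_mag <- config$lambda_grid
  if (is.null(lambda_grad)) lambda_grad <- config$lambda_grid
  scenes <- make_resting_scene(config$seed, config$n_subjects,
                               config$interference,
                               duration = config$duration,
                               space = setup$space,
                               epoch_length = config$epoch_length)
  probes <- setup$space$probe_idx
  nm <- length(lambda_mag); ng <- length(lambda_grad)
  r2 <- array(NA_real_, c(nm, ng, length(probes), length(scenes)))
  nr <- numeric(length(scenes))
  cn_m <- matrix(NA_real_, nm, length(scenes))
  cn_g <- matrix(NA_real_, ng, length(scenes))

  for (s in seq_along(scenes)) {
    M <- render(scenes[[s]], setup$array, leadfield = setup$lf)
    cleaned <- sss_separate(M, setup$basis)$M_in_hat
    nr[s] <- noise_ratio(M, cleaned, channel_indices(setup$array, "MAG"))
    if (sss) {
      Muse <- cleaned
      lf_use <- setup$lf_proj
      rm(M)
    } else {
      Muse <- M
      lf_use <- setup$lf
    }
    rm(cleaned)
    gc(FALSE)
    pf <- prep_filtered(Muse, config)
    rm(Muse)
    gc(FALSE)
    sm <- series_over_lambdas(pf$M, lf_use, setup$array, "MAG",
                              lambda_mag, probes, pf$epochs)
    sg <- series_over_lambdas(pf$M, lf_use, setup$array, "GRAD",
                              lambda_grad, probes, pf$epochs)
    cn_m[, s] <- sm$cn
    cn_g[, s] <- sg$cn
    for (a in seq_len(nm)) for (b in seq_len(ng))
      r2[a, b, , s] <- epoch_r2(sm$series[[a]], sg$series[[b]], pf$epochs)
  }

  surf_mean <- apply(r2, c(1, 2), mean)    # over probes and subjects
  grad_max <- NULL; fits <- NULL
  if (ng > 1) {
    grad_max <- lapply(seq_along(scenes), function(s)
      lambda_grad_max(apply(r2[, , , s, drop = FALSE], c(1, 2), mean),
                      lambda_grad))
    fits <- lapply(grad_max, function(gm) {
      ok <- try(loglog_fit(gm$lambda_mag, gm$lambda_grad_max),
                silent = TRUE)
      if (inherits(ok, "try-error")) NULL else ok
    })
  }
  list(r2 = r2, r2_mean = surf_mean, noise_ratio = nr,
       cn_mag = cn_m, cn_grad = cn_g, grad_max = grad_max, fits = fits,
       lambda_mag = lambda_mag, lambda_grad = lambda_grad, sss = sss)
}

#' Whole-grid correlation map experiment
#'
#' Reconstructs every grid source from magnetometers (lambda_mag) and
#' gradiometers (lambda_grad) after SSS, correlates the source time series
#' per epoch, and averages the per-source r^2 map over subjects.
#'
#' @param config an `experiment_config`.
#' @param setup optional [setup_experiment()] result.
#' @param sss apply SSS (default TRUE).
#' @return list: `map` (subject-averaged r^2 per grid source), `maps`
#'   [sources x subjects], `summary` (min, quantiles, median), `lambda`.
#' @export
run_spatial_map <- function(config = experiment_config(), setup = NULL,
                            sss = TRUE) {
  if (is.null(setup)) setup <- setup_experiment(config)
  scenes <- make_resting_scene(config$seed, config$n_subjects,
                               config$interference,
                               duration = config$duration,
                               space = setup$space,
                               epoch_length = config$epoch_length)
  n_src <- dim(setup$lf$L)[3]
  if (n_src == 0) {
    warning("empty source grid")
    return(list(map = numeric(0), maps = NULL, summary = NULL,
                lambda = config$lambda_map))
  }
  maps <- matrix(NA_real_, n_src, length(scenes))
  for (s in seq_along(scenes)) {
    M <- render(scenes[[s]], setup$array, leadfield = setup$lf)
    if (sss) {
      cleaned <- sss_separate(M, setup$basis)$M_in_hat
      rm(M)
      M <- cleaned
      rm(cleaned)
      lf_use <- setup$lf_proj
    } else lf_use <- setup$lf
    gc(FALSE)
    pf <- prep_filtered(M, config)
    rm(M)
    gc(FALSE)
    sm <- series_over_lambdas(pf$M, lf_use, setup$array, "MAG",
                              config$lambda_map["mag"], seq_len(n_src),
                              pf$epochs)
    sg <- series_over_lambdas(pf$M, lf_use, setup$array, "GRAD",
                              config$lambda_map["grad"], seq_len(n_src),
                              pf$epochs)
    maps[, s] <- epoch_r2(sm$series[[1]], sg$series[[1]], pf$epochs)
    rm(sm, sg, pf)
    gc(FALSE)
  }
  map <- rowMeans(maps)
  list(map = map, maps = maps,
       summary = c(min = min(map),
                   q05 = unname(stats::quantile(map, 0.05)),
                   median = stats::median(map), max = max(map)),
       lambda = config$lambda_map)
}

#' Inter-pipeline reliability experiment
#'
#' For every subject and every configured pipeline (sensor set + lambda),
#' reconstructs all grid sources after SSS and computes relative band
#' power per region (and optionally PLV on a region subset). Reliability
#' of each comparison pipeline against the reference (the first pipeline)
#' is quantified with ICC(1,1) across (subject x region) targets per band
#' (across links for PLV).
#'
#' @param config an `experiment_config`.
#' @param setup optional [setup_experiment()] result.
#' @param bands band definitions (default [default_bands()]).
#' @param plv_regions indices of grid sources used for PLV (NULL disables
#'   PLV; keep small, cost grows quadratically).
#' @return list: `icc_power` (data.frame band x pipeline), `icc_plv` (or
#'   NULL), `power` (array [regions x bands x pipelines x subjects]),
#'   `pipeline_names`.
#' @export
run_reliability <- function(config = experiment_config(), setup = NULL,
                            bands = default_bands(), plv_regions = NULL) {
  if (is.null(setup)) setup <- setup_experiment(config)
  if (config$n_subjects < 2) stop("need >= 2 subjects for reliability")
  scenes <- make_resting_scene(config$seed, config$n_subjects,
                               config$interference,
                               duration = config$duration,
                               space = setup$space,
                               epoch_length = config$epoch_length)
  n_src <- dim(setup$lf$L)[3]
  npipe <- length(config$pipelines)
  pipe_names <- vapply(config$pipelines, function(p)
    sprintf("%s-lambda=%g", tolower(p$sensors), p$lambda), character(1))
  power <- array(NA_real_,
                 c(n_src, nrow(bands), npipe, length(scenes)))
  plv_store <- if (!is.null(plv_regions))
    array(NA_real_, c(length(plv_regions), length(plv_regions),
                      nrow(bands), npipe, length(scenes))) else NULL

  for (s in seq_along(scenes)) {
    M <- render(scenes[[s]], setup$array, leadfield = setup$lf)
    cleaned <- sss_separate(M, setup$basis)$M_in_hat
    ep_len <- round(config$epoch_length * cleaned$sfreq)
    for (p in seq_len(npipe)) {
      pl <- config$pipelines[[p]]
      bm <- beamform_sources(cleaned, setup$lf_proj, setup$array,
                             pl$sensors, pl$lambda,
                             epochs = epoch_ranges(ncol(cleaned$data),
                                                   ep_len))
      eps <- epoch_ranges(ncol(bm$sources$s), ep_len)
      power[, , p, s] <- relative_band_power(bm$sources, bands,
                                             epochs = eps)
      if (!is.null(plv_regions)) {
        sub <- structure(list(s = bm$sources$s[plv_regions, , drop = FALSE],
                              sfreq = bm$sources$sfreq),
                         class = "source_timeseries")
        for (b in seq_len(nrow(bands))) {
          ep_tr <- epoch_ranges(ncol(sub$s) - config$fir_order, ep_len)
          plv_store[, , b, p, s] <- plv(sub, bands$lo[b], bands$hi[b],
                                        epochs = ep_tr,
                                        order = config$fir_order)
        }
      }
    }
  }

  icc_power <- do.call(rbind, lapply(2:npipe, function(p) {
    data.frame(band = bands$name, pipeline = pipe_names[p],
               icc = vapply(seq_len(nrow(bands)), function(b) {
                 ref <- as.vector(power[, b, 1, ])
                 cmp <- as.vector(power[, b, p, ])
                 icc_1_1(cbind(ref, cmp))
               }, numeric(1)))
  }))
  icc_plv <- NULL
  if (!is.null(plv_regions)) {
    lower <- which(lower.tri(matrix(0, length(plv_regions),
                                    length(plv_regions))))
    icc_plv <- do.call(rbind, lapply(2:npipe, function(p) {
      data.frame(band = bands$name, pipeline = pipe_names[p],
                 icc = vapply(seq_len(nrow(bands)), function(b) {
                   ref <- as.vector(apply(plv_store[, , b, 1, ,
                                                    drop = FALSE],
                                          5, function(x) x[lower]))
                   cmp <- as.vector(apply(plv_store[, , b, p, ,
                                                    drop = FALSE],
                                          5, function(x) x[lower]))
                   icc_1_1(cbind(ref, cmp))
                 }, numeric(1)))
    }))
  }
  list(icc_power = icc_power, icc_plv = icc_plv, power = power,
       pipeline_names = pipe_names)
}

#' Evoked-field comparison experiment
#'
#' Renders the synthetic evoked scene, applies SSS, and compares (a) the
#' sensor-space representative evoked fields extracted separately from
#' magnetometers and gradiometers via the principal-component summary, and
#' (b) source activation maps (60-160 ms vs -100-0 ms baseline) derived
#' from magnetometer-only and gradiometer-only beamformers whose
#' covariance is estimated from the whole trial window.
#'
#' @param config an `experiment_config`.
#' @param setup optional [setup_experiment()] result.
#' @param vef_window time window (s) over which the two VEF component time
#'   courses are correlated.
#' @return list: `vef_r2`, `vef_mag`, `vef_grad` (component summaries),
#'   `activation_mag`, `activation_grad` (per-source power changes),
#'   `activation_cor` (spatial Pearson correlation of the two maps),
#'   `peak_mag`, `peak_grad` (grid indices of map maxima).
#' @export
run_vef <- function(config = experiment_config(), setup = NULL,
                    vef_window = c(-0.1, 0.5)) {
  if (is.null(setup)) setup <- setup_experiment(config)
  scene <- make_evoked_scene(config$seed, config$n_trials,
                             space = setup$space)
  rt <- render_trials(scene, setup$array, leadfield = setup$lf)
  dm <- dim(rt$trials)
  flat <- matrix(rt$trials, dm[1])
  flat_clean <- sss_clean_matrix(flat, setup$basis)
  trials_clean <- array(flat_clean, dm)

  magi <- channel_indices(setup$array, "MAG")
  gradi <- channel_indices(setup$array, "GRAD")
  vef_mag <- representative_vef(trials_clean[magi, , , drop = FALSE],
                                rt$sfreq, rt$t0)
  vef_grad <- representative_vef(trials_clean[gradi, , , drop = FALSE],
                                 rt$sfreq, rt$t0)
  win <- rt$times >= vef_window[1] & rt$times <= vef_window[2]
  vef_r2 <- pearson_r2(vef_mag$component[win], vef_grad$component[win])

  # beamformer activation maps; covariance over the full trial window
  n_src <- dim(setup$lf$L)[3]
  flat_cd <- channel_data(flat_clean, rt$sfreq)
  trial_eps <- epoch_ranges(ncol(flat_clean), dm[2])
  act <- list()
  for (ty in c("MAG", "GRAD")) {
    lam <- if (ty == "MAG") config$lambda_map["mag"] else
      config$lambda_map["grad"]
    bm <- beamform_sources(flat_cd, setup$lf_proj, setup$array, ty, lam,
                           epochs = trial_eps)
    s_tr <- array(bm$sources$s, c(n_src, dm[2], dm[3]))
    act[[ty]] <- activation_map(s_tr, rt$sfreq, rt$t0)
  }
  list(vef_r2 = vef_r2, vef_mag = vef_mag, vef_grad = vef_grad,
       activation_mag = act$MAG, activation_grad = act$GRAD,
       activation_cor = stats::cor(act$MAG, act$GRAD),
       peak_mag = which.max(act$MAG), peak_grad = which.max(act$GRAD))
}
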