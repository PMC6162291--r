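#' Specification of a synthetic calibration study
#'
#' Defines the ground-truth parameters, noise levels and experimental design
#' of a synthetic study shaped like the in vitro one: five seeding
#' densities measured daily for 7 days under Mitomycin-C; the same five
#' densities untreated at 10% FBS for 21 days; three densities at each of
#' four reduced-FBS levels for 7 days (the necrosis arm); and five FBS
#' levels of spatial field series every 30 minutes for 12 hours at a single
#' density (the mobility arm).
#'
#' Default truths sit centrally in the calibrated ranges reported for this
#' cell line: `lambda_apop = 0.09 / day`, `lambda_prol = 0.5 / day`,
#' `K = 0.14`, `lambda_VN` rising from `exp(-5.5)` at 7.5% FBS to
#' `exp(-2.2) / day` at 0% FBS, `epsilon_T = 30 um`, `M_T = 200 um/day`,
#' `E_bar_T = 0.65`. These are fixture choices for recovery experiments,
#' not measured claims. Measurement noise is additive Gaussian on the
#' volume-fraction scale with scenario-level standard deviation
#' `noise_frac` times the day-0 signal.
#'
#' @param master_seed Seed from which every scenario's seed derives.
#' @param densities Seeding densities (cells/ml) of the apoptosis and
#'   proliferation arms.
#' @param necrosis_densities Densities of the necrosis arm.
#' @param necrosis_fbs FBS percentages of the necrosis arm.
#' @param mobility_fbs FBS percentages of the mobility arm.
#' @param n_replicates Replicates per time-course scenario.
#' @param noise_frac Noise sd as a fraction of the day-0 viable fraction.
#' @param truth Named list overriding any default true parameter.
#' @param grid_n Mobility grid size (`grid_n x grid_n` pixels).
#' @param pixel_size Mobility pixel size (micrometers).
#' @param field_noise_sd Pixelwise observation noise of the field series.
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(master_seed = 20260101L,
                                 densities = c(5000, 10000, 25000, 50000,
                                               100000),
                                 necrosis_densities = c(25000, 50000,
                                                        100000),
                                 necrosis_fbs = c(0, 2.5, 5, 7.5),
                                 mobility_fbs = c(0, 2.5, 5, 7.5, 10),
                                 n_replicates = 4L,
                                 noise_frac = 0.05,
                                 truth = list(),
                                 grid_n = 32L,
                                 pixel_size = 1160 / 32,
                                 field_noise_sd = 0.01) {
  tr <- utils::modifyList(list(
    lambda_apop = 0.09,
    lambda_prol = 0.5,
    K = 0.14,
    lambda_VN = c(`0` = exp(-2.2), `2.5` = exp(-4.9), `5` = exp(-5.2),
                  `7.5` = exp(-5.5)),
    M_T = 200,
    E_bar_T = 0.65,
    epsilon_T = 30
  ), truth)
  structure(list(master_seed = as.integer(master_seed),
                 densities = densities,
                 necrosis_densities = necrosis_densities,
                 necrosis_fbs = necrosis_fbs,
                 mobility_fbs = mobility_fbs,
                 n_replicates = as.integer(n_replicates),
                 noise_frac = noise_frac, truth = tr,
                 grid_n = as.integer(grid_n), pixel_size = pixel_size,
                 field_noise_sd = field_noise_sd),
            class = "synthetic_study_spec")
}

#' Synthesize a noisy viability time course
#'
#' Simulates the deterministic trajectory of the chosen reduced model at the
#' scenario's measurement days and adds i.i.d. zero-mean Gaussian noise of
#' standard deviation `sigma_noise` to every replicate observation.
#' Negative draws are floored at 0 and flagged in the result's `floored`
#' attribute (a logical matrix), so likelihood-misspecification effects
#' remain traceable.
#'
#' @param model `"exponential"`, `"logistic"` or `"necrosis"`.
#' @param true_params A [reduced_params()] with the ground truth.
#' @param meta A [scenario_meta()]; defines days and nutrient fraction.
#' @param sigma_noise Noise standard deviation (volume-fraction scale).
#' @param n_replicates Number of replicates.
#' @param seed RNG seed.
#' @param dt Solver step for the deterministic trajectory.
#' @return A [timecourse_dataset()]; the deterministic trajectory is kept
#'   in attribute `truth_trajectory`.
#' @export
synth_timecourses <- function(model, true_params, meta, sigma_noise,
                              n_replicates = 4L, seed = 1L, dt = 0.01) {
  stopifnot(inherits(true_params, "reduced_params"),
            inherits(meta, "scenario_meta"))
  days <- seq(0, meta$duration, by = meta$sampling_interval)
  det <- switch(model,
    exponential = simulate_exponential_death(true_params, days, dt)$values,
    logistic = simulate_logistic_growth(true_params, days, dt)$values,
    necrosis = simulate_necrosis_system(true_params, days, dt)$values[, "phi_V"],
    stop("unknown model variant: ", model))
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(days) * n_replicates, 0, sigma_noise),
                  length(days), n_replicates)
  vals <- det + noise
  floored <- vals < 0
  vals[floored] <- 0
  ds <- timecourse_dataset(meta, days, vals)
  attr(ds, "truth_trajectory") <- det
  attr(ds, "floored") <- floored
  ds
}

#' Synthesize an initial clustered tumor field
#'
#' Builds a sum of radially symmetric bumps with tanh interface profiles —
#' clusters of viable tumor cells, the configuration the mobility
#' experiments start from. Cluster centers are drawn uniformly with a
#' margin keeping each cluster inside the domain; the field is clipped to
#' `[0, 1]` (flagged in attribute `clipped` when overlaps exceed 1).
#'
#' @param grid A [grid2d()].
#' @param n_clusters Number of clusters (0 gives the zero field).
#' @param cluster_radius Cluster radius in micrometers.
#' @param peak_fraction Plateau volume fraction of a cluster, in (0, 1].
#' @param interface_width Tanh interface width in micrometers.
#' @param seed RNG seed.
#' @return A [phase_field_state()] with `phi_N = 0`.
#' @export
synth_initial_field <- function(grid, n_clusters = 4L, cluster_radius = 120,
                                peak_fraction = 0.8, interface_width = 40,
                                seed = 1L) {
  stopifnot(inherits(grid, "grid2d"))
  if (peak_fraction <= 0 || peak_fraction > 1)
    stop("`peak_fraction` must lie in (0, 1]")
  h <- grid$spacing
  xs <- (seq_len(grid$nx) - 0.5) * h
  ys <- (seq_len(grid$ny) - 0.5) * h
  phi <- matrix(0, grid$ny, grid$nx)
  if (n_clusters > 0L) {
    margin <- cluster_radius + 2 * interface_width
    if (2 * margin >= min(grid$extent))
      stop("clusters do not fit in the domain")
    set.seed(seed)
    cx <- stats::runif(n_clusters, margin, grid$extent[1L] - margin)
    cy <- stats::runif(n_clusters, margin, grid$extent[2L] - margin)
    for (c in seq_len(n_clusters)) {
      r <- sqrt(outer(ys, xs, function(y, x)
        (x - cx[c])^2 + (y - cy[c])^2))
      phi <- phi + peak_fraction *
        0.5 * (1 - tanh((r - cluster_radius) / interface_width))
    }
  }
  clipped <- any(phi > 1)
  if (clipped) warning("overlapping clusters exceeded phi = 1; clipped")
  st <- phase_field_state(pmin(phi, 1), time = 0)
  attr(st, "clipped") <- clipped
  st
}

#' Synthesize a mobility field series
#'
#' Evolves the mobility-only Cahn-Hilliard model from an initial clustered
#' field and samples frames at the imaging cadence (default every 30
#' minutes for 12 hours, i.e. 25 frames), optionally adding pixelwise
#' Gaussian observation noise; frames are clamped to `[0, 1]`.
#'
#' @param params A [phase_field_params()] with the ground truth.
#' @param initial A [phase_field_state()].
#' @param grid A [grid2d()].
#' @param duration Duration in days (default 0.5 = 12 h).
#' @param interval Frame interval in days (default 1/48 = 30 min).
#' @param observation_noise_sd Pixelwise noise sd (0 for none).
#' @param seed RNG seed for the noise.
#' @param dt Solver step used to generate the series.
#' @return A [field_series()]; the noise-free frames are kept in attribute
#'   `truth_frames`.
#' @export
synth_field_series <- function(params, initial, grid, duration = 0.5,
                               interval = 1 / 48,
                               observation_noise_sd = 0, seed = 1L,
                               dt = 1 / 192) {
  times <- seq(0, duration, by = interval)
  traj <- simulate_mobility_ch(params, initial, times, grid, dt = dt)
  frames <- lapply(traj$values, `[[`, "phi_T")
  set.seed(seed)
  obs <- lapply(frames, function(f) {
    if (observation_noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, observation_noise_sd),
                      nrow(f), ncol(f))
    pmin(pmax(f, 0), 1)
  })
  fs <- field_series(times, obs, pixel_size = grid$spacing)
  attr(fs, "truth_frames") <- frames
  fs
}

#' Build the full synthetic study in memory
#'
#' Generates every scenario of a [synthetic_study_spec()] as a bundle
#' directly consumable by [run_sequential_study()]: `apoptosis` and
#' `proliferation` time courses named by density, `necrosis` time courses
#' named `fbs<percent>_d<density>`, `mobility` field series named by FBS
#' percent, plus the ground-truth manifest.
#'
#' @param spec A [synthetic_study_spec()].
#' @return A list with elements `apoptosis`, `proliferation`, `necrosis`,
#'   `mobility`, `truth` and `master_seed`.
#' @export
build_study_bundle <- function(spec = synthetic_study_spec()) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  tr <- spec$truth
  seed <- spec$master_seed
  nxt <- function() { seed <<- seed + 1L; seed }
  dkey <- function(x) format(x, scientific = FALSE, trim = TRUE)
  bundle <- list(apoptosis = list(), proliferation = list(),
                 necrosis = list(), mobility = list(),
                 truth = tr, master_seed = spec$master_seed)

  for (d in spec$densities) {
    phi0 <- seeding_density_to_volume_fraction(d)
    sig <- spec$noise_frac * phi0
    meta_a <- scenario_meta(paste0("apop_d", dkey(d)), d, 10, "MMC", 7)
    bundle$apoptosis[[dkey(d)]] <- synth_timecourses(
      "exponential",
      reduced_params(lambda_apop = tr$lambda_apop, phi_V0 = phi0),
      meta_a, sig, spec$n_replicates, seed = nxt())
    meta_p <- scenario_meta(paste0("prol_d", dkey(d)), d, 10, "none", 21)
    bundle$proliferation[[dkey(d)]] <- synth_timecourses(
      "logistic",
      reduced_params(lambda_prol = tr$lambda_prol,
                     lambda_apop = tr$lambda_apop, K = tr$K,
                     phi_sigma = 1, phi_V0 = phi0),
      meta_p, sig, spec$n_replicates, seed = nxt())
  }

  for (f in spec$necrosis_fbs) {
    lvn <- tr$lambda_VN[[as.character(f)]]
    if (is.null(lvn)) stop("no true lambda_VN for FBS level ", f)
    for (d in spec$necrosis_densities) {
      phi0 <- seeding_density_to_volume_fraction(d)
      sig <- spec$noise_frac * phi0
      meta_n <- scenario_meta(paste0("necr_fbs", dkey(f), "_d", dkey(d)), d, f,
                              "none", 7)
      bundle$necrosis[[paste0("fbs", dkey(f), "_d", dkey(d))]] <- synth_timecourses(
        "necrosis",
        reduced_params(lambda_prol = tr$lambda_prol,
                       lambda_apop = tr$lambda_apop,
                       lambda_VN = lvn, K = tr$K,
                       phi_sigma = f / 10, phi_V0 = phi0),
        meta_n, sig, spec$n_replicates, seed = nxt())
    }
  }

  if (length(spec$mobility_fbs)) {
    grid <- grid2d(spec$grid_n, spec$grid_n, spacing = spec$pixel_size)
    pf <- phase_field_params(tr$M_T, tr$E_bar_T, tr$epsilon_T)
    for (f in spec$mobility_fbs) {
      init <- synth_initial_field(grid, seed = nxt())
      bundle$mobility[[dkey(f)]] <- synth_field_series(
        pf, init, grid, observation_noise_sd = spec$field_noise_sd,
        seed = nxt())
    }
  }
  bundle
}

#' Write the full synthetic study to disk
#'
#' Materializes [build_study_bundle()] in the package's interchange
#' formats: one delimited time-course file per scenario, one multi-page
#' TIFF (plus YAML sidecar) per mobility scenario, and a `manifest.yaml`
#' recording the ground truth, the master seed and every file written.
#' Regeneration with the same spec is deterministic.
#'
#' @param spec A [synthetic_study_spec()].
#' @param dir Output directory (created if missing).
#' @return The manifest list, invisibly; side effect: files under `dir`.
#' @export
full_study_fixture <- function(spec = synthetic_study_spec(), dir) {
  bundle <- build_study_bundle(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(ds, stem) {
    p <- file.path(dir, paste0(stem, ".csv"))
    write_timecourse_csv(ds, p)
    files[[length(files) + 1L]] <<- basename(p)
  }
  for (nm in names(bundle$apoptosis))
    wr(bundle$apoptosis[[nm]], paste0("apoptosis_d", nm))
  for (nm in names(bundle$proliferation))
    wr(bundle$proliferation[[nm]], paste0("proliferation_d", nm))
  for (nm in names(bundle$necrosis))
    wr(bundle$necrosis[[nm]], paste0("necrosis_", nm))
  for (nm in names(bundle$mobility)) {
    p <- file.path(dir, paste0("mobility_fbs", nm, ".tif"))
    write_field_series(bundle$mobility[[nm]], p)
    files[[length(files) + 1L]] <- basename(p)
  }
  manifest <- list(
    master_seed = bundle$master_seed,
    truth = lapply(bundle$truth, function(v)
      if (length(v) > 1L) as.list(v) else v),
    design = list(densities = as.list(spec$densities),
                  necrosis_densities = as.list(spec$necrosis_densities),
                  necrosis_fbs = as.list(spec$necrosis_fbs),
                  mobility_fbs = as.list(spec$mobility_fbs),
                  n_replicates = spec$n_replicates,
                  noise_frac = spec$noise_frac),
    files = as.list(files))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Load a study fixture written by [full_study_fixture()]
#'
#' @param dir Directory containing `manifest.yaml` and the scenario files.
#' @return A bundle list shaped like [build_study_bundle()]'s output.
#' @export
load_study_bundle <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  bundle <- list(apoptosis = list(), proliferation = list(),
                 necrosis = list(), mobility = list(),
                 truth = manifest$truth,
                 master_seed = manifest$master_seed)
  for (f in unlist(manifest$files)) {
    path <- file.path(dir, f)
    if (grepl("^apoptosis_d", f)) {
      nm <- sub("\\.csv$", "", sub("^apoptosis_d", "", f))
      bundle$apoptosis[[nm]] <- read_timecourse_csv(path)
    } else if (grepl("^proliferation_d", f)) {
      nm <- sub("\\.csv$", "", sub("^proliferation_d", "", f))
      bundle$proliferation[[nm]] <- read_timecourse_csv(path)
    } else if (grepl("^necrosis_", f)) {
      nm <- sub("\\.csv$", "", sub("^necrosis_", "", f))
      bundle$necrosis[[nm]] <- read_timecourse_csv(path)
    } else if (grepl("^mobility_fbs", f)) {
      nm <- sub("\\.tif$", "", sub("^mobility_fbs", "", f))
      bundle$mobility[[nm]] <- read_field_series(path)
    }
  }
  bundle
}
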