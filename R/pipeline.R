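.stage_param_names <- list(
  exponential = c("lambda_apop", "phi_V0", "sigma"),
  logistic = c("lambda_prol", "K", "lambda_apop", "phi_V0", "sigma"),
  necrosis = c("lambda_VN", "lambda_apop", "phi_V0", "lambda_prol", "K",
               "sigma"),
  mobility = c("M_T", "sigma")
)

#' Default priors of each calibration stage
#'
#' Uniform priors for the parameters a stage introduces: rates
#' `U(0, 10) day^-1`, carrying capacity `U(0, 1)`, initial viable fraction
#' `U(1e-5, 1)`, noise `sigma ~ U(1e-5, 20)` for time-course stages and
#' `U(1e-5, 0.2)` for the mobility stage, mobility `M_T ~ U(0, 1000)`.
#' Parameters constrained upstream are substituted via
#' [posterior_to_prior()].
#'
#' @param model Stage model variant.
#' @return A [prior_spec()].
#' @export
default_stage_priors <- function(model = c("exponential", "logistic",
                                           "necrosis", "mobility")) {
  model <- match.arg(model)
  switch(model,
    exponential = prior_spec(
      prior_uniform("lambda_apop", 0, 10),
      prior_uniform("phi_V0", 1e-5, 1),
      prior_uniform("sigma", 1e-5, 20)),
    logistic = prior_spec(
      prior_uniform("lambda_prol", 0, 10),
      prior_uniform("K", 0, 1),
      prior_uniform("lambda_apop", 0, 10),
      prior_uniform("phi_V0", 1e-5, 1),
      prior_uniform("sigma", 1e-5, 20)),
    necrosis = prior_spec(
      prior_uniform("lambda_VN", 0, 10),
      prior_uniform("lambda_apop", 0, 10),
      prior_uniform("phi_V0", 1e-5, 1),
      prior_uniform("lambda_prol", 0, 10),
      prior_uniform("K", 0, 1),
      prior_uniform("sigma", 1e-5, 20)),
    mobility = prior_spec(
      prior_uniform("M_T", 0, 1000),
      prior_uniform("sigma", 1e-5, 0.2)))
}

#' Specification of one calibration stage
#'
#' Bundles everything [run_stage()] needs: the model variant, the data, the
#' priors (configured or propagated from an upstream stage), fixed
#' parameters, and sampler/predictive settings.
#'
#' @param name Stage label (`"apoptosis"`, `"proliferation"`, `"necrosis"`,
#'   `"mobility"`, or any identifier).
#' @param model Forward model variant: `"exponential"`, `"logistic"`,
#'   `"necrosis"` or `"mobility"`.
#' @param data A [timecourse_dataset()] (time-course variants) or a
#'   [field_series()] (mobility).
#' @param priors A [prior_spec()] covering the variant's calibrated
#'   parameters; defaults to [default_stage_priors()].
#' @param fixed Named list of fixed parameter values (mobility: `E_bar_T`,
#'   `epsilon_T`; time-course variants may fix e.g. `phi_N0`).
#' @param phi_sigma Nutrient fraction; defaults to the dataset's metadata.
#' @param sampler Sampler config passed to [run_mcmc()].
#' @param n_predictive Predictive ensemble size (the study default of
#'   200,000 is configured down for test-scale runs).
#' @param dt ODE solver step (days).
#' @param dt_pde Phase-field solver step (days, mobility stage).
#' @param prior_source Optional provenance note (e.g. the upstream stage
#'   name).
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(name, model, data, priors = default_stage_priors(model),
                       fixed = list(), phi_sigma = NULL,
                       sampler = list(n_iter = 3000L, burn_in = 1500L,
                                      seed = 1L),
                       n_predictive = 2000L, dt = 0.05, dt_pde = 1 / 96,
                       prior_source = "configured") {
  model <- match.arg(model, names(.stage_param_names))
  need <- setdiff(.stage_param_names[[model]],
                  c(names(fixed), if (model == "mobility") NULL))
  miss <- setdiff(need, names(priors))
  if (length(miss))
    stop("priors missing for parameter(s): ", paste(miss, collapse = ", "))
  if (model == "mobility") {
    stopifnot(inherits(data, "field_series"))
    for (nm in c("E_bar_T", "epsilon_T"))
      if (!nm %in% names(fixed) && !nm %in% names(priors))
        stop("mobility stage needs `", nm, "` fixed or given a prior")
  } else {
    stopifnot(inherits(data, "timecourse_dataset"))
    if (is.null(phi_sigma)) phi_sigma <- data$meta$nutrient_fraction
  }
  structure(list(name = name, model = model, data = data, priors = priors,
                 fixed = fixed, phi_sigma = phi_sigma, sampler = sampler,
                 n_predictive = n_predictive, dt = dt, dt_pde = dt_pde,
                 prior_source = prior_source),
            class = "stage_spec")
}

# log-posterior closure for a stage; proposals outside the prior support
# short-circuit before any forward solve
.stage_log_posterior <- function(spec) {
  priors <- spec$priors
  pnames <- names(priors)
  if (spec$model == "mobility") {
    grid <- grid2d(ncol(spec$data$grids[[1L]]), nrow(spec$data$grids[[1L]]),
                   spacing = spec$data$pixel_size)
    initial <- phase_field_state(spec$data$grids[[1L]])
    function(theta) {
      lp <- log_prior(theta, priors)
      if (!is.finite(lp)) return(-Inf)
      E_bar <- spec$fixed$E_bar_T %||% theta[["E_bar_T"]]
      eps <- spec$fixed$epsilon_T %||% theta[["epsilon_T"]]
      traj <- tryCatch(
        simulate_mobility_ch(
          phase_field_params(theta[["M_T"]], E_bar, eps),
          initial, spec$data$times, grid, dt = spec$dt_pde),
        error = function(e) NULL)
      if (is.null(traj)) return(-Inf)
      lp + log_likelihood_pcc(spec$data, traj, theta[["sigma"]])
    }
  } else {
    data <- spec$data
    function(theta) {
      lp <- log_prior(theta, priors)
      if (!is.finite(lp)) return(-Inf)
      d <- ensemble_trajectories(
        spec$model, matrix(theta, 1L, dimnames = list(NULL, pnames)),
        data$times, phi_sigma = spec$phi_sigma, dt = spec$dt,
        defaults = spec$fixed)[1L, ]
      lp + log_likelihood_timecourse(data, d, theta[["sigma"]])
    }
  }
}

#' Run one calibration stage
#'
#' Builds the stage's log posterior (forward model + likelihood + priors),
#' samples it with [run_mcmc()], and — for time-course stages — computes the
#' posterior-predictive band at the data days and the per-day/average
#' L1-CDF calibration errors.
#'
#' @param spec A [stage_spec()].
#' @return An object of class `calibration_result` with elements
#'   `posterior`, `band`, `errors`, plus the stage name, model and spec.
#' @export
run_stage <- function(spec) {
  stopifnot(inherits(spec, "stage_spec"))
  post <- run_mcmc(.stage_log_posterior(spec), spec$priors, spec$sampler)
  band <- NULL; errors <- NULL
  if (spec$model != "mobility") {
    sim <- function(draws) ensemble_trajectories(
      spec$model, draws, spec$data$times, phi_sigma = spec$phi_sigma,
      dt = spec$dt, defaults = spec$fixed)
    band <- posterior_predictive(post, sim, spec$data$times,
                                 n_draws = spec$n_predictive,
                                 seed = (spec$sampler$seed %||% 1L) + 1L,
                                 vectorized = TRUE)
    errors <- timecourse_calibration_error(band$samples, spec$data)
  }
  structure(list(name = spec$name, model = spec$model, posterior = post,
                 band = band, errors = errors, spec = spec),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> stage '%s' (%s model)\n",
              x$name, x$model))
  print(x$posterior)
  if (!is.null(x$errors))
    cat(sprintf("  calibration error: %.2f%% (per day: %s)\n",
                x$errors$average,
                paste(sprintf("%.1f", x$errors$per_day), collapse = ", ")))
  invisible(x)
}

#' Run the sequential calibration study
#'
#' Reproduces the four-stage design on a study data bundle (as produced by
#' [full_study_fixture()] or [build_study_bundle()]): per seeding density,
#' the apoptosis stage (Mitomycin-C data, exponential model) is calibrated
#' first; its posteriors for `lambda_apop` and `phi_V0` become priors of the
#' proliferation stage (untreated 10% FBS data, logistic model); the
#' proliferation posteriors for `phi_V0, lambda_apop, lambda_prol, K` become
#' priors of each necrosis stage (one per FBS level at that density); the
#' mobility stages (one per FBS level) are calibrated from the spatial field
#' series with the Pearson-correlation likelihood. Prior provenance is
#' recorded per stage, and a missing upstream stage raises a dependency
#' error.
#'
#' @param bundle Study bundle: a list with elements `apoptosis`,
#'   `proliferation` (named by density), `necrosis` (named
#'   `fbs<percent>_d<density>`), `mobility` (named by FBS percent).
#' @param densities,fbs_levels Subsets to run (defaults: everything in the
#'   bundle).
#' @param stages Which stage types to run, in order.
#' @param sampler,n_predictive,dt,dt_pde See [stage_spec()].
#' @param mobility_fixed Named list with `E_bar_T`, `epsilon_T` held fixed
#'   during mobility calibration.
#' @return An object of class `study_result`: per-stage
#'   `calibration_result`s keyed by stage id, a provenance table, and the
#'   `lambda_apop` prior-to-posterior [distribution_shift()] per density.
#' @export
run_sequential_study <- function(bundle,
                                 densities = names(bundle$apoptosis),
                                 fbs_levels = NULL,
                                 stages = c("apoptosis", "proliferation",
                                            "necrosis", "mobility"),
                                 sampler = list(n_iter = 3000L,
                                                burn_in = 1500L, seed = 1L),
                                 n_predictive = 2000L, dt = 0.05,
                                 dt_pde = 1 / 96,
                                 mobility_fixed = list(E_bar_T = 0.65,
                                                       epsilon_T = 30)) {
  results <- list()
  provenance <- list()
  shifts <- list()
  seed0 <- sampler$seed %||% 1L
  stage_seed <- function(k) { s <- sampler; s$seed <- seed0 + k; s }
  k <- 0L

  if ("apoptosis" %in% stages) {
    for (d in densities) {
      ds <- bundle$apoptosis[[d]]
      if (is.null(ds)) stop("no apoptosis dataset for density ", d)
      k <- k + 1L
      key <- paste0("apoptosis_", d)
      results[[key]] <- run_stage(stage_spec(
        key, "exponential", ds, sampler = stage_seed(k),
        n_predictive = n_predictive, dt = dt))
      provenance[[key]] <- "configured"
    }
  }

  if ("proliferation" %in% stages) {
    for (d in densities) {
      ds <- bundle$proliferation[[d]]
      if (is.null(ds)) stop("no proliferation dataset for density ", d)
      upstream <- results[[paste0("apoptosis_", d)]]
      if (is.null(upstream))
        stop("dependency error: proliferation stage for density ", d,
             " requires the apoptosis stage posterior")
      priors <- posterior_to_prior(
        upstream$posterior,
        default_stage_priors("logistic"),
        stage = paste0("apoptosis_", d))
      # sigma is a fresh hyperparameter per scenario
      priors[["sigma"]] <- prior_uniform("sigma", 1e-5, 20)
      k <- k + 1L
      key <- paste0("proliferation_", d)
      results[[key]] <- run_stage(stage_spec(
        key, "logistic", ds, priors = priors, phi_sigma = 1,
        sampler = stage_seed(k), n_predictive = n_predictive, dt = dt,
        prior_source = paste0("apoptosis_", d)))
      provenance[[key]] <- c(lambda_apop = paste0("apoptosis_", d),
                             phi_V0 = paste0("apoptosis_", d))
      set.seed(seed0 + 10000L + k)
      prior_draws <- .prior_draw(priors[["lambda_apop"]], 20000L)
      shifts[[d]] <- distribution_shift(
        prior_draws, results[[key]]$posterior$draws[, "lambda_apop"])
    }
  }

  if ("necrosis" %in% stages) {
    nec_keys <- names(bundle$necrosis)
    if (!is.null(fbs_levels)) {
      pat <- paste0("^fbs(", paste(fbs_levels, collapse = "|"), ")_")
      nec_keys <- grep(pat, nec_keys, value = TRUE)
    }
    nec_keys <- nec_keys[sub("^.*_d", "", nec_keys) %in% densities]
    for (nk in nec_keys) {
      ds <- bundle$necrosis[[nk]]
      d <- sub("^.*_d", "", nk)
      upstream <- results[[paste0("proliferation_", d)]]
      if (is.null(upstream))
        stop("dependency error: necrosis stage ", nk,
             " requires the proliferation stage posterior for density ", d)
      priors <- posterior_to_prior(
        upstream$posterior, default_stage_priors("necrosis"),
        stage = paste0("proliferation_", d))
      priors[["sigma"]] <- prior_uniform("sigma", 1e-5, 20)
      k <- k + 1L
      key <- paste0("necrosis_", nk)
      results[[key]] <- run_stage(stage_spec(
        key, "necrosis", ds, priors = priors,
        sampler = stage_seed(k), n_predictive = n_predictive, dt = dt,
        prior_source = paste0("proliferation_", d)))
      provenance[[key]] <- c(lambda_apop = paste0("proliferation_", d),
                             phi_V0 = paste0("proliferation_", d),
                             lambda_prol = paste0("proliferation_", d),
                             K = paste0("proliferation_", d))
    }
  }

  if ("mobility" %in% stages && length(bundle$mobility)) {
    mob_keys <- names(bundle$mobility)
    if (!is.null(fbs_levels))
      mob_keys <- intersect(mob_keys, as.character(fbs_levels))
    for (mk in mob_keys) {
      k <- k + 1L
      key <- paste0("mobility_fbs", mk)
      results[[key]] <- run_stage(stage_spec(
        key, "mobility", bundle$mobility[[mk]],
        fixed = mobility_fixed, sampler = stage_seed(k),
        dt_pde = dt_pde))
      provenance[[key]] <- "configured"
    }
  }

  structure(list(stages = results, provenance = provenance,
                 lambda_apop_shift = shifts,
                 config = list(sampler = sampler,
                               n_predictive = n_predictive,
                               dt = dt, dt_pde = dt_pde)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d stages\n", length(x$stages)))
  for (key in names(x$stages)) {
    r <- x$stages[[key]]
    err <- if (!is.null(r$errors)) sprintf(" error %.2f%%", r$errors$average)
           else ""
    cat(sprintf("  %s (%s)%s\n", key, r$model, err))
  }
  if (length(x$lambda_apop_shift))
    cat("  lambda_apop prior->posterior shift (%):",
        paste(sprintf("%s=%.2f", names(x$lambda_apop_shift),
                      unlist(x$lambda_apop_shift)), collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-replicate-out cross-validation of a time-course stage
#'
#' For each replicate: calibrate the stage on the remaining replicates,
#' simulate the predictive ensemble with the held-out replicate's first
#' measurement as the initial condition, and score the prediction against
#' the held-out time course with the L1-CDF metric (percent, averaged over
#' days).
#'
#' @param spec A [stage_spec()] for a time-course model; its dataset must
#'   have at least 2 replicates.
#' @return List with `per_fold` (each fold's per-day and average errors)
#'   and `average` (mean across folds, percent).
#' @export
cross_validate <- function(spec) {
  stopifnot(inherits(spec, "stage_spec"), spec$model != "mobility")
  data <- spec$data
  if (data$n_replicates < 2L) stop("cross-validation needs N_r >= 2")
  folds <- vector("list", data$n_replicates)
  for (r in seq_len(data$n_replicates)) {
    train <- timecourse_dataset(data$meta, data$times,
                                data$values[, -r, drop = FALSE])
    sub <- spec
    sub$data <- train
    sub$sampler$seed <- (spec$sampler$seed %||% 1L) + r
    fit <- run_mcmc(.stage_log_posterior(sub), sub$priors, sub$sampler)
    # predictive ensemble anchored at the held-out initial measurement
    set.seed(sub$sampler$seed + 500L)
    nd <- min(spec$n_predictive, .Machine$integer.max)
    idx <- sample.int(nrow(fit$draws), nd, replace = nd > nrow(fit$draws))
    draws <- fit$draws[idx, , drop = FALSE]
    draws[, "phi_V0"] <- data$values[1L, r]
    sims <- ensemble_trajectories(spec$model, draws, data$times,
                                  phi_sigma = spec$phi_sigma, dt = spec$dt,
                                  defaults = spec$fixed)
    held <- timecourse_dataset(data$meta, data$times,
                               data$values[, r, drop = FALSE])
    folds[[r]] <- timecourse_calibration_error(sims, held)
  }
  list(per_fold = folds,
       average = mean(vapply(folds, `[[`, 0, "average")))
}
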