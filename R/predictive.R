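#' Posterior-predictive trajectory band
#'
#' Resamples parameter vectors from a posterior (with replacement when
#' `n_draws` exceeds the retained chain length), runs the forward simulator
#' for each, and summarizes the trajectories pointwise by their mean and
#' 2.5/97.5 percentile (equal-tail 95%) band.
#'
#' @param posterior A `posterior_sample` from [run_mcmc()].
#' @param simulator Function mapping a named parameter vector to a numeric
#'   trajectory over `times`. If `vectorized = TRUE` it instead receives the
#'   whole draw matrix and must return an `n_draws x length(times)` matrix.
#' @param times Output times.
#' @param n_draws Ensemble size (the study default of 200,000 is configured
#'   down in test settings).
#' @param seed RNG seed for the resampling step.
#' @param vectorized Whether `simulator` handles a matrix of draws at once.
#' @param max_failures Abort when more than this fraction of draws yields a
#'   non-finite trajectory.
#' @return An object of class `predictive_band` with `times`, `mean`,
#'   `lower`, `upper`, `n_draws`, and the simulated `samples` matrix.
#' @export
posterior_predictive <- function(posterior, simulator, times,
                                 n_draws = 200000L, seed = 1L,
                                 vectorized = FALSE,
                                 max_failures = 0.001) {
  stopifnot(inherits(posterior, "posterior_sample"))
  set.seed(seed)
  nd <- nrow(posterior$draws)
  idx <- if (n_draws <= nd) sample.int(nd, n_draws)
         else sample.int(nd, n_draws, replace = TRUE)
  draws <- posterior$draws[idx, , drop = FALSE]
  if (vectorized) {
    sims <- simulator(draws)
    if (!is.matrix(sims) || nrow(sims) != n_draws ||
        ncol(sims) != length(times))
      stop("vectorized simulator must return an n_draws x n_times matrix")
  } else {
    sims <- matrix(NA_real_, n_draws, length(times))
    for (i in seq_len(n_draws)) {
      v <- tryCatch(simulator(draws[i, ]), error = function(e) NULL)
      if (!is.null(v) && length(v) == length(times)) sims[i, ] <- v
    }
  }
  bad <- !stats::complete.cases(sims)
  if (mean(bad) > max_failures)
    stop(sprintf("simulator failed on %.2f%% of draws (limit %.2f%%)",
                 100 * mean(bad), 100 * max_failures))
  sims <- sims[!bad, , drop = FALSE]
  qs <- apply(sims, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  structure(list(times = times,
                 mean = colMeans(sims),
                 lower = qs[1L, ], upper = qs[2L, ],
                 n_draws = nrow(sims),
                 samples = sims),
            class = "predictive_band")
}

#' @export
print.predictive_band <- function(x, ...) {
  cat(sprintf("<predictive_band> %d draws over %d times\n",
              x$n_draws, length(x$times)))
  df <- data.frame(time = x$times, mean = x$mean,
                   lower = x$lower, upper = x$upper)
  print(utils::head(signif(df, 4L), 10L))
  if (length(x$times) > 10L) cat("  ...\n")
  invisible(x)
}

#' Vectorized ensemble trajectories of the reduced models
#'
#' Integrates one of the reduced models for a whole matrix of parameter
#' draws at once (RK4 on an ensemble state vector), returning the viable
#' fraction at each requested time. Columns of `draws` are matched by name:
#' `lambda_apop`, `phi_V0`, and for the richer variants `lambda_prol`, `K`,
#' `lambda_VN`, `phi_N0`. Missing columns fall back to `defaults`.
#'
#' @param model `"exponential"`, `"logistic"` or `"necrosis"`.
#' @param draws Matrix of parameter draws with named columns.
#' @param times Output times (days).
#' @param phi_sigma Nutrient fraction (scenario constant).
#' @param dt RK4 step (days).
#' @param defaults Named list of fallback parameter values.
#' @return Matrix `nrow(draws) x length(times)` of viable fractions.
#' @export
ensemble_trajectories <- function(model, draws, times, phi_sigma = 1,
                                  dt = 0.01, defaults = list()) {
  getp <- function(nm, fallback = 0) {
    if (nm %in% colnames(draws)) draws[, nm]
    else rep(defaults[[nm]] %||% fallback, nrow(draws))
  }
  la <- getp("lambda_apop")
  phi0 <- getp("phi_V0")
  out <- switch(model,
    exponential = {
      st <- rk4_integrate(function(t, y) -la * y, phi0, times, dt)$states
      do.call(cbind, st)
    },
    logistic = {
      lp <- getp("lambda_prol") * phi_sigma
      K <- getp("K", 1)
      st <- rk4_integrate(function(t, y) lp * y * (1 - y / K) - la * y,
                          phi0, times, dt)$states
      do.call(cbind, st)
    },
    necrosis = {
      lp <- getp("lambda_prol") * phi_sigma
      K <- getp("K", 1)
      lv <- getp("lambda_VN")
      n <- nrow(draws)
      y0 <- cbind(phi0 + getp("phi_N0"), getp("phi_N0"))
      st <- rk4_integrate(function(t, y) {
        v <- y[, 1L] - y[, 2L]
        cbind(lp * v * (1 - y[, 1L] / K) - la * v, lv * v)
      }, y0, times, dt)$states
      vapply(st, function(y) y[, 1L] - y[, 2L], numeric(n))
    },
    stop("unknown model variant: ", model))
  matrix(out, nrow = nrow(draws))
}
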