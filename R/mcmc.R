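#' Adaptive random-walk Metropolis sampling
#'
#' Samples a posterior defined by a log-density callable using a Gaussian
#' random-walk proposal with a diagonal covariance. During burn-in the
#' proposal is adapted: the global scale is tuned toward a 20-40% acceptance
#' window, and the per-parameter scales are periodically reset to the
#' trailing chain window's standard deviations (scaled by `2.38 / sqrt(p)`).
#' After burn-in the proposal is frozen, so the retained draws target the
#' exact posterior. The chain starts from the best of `n_init` prior draws
#' (wide uniform priors put most of their mass where the likelihood is
#' flat, so a purely random start can mix arbitrarily slowly).
#'
#' @param log_posterior Function mapping a named parameter vector to a
#'   scalar log posterior density (may be `-Inf`).
#' @param priors A [prior_spec()]; defines parameter names, order, supports,
#'   initial proposal scales, and the initialization distribution.
#' @param config List of sampler settings: `n_iter` (post-burn-in
#'   iterations), `burn_in`, `thin`, `seed`, `adapt_interval`, `n_init`
#'   (prior draws scanned for the start point, default 200), and optional
#'   `init` (named start vector, overriding the scan).
#' @return An object of class `posterior_sample` with elements `draws`
#'   (matrix, parameter-named columns), `log_post`, `diagnostics`
#'   (acceptance rate, crude effective sample sizes), `seed` and `config`.
#' @export
run_mcmc <- function(log_posterior, priors,
                     config = list(n_iter = 5000L, burn_in = 2000L,
                                   thin = 1L, seed = 1L)) {
  stopifnot(inherits(priors, "prior_spec"))
  n_iter <- as.integer(config$n_iter %||% 5000L)
  burn_in <- as.integer(config$burn_in %||% 2000L)
  thin <- as.integer(config$thin %||% 1L)
  seed <- as.integer(config$seed %||% 1L)
  adapt_interval <- as.integer(config$adapt_interval %||% 50L)
  p <- length(priors)
  pnames <- names(priors)
  set.seed(seed)

  # initialization: the best of `n_init` prior draws (wide uniform priors
  # put most mass in regions where the likelihood is flat, so a random
  # start mixes very slowly)
  theta <- config$init
  if (is.null(theta)) {
    n_init <- as.integer(config$n_init %||% 200L)
    best <- -Inf; tries <- 0L
    while (tries < 1000L) {
      cand <- drop(sample_prior(priors, 1L))
      names(cand) <- pnames
      lpc <- log_posterior(cand)
      tries <- tries + 1L
      if (is.finite(lpc) && lpc > best) { best <- lpc; theta <- cand }
      if (tries >= n_init && is.finite(best)) break
    }
    if (!is.finite(best))
      stop("unidentifiable setup: log posterior is -Inf over 1,000 prior draws")
  } else {
    theta <- theta[pnames]
  }
  lp <- log_posterior(theta)

  prop_sd <- vapply(priors, .prior_scale, 0)
  global <- 1
  total <- burn_in + n_iter * thin
  keep <- floor(n_iter)
  draws <- matrix(NA_real_, keep, p, dimnames = list(NULL, pnames))
  lps <- numeric(keep)
  acc_window <- 0L; acc_post <- 0L; n_post <- 0L
  cov_interval <- max(200L, burn_in %/% 10L)
  win <- matrix(NA_real_, cov_interval, p)
  win_i <- 0L
  ki <- 0L

  for (it in seq_len(total)) {
    prop <- theta + stats::rnorm(p) * prop_sd * global
    names(prop) <- pnames
    lp_prop <- log_posterior(prop)
    if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      acc_window <- acc_window + 1L
      if (it > burn_in) acc_post <- acc_post + 1L
    }
    if (it <= burn_in) {
      win_i <- win_i + 1L
      win[win_i, ] <- theta
      if (it %% adapt_interval == 0L) {
        rate <- acc_window / adapt_interval
        if (rate < 0.2) global <- global * 0.8
        else if (rate > 0.4) global <- global * 1.25
        acc_window <- 0L
      }
      # periodic diagonal-covariance rescale from the trailing window
      if (win_i == cov_interval) {
        sds <- apply(win, 2L, stats::sd)
        ok <- is.finite(sds) & sds > 0
        if (any(ok)) {
          prop_sd[ok] <- sds[ok] * 2.38 / sqrt(p)
          global <- 1
        }
        win_i <- 0L
      }
    } else {
      n_post <- n_post + 1L
      if ((it - burn_in) %% thin == 0L && ki < keep) {
        ki <- ki + 1L
        draws[ki, ] <- theta
        lps[ki] <- lp
      }
    }
  }

  structure(list(
    draws = draws[seq_len(ki), , drop = FALSE],
    log_post = lps[seq_len(ki)],
    diagnostics = list(
      acceptance_rate = if (n_post > 0L) acc_post / n_post else NA_real_,
      ess = apply(draws[seq_len(ki), , drop = FALSE], 2L, .crude_ess),
      proposal_sd = prop_sd * global
    ),
    seed = seed,
    config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                  adapt_interval = adapt_interval)
  ), class = "posterior_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# effective sample size from the autocorrelation sum truncated at the first
# non-positive lag (crude but adequate as a mixing diagnostic)
.crude_ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n %/% 3L, 500L), plot = FALSE)$acf[-1L]
  cut <- which(rho <= 0)[1L]
  if (!is.na(cut)) rho <- rho[seq_len(cut - 1L)]
  n / (1 + 2 * sum(rho))
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("<posterior_sample> %d draws x %d parameters (seed %d)\n",
              nrow(x$draws), ncol(x$draws), x$seed))
  cat(sprintf("  acceptance %.2f; ESS: %s\n",
              x$diagnostics$acceptance_rate,
              paste(sprintf("%s=%.0f", colnames(x$draws),
                            x$diagnostics$ess), collapse = ", ")))
  summ <- rbind(mean = colMeans(x$draws), sd = apply(x$draws, 2L, stats::sd))
  print(signif(summ, 4L))
  invisible(x)
}

#' Write and read posterior samples as delimited text
#'
#' One column per parameter; seed, diagnostics and sampler settings go in a
#' YAML sidecar (`<path>.yaml`).
#'
#' @param posterior A `posterior_sample`.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_posterior_csv()` returns a
#'   `posterior_sample`.
#' @export
write_posterior_csv <- function(posterior, path) {
  stopifnot(inherits(posterior, "posterior_sample"))
  df <- as.data.frame(posterior$draws)
  df$log_post <- posterior$log_post
  utils::write.csv(format(df, digits = 17L), path, row.names = FALSE,
                   quote = FALSE)
  yaml::write_yaml(list(seed = posterior$seed,
                        config = posterior$config,
                        acceptance_rate =
                          posterior$diagnostics$acceptance_rate,
                        ess = as.list(posterior$diagnostics$ess)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
read_posterior_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- if (file.exists(paste0(path, ".yaml")))
    yaml::read_yaml(paste0(path, ".yaml")) else list()
  lp <- df$log_post
  df$log_post <- NULL
  draws <- as.matrix(df)
  structure(list(draws = draws, log_post = lp,
                 diagnostics = list(
                   acceptance_rate = meta$acceptance_rate %||% NA_real_,
                   ess = unlist(meta$ess %||% list())),
                 seed = meta$seed %||% NA_integer_,
                 config = meta$config %||% list()),
            class = "posterior_sample")
}
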