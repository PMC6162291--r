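#' Prior specifications
#'
#' A `prior_spec` is an ordered, named collection of per-parameter marginal
#' priors. Supported families: uniform, (truncated) normal, (truncated)
#' lognormal, and empirical (kernel density fitted to a retained sample).
#' Calibration chains propagate information by replacing entries with
#' distributions fitted to upstream posterior draws
#' (see [posterior_to_prior()]).
#'
#' @param ... Prior entries created by [prior_uniform()], [prior_normal()],
#'   [prior_lognormal()] or [prior_empirical()].
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) &&
      !inherits(entries[[1L]], "prior_entry"))
    entries <- entries[[1L]]
  for (e in entries)
    if (!inherits(e, "prior_entry")) stop("all entries must be prior entries")
  names(entries) <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(names(entries))) stop("duplicate parameter names")
  structure(entries, class = "prior_spec")
}

#' @rdname prior_spec
#' @param name Parameter name.
#' @param min,max Finite bounds of the uniform support.
#' @export
prior_uniform <- function(name, min, max) {
  if (!is.finite(min) || !is.finite(max) || min >= max)
    stop("uniform prior needs finite bounds with min < max")
  structure(list(name = name, family = "uniform", min = min, max = max,
                 lower = min, upper = max),
            class = "prior_entry")
}

#' @rdname prior_spec
#' @param mean,sd Location and scale (sd > 0).
#' @param lower,upper Optional truncation bounds.
#' @export
prior_normal <- function(name, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) stop("normal prior needs sd > 0")
  if (lower >= upper) stop("need lower < upper")
  structure(list(name = name, family = "normal", mean = mean, sd = sd,
                 lower = lower, upper = upper,
                 lognorm = log(stats::pnorm(upper, mean, sd) -
                                 stats::pnorm(lower, mean, sd))),
            class = "prior_entry")
}

#' @rdname prior_spec
#' @param meanlog,sdlog Log-scale location and scale (sdlog > 0).
#' @export
prior_lognormal <- function(name, meanlog, sdlog, lower = 0, upper = Inf) {
  if (sdlog <= 0) stop("lognormal prior needs sdlog > 0")
  if (lower < 0 || lower >= upper) stop("need 0 <= lower < upper")
  structure(list(name = name, family = "lognormal", meanlog = meanlog,
                 sdlog = sdlog, lower = lower, upper = upper,
                 lognorm = log(stats::plnorm(upper, meanlog, sdlog) -
                                 stats::plnorm(lower, meanlog, sdlog))),
            class = "prior_entry")
}

#' @rdname prior_spec
#' @param samples Sample the kernel density is fitted from (retained in the
#'   entry).
#' @export
prior_empirical <- function(name, samples, lower = -Inf, upper = Inf) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L) stop("empirical prior needs >= 10 samples")
  d <- stats::density(samples, n = 1024L)
  f <- stats::approxfun(d$x, pmax(d$y, 0), rule = 2L)
  lo <- max(lower, min(d$x)); hi <- min(upper, max(d$x))
  xs <- seq(lo, hi, length.out = 2048L)
  ys <- pmax(f(xs), 1e-12)
  Z <- sum((ys[-1L] + ys[-length(ys)]) / 2 * diff(xs))
  structure(list(name = name, family = "empirical", samples = samples,
                 densfun = f, lower = lower, upper = upper, floor = 1e-12,
                 logZ = log(Z)),
            class = "prior_entry")
}

.prior_logdens <- function(entry, x) {
  if (x < entry$lower || x > entry$upper) return(-Inf)
  switch(entry$family,
    uniform = -log(entry$max - entry$min),
    normal = stats::dnorm(x, entry$mean, entry$sd, log = TRUE) - entry$lognorm,
    lognormal = stats::dlnorm(x, entry$meanlog, entry$sdlog, log = TRUE) -
      entry$lognorm,
    empirical = log(max(entry$densfun(x), entry$floor)) - entry$logZ,
    stop("unknown prior family: ", entry$family))
}

.prior_draw <- function(entry, n) {
  switch(entry$family,
    uniform = stats::runif(n, entry$min, entry$max),
    normal = {
      plo <- stats::pnorm(entry$lower, entry$mean, entry$sd)
      phi <- stats::pnorm(entry$upper, entry$mean, entry$sd)
      stats::qnorm(stats::runif(n, plo, phi), entry$mean, entry$sd)
    },
    lognormal = {
      plo <- stats::plnorm(entry$lower, entry$meanlog, entry$sdlog)
      phi <- stats::plnorm(entry$upper, entry$meanlog, entry$sdlog)
      stats::qlnorm(stats::runif(n, plo, phi), entry$meanlog, entry$sdlog)
    },
    empirical = sample(entry$samples, n, replace = TRUE),
    stop("unknown prior family: ", entry$family))
}

# rough per-parameter scale used to seed the Metropolis proposal
.prior_scale <- function(entry) {
  switch(entry$family,
    uniform = (entry$max - entry$min) / 20,
    normal = entry$sd,
    lognormal = {
      m <- exp(entry$meanlog + entry$sdlog^2 / 2)
      m * sqrt(exp(entry$sdlog^2) - 1)
    },
    empirical = stats::sd(entry$samples),
    stop("unknown prior family: ", entry$family))
}

#' Joint log prior density
#'
#' Sum of the per-parameter marginal log densities; `-Inf` outside any
#' support.
#'
#' @param theta Named (or prior-ordered) numeric vector of parameter values.
#' @param priors A [prior_spec()].
#' @return Scalar log density.
#' @export
log_prior <- function(theta, priors) {
  stopifnot(inherits(priors, "prior_spec"))
  if (!is.null(names(theta))) {
    if (!setequal(names(theta), names(priors)))
      stop("configuration error: parameter names do not match the prior spec")
    theta <- theta[names(priors)]
  } else if (length(theta) != length(priors)) {
    stop("configuration error: theta length does not match the prior spec")
  }
  tot <- 0
  for (k in seq_along(priors)) {
    lp <- .prior_logdens(priors[[k]], theta[[k]])
    if (!is.finite(lp)) return(-Inf)
    tot <- tot + lp
  }
  tot
}

#' Draw parameter vectors from the prior
#'
#' @param priors A [prior_spec()].
#' @param n Number of draws.
#' @return Matrix `n x length(priors)` with parameter-named columns.
#' @export
sample_prior <- function(priors, n) {
  stopifnot(inherits(priors, "prior_spec"))
  out <- vapply(priors, .prior_draw, numeric(n), n = n)
  if (n == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(priors)))
  out
}

# integral of |F_fit - S_emp| over a fine grid spanning the sample range
# (plus fitted-distribution tails), by trapezoid; used only to rank candidate
# families, so grid accuracy is ample
.l1_cdf_fit_vs_empirical <- function(cdf, samples, n_grid = 4096L) {
  s <- sort(samples)
  pad <- max(stats::sd(s), 1e-12) * 6
  xs <- sort(unique(c(seq(s[1L] - pad, s[length(s)] + pad,
                          length.out = n_grid), s)))
  Fv <- cdf(xs)
  Sv <- stats::ecdf(s)(xs)
  dv <- abs(Fv - Sv)
  sum((dv[-1L] + dv[-length(dv)]) / 2 * diff(xs))
}

#' Fit a parametric distribution to posterior draws
#'
#' Fits a moment-matched Normal and (for positive samples) a LogNormal with
#' the moments of the log, then selects the family whose cumulative
#' distribution function is closer to the empirical one in the L1 sense
#' (normalized by the sample mean, as in [l1_cdf_distance()]). Both
#' candidates and their distances are recorded in the returned entry's
#' `fit` field.
#'
#' @param samples Numeric vector of draws (>= 100).
#' @param name Parameter name for the resulting prior entry.
#' @param lower,upper Support bounds the fitted distribution is truncated to.
#' @return A prior entry (as from [prior_normal()] / [prior_lognormal()])
#'   with a `fit` attribute listing both candidates.
#' @export
fit_posterior_distribution <- function(samples, name = "theta",
                                       lower = -Inf, upper = Inf) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100L) stop("need >= 100 samples")
  m <- mean(samples); s <- stats::sd(samples)
  if (s < 1e-12 * max(abs(m), 1))
    stop("degenerate distribution: sample variance is (near) zero")
  d_norm <- .l1_cdf_fit_vs_empirical(function(x) stats::pnorm(x, m, s),
                                     samples) / abs(m)
  cand <- list(normal = list(mean = m, sd = s, distance = d_norm))
  if (all(samples > 0)) {
    ml <- mean(log(samples)); sl <- stats::sd(log(samples))
    if (sl > 1e-12) {
      d_ln <- .l1_cdf_fit_vs_empirical(function(x) stats::plnorm(x, ml, sl),
                                       samples) / abs(m)
      cand$lognormal <- list(meanlog = ml, sdlog = sl, distance = d_ln)
    }
  }
  pick <- names(cand)[which.min(vapply(cand, `[[`, 0, "distance"))]
  entry <- if (pick == "normal") {
    prior_normal(name, m, s, lower = lower, upper = upper)
  } else {
    prior_lognormal(name, cand$lognormal$meanlog, cand$lognormal$sdlog,
                    lower = max(lower, 0), upper = upper)
  }
  entry$fit <- cand
  entry$selected <- pick
  entry
}

#' Turn a posterior sample into a downstream prior
#'
#' Each calibrated parameter's marginal is replaced by its fitted
#' distribution (via [fit_posterior_distribution()], or a kernel density
#' when `method = "empirical"`), truncated to the parameter's original
#' support. Parameters present in `priors` but absent from the posterior
#' keep their configured entries. Each replaced entry records its source in
#' `$source_stage` for provenance.
#'
#' @param posterior A `posterior_sample` from [run_mcmc()].
#' @param priors The [prior_spec()] whose entries define the original
#'   supports (and supply the untouched parameters).
#' @param method `"parametric"` (default) or `"empirical"`.
#' @param stage Optional label recorded as the provenance source.
#' @return A [prior_spec()].
#' @export
posterior_to_prior <- function(posterior, priors,
                               method = c("parametric", "empirical"),
                               stage = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(posterior, "posterior_sample"),
            inherits(priors, "prior_spec"))
  out <- unclass(priors)
  for (nm in colnames(posterior$draws)) {
    if (!nm %in% names(out)) next
    old <- out[[nm]]
    draws <- posterior$draws[, nm]
    entry <- if (method == "parametric") {
      fit_posterior_distribution(draws, name = nm,
                                 lower = old$lower, upper = old$upper)
    } else {
      prior_empirical(nm, draws, lower = old$lower, upper = old$upper)
    }
    entry$source_stage <- stage
    out[[nm]] <- entry
  }
  structure(out, class = "prior_spec")
}
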