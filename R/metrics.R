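#' L1 distance between empirical cumulative distribution functions
#'
#' Computes `d(F, S) = integral |F - S| dphi / normalizer`, where `F` and
#' `S` are the empirical CDFs of the model and data samples. The integrand
#' is piecewise constant between the merged sample breakpoints, so the
#' integral is evaluated exactly; the nominal upper limit of infinity is
#' harmless because `|F - S| = 0` beyond the largest sample. The result is
#' a pseudometric: nonnegative, symmetric in the integral term, and zero
#' iff the two empirical CDFs coincide.
#'
#' @param model_samples,data_samples Non-empty numeric vectors.
#' @param normalizer Positive scalar, conventionally the mean of the data
#'   samples at that timepoint.
#' @return Scalar distance (>= 0).
#' @export
l1_cdf_distance <- function(model_samples, data_samples, normalizer) {
  if (length(model_samples) == 0L || length(data_samples) == 0L)
    stop("both sample sets must be non-empty")
  if (!is.finite(normalizer) || normalizer <= 0)
    stop("invalid normalizer: must be > 0")
  br <- sort(unique(c(model_samples, data_samples)))
  if (length(br) == 1L) return(0)
  Fv <- stats::ecdf(model_samples)(br)
  Sv <- stats::ecdf(data_samples)(br)
  nb <- length(br)
  area <- sum(abs(Fv[-nb] - Sv[-nb]) * diff(br))
  area / normalizer
}

#' Per-day and average calibration error of a time course
#'
#' Applies [l1_cdf_distance()] at each measurement day, comparing the
#' model-side samples (posterior-predictive draws of the viable fraction at
#' that day) against the day's replicate measurements, normalized by the
#' day's data mean; returns the per-day distances and their arithmetic mean
#' across days, both as percentages.
#'
#' @param model_samples Matrix of predictive draws (`n_draws x N_t`, one
#'   column per data day), or a list of numeric vectors (one per day).
#' @param data A [timecourse_dataset()].
#' @return List with `per_day` (percent, one entry per day) and `average`
#'   (percent).
#' @export
timecourse_calibration_error <- function(model_samples, data) {
  stopifnot(inherits(data, "timecourse_dataset"))
  nt <- length(data$times)
  cols <- if (is.matrix(model_samples)) {
    if (ncol(model_samples) != nt)
      stop("alignment error: one predictive column per data day required")
    lapply(seq_len(nt), function(j) model_samples[, j])
  } else {
    if (length(model_samples) != nt)
      stop("alignment error: one predictive sample set per data day required")
    model_samples
  }
  per_day <- vapply(seq_len(nt), function(j) {
    yj <- data$values[j, ]
    100 * l1_cdf_distance(cols[[j]], yj, normalizer = mean(yj))
  }, 0)
  list(per_day = per_day, average = mean(per_day))
}

#' Prior-to-posterior distribution shift
#'
#' The same L1-CDF metric applied to parameter distributions: the distance
#' between the posterior and prior sample CDFs, normalized by the prior
#' mean, reported as a percentage. A small shift indicates the upstream
#' calibration already pinned the parameter down.
#'
#' @param prior_samples,posterior_samples Non-empty numeric vectors.
#' @return Scalar percentage.
#' @export
distribution_shift <- function(prior_samples, posterior_samples) {
  100 * l1_cdf_distance(posterior_samples, prior_samples,
                        normalizer = mean(prior_samples))
}
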