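#' Gaussian log likelihood of a viability time course
#'
#' Combined measurement-noise and model-inadequacy error collapse to a
#' single zero-mean Gaussian with calibrated standard deviation `sigma`, so
#' the log likelihood is
#' `sum_j sum_i [ -log(2 pi sigma^2)/2 - (y_ij - d_j)^2 / (2 sigma^2) ]`
#' over `N_t` measurement days and `N_r` replicates per day.
#'
#' @param data A [timecourse_dataset()].
#' @param model_values Model-predicted viable fractions `d_j` evaluated at
#'   exactly the data days (numeric vector, or a `trajectory` whose values
#'   are the viable fraction).
#' @param sigma Noise standard deviation (> 0).
#' @return Scalar log likelihood.
#' @export
log_likelihood_timecourse <- function(data, model_values, sigma) {
  stopifnot(inherits(data, "timecourse_dataset"))
  if (inherits(model_values, "trajectory")) {
    if (length(model_values$times) != length(data$times) ||
        max(abs(model_values$times - data$times)) > 1e-9)
      stop("alignment error: model times do not match the data days")
    model_values <- if (is.matrix(model_values$values))
      model_values$values[, "phi_V"] else model_values$values
  }
  if (length(model_values) != length(data$times))
    stop("alignment error: one model value per data day required")
  if (sigma <= 0) stop("`sigma` must be > 0")
  res <- data$values - model_values  # recycles d_j down each column
  n <- length(res)
  -n / 2 * log(2 * pi * sigma^2) - sum(res^2) / (2 * sigma^2)
}

#' Pearson correlation between two spatially matched fields
#'
#' Standard centered product-moment correlation over the flattened elements,
#' pairing each element with its corresponding position. Returns a value in
#' `[-1, 1]`: 1 for total positive, -1 for total negative linear
#' correlation, 0 for none.
#'
#' @param a,b Numeric arrays of identical shape with >= 2 elements and
#'   nonzero variance.
#' @return Scalar correlation.
#' @export
pearson_cc <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("`a` and `b` must share one shape")
  if (length(a) < 2L) stop("need at least 2 elements")
  av <- as.vector(a); bv <- as.vector(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("undefined correlation: zero-variance input")
  stats::cor(av, bv)
}

#' Pearson-correlation log likelihood for spatial field series
#'
#' For mobility calibration the model-data residual at each frame is
#' `1 - PCC` between the observed and simulated viable-fraction fields, and
#' the likelihood treats it as zero-mean Gaussian:
#' `sum_j [ -log(2 pi sigma^2)/2 - (1 - PCC_j)^2 / (2 sigma^2) ]`.
#'
#' @param data A [field_series()].
#' @param model A `trajectory` of [phase_field_state()]s at the data times,
#'   or a list of matrices matching the data grids.
#' @param sigma Noise standard deviation (> 0).
#' @param skip_first Drop the first frame from the sum (it typically seeds
#'   the simulation, so its correlation is trivially 1). Default `TRUE`.
#' @return Scalar log likelihood.
#' @export
log_likelihood_pcc <- function(data, model, sigma, skip_first = TRUE) {
  stopifnot(inherits(data, "field_series"))
  if (sigma <= 0) stop("`sigma` must be > 0")
  frames <- if (inherits(model, "trajectory")) {
    if (length(model$times) != length(data$times) ||
        max(abs(model$times - data$times)) > 1e-9)
      stop("alignment error: model times do not match the data times")
    lapply(model$values, function(s) s$phi_T - s$phi_N)
  } else model
  if (length(frames) != length(data$times))
    stop("alignment error: one model frame per data frame required")
  idx <- seq_along(frames)
  if (skip_first && length(idx) > 1L) idx <- idx[-1L]
  ll <- 0
  for (j in idx) {
    pcc <- pearson_cc(data$grids[[j]], frames[[j]])
    ll <- ll - 0.5 * log(2 * pi * sigma^2) - (1 - pcc)^2 / (2 * sigma^2)
  }
  ll
}
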