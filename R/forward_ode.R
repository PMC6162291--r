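#' Parameters of the reduced tumor growth models
#'
#' Collects the rate constants and initial conditions shared by the reduced
#' scenario models: exponential apoptotic death, nutrient-modulated logistic
#' growth, and the viable/necrotic two-compartment system.
#'
#' @param lambda_prol Proliferation (mitosis) rate, day^-1, >= 0.
#' @param lambda_apop Apoptosis rate, day^-1, >= 0.
#' @param lambda_VN Viable-to-necrotic transfer rate, day^-1, >= 0.
#' @param K Carrying capacity, dimensionless in (0, 1].
#' @param phi_sigma Nutrient volume fraction in \[0, 1\] (FBS% / 10).
#' @param phi_V0 Initial viable volume fraction in (0, 1).
#' @param phi_N0 Initial necrotic volume fraction, >= 0 (default 0).
#' @return An object of class `reduced_params`.
#' @export
reduced_params <- function(lambda_prol = 0, lambda_apop = 0, lambda_VN = 0,
                           K = 1, phi_sigma = 1, phi_V0 = 0.01,
                           phi_N0 = 0) {
  if (lambda_prol < 0 || lambda_apop < 0 || lambda_VN < 0)
    stop("invalid parameter: rates must be >= 0")
  if (K <= 0 || K > 1) stop("invalid parameter: K must lie in (0, 1]")
  if (phi_sigma < 0 || phi_sigma > 1)
    stop("invalid parameter: phi_sigma must lie in [0, 1]")
  if (phi_V0 <= 0 || phi_V0 >= 1)
    stop("invalid parameter: phi_V0 must lie in (0, 1)")
  if (phi_N0 < 0) stop("invalid parameter: phi_N0 must be >= 0")
  if (phi_V0 + phi_N0 > 1)
    stop("invalid parameter: phi_V0 + phi_N0 must be <= 1")
  structure(list(lambda_prol = unname(lambda_prol),
                 lambda_apop = unname(lambda_apop),
                 lambda_VN = unname(lambda_VN), K = unname(K),
                 phi_sigma = unname(phi_sigma), phi_V0 = unname(phi_V0),
                 phi_N0 = unname(phi_N0)),
            class = "reduced_params")
}

#' Classical fixed-step fourth-order Runge-Kutta integration
#'
#' Integrates `dy/dt = deriv(t, y)` from `times[1]` and returns the state at
#' each requested time. The nominal step `dt` is shrunk per interval so that
#' every requested time is hit exactly. The state may be a vector or a
#' matrix (e.g. an ensemble with one row per parameter draw, or a flattened
#' field), as long as `deriv` returns the same shape.
#'
#' @param deriv Function `(t, y) -> dy/dt`.
#' @param y0 Initial state (numeric vector or matrix).
#' @param times Strictly increasing output times; `times[1]` is the initial
#'   time.
#' @param dt Nominal step size (default 0.01 day).
#' @return A list with `times` and `states` (a list of states, one per
#'   requested time, the first being `y0`).
#' @export
rk4_integrate <- function(deriv, y0, times, dt = 0.01) {
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (dt <= 0) stop("`dt` must be positive")
  states <- vector("list", length(times))
  states[[1L]] <- y0
  y <- y0
  for (i in seq_len(length(times) - 1L)) {
    t0 <- times[i]; t1 <- times[i + 1L]
    nstep <- max(1L, ceiling((t1 - t0) / dt - 1e-9))
    h <- (t1 - t0) / nstep
    t <- t0
    for (s in seq_len(nstep)) {
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 2, y + h / 2 * k1)
      k3 <- deriv(t + h / 2, y + h / 2 * k2)
      k4 <- deriv(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t0 + s * h
    }
    states[[i + 1L]] <- y
  }
  list(times = times, states = states)
}

.trajectory <- function(times, values) {
  structure(list(times = times, values = values), class = "trajectory")
}

#' Exponential apoptotic death of viable cells
#'
#' With proliferation inhibited (Mitomycin-C) and ample nutrient, the viable
#' fraction obeys `d phi_V / dt = -lambda_apop * phi_V`. Integrated by
#' fixed-step RK4; the closed form is available separately via
#' [exponential_death_closed_form()] for verification.
#'
#' @param params A [reduced_params()] (uses `lambda_apop`, `phi_V0`).
#' @param times Output times in days (first entry = initial time).
#' @param dt RK4 step size in days.
#' @return A `trajectory` with `times` and `values` (`phi_V` per time).
#' @export
simulate_exponential_death <- function(params, times, dt = 0.01) {
  stopifnot(inherits(params, "reduced_params"))
  la <- params$lambda_apop
  out <- rk4_integrate(function(t, y) -la * y, params$phi_V0, times, dt)
  .trajectory(times, unlist(out$states))
}

#' @rdname simulate_exponential_death
#' @export
exponential_death_closed_form <- function(params, times) {
  params$phi_V0 * exp(-params$lambda_apop * (times - times[1L]))
}

#' Nutrient-modulated logistic growth of viable cells
#'
#' Integrates `d phi_V / dt = lambda_prol * phi_sigma * phi_V (1 - phi_V / K)
#' - lambda_apop * phi_V` by fixed-step RK4.
#' [logistic_growth_closed_form()] gives the shifted-logistic solution: with
#' `r = lambda_prol * phi_sigma - lambda_apop` and
#' `K_eff = K (1 - lambda_apop / (lambda_prol * phi_sigma))`,
#' `phi_V(t) = K_eff / (1 + (K_eff / phi_V0 - 1) exp(-r t))`; the `r = 0`
#' boundary collapses to algebraic decay of the quadratic term.
#'
#' @inheritParams simulate_exponential_death
#' @return A `trajectory` of `phi_V`.
#' @export
simulate_logistic_growth <- function(params, times, dt = 0.01) {
  stopifnot(inherits(params, "reduced_params"))
  lp <- params$lambda_prol * params$phi_sigma
  la <- params$lambda_apop
  K <- params$K
  out <- rk4_integrate(function(t, y) lp * y * (1 - y / K) - la * y,
                       params$phi_V0, times, dt)
  .trajectory(times, unlist(out$states))
}

#' @rdname simulate_logistic_growth
#' @export
logistic_growth_closed_form <- function(params, times) {
  lp <- params$lambda_prol * params$phi_sigma
  la <- params$lambda_apop
  K <- params$K
  phi0 <- params$phi_V0
  tau <- times - times[1L]
  if (lp == 0) return(phi0 * exp(-la * tau))
  r <- lp - la
  if (abs(r) < 1e-14) {
    # r = 0: d phi/dt = -(lp / K) phi^2
    return(phi0 / (1 + (lp / K) * phi0 * tau))
  }
  K_eff <- K * (1 - la / lp)
  K_eff / (1 + (K_eff / phi0 - 1) * exp(-r * tau))
}

#' Coupled viable/necrotic compartment model
#'
#' Integrates, by fixed-step RK4,
#' `d phi_T / dt = lambda_prol * phi_sigma (phi_T - phi_N)(1 - phi_T / K)
#'               - lambda_apop (phi_T - phi_N)` and
#' `d phi_N / dt = lambda_VN (phi_T - phi_N)`. The Heaviside nutrient gate is
#' dropped here: below-optimal nutrient scenarios always have the transfer
#' active. The necrotic core is monotone non-decreasing since
#' `phi_N <= phi_T` is preserved.
#'
#' @inheritParams simulate_exponential_death
#' @return A `trajectory` whose `values` is a matrix with columns
#'   `phi_T`, `phi_N`, `phi_V` (`= phi_T - phi_N`).
#' @export
simulate_necrosis_system <- function(params, times, dt = 0.01) {
  stopifnot(inherits(params, "reduced_params"))
  phiT0 <- params$phi_V0 + params$phi_N0
  if (params$phi_N0 > phiT0)
    stop("invalid initial condition: phi_N0 > phi_T0")
  lp <- params$lambda_prol * params$phi_sigma
  la <- params$lambda_apop
  lv <- params$lambda_VN
  K <- params$K
  deriv <- function(t, y) {
    v <- y[1L] - y[2L]
    c(lp * v * (1 - y[1L] / K) - la * v, lv * v)
  }
  out <- rk4_integrate(deriv, c(phiT0, params$phi_N0), times, dt)
  m <- do.call(rbind, out$states)
  colnames(m) <- c("phi_T", "phi_N")
  m <- cbind(m, phi_V = m[, 1L] - m[, 2L])
  .trajectory(times, m)
}

#' Starvation-limit closed form of the necrosis model
#'
#' With `phi_sigma = 0` the viable fraction decays linearly:
#' `phi_V(t) = phi_V0 * exp(-(lambda_apop + lambda_VN) t)`.
#'
#' @inheritParams simulate_exponential_death
#' @return Numeric vector of `phi_V` at `times`.
#' @export
necrosis_starvation_closed_form <- function(params, times) {
  params$phi_V0 *
    exp(-(params$lambda_apop + params$lambda_VN) * (times - times[1L]))
}
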