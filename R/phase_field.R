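#' Quartic double-well bulk energy and its derivatives
#'
#' `double_well()` evaluates `Psi(phi) = E_bar * phi^2 (1 - phi)^2`, the
#' bulk free-energy density with minima at the pure phases `phi = 0, 1`.
#' `double_well_prime()` is its derivative
#' `E_bar * (2 phi - 6 phi^2 + 4 phi^3)`.
#' `split_contractive_expansive()` returns the convex (contractive /
#' expansive) splitting `Psi = Psi_c - Psi_e` with
#' `Psi_c = (3/2) E_bar phi^2` and
#' `Psi_e = -E_bar (phi^4 - 2 phi^3 - phi^2 / 2)`, the basis of the
#' unconditionally energy-stable semi-implicit scheme.
#'
#' @param phi Volume fraction (scalar, vector or matrix).
#' @param E_bar Energy scale, dimensionless > 0.
#' @return Energy density (same shape as `phi`); for the splitting, a list
#'   with components `contractive` and `expansive`.
#' @export
double_well <- function(phi, E_bar) E_bar * phi^2 * (1 - phi)^2

#' @rdname double_well
#' @export
double_well_prime <- function(phi, E_bar)
  E_bar * (2 * phi - 6 * phi^2 + 4 * phi^3)

#' @rdname double_well
#' @export
split_contractive_expansive <- function(phi, E_bar) {
  list(contractive = 1.5 * E_bar * phi^2,
       expansive = -E_bar * (phi^4 - 2 * phi^3 - 0.5 * phi^2))
}

# derivatives of the splitting terms; Psi_c' is linear in phi, which keeps
# the implicit part of the scheme a linear solve
.psi_c_prime <- function(phi, E_bar) 3 * E_bar * phi
.psi_e_prime <- function(phi, E_bar) -E_bar * (4 * phi^3 - 6 * phi^2 - phi)

#' Uniform 2D grid for the phase-field solver
#'
#' Fields on the grid are `ny x nx` matrices: row = y index (downward),
#' column = x index (rightward), origin at top-left, pixel centers at
#' `(i + 1/2) * spacing`.
#'
#' @param nx,ny Number of cells in x and y (each >= 4).
#' @param spacing Cell size in micrometers (> 0).
#' @param bc Boundary condition: `"neumann"` (zero flux, the model's
#'   contract) or `"periodic"` (analysis harness).
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(nx, ny, spacing, bc = c("neumann", "periodic")) {
  bc <- match.arg(bc)
  if (nx < 4L || ny < 4L) stop("`nx` and `ny` must be >= 4")
  if (spacing <= 0) stop("`spacing` must be positive (micrometers)")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 spacing = spacing, bc = bc,
                 extent = c(nx * spacing, ny * spacing)),
            class = "grid2d")
}

# neighbor linear indices for each of the 4 faces; NA where the face lies on
# a zero-flux boundary (mirror ghost => zero difference => dropped term)
.grid_neighbors <- function(grid) {
  ny <- grid$ny; nx <- grid$nx
  ii <- matrix(seq_len(ny * nx), ny, nx)
  shift <- function(di, dj) {
    ri <- seq_len(ny) + di; cj <- seq_len(nx) + dj
    if (grid$bc == "periodic") {
      ri <- (ri - 1L) %% ny + 1L; cj <- (cj - 1L) %% nx + 1L
      ii[ri, cj, drop = FALSE]
    } else {
      out <- matrix(NA_integer_, ny, nx)
      keep_i <- ri >= 1L & ri <= ny; keep_j <- cj >= 1L & cj <= nx
      out[keep_i, keep_j] <- ii[ri[keep_i], cj[keep_j], drop = FALSE]
      out
    }
  }
  list(up = shift(-1L, 0L), down = shift(1L, 0L),
       left = shift(0L, -1L), right = shift(0L, 1L))
}

#' Discrete Laplacian with zero-flux (or periodic) boundaries
#'
#' Five-point stencil scaled by `1 / spacing^2`; missing neighbors at a
#' zero-flux boundary are mirrored, which drops their contribution.
#'
#' @param grid A [grid2d()].
#' @return A sparse `Matrix` of size `(nx*ny) x (nx*ny)` acting on fields
#'   flattened column-major.
#' @export
laplacian_matrix <- function(grid) {
  nb <- .grid_neighbors(grid)
  n <- grid$nx * grid$ny
  idx <- seq_len(n)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  diag_cnt <- numeric(n)
  for (f in nb) {
    v <- as.vector(f)
    ok <- !is.na(v)
    i <- c(i, idx[ok]); j <- c(j, v[ok]); x <- c(x, rep(1, sum(ok)))
    diag_cnt[ok] <- diag_cnt[ok] + 1
  }
  i <- c(i, idx); j <- c(j, idx); x <- c(x, -diag_cnt)
  Matrix::sparseMatrix(i = i, j = j, x = x / grid$spacing^2, dims = c(n, n))
}

# divergence of M grad(.) with face mobilities (arithmetic mean of the two
# adjacent cells); zero-flux faces contribute nothing, so column sums vanish
# and total mass is conserved exactly by construction
.div_M_grad_matrix <- function(M, grid) {
  nb <- .grid_neighbors(grid)
  n <- grid$nx * grid$ny
  idx <- seq_len(n)
  Mv <- as.vector(M)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  diag_acc <- numeric(n)
  for (f in nb) {
    v <- as.vector(f)
    ok <- !is.na(v)
    mf <- (Mv[idx[ok]] + Mv[v[ok]]) / 2
    i <- c(i, idx[ok]); j <- c(j, v[ok]); x <- c(x, mf)
    diag_acc[ok] <- diag_acc[ok] + mf
  }
  i <- c(i, idx); j <- c(j, idx); x <- c(x, -diag_acc)
  Matrix::sparseMatrix(i = i, j = j, x = x / grid$spacing^2, dims = c(n, n))
}

#' Mobility degraded by the necrotic fraction
#'
#' Necrotic cells are immobile, so the effective tumor mobility is
#' `M_T (1 - phi_N / phi_T)`, defaulting to `M_T` where `phi_T = 0`.
#'
#' @param phi_T,phi_N Total and necrotic volume-fraction fields with
#'   `0 <= phi_N <= phi_T` elementwise.
#' @param M_T Mobility coefficient (micrometers/day, >= 0).
#' @param tol Ordering tolerance for the `phi_N <= phi_T` check.
#' @return Field of effective mobilities in `[0, M_T]`.
#' @export
degraded_mobility <- function(phi_T, phi_N, M_T, tol = 1e-6) {
  if (any(phi_N > phi_T + tol))
    stop("invariant violation: phi_N > phi_T")
  if (M_T < 0) stop("`M_T` must be >= 0")
  out <- ifelse(phi_T == 0, M_T, M_T * pmax(0, 1 - phi_N / pmax(phi_T, .Machine$double.xmin)))
  out[phi_T == 0] <- M_T
  pmin(pmax(out, 0), M_T)
}

#' Chemical potential of the tumor phase
#'
#' `mu = Psi'(phi_T) - epsilon_T^2 * Laplacian(phi_T)` with the five-point
#' Laplacian and mirrored (zero-flux) boundary ghosts.
#'
#' @param phi_T Tumor volume-fraction field (`ny x nx` matrix).
#' @param E_bar Energy scale.
#' @param epsilon_T Interaction length (micrometers).
#' @param grid A [grid2d()] consistent with `phi_T`.
#' @return Matrix of the same shape as `phi_T`.
#' @export
chemical_potential <- function(phi_T, E_bar, epsilon_T, grid) {
  L <- laplacian_matrix(grid)
  mu <- double_well_prime(phi_T, E_bar) -
    epsilon_T^2 * matrix(as.vector(L %*% as.vector(phi_T)),
                         grid$ny, grid$nx)
  mu
}

#' Discrete total free energy
#'
#' `E = sum_cells Psi(phi) h^2 + (epsilon^2 / 2) sum_faces (dphi)^2`, the
#' Lyapunov functional that the convex-splitting scheme dissipates. Always
#' >= 0.
#'
#' @inheritParams chemical_potential
#' @return Scalar energy.
#' @export
total_free_energy <- function(phi_T, E_bar, epsilon_T, grid) {
  h <- grid$spacing
  bulk <- sum(double_well(phi_T, E_bar)) * h^2
  dx <- phi_T[, -1L, drop = FALSE] - phi_T[, -ncol(phi_T), drop = FALSE]
  dy <- phi_T[-1L, , drop = FALSE] - phi_T[-nrow(phi_T), , drop = FALSE]
  grad2 <- sum(dx^2) + sum(dy^2)
  if (grid$bc == "periodic") {
    grad2 <- grad2 + sum((phi_T[, 1L] - phi_T[, ncol(phi_T)])^2) +
      sum((phi_T[1L, ] - phi_T[nrow(phi_T), ])^2)
  }
  bulk + epsilon_T^2 / 2 * grad2
}

#' Phase-field model parameters
#'
#' @param M_T Tumor mobility (micrometers/day, >= 0).
#' @param E_bar_T Energy scale (dimensionless, > 0).
#' @param epsilon_T Interaction length (micrometers, > 0); larger adhesion
#'   means a thinner interface.
#' @param sigma_VN Nutrient threshold below which necrosis activates; fixed
#'   at 1 (the 10% FBS vendor-optimal level) unless overridden.
#' @param reduced A [reduced_params()] block supplying the source-term rates
#'   for the full model.
#' @return An object of class `phase_field_params`.
#' @export
phase_field_params <- function(M_T, E_bar_T, epsilon_T, sigma_VN = 1,
                               reduced = reduced_params()) {
  if (M_T < 0) stop("`M_T` must be >= 0")
  if (E_bar_T <= 0) stop("`E_bar_T` must be > 0")
  if (epsilon_T <= 0) stop("`epsilon_T` must be > 0")
  stopifnot(inherits(reduced, "reduced_params"))
  structure(list(M_T = M_T, E_bar_T = E_bar_T, epsilon_T = epsilon_T,
                 sigma_VN = sigma_VN, reduced = reduced),
            class = "phase_field_params")
}

#' Coupled phase-field state
#'
#' Holds the tumor and necrotic fields, the derived chemical potential, and
#' the simulation time. The ordering `0 <= phi_N <= phi_T` is enforced to
#' tolerance `tol`.
#'
#' @param phi_T,phi_N `ny x nx` matrices.
#' @param mu Chemical-potential matrix (optional; may be `NULL`).
#' @param time Time in days.
#' @param tol Ordering tolerance (default 1e-6).
#' @return An object of class `phase_field_state`.
#' @export
phase_field_state <- function(phi_T, phi_N = 0 * phi_T, mu = NULL,
                              time = 0, tol = 1e-6) {
  phi_T <- as.matrix(phi_T); phi_N <- as.matrix(phi_N)
  if (!identical(dim(phi_T), dim(phi_N)))
    stop("`phi_T` and `phi_N` must share one shape")
  if (any(phi_N < -tol) || any(phi_N > phi_T + tol))
    stop("invariant violation: need 0 <= phi_N <= phi_T")
  structure(list(phi_T = phi_T, phi_N = phi_N, mu = mu, time = time),
            class = "phase_field_state")
}

# one semi-implicit convex-splitting step (Psi' = Psi_c' - Psi_e'):
#   (I - dt * D_M (3 E_bar I - eps^2 L)) phi^{n+1}
#       = phi^n - dt * D_M Psi_e'(phi^n)
# with the mobility lagged at step n. The factorized system is reused when
# the mobility field is constant over the run.
.ch_system_matrix <- function(DM, L, E_bar, eps, dt, n) {
  I <- Matrix::Diagonal(n)
  I - dt * (DM %*% (3 * E_bar * I - eps^2 * L))
}

.ch_solve_checked <- function(fac, A, b, step) {
  x <- as.vector(Matrix::solve(fac, b))
  res <- sqrt(sum((as.vector(A %*% x) - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (!is.finite(res) || res > 1e-10)
    stop(sprintf("convergence error: CH linear solve at step %d, relative residual %.3e",
                 step, res))
  x
}

#' Mobility-only Cahn-Hilliard evolution
#'
#' Evolves `d phi_T / dt = div(M_bar(phi) grad mu)` with
#' `mu = Psi'(phi_T) - epsilon_T^2 Laplacian(phi_T)` and zero-flux
#' boundaries, using the semi-implicit convex-splitting scheme: the
#' contractive part `Psi_c'` and the `-epsilon^2 Laplacian` term are
#' implicit, the expansive part `Psi_e'` is explicit, and the degraded
#' mobility is lagged from the previous step. The necrotic field is frozen
#' (this scenario has no source terms). Total mass is conserved to solver
#' precision and the discrete energy is non-increasing.
#'
#' @param params A [phase_field_params()].
#' @param initial A [phase_field_state()].
#' @param times Strictly increasing output times (days); `times[1]` is the
#'   initial time.
#' @param grid A [grid2d()].
#' @param dt Nominal time step (days); shrunk per interval to hit every
#'   output time exactly.
#' @param bound_tol Allowed excursion of `phi_T` beyond `[0, 1]` before the
#'   run aborts. Polynomial-potential Cahn-Hilliard obeys no maximum
#'   principle, so small interface under/overshoots are expected; the
#'   default 0.05 flags genuine blow-up only.
#' @return A `trajectory` whose `values` is a list of
#'   [phase_field_state()]s at `times`.
#' @export
simulate_mobility_ch <- function(params, initial, times, grid, dt = 0.005,
                                 bound_tol = 0.05) {
  stopifnot(inherits(params, "phase_field_params"),
            inherits(initial, "phase_field_state"),
            inherits(grid, "grid2d"))
  phi_N <- initial$phi_N
  runner <- .ch_runner(params, phi_N, grid, dt, bound_tol)
  phi <- initial$phi_T
  states <- vector("list", length(times))
  states[[1L]] <- .ch_state(phi, phi_N, params, grid, times[1L])
  for (k in seq_len(length(times) - 1L)) {
    phi <- runner(phi, times[k], times[k + 1L])
    states[[k + 1L]] <- .ch_state(phi, phi_N, params, grid, times[k + 1L])
  }
  .trajectory(times, states)
}

.ch_state <- function(phi, phi_N, params, grid, time) {
  phase_field_state(phi, phi_N,
                    mu = chemical_potential(phi, params$E_bar_T,
                                            params$epsilon_T, grid),
                    time = time, tol = Inf)
}

# returns function(phi, t0, t1) advancing the CH operator; factorizes the
# system once when the mobility field cannot change (phi_N identically 0
# gives M_bar = M_T everywhere, independent of phi_T)
.ch_runner <- function(params, phi_N, grid, dt, bound_tol) {
  n <- grid$nx * grid$ny
  L <- laplacian_matrix(grid)
  E <- params$E_bar_T; eps <- params$epsilon_T
  constM <- all(phi_N == 0)
  fac <- NULL; A <- NULL; DM <- NULL
  if (constM) {
    DM <- params$M_T * L
    A <- .ch_system_matrix(DM, L, E, eps, dt, n)
    fac <- Matrix::lu(A)
  }
  step_id <- 0L
  function(phi, t0, t1) {
    nstep <- max(1L, ceiling((t1 - t0) / dt - 1e-9))
    h <- (t1 - t0) / nstep
    for (s in seq_len(nstep)) {
      step_id <<- step_id + 1L
      if (!constM) {
        M <- degraded_mobility(phi, phi_N, params$M_T)
        DM <- .div_M_grad_matrix(M, grid)
        A <- .ch_system_matrix(DM, L, E, eps, h, n)
        fac <- A
      } else if (abs(h - dt) > 1e-12 * dt) {
        A <- .ch_system_matrix(DM, L, E, eps, h, n)
        fac <- Matrix::lu(A)
      }
      b <- as.vector(phi) - h * as.vector(DM %*% .psi_e_prime(as.vector(phi), E))
      phi <- matrix(.ch_solve_checked(fac, A, b, step_id), grid$ny, grid$nx)
      if (min(phi) < -bound_tol || max(phi) > 1 + bound_tol)
        stop(sprintf(
          "invariant violation: phi_T left [%.3g, %.3g] at step %d (range %.3g..%.3g)",
          -bound_tol, 1 + bound_tol, step_id, min(phi), max(phi)))
    }
    phi
  }
}

#' Full coupled phase-field model with growth, apoptosis and necrosis
#'
#' Operator-split integration of
#' `d phi_T / dt = div(M_bar grad mu) + lambda_prol phi_sigma (phi_T -
#' phi_N)(1 - phi_T / K) - lambda_apop (phi_T - phi_N)` and
#' `d phi_N / dt = lambda_VN H(sigma_VN - phi_sigma) (phi_T - phi_N)`:
#' each step advances the Cahn-Hilliard operator semi-implicitly (as in
#' [simulate_mobility_ch()]) and then the local reaction terms pointwise by
#' RK4. The Heaviside gate is exact: necrosis is active only when
#' `phi_sigma < sigma_VN`, and since `phi_sigma` is a per-scenario constant
#' the gate never switches mid-run.
#'
#' @inheritParams simulate_mobility_ch
#' @param phi_sigma Nutrient volume fraction (per-scenario constant).
#' @return A `trajectory` of [phase_field_state()]s.
#' @export
simulate_full_phase_field <- function(params, initial, phi_sigma, times,
                                      grid, dt = 0.005, bound_tol = 0.05) {
  stopifnot(inherits(params, "phase_field_params"),
            inherits(initial, "phase_field_state"),
            inherits(grid, "grid2d"))
  rp <- params$reduced
  gate <- as.numeric(phi_sigma < params$sigma_VN)
  lp <- rp$lambda_prol * phi_sigma
  la <- rp$lambda_apop
  lv <- rp$lambda_VN * gate
  K <- rp$K
  react <- function(t, y) {
    nn <- length(y) / 2L
    phiT <- y[seq_len(nn)]; phiN <- y[nn + seq_len(nn)]
    v <- phiT - phiN
    c(lp * v * (1 - phiT / K) - la * v, lv * v)
  }
  n <- grid$nx * grid$ny
  L <- laplacian_matrix(grid)
  E <- params$E_bar_T; eps <- params$epsilon_T
  phi_T <- initial$phi_T; phi_N <- initial$phi_N
  states <- vector("list", length(times))
  states[[1L]] <- .ch_state(phi_T, phi_N, params, grid, times[1L])
  # mobility constant when no necrotic mass can ever appear
  constM <- all(phi_N == 0) && (lv == 0 || params$M_T == 0)
  fac <- NULL; A <- NULL; DM <- NULL; hcur <- NA_real_
  step_id <- 0L
  for (k in seq_len(length(times) - 1L)) {
    t0 <- times[k]; t1 <- times[k + 1L]
    nstep <- max(1L, ceiling((t1 - t0) / dt - 1e-9))
    h <- (t1 - t0) / nstep
    for (s in seq_len(nstep)) {
      step_id <- step_id + 1L
      if (!constM || !identical(h, hcur)) {
        M <- if (constM) matrix(params$M_T, grid$ny, grid$nx)
             else degraded_mobility(phi_T, phi_N, params$M_T)
        DM <- if (constM) params$M_T * L else .div_M_grad_matrix(M, grid)
        A <- .ch_system_matrix(DM, L, E, eps, h, n)
        fac <- if (constM) Matrix::lu(A) else A
        hcur <- if (constM) h else NA_real_
      }
      b <- as.vector(phi_T) - h * as.vector(DM %*% .psi_e_prime(as.vector(phi_T), E))
      phi_T <- matrix(.ch_solve_checked(fac, A, b, step_id), grid$ny, grid$nx)
      y <- rk4_integrate(react, c(as.vector(phi_T), as.vector(phi_N)),
                         c(0, h), dt = h)$states[[2L]]
      phi_T <- matrix(y[seq_len(n)], grid$ny, grid$nx)
      phi_N <- matrix(y[n + seq_len(n)], grid$ny, grid$nx)
      if (min(phi_T) < -bound_tol || max(phi_T) > 1 + bound_tol)
        stop(sprintf(
          "invariant violation: phi_T left [%.3g, %.3g] at step %d",
          -bound_tol, 1 + bound_tol, step_id))
    }
    states[[k + 1L]] <- .ch_state(phi_T, phi_N, params, grid, t1)
  }
  .trajectory(times, states)
}
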