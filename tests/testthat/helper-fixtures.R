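# shared fixture builders; everything is generated in code at test time

fx_meta <- function(id = "apop_d100000", density = 1e5, fbs = 10,
                    treatment = "MMC", duration = 7) {
  scenario_meta(id, density, fbs, treatment, duration)
}

fx_timecourse <- function(n_days = 4, n_rep = 3, seed = 1) {
  set.seed(seed)
  vals <- matrix(abs(rnorm(n_days * n_rep, 0.05, 0.01)), n_days, n_rep)
  timecourse_dataset(fx_meta(duration = n_days), seq(0, n_days - 1), vals)
}

fx_grid <- function(n = 16, spacing = 20, bc = "neumann") {
  grid2d(n, n, spacing = spacing, bc = bc)
}

fx_smooth_field <- function(grid, base = 0.4, amp = 0.2) {
  # smooth cosine bump compatible with zero-flux boundaries
  x <- (seq_len(grid$nx) - 0.5) / grid$nx
  y <- (seq_len(grid$ny) - 0.5) / grid$ny
  base + amp * outer(cospi(y), cospi(x))
}

.trajectory_for_test <- function(times, values) {
  structure(list(times = times, values = values), class = "trajectory")
}

# synthetic apoptosis-arm dataset at the study's highest seeding density
fx_apoptosis_data <- function(seed, lambda = 0.1, noise_frac = 0.05,
                              duration = 7) {
  phi0 <- seeding_density_to_volume_fraction(1e5)
  synth_timecourses(
    "exponential", reduced_params(lambda_apop = lambda, phi_V0 = phi0),
    fx_meta(duration = duration), noise_frac * phi0, 4L, seed = seed)
}
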