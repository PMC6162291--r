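test_that("noiseless synthesis reproduces the deterministic trajectory", {
  p <- reduced_params(lambda_apop = 0.09, phi_V0 = 0.0422)
  ds <- synth_timecourses("exponential", p, fx_meta(), 0, 4, seed = 1)
  det <- exponential_death_closed_form(p, ds$times)
  expect_lt(max(abs(ds$values - det)), 1e-8)
  expect_false(any(attr(ds, "floored")))
})

test_that("synthesis is reproducible and honest about flooring", {
  p <- reduced_params(lambda_apop = 0.5, phi_V0 = 0.005)
  a <- synth_timecourses("exponential", p, fx_meta(), 0.01, 4, seed = 9)
  b <- synth_timecourses("exponential", p, fx_meta(), 0.01, 4, seed = 9)
  expect_identical(a$values, b$values)
  # large noise against a small signal must floor some draws, flagged
  expect_true(any(attr(a, "floored")))
  expect_true(all(a$values[attr(a, "floored")] == 0))
})

test_that("replicate means concentrate around the truth like 1/sqrt(N_r)", {
  phi0 <- 8.44e-2; sigma <- 0.05 * phi0
  p <- reduced_params(lambda_apop = 0.1, phi_V0 = phi0)
  hits <- 0L; total <- 0L
  for (s in 1:6) {
    ds <- synth_timecourses("exponential", p, fx_meta(), sigma, 4,
                            seed = 40 + s)
    det <- attr(ds, "truth_trajectory")
    dev <- abs(rowMeans(ds$values) - det)
    hits <- hits + sum(dev <= 3 * sigma / sqrt(4))
    total <- total + length(dev)
  }
  expect_gte(hits / total, 0.95)
})

test_that("initial fields are clustered tanh bumps with reproducible seeds", {
  g <- fx_grid(32, 1160 / 32)
  z <- synth_initial_field(g, n_clusters = 0)
  expect_true(all(z$phi_T == 0))
  one <- synth_initial_field(g, n_clusters = 1, cluster_radius = 150,
                             interface_width = 40, seed = 4)
  expect_equal(max(one$phi_T), 0.8, tolerance = 0.02)
  expect_true(all(one$phi_N == 0))
  again <- synth_initial_field(g, n_clusters = 1, cluster_radius = 150,
                               interface_width = 40, seed = 4)
  expect_identical(one$phi_T, again$phi_T)
  expect_error(synth_initial_field(g, cluster_radius = 900), "fit")
})

test_that("field series inherit conservation and distinguish mobilities", {
  g <- fx_grid(24, 1160 / 24)
  init <- suppressWarnings(
    synth_initial_field(g, n_clusters = 2, cluster_radius = 160,
                        interface_width = 60, seed = 8))
  frozen <- synth_field_series(phase_field_params(0, 0.65, 30), init, g,
                               duration = 0.1, interval = 0.05,
                               observation_noise_sd = 0, seed = 1)
  for (f in frozen$grids) expect_identical(f, frozen$grids[[1]])

  fs <- synth_field_series(phase_field_params(200, 0.65, 30), init, g,
                           duration = 0.25, interval = 1 / 48,
                           observation_noise_sd = 0, seed = 1)
  # the evolved fields conserve mass exactly; the observed (clamped)
  # frames only lose the tiny interface under/overshoots
  mass_true <- vapply(attr(fs, "truth_frames"), sum, 0)
  expect_lt(max(abs(mass_true - mass_true[1])) / mass_true[1], 1e-10)
  mass_obs <- vapply(fs$grids, sum, 0)
  expect_lt(max(abs(mass_obs - mass_true)) / mass_true[1], 1e-3)
  expect_length(fs$times, 13L)

  fast <- synth_field_series(phase_field_params(800, 0.65, 30), init, g,
                             duration = 0.25, interval = 1 / 48,
                             observation_noise_sd = 0, seed = 1)
  last <- length(fs$grids)
  expect_lt(pearson_cc(fs$grids[[last]], fast$grids[[last]]), 1 - 1e-4)
})

test_that("the full study fixture writes every scenario plus a faithful manifest", {
  dir <- withr::local_tempdir()
  spec <- synthetic_study_spec(mobility_fbs = c(0, 10), grid_n = 16,
                               pixel_size = 1160 / 16)
  manifest <- suppressWarnings(full_study_fixture(spec, dir))
  # 5 apoptosis + 5 proliferation + 12 necrosis + 2 mobility
  expect_length(manifest$files, 24L)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_equal(manifest$truth$lambda_apop, spec$truth[["lambda_apop"]])
  expect_equal(unlist(manifest$truth$lambda_VN),
               unlist(spec$truth[["lambda_VN"]]), tolerance = 1e-12)

  bundle <- load_study_bundle(dir)
  expect_setequal(names(bundle$apoptosis),
                  c("5000", "10000", "25000", "50000", "100000"))
  expect_length(bundle$necrosis, 12L)
  expect_setequal(names(bundle$mobility), c("0", "10"))
  mem <- suppressWarnings(build_study_bundle(spec))
  expect_equal(bundle$apoptosis[["100000"]]$values,
               unname(mem$apoptosis[["100000"]]$values))
  expect_lt(max(abs(bundle$mobility[["10"]]$grids[[5]] -
                      mem$mobility[["10"]]$grids[[5]])), 1e-6)

  # regeneration determinism: byte-identical time-course files
  dir2 <- withr::local_tempdir()
  suppressWarnings(full_study_fixture(spec, dir2))
  f <- "apoptosis_d50000.csv"
  expect_identical(readLines(file.path(dir, f)),
                   readLines(file.path(dir2, f)))
})

test_that("generated datasets feed the pipeline stages without adaptation", {
  spec <- synthetic_study_spec(mobility_fbs = numeric(0))
  b <- build_study_bundle(spec)
  ds <- b$necrosis[["fbs0_d50000"]]
  expect_s3_class(ds, "timecourse_dataset")
  expect_equal(ds$meta$nutrient_fraction, 0)
  expect_equal(ds$n_replicates, 4L)
  sp <- stage_spec("necr", "necrosis", ds)  # validates priors vs model
  expect_s3_class(sp, "stage_spec")
})
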