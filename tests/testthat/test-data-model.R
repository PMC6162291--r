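test_that("seeding-density conversion is linear through the origin and hits all anchors", {
  densities <- c(5e3, 1e4, 2.5e4, 5e4, 1e5)
  fractions <- c(4.22e-3, 8.44e-3, 2.11e-2, 4.22e-2, 8.44e-2)
  got <- seeding_density_to_volume_fraction(densities)
  expect_true(all(abs(got - fractions) / fractions <= 1e-12))
  # any anchor reproduces the whole set
  got2 <- seeding_density_to_volume_fraction(densities,
                                             anchor_density = 2.5e4,
                                             anchor_fraction = 2.11e-2)
  expect_true(all(abs(got2 - fractions) / fractions <= 1e-12))
  expect_error(seeding_density_to_volume_fraction(-1), "positive")
  expect_error(seeding_density_to_volume_fraction(5e3, anchor_fraction = 0),
               "anchor")
})

test_that("fluorescence conversion is the anchored linear map", {
  expect_equal(fluorescence_to_volume_fraction(120, 120, 0.01), 0.01)
  expect_equal(fluorescence_to_volume_fraction(240, 120, 0.01), 0.02)
  out <- fluorescence_to_volume_fraction(c(10, 400, 80), 120, 0.01)
  expect_identical(order(out), order(c(10, 400, 80)))
  expect_error(fluorescence_to_volume_fraction(1, 0, 0.01), "anchor")
})

test_that("area-fraction mode scales with count and diameter", {
  a <- cell_count_to_area_fraction(100, well_area = 0.32e8)
  expect_equal(cell_count_to_area_fraction(200, 0.32e8), 2 * a)
  expect_equal(cell_count_to_area_fraction(100, 0.32e8, cell_diameter = 40),
               4 * a)
})

test_that("scenario metadata maps FBS to nutrient fraction and validates", {
  m <- scenario_meta("s", 5e4, 7.5, "none", 7)
  expect_equal(m$nutrient_fraction, 0.75)
  expect_error(scenario_meta("s", 5e4, 3, "none", 7), "fbs_percent")
  expect_error(scenario_meta("s", 0, 10, "none", 7), "seeding_density")
  expect_error(scenario_meta("s", 5e4, 10, "none", -1), "duration")
})

test_that("timecourse datasets validate their shape", {
  expect_error(timecourse_dataset(fx_meta(), c(0, 1, 1),
                                  matrix(0.1, 3, 2)), "increasing")
  expect_error(timecourse_dataset(fx_meta(), 0:2, matrix(-0.1, 3, 2)),
               ">= 0")
  expect_error(timecourse_dataset(fx_meta(), 0:2, matrix(0.1, 2, 2)),
               "one row per")
})

test_that("timecourse CSV round trip is bit-exact", {
  ds <- fx_timecourse(n_days = 5, n_rep = 4, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(ds, path)
  back <- read_timecourse_csv(path)
  expect_identical(back$values, unname(ds$values))
  expect_identical(back$times, ds$times)
  expect_equal(back$meta, ds$meta)
})

test_that("malformed timecourse files raise format errors naming the defect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path)
  expect_error(read_timecourse_csv(path), "empty")

  ds <- fx_timecourse()
  write_timecourse_csv(ds, path)
  lines <- readLines(path)
  dup <- c(lines, lines[length(lines)])   # duplicate final (day, replicate)
  writeLines(dup, path)
  expect_error(read_timecourse_csv(path), "duplicate")

  writeLines(lines[-length(lines)], path) # drop one replicate of last day
  expect_error(read_timecourse_csv(path), "ragged")

  writeLines(sub("^scenario_id,day", "scenario_id,d", lines), path)
  expect_error(read_timecourse_csv(path), "day")
})

test_that("field series clamp on ingest and round trip through TIFF", {
  g <- matrix(seq(-0.2, 1.2, length.out = 64), 8, 8)
  fs <- field_series(c(0, 0.5), list(g, g / 2), pixel_size = 2.275)
  expect_true(all(fs$grids[[1]] >= 0 & fs$grids[[1]] <= 1))
  expect_equal(fs$extent, c(8 * 2.275, 8 * 2.275))

  path <- withr::local_tempfile(fileext = ".tif")
  write_field_series(fs, path)
  back <- read_field_series(path)
  expect_identical(back$times, fs$times)
  expect_lt(max(abs(back$grids[[1]] - fs$grids[[1]])), 1e-6)
  expect_lt(max(abs(back$grids[[2]] - fs$grids[[2]])), 1e-6)
  expect_equal(back$pixel_size, fs$pixel_size)
})

test_that("single-frame field series survive the round trip", {
  fs <- field_series(0.25, list(matrix(0.5, 6, 6)), pixel_size = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_field_series(fs, path)
  back <- read_field_series(path)
  expect_length(back$grids, 1L)
  expect_lt(max(abs(back$grids[[1]] - 0.5)), 1e-6)
})

test_that("field series reader rejects missing or inconsistent sidecars", {
  fs <- field_series(c(0, 1), list(matrix(0.3, 5, 5), matrix(0.6, 5, 5)),
                     pixel_size = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_field_series(fs, path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  meta$times <- list(0)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  expect_error(read_field_series(path), "sidecar")
  file.remove(paste0(path, ".yaml"))
  expect_error(read_field_series(path), "sidecar")
})
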