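#' Scenario metadata for a viability experiment
#'
#' Describes one experimental condition: seeding density, serum (FBS) level
#' with its mapped nutrient volume fraction, treatment, and sampling design.
#' FBS percentages are mapped to nutrient volume fractions as
#' `fbs_percent / 10`, so 10% FBS (the vendor-optimal level) corresponds to
#' `nutrient_fraction = 1`.
#'
#' @param scenario_id Character label, unique within a study.
#' @param seeding_density Initial seeding density in cells/ml (> 0).
#' @param fbs_percent Fetal bovine serum percentage, one of
#'   0, 2.5, 5, 7.5, 10.
#' @param treatment `"MMC"` (Mitomycin-C, proliferation inhibited) or
#'   `"none"`.
#' @param duration Experiment duration in days (> 0).
#' @param sampling_interval Time between measurements in days
#'   (default 1, i.e. daily).
#' @return An object of class `scenario_meta`.
#' @export
scenario_meta <- function(scenario_id, seeding_density, fbs_percent,
                          treatment = c("none", "MMC"),
                          duration, sampling_interval = 1) {
  treatment <- match.arg(treatment)
  if (!is.numeric(seeding_density) || length(seeding_density) != 1L ||
      seeding_density <= 0)
    stop("`seeding_density` must be a single positive number (cells/ml)")
  if (!fbs_percent %in% c(0, 2.5, 5, 7.5, 10))
    stop("`fbs_percent` must be one of 0, 2.5, 5, 7.5, 10")
  if (duration <= 0) stop("`duration` must be positive (days)")
  if (sampling_interval <= 0) stop("`sampling_interval` must be positive")
  structure(list(
    scenario_id = as.character(scenario_id),
    seeding_density = seeding_density,
    fbs_percent = fbs_percent,
    nutrient_fraction = fbs_percent / 10,
    treatment = treatment,
    duration = duration,
    sampling_interval = sampling_interval
  ), class = "scenario_meta")
}

#' Viability time-course dataset
#'
#' Daily replicate measurements of the viable tumor volume fraction for one
#' scenario. Values are stored as an `N_t x N_r` matrix (days by replicates).
#'
#' @param meta A [scenario_meta()] object.
#' @param times Strictly increasing measurement days.
#' @param values Numeric matrix `length(times) x n_replicates` of viable
#'   volume fractions (all >= 0).
#' @return An object of class `timecourse_dataset`.
#' @export
timecourse_dataset <- function(meta, times, values) {
  stopifnot(inherits(meta, "scenario_meta"))
  times <- as.numeric(times)
  if (is.vector(values)) values <- matrix(values, nrow = length(times))
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop("`values` must have one row per measurement day")
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("`times` must be non-empty and strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("all `values` must be finite and >= 0")
  if (ncol(values) < 1L) stop("need at least one replicate")
  structure(list(meta = meta, times = times, values = values,
                 n_replicates = ncol(values)),
            class = "timecourse_dataset")
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  cat(sprintf(
    "<timecourse_dataset> scenario '%s': %d days x %d replicates\n",
    x$meta$scenario_id, length(x$times), x$n_replicates))
  cat(sprintf("  density %g cells/ml, FBS %g%% (phi_sigma = %g), %s\n",
              x$meta$seeding_density, x$meta$fbs_percent,
              x$meta$nutrient_fraction, x$meta$treatment))
  invisible(x)
}

#' Time series of 2D tumor volume-fraction fields
#'
#' A stack of equally shaped 2D grids of total tumor volume fraction
#' `phi_T` in `[0, 1]`, one per timepoint, on a uniform spatial grid.
#' Values are clamped to `[0, 1]` on construction (ingest contract).
#'
#' @param times Strictly increasing timepoints in days.
#' @param grids List of numeric matrices, all the same shape.
#' @param pixel_size Grid spacing in micrometers (> 0).
#' @return An object of class `field_series` with `extent` (micrometers,
#'   x by y) derived from the grid shape.
#' @export
field_series <- function(times, grids, pixel_size) {
  times <- as.numeric(times)
  if (length(times) != length(grids))
    stop("`times` and `grids` lengths differ")
  if (length(times) < 1L || (length(times) > 1L && any(diff(times) <= 0)))
    stop("`times` must be non-empty and strictly increasing")
  if (pixel_size <= 0) stop("`pixel_size` must be positive (micrometers)")
  dims <- dim(grids[[1L]])
  grids <- lapply(grids, function(g) {
    g <- as.matrix(g)
    if (!identical(dim(g), dims)) stop("all grids must share one shape")
    pmin(pmax(g, 0), 1)
  })
  structure(list(times = times, grids = grids, pixel_size = pixel_size,
                 extent = rev(dims) * pixel_size),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  d <- dim(x$grids[[1L]])
  cat(sprintf(
    "<field_series> %d frames of %dx%d pixels (%.3g um/px, %.3g x %.3g um)\n",
    length(x$times), d[1L], d[2L], x$pixel_size, x$extent[1L], x$extent[2L]))
  invisible(x)
}

#' Convert a seeding density to an initial viable volume fraction
#'
#' The assay's day-0 fluorescence calibration is a linear correlation through
#' the origin between seeded cell count and signal, so volume fractions are
#' proportional to seeding density. A single anchor pair (a density and its
#' measured volume fraction) fixes the slope.
#'
#' @param density Seeding density in cells/ml (> 0); vectorized.
#' @param anchor_density,anchor_fraction The anchor pair; defaults are the
#'   5,000 cells/ml condition and its measured day-0 viable fraction.
#' @return Volume fraction(s) `anchor_fraction * density / anchor_density`.
#' @export
#' @examples
#' seeding_density_to_volume_fraction(1e5)  # 8.44e-2
seeding_density_to_volume_fraction <- function(density,
                                               anchor_density = 5000,
                                               anchor_fraction = 4.22e-3) {
  if (any(!is.finite(density)) || any(density <= 0))
    stop("`density` must be positive")
  if (anchor_density <= 0 || anchor_fraction <= 0 || anchor_fraction >= 1)
    stop("anchor must have positive density and fraction in (0, 1)")
  anchor_fraction * density / anchor_density
}

#' Convert fluorescence intensities to viable volume fractions
#'
#' Applies the day-0 linear correlation: each intensity is scaled by
#' `day0_fraction / day0_intensity`. Order is preserved; no background
#' subtraction is performed.
#'
#' @param intensities Numeric vector of fluorescence readings.
#' @param day0_intensity Day-0 anchor intensity (> 0).
#' @param day0_fraction Day-0 viable volume fraction matching the anchor.
#' @return Numeric vector of volume fractions.
#' @export
fluorescence_to_volume_fraction <- function(intensities, day0_intensity,
                                            day0_fraction) {
  if (!is.numeric(day0_intensity) || length(day0_intensity) != 1L ||
      !is.finite(day0_intensity) || day0_intensity <= 0)
    stop("invalid anchor: `day0_intensity` must be a single positive number")
  day0_fraction * intensities / day0_intensity
}

#' Alternative conversion via cell footprint area
#'
#' Converts a cell count to a volume (area) fraction by dividing the total
#' projected cell area by the well area, assuming a constant cell diameter.
#' Exposed as an optional mode; the anchored linear map
#' ([seeding_density_to_volume_fraction()]) is the default pathway because it
#' requires no diameter assumption.
#'
#' @param n_cells Number of cells (>= 0); vectorized.
#' @param well_area Well area in square micrometers (> 0).
#' @param cell_diameter Assumed cell diameter in micrometers (> 0).
#' @return Fraction of the well area covered by cells.
#' @export
cell_count_to_area_fraction <- function(n_cells, well_area,
                                        cell_diameter = 20) {
  if (well_area <= 0 || cell_diameter <= 0)
    stop("`well_area` and `cell_diameter` must be positive")
  if (any(n_cells < 0)) stop("`n_cells` must be >= 0")
  n_cells * pi * (cell_diameter / 2)^2 / well_area
}

# -- delimited-text time-course I/O ------------------------------------------
# Long format, one row per (day, replicate); scenario metadata in a
# commented header. Values printed at 17 significant digits so the
# write -> read round trip is bit-exact for doubles.

#' Write a viability time course to a delimited text file
#'
#' Long format with columns `scenario_id, day, replicate, value` and the
#' scenario metadata in `# key: value` header lines.
#'
#' @param dataset A [timecourse_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  m <- dataset$meta
  hdr <- c(
    sprintf("# scenario_id: %s", m$scenario_id),
    sprintf("# seeding_density: %.17g", m$seeding_density),
    sprintf("# fbs_percent: %.17g", m$fbs_percent),
    sprintf("# treatment: %s", m$treatment),
    sprintf("# duration: %.17g", m$duration),
    sprintf("# sampling_interval: %.17g", m$sampling_interval)
  )
  nt <- length(dataset$times); nr <- dataset$n_replicates
  rows <- sprintf("%s,%.17g,%d,%.17g",
                  m$scenario_id,
                  rep(dataset$times, each = nr),
                  rep(seq_len(nr), times = nt),
                  as.vector(t(dataset$values)))
  writeLines(c(hdr, "scenario_id,day,replicate,value", rows), path)
  invisible(path)
}

#' Read a viability time course written by [write_timecourse_csv()]
#'
#' @param path Input file path.
#' @return A [timecourse_dataset()].
#' @export
read_timecourse_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("format error: empty file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  meta_kv <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta_kv[[key]] <- val
  }
  need <- c("scenario_id", "seeding_density", "fbs_percent", "treatment",
            "duration", "sampling_interval")
  miss <- setdiff(need, names(meta_kv))
  if (length(miss))
    stop("format error: missing metadata header(s): ",
         paste(miss, collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("format error: no data rows in ", path)
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  for (col in c("scenario_id", "day", "replicate", "value"))
    if (!col %in% names(df))
      stop("format error: missing column '", col, "'")
  key <- paste(df$day, df$replicate)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("format error: duplicate (day, replicate) at data row %d", bad))
  }
  days <- sort(unique(df$day))
  reps <- sort(unique(df$replicate))
  if (!identical(sort(as.numeric(reps)), as.numeric(seq_along(reps))))
    stop("format error: replicate labels must be 1..N_r")
  values <- matrix(NA_real_, length(days), length(reps))
  values[cbind(match(df$day, days), match(df$replicate, reps))] <- df$value
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("format error: ragged replicates (day %g missing replicate %d)",
                 days[bad[1L]], bad[2L]))
  }
  meta <- scenario_meta(
    scenario_id = meta_kv$scenario_id,
    seeding_density = as.numeric(meta_kv$seeding_density),
    fbs_percent = as.numeric(meta_kv$fbs_percent),
    treatment = meta_kv$treatment,
    duration = as.numeric(meta_kv$duration),
    sampling_interval = as.numeric(meta_kv$sampling_interval)
  )
  timecourse_dataset(meta, days, values)
}

# -- field-series I/O --------------------------------------------------------
# Multi-page 32-bit TIFF (one page per timepoint, values stored on [0, 1])
# plus a YAML sidecar carrying times, pixel size and the scaling convention.
# Grids are row-major with the origin at top-left, x rightward, y downward;
# pixel centers sit at (i + 1/2) * pixel_size.

#' Write a field series as a multi-page TIFF plus YAML sidecar
#'
#' Pages are written as 32-bit samples on `[0, 1]`; the sidecar
#' (`<path>.yaml`) records `times` (days), `pixel_size` (micrometers) and the
#' scaling, so the round trip preserves values to well under 1e-6 absolute.
#'
#' @param series A [field_series()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_field_series <- function(series, path) {
  stopifnot(inherits(series, "field_series"))
  grids <- lapply(series$grids, function(g) pmin(pmax(g, 0), 1))
  tiff::writeTIFF(grids, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(
    times = as.list(series$times),
    time_unit = "day",
    pixel_size = series$pixel_size,
    pixel_size_unit = "micrometer",
    scaling = "unit_interval"
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a field series written by [write_field_series()]
#'
#' @param path TIFF path; `<path>.yaml` must exist alongside.
#' @return A [field_series()].
#' @export
read_field_series <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("format error: missing sidecar ", side)
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1L]])
  for (p in pages)
    if (!identical(dim(p), dims))
      stop("format error: mismatched page shapes in ", path)
  times <- as.numeric(unlist(meta$times))
  if (length(times) != length(pages))
    stop("format error: sidecar lists ", length(times),
         " times for ", length(pages), " pages")
  field_series(times, pages, pixel_size = as.numeric(meta$pixel_size))
}
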