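# --- file formats, configuration, acquisition-geometry helpers ---

#' Excitation irradiance from laser power and beam diameter
#'
#' For a flat-top beam of diameter `d`, the irradiance at the sample is
#' `E = 4 P / (pi d^2)`, reported in W/cm^2 and optionally rounded to the
#' nearest 5 W/cm^2 (the customary reporting precision).
#'
#' @param P laser power (W), >= 0.
#' @param d beam diameter (m), > 0.
#' @param round_to_5 round to the nearest 5 W/cm^2 (default FALSE).
#' @return Irradiance in W/cm^2.
#' @examples
#' irradiance_from_power(4.1e-3, 130e-6, round_to_5 = TRUE)  # 30 W/cm^2
#' @export
irradiance_from_power <- function(P, d, round_to_5 = FALSE) {
  if (any(d <= 0)) stop("beam diameter must be > 0")
  if (any(P < 0)) stop("power must be >= 0")
  E <- 4 * P / (pi * d^2) / 1e4        # W/m^2 -> W/cm^2
  if (round_to_5) E <- 5 * round(E / 5)
  E
}

#' Effective pixel size in sample space
#'
#' `camera_pixel / magnification * binning`, returned in nm.
#'
#' @param camera_pixel_um physical camera pixel size (um).
#' @param magnification objective/tube magnification (> 0).
#' @param binning camera binning factor (default 1).
#' @return Effective pixel size in nm.
#' @examples
#' effective_pixel_size(6.5, 100, 2)  # 130 nm
#' @export
effective_pixel_size <- function(camera_pixel_um, magnification, binning = 1) {
  if (any(magnification <= 0)) stop("magnification must be > 0")
  stopifnot(all(camera_pixel_um > 0), all(binning >= 1))
  camera_pixel_um / magnification * binning * 1000
}

.loc_required_cols <- c("frame", "x", "y", "photons")

#' Write a localization table to CSV
#'
#' Columns `frame` (0-based), `x`, `y` (px), `photons` are mandatory; any
#' extra columns (e.g. `bg`, `sigma`, `precision`) are preserved. The format
#' round-trips losslessly through [read_localizations()].
#'
#' @param locs localization table (data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  missing_cols <- setdiff(.loc_required_cols, names(locs))
  if (length(missing_cols))
    stop("localization table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' @param path CSV file with at least columns `frame`, `x`, `y`, `photons`
#'   (unknown extra columns are kept).
#' @return A data.frame of class `localization_table`, sorted by frame.
#' @export
read_localizations <- function(path) {
  locs <- utils::read.csv(path)
  missing_cols <- setdiff(.loc_required_cols, names(locs))
  if (length(missing_cols))
    stop("localization file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  locs <- locs[order(locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  class(locs) <- c("localization_table", "data.frame")
  locs
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' @param stack an `image_stack` (list of integer matrices, values 0..65535).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(stack, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file.
#' @param cfg optional [movie_config()] to attach.
#' @return An `image_stack` (list of integer matrices).
#' @export
read_stack_tiff <- function(path, cfg = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(m) {
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
  structure(frames, class = "image_stack", config = cfg)
}

#' Acquisition configuration
#'
#' Validated bundle of acquisition geometry used across simulation and
#' analysis; serializes losslessly to YAML via [write_config()] /
#' [read_config()].
#'
#' @param frame_time frame interval (s).
#' @param pixel_size effective pixel size (nm).
#' @param fov_px field of view (px).
#' @param laser_power laser power (W).
#' @param beam_diameter flat-top beam diameter (m).
#' @param baseline camera offset (counts).
#' @param gain counts per photon.
#' @param seed integer master seed.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_time = 0.2, pixel_size = 130,
                               fov_px = 64L, laser_power = 4.1e-3,
                               beam_diameter = 130e-6, baseline = 100,
                               gain = 1, seed = 1L) {
  vals <- list(frame_time = frame_time, pixel_size = pixel_size,
               fov_px = as.integer(fov_px), laser_power = laser_power,
               beam_diameter = beam_diameter, baseline = baseline,
               gain = gain, seed = as.integer(seed))
  for (nm in c("frame_time", "pixel_size", "fov_px", "laser_power",
               "beam_diameter", "gain"))
    if (vals[[nm]] <= 0) stop(nm, " must be > 0")
  if (vals$baseline < 0) stop("baseline must be >= 0")
  structure(vals, class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("Acquisition: %.3g s frames, %.0f nm px, %dx%d FOV, E = %.0f W/cm^2, seed %d\n",
              x$frame_time, x$pixel_size, x$fov_px, x$fov_px,
              irradiance_from_power(x$laser_power, x$beam_diameter), x$seed))
  invisible(x)
}

#' Write / read an acquisition configuration as YAML
#'
#' @param cfg an [acquisition_config()].
#' @param path YAML file.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   reconstructed `acquisition_config` (round-trip identity).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "acquisition_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(acquisition_config, vals)
}

#' Derive independent per-stage seeds from one master seed
#'
#' Pipeline stages draw their own child seed so that stages stay reproducible
#' independently of how many random numbers earlier stages consumed. Children
#' are a deterministic integer hash of (master seed, stage name), kept within
#' the 32-bit signed range.
#'
#' @param master_seed integer master seed.
#' @param stage stage name (character).
#' @return An integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483647)
}

#' Run manifest for pipeline provenance
#'
#' A JSON-backed record of configuration snapshot, package version, seeds,
#' stage inputs/outputs and record counts, written before and finalized after
#' every pipeline stage.
#'
#' @param config list or `acquisition_config` snapshot.
#' @param path JSON file backing the manifest.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(config, path) {
  man <- list(package = "thtrack",
              version = as.character(utils::packageVersion("thtrack")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = unclass(config), stages = list())
  structure(list(data = man, path = path), class = "run_manifest")
}

#' Record a pipeline stage in a manifest
#'
#' @param manifest a [run_manifest()].
#' @param stage stage name.
#' @param seed stage seed.
#' @param inputs,outputs character paths.
#' @param n_records record count produced by the stage (NA while running).
#' @return The updated manifest (also written to its JSON path).
#' @export
manifest_stage <- function(manifest, stage, seed = NA_integer_,
                           inputs = character(0), outputs = character(0),
                           n_records = NA_integer_) {
  manifest$data$stages[[stage]] <- list(
    seed = seed, inputs = inputs, outputs = outputs, n_records = n_records,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest$data, manifest$path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}

#' Write a photon trace as CSV
#'
#' Columns: `frame` (0-based), `photons`, `truth_bright` (NA when no ground
#' truth is carried).
#'
#' @param trace a [photon_trace()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  df <- data.frame(frame = trace$frame_index, photons = trace$photons,
                   truth_bright = if (is.null(trace$truth_bright)) NA_real_
                                  else trace$truth_bright)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a photon trace from CSV
#'
#' @param path CSV written by [write_trace()].
#' @return A [photon_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  tb <- if (all(is.na(df$truth_bright))) NULL else df$truth_bright
  photon_trace(df$photons, truth_bright = tb)
}
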