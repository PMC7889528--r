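#' Row-major well identifiers
#'
#' `"A1"`, `"A2"`, ... in the row-major order of a standard 96-well plate.
#'
#' @param n Number of wells (<= 96 for the default 8 x 12 layout).
#' @param nrow,ncol Plate dimensions.
#' @return Character vector of well IDs.
#' @export
well_ids <- function(n, nrow = 8, ncol = 12) {
  if (n > nrow * ncol) abort("More wells requested than the plate holds.")
  ids <- as.vector(t(outer(LETTERS[seq_len(nrow)], seq_len(ncol), paste0)))
  ids[seq_len(n)]
}

# First frame at which `temps` cools through `threshold` (NA if never).
first_crossing <- function(temps, threshold) {
  if (is.na(threshold)) return(NA_integer_)
  hit <- which(temps <= threshold)
  if (length(hit)) hit[1] else NA_integer_
}

#' Generate the image sequence for one synthetic well
#'
#' Integrates the sample temperature under the thermal lag, latches the
#' frozen state at the first nucleation crossing (so the latent-heat
#' re-warming cannot thaw the render), and renders one frame per captured
#' device temperature.
#'
#' @param spec A [well_spec()].
#' @param profile A [cooling_profile()].
#' @param lag A [thermal_lag()].
#' @param seed Integer seed for this well's pixel noise.
#' @param dims Raster size.
#' @param well_id Label.
#' @param device_log Optional precomputed [simulate_device_temperature()]
#'   output (shared across a plate).
#' @return A `frame_sequence`: list with `frames` (list of 8-bit RGB
#'   arrays), `capture_interval`, `time_s`, `device_temp_C`,
#'   `sample_temp_C`, `well_id`, `spec`.
#' @export
generate_well_sequence <- function(spec, profile, lag, seed = 1L,
                                   dims = c(64, 64), well_id = "A1",
                                   device_log = NULL) {
  stopifnot(inherits(spec, "well_spec"), inherits(profile, "cooling_profile"),
            inherits(lag, "thermal_lag"))
  device_log <- device_log %||% simulate_device_temperature(profile)
  sample_temps <- simulate_sample_temperature(
    device_log$device_temp_C, lag, profile$capture_interval,
    true_t_nuc = spec$true_t_nuc)
  nuc_frame <- attr(sample_temps, "nucleation_frame")
  n <- nrow(device_log)
  frozen <- if (is.na(nuc_frame)) rep(FALSE, n) else seq_len(n) >= nuc_frame
  set.seed(seed)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    frames[[i]] <- render_well_frame(spec, sample_temps[i], dims = dims,
                                     frozen = frozen[i])
  }
  structure(
    list(frames = frames, capture_interval = profile$capture_interval,
         time_s = device_log$time_s, device_temp_C = device_log$device_temp_C,
         sample_temp_C = as.numeric(sample_temps), well_id = well_id,
         spec = spec, nucleation_frame = nuc_frame),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> well %s: %d frames of %dx%d, %g s apart\n",
              x$well_id, length(x$frames), d[1], d[2], x$capture_interval))
  invisible(x)
}

#' Generate a synthetic well plate
#'
#' Renders every well of a plate against one shared device-temperature log
#' and returns the sequences together with a ground-truth table recording,
#' per well, the true event temperatures and the frames at which the sample
#' temperature cools through them: `cloud_frame` (clouding onset, crossing
#' of the true cloud point), `cloud_end_frame` (clouding completed,
#' crossing of cloud point minus transition width - the event the
#' detectors report), and `nuc_frame`.
#'
#' Reproducible: per-well noise streams are seeded from `seed`, so the same
#' call yields byte-identical frames.
#'
#' @param specs List of [well_spec()]s (one per well), e.g. from
#'   [replicate_specs()].
#' @param profile A [cooling_profile()].
#' @param lag A [thermal_lag()].
#' @param seed Integer seed.
#' @param dims Raster size per well.
#' @param ids Well IDs; defaults to row-major `"A1"`, `"A2"`, ...
#' @return A `well_plate`: list with `wells` (named list of
#'   `frame_sequence`), `device_log`, `ground_truth` (tibble), `profile`,
#'   `lag`, `seed`.
#' @examples
#' plate <- generate_plate(
#'   replicate_specs(well_spec("protein", noise_sd = 0), 2),
#'   cooling_profile(10, -25, rate = 1, capture_interval = 5),
#'   thermal_lag(volume = 20), seed = 7, dims = c(16, 16))
#' plate$ground_truth
#' @export
generate_plate <- function(specs, profile, lag, seed = 1L, dims = c(64, 64),
                           ids = NULL) {
  if (length(specs) < 1) abort("At least one well spec is required.")
  if (inherits(specs, "well_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "well_spec")))
  ids <- ids %||% well_ids(length(specs))
  stopifnot(length(ids) == length(specs), !anyDuplicated(ids))
  device_log <- simulate_device_temperature(profile)
  set.seed(seed)
  well_seeds <- sample.int(.Machine$integer.max - 1L, length(specs))
  wells <- vector("list", length(specs))
  names(wells) <- ids
  gt <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    sq <- generate_well_sequence(specs[[j]], profile, lag,
                                 seed = well_seeds[j], dims = dims,
                                 well_id = ids[j], device_log = device_log)
    wells[[j]] <- sq
    gt[[j]] <- ground_truth_row(sq)
  }
  structure(
    list(wells = wells, device_log = device_log,
         ground_truth = dplyr::bind_rows(gt), profile = profile, lag = lag,
         seed = seed),
    class = "well_plate"
  )
}

# Ground-truth record for one synthetic sequence. Clouding crossings are
# read off the sample-temperature log (identical to the lag solution before
# nucleation); the nucleation frame is the latched one - the first crossing
# of the *unperturbed* lag solution, i.e. the event that triggers the
# latent-heat pulse, not a re-crossing of the pulse-warmed series.
ground_truth_row <- function(sq) {
  spec <- sq$spec
  ts <- sq$sample_temp_C
  cloud_frame <- first_crossing(ts, spec$true_t_cloud)
  cloud_end_frame <- first_crossing(
    ts, if (is.na(spec$true_t_cloud)) NA_real_
        else spec$true_t_cloud - spec$transition_width)
  nuc_frame <- sq$nucleation_frame %||% first_crossing(ts, spec$true_t_nuc)
  tibble(
    well_id = sq$well_id, kind = spec$kind,
    true_t_cloud_C = spec$true_t_cloud, true_t_nuc_C = spec$true_t_nuc,
    cloud_frame = cloud_frame, cloud_end_frame = cloud_end_frame,
    nuc_frame = nuc_frame,
    cloud_end_device_temp_C =
      if (is.na(cloud_end_frame)) NA_real_ else sq$device_temp_C[cloud_end_frame],
    nuc_device_temp_C =
      if (is.na(nuc_frame)) NA_real_ else sq$device_temp_C[nuc_frame]
  )
}

#' @export
print.well_plate <- function(x, ...) {
  cat(sprintf("<well_plate> %d wells x %d frames (seed %s)\n",
              length(x$wells), nrow(x$device_log), format(x$seed)))
  print(x$ground_truth)
  invisible(x)
}

#' Write a plate to disk
#'
#' One directory per well holding zero-padded 8-bit RGB PNG frames
#' (`frame_000001.png`, ...), plus `temperature_log.csv` (columns
#' `frame_index`, `time_s`, `device_temp_C`, `sample_temp_C`) and
#' `ground_truth.csv`.
#'
#' @param plate A `well_plate`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "well_plate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sq in plate$wells) {
    wdir <- file.path(dir, sq$well_id)
    dir.create(wdir, showWarnings = FALSE)
    for (i in seq_along(sq$frames)) {
      png::writePNG(sq$frames[[i]] / 255,
                    file.path(wdir, sprintf("frame_%06d.png", i)))
    }
  }
  log <- plate$device_log
  log <- tibble(frame_index = log$frame, time_s = log$time_s,
                device_temp_C = log$device_temp_C,
                sample_temp_C = plate$wells[[1]]$sample_temp_C)
  utils::write.csv(log, file.path(dir, "temperature_log.csv"),
                   row.names = FALSE)
  utils::write.csv(plate$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a well's frame stack from disk
#'
#' Counterpart of [write_plate()] for user-supplied imagery: reads the PNG
#' frames of one well directory together with the plate's temperature log.
#'
#' @param dir Plate directory.
#' @param well_id Well subdirectory name.
#' @return A `frame_sequence` (without a `spec`; `sample_temp_C` only if
#'   the log has it).
#' @export
read_well_sequence <- function(dir, well_id) {
  wdir <- file.path(dir, well_id)
  files <- sort(list.files(wdir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) abort(sprintf("No frames found under %s.", wdir))
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    arr <- array(as.integer(round(img[, , 1:3] * 255)), dim = c(dim(img)[1:2], 3))
    arr
  })
  log <- utils::read.csv(file.path(dir, "temperature_log.csv"))
  stopifnot(nrow(log) == length(frames))
  structure(
    list(frames = frames,
         capture_interval = if (nrow(log) > 1) diff(log$time_s[1:2]) else NA_real_,
         time_s = log$time_s, device_temp_C = log$device_temp_C,
         sample_temp_C = log$sample_temp_C %||% NULL, well_id = well_id,
         spec = NULL),
    class = "frame_sequence"
  )
}
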