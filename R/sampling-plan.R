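#' Camera intervals supported by the acquisition camera
#'
#' The time-lapse camera used for plate monitoring only supports a fixed set
#' of seconds-per-image settings, which is why the temperature sampling per
#' image can only approximately be matched across cooling rates.
#'
#' @export
allowed_capture_intervals <- c(1, 5, 10, 20, 30, 60)

#' Number of images captured over a cooling ramp
#'
#' For a linear ramp from `start_temp` to `end_temp` at `rate`, a camera
#' firing every `sec_per_image` seconds captures
#' `floor((start_temp - end_temp) / rate * 60 / sec_per_image)` images after
#' the initial frame. A 15 to -40 degC ramp at 0.1 degC/min with a 10 s
#' interval gives 3300 images.
#'
#' @param start_temp,end_temp Ramp start and end temperatures (degC);
#'   `start_temp` must exceed `end_temp` (cooling).
#' @param rate Cooling rate in degC per minute (> 0).
#' @param sec_per_image Seconds between consecutive images (> 0).
#' @return Integer image count (excluding the frame at t = 0).
#' @seealso [degrees_per_image()], [choose_interval()], [sampling_plan()]
#' @examples
#' images_for_ramp(15, -40, 0.1, 10) # 3300
#' @export
images_for_ramp <- function(start_temp, end_temp, rate, sec_per_image) {
  if (any(start_temp <= end_temp)) {
    abort("`start_temp` must be greater than `end_temp` (cooling ramp).")
  }
  if (any(rate <= 0)) abort("`rate` must be positive.")
  if (any(sec_per_image <= 0)) abort("`sec_per_image` must be positive.")
  as.integer(floor((start_temp - end_temp) / rate * 60 / sec_per_image))
}

#' Temperature change per captured image
#'
#' The ramp span divided by the number of captured images; for ramps whose
#' duration is an exact multiple of the capture interval this equals
#' `rate / 60 * sec_per_image`. The exact value is returned; reports in this
#' field conventionally round it half away from zero to two decimals (e.g.
#' 0.0167 -> 0.02), which [round_degrees()] reproduces.
#'
#' @inheritParams images_for_ramp
#' @return Temperature step per image in degC (exact, unrounded).
#' @examples
#' degrees_per_image(15, -40, 0.5, 10) # 0.0833...
#' round_degrees(degrees_per_image(15, -40, 0.5, 10)) # 0.08
#' @export
degrees_per_image <- function(start_temp, end_temp, rate, sec_per_image) {
  (start_temp - end_temp) /
    images_for_ramp(start_temp, end_temp, rate, sec_per_image)
}

#' @rdname degrees_per_image
#' @param x Numeric values to round.
#' @param digits Decimal places (default 2).
#' @export
round_degrees <- function(x, digits = 2) {
  # round half away from zero, the convention of the printed 0.02/0.03/...
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Choose the camera interval that best matches a target sampling density
#'
#' Picks the member of `allowed` minimizing the absolute difference between
#' the achieved degrees-per-image (`rate / 60 * s`) and `target`. Ties are
#' broken toward the larger interval, which produces less data.
#'
#' @param rate Cooling rate (degC/min, > 0).
#' @param target Target temperature step per image (degC, > 0).
#' @param allowed Candidate seconds-per-image settings.
#' @return One element of `allowed`.
#' @examples
#' choose_interval(0.1, 0.05) # 30
#' @export
choose_interval <- function(rate, target,
                            allowed = allowed_capture_intervals) {
  if (rate <= 0) abort("`rate` must be positive.")
  if (target <= 0) abort("`target` must be positive.")
  achieved <- rate / 60 * allowed
  dev <- abs(achieved - target)
  candidates <- allowed[dev == min(dev)]
  max(candidates)
}

#' Tabulate a sampling plan across cooling rates
#'
#' One row per cooling rate with the interval used, image count over the
#' ramp, and the exact and conventionally rounded degrees per image.
#'
#' @param rates Cooling rates (degC/min).
#' @param sec_per_image Seconds per image for each rate; recycled if length
#'   one. If `NULL`, chosen by [choose_interval()] against `target`.
#' @param start_temp,end_temp Ramp limits (degC).
#' @param target Target degC per image used when `sec_per_image` is `NULL`.
#' @return A tibble with columns `rate`, `sec_per_image`, `n_images`,
#'   `degC_per_image`, `degC_per_image_reported`.
#' @examples
#' sampling_plan(c(0.1, 0.2, 0.3, 0.4, 0.5),
#'               sec_per_image = c(30, 10, 10, 10, 10))
#' @export
sampling_plan <- function(rates, sec_per_image = NULL,
                          start_temp = 15, end_temp = -40, target = 0.05) {
  if (is.null(sec_per_image)) {
    sec_per_image <- vapply(rates, choose_interval, numeric(1),
                            target = target)
  } else if (length(sec_per_image) == 1L) {
    sec_per_image <- rep(sec_per_image, length(rates))
  }
  stopifnot(length(sec_per_image) == length(rates))
  n <- mapply(images_for_ramp, rate = rates, sec_per_image = sec_per_image,
              MoreArgs = list(start_temp = start_temp, end_temp = end_temp))
  d <- mapply(degrees_per_image, rate = rates, sec_per_image = sec_per_image,
              MoreArgs = list(start_temp = start_temp, end_temp = end_temp))
  tibble(
    rate = rates,
    sec_per_image = as.numeric(sec_per_image),
    n_images = as.integer(n),
    degC_per_image = d,
    degC_per_image_reported = round_degrees(d)
  )
}

#' Equivalent spherical diameter of a well volume
#'
#' Diameter of a perfect sphere holding `volume` microliters, in
#' micrometers: `d = (6 V / pi)^(1/3)` with 1 uL = 1e9 um^3. Used to relate
#' well volumes to the droplet diameters of the freezing-assay literature;
#' the 5-24 uL working range corresponds to roughly 2000-5000 um.
#'
#' @param volume Sample volume in microliters (> 0).
#' @return Diameter in micrometers.
#' @examples
#' equivalent_sphere_diameter(c(5, 24))
#' @export
equivalent_sphere_diameter <- function(volume) {
  if (any(volume <= 0)) abort("`volume` must be positive.")
  (6 * volume * 1e9 / pi)^(1 / 3)
}
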