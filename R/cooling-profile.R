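#' Programmed cooling profile of the cryogenic device
#'
#' Describes the temperature trajectory the device is programmed to run: a
#' linear ramp from `start_temp` down to `end_temp` at `rate`, optionally
#' pausing at intermediate hold temperatures, imaged every
#' `capture_interval` seconds. The default mirrors the standard cloud-point
#' run: 15 to -40 degC at 0.5 degC/min with one image every 10 s.
#'
#' @param start_temp Ramp start (degC); must exceed `end_temp`.
#' @param end_temp Ramp end (degC).
#' @param rate Cooling rate (degC/min, > 0).
#' @param capture_interval Seconds per image. The acquisition camera only
#'   supports `r paste(allowed_capture_intervals, collapse = ", ")` s; other
#'   values are accepted (for synthetic work) with a warning.
#' @param holds Optional holds: a data frame with columns `temp` (degC) and
#'   `duration` (s), or a list of `c(temp, duration)` pairs. Hold
#'   temperatures must lie within `[end_temp, start_temp]`.
#' @return A `cooling_profile` object.
#' @examples
#' cooling_profile(15, -40, rate = 0.1, capture_interval = 10)
#' @export
cooling_profile <- function(start_temp = 15, end_temp = -40, rate = 0.5,
                            capture_interval = 10, holds = NULL) {
  if (start_temp <= end_temp) {
    abort("`start_temp` must be greater than `end_temp` (zero-length or heating ramp).")
  }
  if (rate <= 0) abort("`rate` must be positive.")
  if (capture_interval <= 0) abort("`capture_interval` must be positive.")
  if (!capture_interval %in% allowed_capture_intervals) {
    warn(paste0("`capture_interval` = ", capture_interval,
                " s is not a setting of the reference camera (",
                paste(allowed_capture_intervals, collapse = ", "), " s)."))
  }
  if (!is.null(holds)) {
    if (is.list(holds) && !is.data.frame(holds)) {
      holds <- do.call(rbind, lapply(holds, function(h) {
        data.frame(temp = h[[1]], duration = h[[2]])
      }))
    }
    holds <- as_tibble(holds)
    stopifnot(all(c("temp", "duration") %in% names(holds)))
    if (any(holds$temp > start_temp | holds$temp < end_temp)) {
      abort("Hold temperatures must lie within [end_temp, start_temp].")
    }
    if (any(holds$duration < 0)) abort("Hold durations must be non-negative.")
    holds <- dplyr::arrange(holds, dplyr::desc(.data$temp))
  }
  structure(
    list(start_temp = start_temp, end_temp = end_temp, rate = rate,
         capture_interval = capture_interval, holds = holds),
    class = "cooling_profile"
  )
}

#' @export
print.cooling_profile <- function(x, ...) {
  cat(sprintf("<cooling_profile> %g -> %g degC at %g degC/min, %g s/frame",
              x$start_temp, x$end_temp, x$rate, x$capture_interval))
  if (!is.null(x$holds)) cat(sprintf(", %d hold(s)", nrow(x$holds)))
  cat("\n")
  invisible(x)
}

#' Total duration of a cooling profile
#'
#' Ramp time (`span / rate * 60`) plus the summed hold durations.
#'
#' @param profile A [cooling_profile()].
#' @return Duration in seconds.
#' @export
profile_duration <- function(profile) {
  stopifnot(inherits(profile, "cooling_profile"))
  ramp <- (profile$start_temp - profile$end_temp) / profile$rate * 60
  ramp + if (is.null(profile$holds)) 0 else sum(profile$holds$duration)
}

#' Device temperature at each captured frame
#'
#' Evaluates the programmed trajectory on the capture grid: a linear ramp at
#' `rate`, pausing at each hold, sampled every `capture_interval` seconds
#' starting at t = 0. The first value is `start_temp`; when the total
#' duration is a multiple of the capture interval (as in all the standard
#' profiles) the final value is `end_temp`.
#'
#' @param profile A [cooling_profile()].
#' @return A tibble with columns `frame` (1-based), `time_s`,
#'   `device_temp_C`.
#' @examples
#' log <- simulate_device_temperature(
#'   cooling_profile(15, -40, rate = 0.1, capture_interval = 10))
#' nrow(log) # 3301: the initial frame plus 3300 images
#' @export
simulate_device_temperature <- function(profile) {
  stopifnot(inherits(profile, "cooling_profile"))
  total <- profile_duration(profile)
  # knots of the piecewise-linear time -> temperature map
  kt <- 0
  kT <- profile$start_temp
  elapsed_hold <- 0
  if (!is.null(profile$holds)) {
    for (i in seq_len(nrow(profile$holds))) {
      h_temp <- profile$holds$temp[i]
      h_dur <- profile$holds$duration[i]
      arrive <- (profile$start_temp - h_temp) / profile$rate * 60 + elapsed_hold
      kt <- c(kt, arrive, arrive + h_dur)
      kT <- c(kT, h_temp, h_temp)
      elapsed_hold <- elapsed_hold + h_dur
    }
  }
  kt <- c(kt, total)
  kT <- c(kT, profile$end_temp)
  keep <- !duplicated(cbind(kt, kT))
  kt <- kt[keep]; kT <- kT[keep]
  times <- seq(0, total, by = profile$capture_interval)
  temp <- stats::approx(kt, kT, xout = times, ties = "ordered")$y
  tibble(frame = seq_along(times), time_s = times, device_temp_C = temp)
}

.lag_calibration <- 1 / 15 # uL/s; 24 uL at 0.5 degC/min -> 3 degC offset

#' First-order thermal-lag parameters
#'
#' The sample inside a well does not follow the device temperature
#' instantaneously: it relaxes toward it at a rate `k` (1/s), so
#' `dT_sample/dt = k (T_device - T_sample)`. On a linear ramp of slope
#' `-r` the sample settles `r/k` degC above the device - the mechanism
#' that makes detected cloud points *apparent*: faster ramps and larger
#' volumes (smaller `k`) push the device reading further below the sample.
#' At nucleation the latent heat of fusion is released, modeled as an
#' additive exponential pulse on the sample temperature.
#'
#' When `lag_coefficient` is not given it is derived from the volume as
#' `k = c / volume` with `c` calibrated so a 24 uL sample on a 0.5 degC/min
#' ramp sits about 3 degC above the device reading. The scaling is
#' illustrative (thermal mass grows with volume), not a fitted model.
#'
#' @param volume Sample volume (uL, > 0).
#' @param lag_coefficient Relaxation rate `k` (1/s); overrides the
#'   volume-derived value.
#' @param latent_heat_magnitude Peak transient rise at nucleation (degC).
#' @param latent_heat_duration e-folding time of the pulse decay (s).
#' @return A `thermal_lag` object.
#' @examples
#' thermal_lag(volume = 24)
#' @export
thermal_lag <- function(volume = 20, lag_coefficient = NULL,
                        latent_heat_magnitude = 5,
                        latent_heat_duration = 60) {
  if (volume <= 0) abort("`volume` must be positive.")
  k <- lag_coefficient %||% (.lag_calibration / volume)
  if (k <= 0) abort("`lag_coefficient` must be positive.")
  structure(
    list(lag_coefficient = k, volume = volume,
         latent_heat_magnitude = latent_heat_magnitude,
         latent_heat_duration = latent_heat_duration),
    class = "thermal_lag"
  )
}

#' @export
print.thermal_lag <- function(x, ...) {
  cat(sprintf("<thermal_lag> k = %.4g 1/s (volume %g uL), latent pulse %g degC / %g s\n",
              x$lag_coefficient, x$volume,
              x$latent_heat_magnitude, x$latent_heat_duration))
  invisible(x)
}

#' Sample temperature under first-order thermal lag
#'
#' Forward (explicit Euler) integration of
#' `dT_sample/dt = k (T_device - T_sample)` on the capture grid,
#' initialized at the first device temperature. Explicit Euler is adequate
#' here because `k * dt` is far below 1 for realistic volumes and capture
#' intervals; the integration refuses to run outside its monotone-stability
#' bound `k * dt <= 1`.
#'
#' If `true_t_nuc` is given, the frame where the sample first cools through
#' it is taken as the nucleation frame and a latent-heat pulse
#' `magnitude * exp(-(t - t_nuc) / duration)` is superimposed from that
#' frame on.
#'
#' @param device_temps Device temperature per frame (degC).
#' @param lag A [thermal_lag()].
#' @param capture_interval Seconds between frames.
#' @param true_t_nuc Optional nucleation temperature (degC) wiring the
#'   latent-heat pulse.
#' @return Numeric vector of sample temperatures, one per frame, with
#'   attribute `nucleation_frame` (NA if no crossing / no `true_t_nuc`).
#' @examples
#' log <- simulate_device_temperature(cooling_profile())
#' ts <- simulate_sample_temperature(log$device_temp_C, thermal_lag(24), 10)
#' max(ts - log$device_temp_C) # approaches rate / (60 k)
#' @export
simulate_sample_temperature <- function(device_temps, lag, capture_interval,
                                        true_t_nuc = NULL) {
  stopifnot(inherits(lag, "thermal_lag"))
  n <- length(device_temps)
  if (n == 0) abort("`device_temps` must be non-empty.")
  k <- lag$lag_coefficient
  dt <- capture_interval
  if (k * dt > 1) {
    abort(sprintf(
      "Explicit Euler requires k * dt <= 1 (got %.3g); use a finer capture interval.",
      k * dt))
  }
  ts <- numeric(n)
  ts[1] <- device_temps[1]
  for (i in seq_len(n - 1)) {
    ts[i + 1] <- ts[i] + k * (device_temps[i] - ts[i]) * dt
  }
  nuc_frame <- NA_integer_
  if (!is.null(true_t_nuc) && !is.na(true_t_nuc)) {
    hit <- which(ts <= true_t_nuc)
    if (length(hit)) {
      nuc_frame <- hit[1]
      t_rel <- (seq_len(n) - nuc_frame) * dt
      pulse <- ifelse(t_rel >= 0,
                      lag$latent_heat_magnitude *
                        exp(-t_rel / lag$latent_heat_duration),
                      0)
      ts <- ts + pulse
    }
  }
  attr(ts, "nucleation_frame") <- nuc_frame
  ts
}
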