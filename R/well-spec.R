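.spot_brightness <- 0.95   # specular reflection intensity (fraction)
.speckle_depth_cap <- 20   # degC below clouding after which speckle saturates

#' Ground truth for one synthetic well
#'
#' Describes what a synthetic well contains and how it looks through the
#' three optical regimes the pipeline must distinguish:
#'
#' * clear (above the cloud point): uniform background at `base_brightness`
#'   with a bright specular reflection covering `reflection_fraction` of the
#'   well area - the reflection is what a transparent, sealed well shows to
#'   the camera;
#' * turbid (between cloud point and nucleation, protein wells only): the
#'   reflection is lost and the background darkens by `turbidity_darkening`,
#'   while pixel speckle grows with depth below the cloud point
#'   (`speckle_gain` multiplies `noise_sd` per degC, capped) - coarsening
#'   of the dense phase slowly raises the count of stray bright pixels;
#' * frozen (below nucleation): uniform `ice_brightness`. Protein and
#'   buffer wells freeze white (bright, above the usual white levels), water
#'   wells freeze to gray ice (dark), which is why their white-pixel traces
#'   move in opposite directions at nucleation.
#'
#' The clouding transition is rendered over a finite temperature width
#' (default 1 degC, linear interpolation of the optical state) so detection
#' operators see a ramp rather than a step; set `transition_width = 0` for
#' step-response tests.
#'
#' @param kind One of `"protein"`, `"buffer"`, `"water"`.
#' @param true_t_cloud True clouding temperature (degC); protein wells only
#'   (default 4 degC), `NA` otherwise.
#' @param true_t_nuc True nucleation temperature (degC). Defaults: -20 for
#'   protein/buffer, -30 for water (solute-free wells supercool deeper).
#' @param base_brightness Clear-state background intensity fraction.
#' @param reflection_fraction Fraction of well area under the specular spot.
#' @param turbidity_darkening Background intensity drop once fully turbid.
#' @param ice_brightness Frozen-state intensity fraction; defaults 0.92
#'   (white ice) for protein/buffer and 0.35 (gray ice) for water.
#' @param noise_sd Gaussian pixel noise, intensity fraction.
#' @param speckle_gain Growth of the turbid-state noise multiplier per degC
#'   below the completed transition.
#' @param transition_width Temperature width of the clouding transition
#'   (degC, >= 0).
#' @param tint Length-3 RGB multipliers; the default `c(1, 1, 1)` renders
#'   achromatic wells (all described signals are luminance phenomena); a
#'   chromatic tint exercises the per-channel mean levels.
#' @return A `well_spec` object.
#' @examples
#' well_spec("protein", true_t_cloud = 5)
#' well_spec("water")
#' @export
well_spec <- function(kind = c("protein", "buffer", "water"),
                      true_t_cloud = NULL, true_t_nuc = NULL,
                      base_brightness = 0.45, reflection_fraction = 0.05,
                      turbidity_darkening = 0.01, ice_brightness = NULL,
                      noise_sd = 0.02, speckle_gain = 0.075,
                      transition_width = 1, tint = c(1, 1, 1)) {
  kind <- match.arg(kind)
  true_t_cloud <- true_t_cloud %||% if (kind == "protein") 4 else NA_real_
  true_t_nuc <- true_t_nuc %||% if (kind == "water") -30 else -20
  ice_brightness <- ice_brightness %||% if (kind == "water") 0.35 else 0.92
  if (kind != "protein" && !is.na(true_t_cloud)) {
    abort("Only protein wells have a cloud point; leave `true_t_cloud` unset.")
  }
  if (!is.na(true_t_cloud) && true_t_cloud <= true_t_nuc) {
    abort("`true_t_cloud` must be greater than `true_t_nuc`.")
  }
  fracs <- c(base_brightness = base_brightness,
             reflection_fraction = reflection_fraction,
             turbidity_darkening = turbidity_darkening,
             ice_brightness = ice_brightness, noise_sd = noise_sd)
  if (any(fracs < 0 | fracs > 1)) {
    abort("Intensity fractions must lie in [0, 1].")
  }
  if (transition_width < 0) abort("`transition_width` must be >= 0.")
  stopifnot(length(tint) == 3, all(tint >= 0), all(tint <= 1))
  structure(
    list(kind = kind, true_t_cloud = true_t_cloud, true_t_nuc = true_t_nuc,
         base_brightness = base_brightness,
         reflection_fraction = reflection_fraction,
         turbidity_darkening = turbidity_darkening,
         ice_brightness = ice_brightness, noise_sd = noise_sd,
         speckle_gain = speckle_gain, transition_width = transition_width,
         tint = tint),
    class = "well_spec"
  )
}

#' @export
print.well_spec <- function(x, ...) {
  cat(sprintf("<well_spec> %s: T_cloud = %s, T_nuc = %g degC\n", x$kind,
              if (is.na(x$true_t_cloud)) "-" else format(x$true_t_cloud),
              x$true_t_nuc))
  invisible(x)
}

#' Replicate a well specification
#'
#' @param spec A [well_spec()].
#' @param n Number of technical replicates.
#' @return List of `n` identical specs.
#' @export
replicate_specs <- function(spec, n = 6) {
  stopifnot(inherits(spec, "well_spec"), n >= 1)
  rep(list(spec), n)
}

# Optical state of a well at one sample temperature.
# `frozen` latches freezing across the latent-heat re-warming; when NULL it
# is inferred from the instantaneous temperature.
optical_state <- function(spec, sample_temp, frozen = NULL) {
  frozen <- frozen %||% (sample_temp <= spec$true_t_nuc)
  if (frozen) {
    return(list(background = spec$ice_brightness, spot = NA_real_,
                noise_mult = 1))
  }
  cloudy <- !is.na(spec$true_t_cloud) && sample_temp < spec$true_t_cloud
  if (!cloudy) {
    return(list(background = spec$base_brightness, spot = .spot_brightness,
                noise_mult = 1))
  }
  w <- spec$transition_width
  p <- if (w > 0) min(1, (spec$true_t_cloud - sample_temp) / w) else 1
  turbid_bg <- spec$base_brightness - spec$turbidity_darkening
  bg <- (1 - p) * spec$base_brightness + p * turbid_bg
  spot <- if (p < 1) (1 - p) * .spot_brightness + p * turbid_bg else NA_real_
  depth <- max(0, (spec$true_t_cloud - w) - sample_temp)
  mult <- 1 + spec$speckle_gain * min(depth, .speckle_depth_cap)
  list(background = bg, spot = spot, noise_mult = mult)
}

# Row/column indices of the specular spot for a raster of size dims.
spot_mask <- function(dims, reflection_fraction) {
  if (reflection_fraction <= 0) return(matrix(FALSE, dims[1], dims[2]))
  r <- sqrt(reflection_fraction * dims[1] * dims[2] / pi)
  cy <- 0.35 * dims[1]
  cx <- 0.35 * dims[2]
  row <- matrix(seq_len(dims[1]), dims[1], dims[2])
  col <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (row - cy)^2 + (col - cx)^2 <= r^2
}

#' Render one well frame
#'
#' Produces an 8-bit RGB raster of a well at the given sample temperature,
#' according to the optical model documented in [well_spec()]. Gaussian
#' pixel noise with sd `noise_sd` (times the turbid-state speckle
#' multiplier) is shared across channels - the rendered scene is a
#' luminance field - then the `tint` multipliers are applied per channel
#' and the result is clipped to 0-255. With `noise_sd = 0` rendering is
#' deterministic.
#'
#' @param spec A [well_spec()].
#' @param sample_temp Sample temperature (degC).
#' @param dims Raster height and width (each >= 16).
#' @param frozen Optional logical overriding the frozen state (used by the
#'   sequence generator to latch freezing through the latent-heat pulse).
#' @return Integer array `dims[1] x dims[2] x 3` with values 0-255.
#' @examples
#' fr <- render_well_frame(well_spec("protein"), 10)
#' dim(fr)
#' @export
render_well_frame <- function(spec, sample_temp, dims = c(64, 64),
                              frozen = NULL) {
  stopifnot(inherits(spec, "well_spec"))
  if (any(dims < 16)) abort("Raster size must be at least 16 x 16.")
  st <- optical_state(spec, sample_temp, frozen)
  intensity <- matrix(st$background, dims[1], dims[2])
  if (!is.na(st$spot)) {
    intensity[spot_mask(dims, spec$reflection_fraction)] <- st$spot
  }
  if (spec$noise_sd > 0) {
    intensity <- intensity +
      rnorm(length(intensity), 0, spec$noise_sd * st$noise_mult)
  }
  frame <- array(0L, c(dims, 3L))
  for (ch in 1:3) {
    v <- round(intensity * spec$tint[ch] * 255)
    frame[, , ch] <- pmax(0L, pmin(255L, as.integer(v)))
  }
  frame
}
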