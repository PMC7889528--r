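#' Convert an RGB raster to gray
#'
#' Per-pixel luminance with the ITU-R BT.601 weights (0.2989, 0.5870,
#' 0.1140) rounded to the nearest integer in 0-255 - the convention of the
#' classic MATLAB-style `rgb2gray` conversion this field's image work uses.
#'
#' @param frame Integer array `H x W x 3`, values 0-255.
#' @return Integer matrix `H x W`.
#' @examples
#' to_gray(render_well_frame(well_spec("water", noise_sd = 0), 10))[1, 1]
#' @export
to_gray <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3) {
    abort("`frame` must be an H x W x 3 RGB raster.")
  }
  g <- 0.2989 * frame[, , 1] + 0.5870 * frame[, , 2] + 0.1140 * frame[, , 3]
  matrix(as.integer(round(g)), d[1], d[2])
}

#' Mean pixel level of a well image
#'
#' Arithmetic mean of the selected channel of the cropped well image; the
#' gray channel goes through [to_gray()]. These are the MGL/MRL/MGrL/MBL
#' statistics of the mean-color-level strategy.
#'
#' @param frame RGB raster.
#' @param channel `"gray"`, `"red"`, `"green"` or `"blue"`.
#' @return Scalar mean on the 0-255 scale.
#' @export
mean_level <- function(frame, channel = c("gray", "red", "green", "blue")) {
  channel <- match.arg(channel)
  if (channel == "gray") return(mean(to_gray(frame)))
  ch <- match(channel, c("red", "green", "blue"))
  mean(frame[, , ch])
}

#' Otsu threshold of a gray image
#'
#' Exhaustive search over the 256-bin histogram for the threshold
#' maximizing the between-class variance (equivalently, minimizing the
#' within-class variance), the classic optimal black/white separation.
#' Candidate thresholds `t` split pixels into `value < t` versus
#' `value >= t` for `t = 1..255`; the returned level is `t / 255`, so a
#' pixel is white when its normalized intensity exceeds the level (see
#' [binarize()]). Ties are broken toward the lower threshold. A constant
#' image has no separation; its own normalized value is returned so blank
#' wells do not error.
#'
#' @param gray Integer matrix of values 0-255 (see [to_gray()]).
#' @return Threshold level in `[0, 1]`.
#' @examples
#' g <- matrix(c(50, 200), 16, 16)
#' otsu_threshold(g) * 255
#' @export
otsu_threshold <- function(gray) {
  if (!length(gray)) abort("`gray` must be non-empty.")
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  n <- sum(counts)
  vals <- 0:255
  if (sum(counts > 0) == 1) return(vals[counts > 0] / 255)
  # cumulative weight and mean of the lower class (values < t)
  w0 <- cumsum(counts)[1:255]          # t = 1..255
  s0 <- cumsum(counts * vals)[1:255]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(counts * vals) - s0) / w1, 0)
  between <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- 0
  t <- which.max(between)              # first max: lower threshold on ties
  t / 255
}

#' White-level specification
#'
#' How the black/white separation level of the white-pixel count is chosen:
#' a fixed level in (0, 1), the Otsu threshold of the well's first (t0)
#' frame, or the mean gray intensity of the t0 frame divided by 255. The
#' data-dependent modes resolve per well, from that well's first frame
#' only.
#'
#' @param mode `"fixed"`, `"otsu_t0"` or `"mean_gray_t0"`.
#' @param value Fixed level in (0, 1) (fixed mode only).
#' @return A `white_level_spec`.
#' @examples
#' white_level_spec("fixed", 0.5)
#' white_level_spec("otsu_t0")
#' @export
white_level_spec <- function(mode = c("fixed", "otsu_t0", "mean_gray_t0"),
                             value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(value) || value <= 0 || value >= 1) {
      abort("Fixed white levels must lie strictly inside (0, 1).")
    }
  } else if (!is.null(value)) {
    abort("`value` only applies to fixed white levels.")
  }
  structure(list(mode = mode, value = value), class = "white_level_spec")
}

#' Resolve a white level against a well's first frame
#'
#' @param spec A [white_level_spec()].
#' @param first_frame The t0 RGB frame of the same well (required for the
#'   data-dependent modes).
#' @return Level in `[0, 1]`.
#' @export
resolve_white_level <- function(spec, first_frame = NULL) {
  stopifnot(inherits(spec, "white_level_spec"))
  switch(spec$mode,
    fixed = spec$value,
    otsu_t0 = otsu_threshold(to_gray(first_frame)),
    mean_gray_t0 = mean_level(first_frame, "gray") / 255
  )
}

#' Binarize a gray image at a white level
#'
#' A pixel is white iff its normalized intensity `value / 255` strictly
#' exceeds `level`. The comparison is strict at the threshold; boundary
#' pixels flip between conventions, so the choice is fixed and documented.
#'
#' @param gray Integer matrix 0-255.
#' @param level White level in `[0, 1]`.
#' @return Logical matrix (TRUE = white).
#' @export
binarize <- function(gray, level) {
  if (level < 0 || level > 1) abort("`level` must lie in [0, 1].")
  gray / 255 > level
}

#' Count white pixels
#'
#' @param binary Logical raster from [binarize()].
#' @return Integer count.
#' @export
total_white_pixels <- function(binary) {
  as.integer(sum(binary))
}

#' Total intensity difference between two frames
#'
#' Image dissimilarity versus a reference frame (conventionally the first,
#' t0, frame of the well): by default the sum over all pixels and channels
#' of the absolute intensity difference, which is non-negative and
#' sign-free. `variant = "signed_gray"` instead sums the signed gray-level
#' differences (it can be negative and cancels opposing changes; kept for
#' comparison with mean-level-style analyses).
#'
#' @param frame,reference_frame RGB rasters of identical shape.
#' @param variant `"abs_rgb"` (default) or `"signed_gray"`.
#' @return Scalar.
#' @examples
#' f <- render_well_frame(well_spec("protein", noise_sd = 0), 10)
#' total_intensity_difference(f, f) # 0
#' @export
total_intensity_difference <- function(frame, reference_frame,
                                       variant = c("abs_rgb", "signed_gray")) {
  variant <- match.arg(variant)
  if (!identical(dim(frame), dim(reference_frame))) {
    abort("`frame` and `reference_frame` must have identical shape.")
  }
  if (variant == "abs_rgb") {
    sum(abs(frame - reference_frame))
  } else {
    sum(as.numeric(to_gray(frame)) - as.numeric(to_gray(reference_frame)))
  }
}
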