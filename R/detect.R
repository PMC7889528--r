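#' Moving-mean smoothing of a trace
#'
#' Centered moving mean with a window of `max(1, round(window_fraction *
#' n))` points, truncated (not padded) at the edges. The standard window is
#' 5 % of the data points; 2.5 % is the documented fallback for noisier
#' runs. For a window of `W` points the mean at frame `i` covers frames
#' `i - floor((W-1)/2)` through `i + floor(W/2)` (clipped to the trace).
#'
#' The window geometry is recorded on the result
#' (`attr(, "smooth_window")`, `attr(, "smooth_lag")`,
#' `attr(, "smooth_lead")`): the detectors use it to compensate the known
#' delay with which one-sided features (plateau entries, flattenings) show
#' up in a box-smoothed trace.
#'
#' @param trace A `cp_trace` tibble (see [new_trace()], [extract_trace()]).
#' @param window_fraction Fraction of the trace length in (0, 0.5].
#' @return The smoothed trace.
#' @export
smooth_trace <- function(trace, window_fraction = 0.05) {
  if (!nrow(trace)) abort("Cannot smooth an empty trace.")
  if (window_fraction <= 0 || window_fraction > 0.5) {
    abort("`window_fraction` must lie in (0, 0.5].")
  }
  x <- trace$value
  n <- length(x)
  w <- max(1L, as.integer(round(window_fraction * n)))
  hb <- (w - 1L) %/% 2L
  ha <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hb, 1L)
  hi <- pmin(seq_len(n) + ha, n)
  out <- trace
  out$value <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  attr(out, "smooth_window") <- w
  attr(out, "smooth_lag") <- hb
  attr(out, "smooth_lead") <- ha
  attr(out, "white_level") <- attr(trace, "white_level")
  # noise floors are defined on the unsmoothed series; keep it available
  attr(out, "raw_values") <- attr(trace, "raw_values") %||% x
  out
}

# window geometry of a (possibly unsmoothed) trace
smooth_geometry <- function(trace) {
  list(lag = attr(trace, "smooth_lag") %||% 0L,
       lead = attr(trace, "smooth_lead") %||% 0L,
       window = attr(trace, "smooth_window") %||% 1L)
}

# forward differences d[i] = x[i] - x[i-1], attributed to frame i (d[1] = NA)
trace_gradient <- function(values) {
  c(NA_real_, diff(values))
}

# robust noise scale: median absolute successive difference of the
# unsmoothed trace over the searched region (falls back to the trace as
# given when it was never smoothed)
noise_scale <- function(values) {
  d <- diff(values)
  if (!length(d)) return(0)
  median(abs(d))
}

raw_noise_scale <- function(trace, n_keep = nrow(trace)) {
  raw <- attr(trace, "raw_values") %||% trace$value
  noise_scale(raw[seq_len(min(n_keep, length(raw)))])
}

# Noise floor for first-difference peaks: a W-point box mean divides the
# first difference of both a sharp event and the frame noise by W, so the
# raw-scale msd must be scaled by the window before comparing.
gradient_noise_floor <- function(trace, mult, n_keep = nrow(trace)) {
  mult * raw_noise_scale(trace, n_keep) / smooth_geometry(trace)$window
}

detection_row <- function(trace, method, t_cloud = NA_real_,
                          t_nuc = NA_real_, diagnostics = list()) {
  out <- tibble(
    well_id = trace$well_id[1], strategy = trace$strategy[1],
    method = method, t_cloud_app_C = t_cloud, t_nuc_C = t_nuc,
    peak_slope_frame = NA_integer_, flattening_frame = NA_integer_,
    minimum_frame = NA_integer_, max_gradient_frame = NA_integer_,
    direction = NA_character_
  )
  for (nm in names(diagnostics)) out[[nm]] <- diagnostics[[nm]]
  out
}

#' Cloud-point detection on a TID trace
#'
#' The apparent cloud point is the temperature at which the sharp TID
#' increase flattens, i.e. where clouding is concluded: locate the global
#' maximum of the first difference, then the first subsequent frame whose
#' first difference falls below `flatten_fraction` of that peak slope. The
#' result is absent (NA) when the peak slope does not rise above
#' `noise_floor_mult` times the median absolute successive difference of
#' the unsmoothed trace (scaled by the smoothing window, which divides
#' first differences of signal and noise alike), or when the trace never
#' flattens.
#'
#' On a smoothed trace the flattening of the *smoothed* series trails the
#' underlying feature by the window lag recorded by [smooth_trace()]; the
#' reported frame is compensated accordingly (both frames are in the
#' diagnostics).
#'
#' @param trace A smoothed TID `cp_trace`.
#' @param search_end Optional frame index; only frames strictly before it
#'   are searched. Used to restrict the clouding search to pre-nucleation
#'   frames, where the far sharper freezing signal cannot capture the peak
#'   slope.
#' @param flatten_fraction Slope fraction defining "flattened"
#'   (default 0.10).
#' @param noise_floor_mult Noise-floor multiple (default 5).
#' @return One-row detection tibble (`t_cloud_app_C` is NA when absent).
#' @export
detect_tcloud_tid <- function(trace, search_end = NULL,
                              flatten_fraction = 0.10,
                              noise_floor_mult = 5) {
  geo <- smooth_geometry(trace)
  n_keep <- if (is.null(search_end) || is.na(search_end)) {
    nrow(trace)
  } else {
    min(nrow(trace), search_end - 1L)
  }
  if (n_keep < 3) return(detection_row(trace, "tid_flatten"))
  v <- trace$value[seq_len(n_keep)]
  d <- trace_gradient(v)
  # the reference frame's TID is 0 by identity, so the step up to the noise
  # baseline right after t0 is an artifact: skip gradients whose smoothing
  # window still touches the first frame
  d[seq_len(min(length(d), geo$lead + 2L))] <- NA_real_
  if (all(is.na(d))) return(detection_row(trace, "tid_flatten"))
  peak <- max(d, na.rm = TRUE)
  ip <- which.max(d)
  if (!is.finite(peak) ||
      peak <= gradient_noise_floor(trace, noise_floor_mult, n_keep)) {
    return(detection_row(trace, "tid_flatten"))
  }
  after <- which(d < flatten_fraction * peak & seq_along(d) > ip)
  if (!length(after)) return(detection_row(trace, "tid_flatten"))
  f_raw <- after[1]
  f <- max(1L, f_raw - geo$lag)
  detection_row(trace, "tid_flatten", t_cloud = trace$temp_C[f],
                diagnostics = list(peak_slope_frame = as.integer(ip),
                                   flattening_frame = as.integer(f)))
}

#' Cloud-point detection on a TWP trace
#'
#' The apparent cloud point is the minimum of the white-pixel trace - the
#' well is darkest once clouding has removed the specular reflection -
#' restricted to frames before `search_end` (conventionally the detected
#' nucleation frame, so that gray-ice minima of frozen wells cannot win).
#' Ties break to the earliest frame. Absent when the drop from the initial
#' plateau does not exceed `noise_floor_mult` times the median absolute
#' successive difference.
#'
#' @param trace A smoothed TWP `cp_trace`.
#' @param search_end Optional frame index bounding the search (exclusive).
#' @param noise_floor_mult Noise-floor multiple (default 5).
#' @return One-row detection tibble.
#' @export
detect_tcloud_twp <- function(trace, search_end = NULL,
                              noise_floor_mult = 5) {
  geo <- smooth_geometry(trace)
  n_keep <- if (is.null(search_end) || is.na(search_end)) {
    nrow(trace)
  } else {
    min(nrow(trace), search_end - 1L)
  }
  if (n_keep < 3) return(detection_row(trace, "twp_minimum"))
  v <- trace$value[seq_len(n_keep)]
  f_raw <- which.min(v) # first index on ties
  baseline <- median(v[seq_len(max(3L, geo$lag + 1L))])
  drop <- baseline - v[f_raw]
  if (drop <= noise_floor_mult * raw_noise_scale(trace, n_keep)) {
    return(detection_row(trace, "twp_minimum"))
  }
  f <- max(1L, f_raw - geo$lag)
  detection_row(trace, "twp_minimum", t_cloud = trace$temp_C[f],
                diagnostics = list(minimum_frame = as.integer(f)))
}

#' Ice-nucleation detection on a trace
#'
#' The nucleation temperature is the maximum gradient of the white-pixel
#' count: freezing turns protein and buffer wells abruptly white (TWP
#' increase) and water wells abruptly gray (TWP decrease), so `direction`
#' selects the maximum positive first difference, the maximum negative
#' one, or - `"auto"` - whichever has the larger magnitude.
#'
#' A single-frame step smoothed with a W-point box produces a W-frame
#' plateau of near-equal gradients; the reported frame is the midpoint of
#' the contiguous run of gradients within `plateau_fraction` of the peak,
#' which is unbiased for the step location (and exact on unsmoothed
#' traces). Absent when the peak gradient magnitude does not exceed
#' `noise_floor_mult` times the window-scaled median absolute successive
#' difference of the unsmoothed trace.
#'
#' @param trace A smoothed `cp_trace` (TWP by convention; TID freezing
#'   signals are also sharp and detectable with `direction = "increase"`).
#' @param direction `"auto"`, `"increase"` or `"decrease"`.
#' @param noise_floor_mult Noise-floor multiple (default 5).
#' @param plateau_fraction Run definition (default 0.9).
#' @return One-row detection tibble (`t_nuc_C` is NA when absent;
#'   diagnostics include the resolved direction).
#' @export
detect_tnuc <- function(trace, direction = c("auto", "increase", "decrease"),
                        noise_floor_mult = 5, plateau_fraction = 0.9) {
  direction <- match.arg(direction)
  geo <- smooth_geometry(trace)
  if (nrow(trace) < 3) return(detection_row(trace, "max_gradient"))
  d <- trace_gradient(trace$value)
  d[seq_len(min(length(d), geo$lead + 2L))] <- NA_real_
  if (all(is.na(d))) return(detection_row(trace, "max_gradient"))
  floor_ <- gradient_noise_floor(trace, noise_floor_mult)
  pick <- function(g) { # g: gradient oriented so the event is a max
    peak <- max(g, na.rm = TRUE)
    if (!is.finite(peak) || peak <= floor_ || peak <= 0) return(NULL)
    ip <- which.max(g)
    on_plateau <- !is.na(g) & g >= plateau_fraction * peak
    run <- ip
    while (run[1] > 2 && on_plateau[run[1] - 1]) run <- c(run[1] - 1, run)
    while (run[length(run)] < length(g) && on_plateau[run[length(run)] + 1]) {
      run <- c(run, run[length(run)] + 1)
    }
    list(frame = as.integer(round(mean(range(run)))), peak = peak)
  }
  up <- if (direction != "decrease") pick(d) else NULL
  down <- if (direction != "increase") pick(-d) else NULL
  res <- if (is.null(up) && is.null(down)) {
    NULL
  } else if (is.null(down) || (!is.null(up) && up$peak >= down$peak)) {
    c(up, dir = "increase")
  } else {
    c(down, dir = "decrease")
  }
  if (is.null(res)) return(detection_row(trace, "max_gradient"))
  out <- detection_row(trace, "max_gradient", t_nuc = trace$temp_C[res$frame],
                       diagnostics = list(max_gradient_frame = res$frame))
  out$direction <- res$dir
  out
}

#' Temperature of a frame on a sequence's logged grid
#'
#' Frames and temperatures are interchangeable grids on a linear ramp (an
#' image every `rate / 60 * capture_interval` degC); this helper returns
#' the logged device temperature at a frame index. Reported event
#' temperatures are device temperatures by convention - the instrument's
#' own reading, which is what makes them apparent.
#'
#' @param frame_index 1-based frame index.
#' @param sequence A `frame_sequence` or `cp_trace`.
#' @return Temperature (degC).
#' @export
frame_to_temperature <- function(frame_index, sequence) {
  temps <- if (inherits(sequence, "frame_sequence")) {
    sequence$device_temp_C
  } else {
    sequence$temp_C
  }
  if (any(frame_index < 1 | frame_index > length(temps))) {
    abort("`frame_index` out of range.")
  }
  temps[frame_index]
}

#' Detect clouding and nucleation events across a plate
#'
#' The standard per-well pipeline: extract each strategy's trace, smooth
#' it, detect nucleation first (TWP: `"auto"` direction; TID:
#' `"increase"`), then search for the cloud point on frames safely before
#' the nucleation signal (its smoothing window must not touch the freeze).
#' TID cloud points come from the flattening rule, TWP cloud points from
#' the trace minimum; mean-level strategies are extracted for comparison
#' but carry no event definition here.
#'
#' @param x A `well_plate`, a single `frame_sequence`, or a list of them.
#' @param strategies Strategy labels (see [extract_trace()]).
#' @param window_fraction Smoothing window fraction (default 0.05).
#' @param temperature `"device"` (instrument convention) or `"sample"`.
#' @param flatten_fraction,noise_floor_mult Detector settings.
#' @return A tibble with one row per well x strategy: `well_id`,
#'   `strategy`, `method`, `t_cloud_app_C`, `t_nuc_C` and frame
#'   diagnostics. The settings used are in `attr(, "settings")`.
#' @export
detect_events <- function(x, strategies = c("TID", "TWP:0.50"),
                          window_fraction = 0.05,
                          temperature = c("device", "sample"),
                          flatten_fraction = 0.10, noise_floor_mult = 5) {
  temperature <- match.arg(temperature)
  seqs <- if (inherits(x, "well_plate")) {
    x$wells
  } else if (inherits(x, "frame_sequence")) {
    list(x)
  } else {
    x
  }
  out <- purrr::map_dfr(seqs, function(sq) {
    purrr::map_dfr(strategies, function(s) {
      tr <- extract_trace(sq, s, temperature = temperature)
      detect_trace_events(tr, window_fraction = window_fraction,
                          flatten_fraction = flatten_fraction,
                          noise_floor_mult = noise_floor_mult)
    })
  })
  attr(out, "settings") <- list(
    strategies = strategies, window_fraction = window_fraction,
    temperature = temperature, flatten_fraction = flatten_fraction,
    noise_floor_mult = noise_floor_mult)
  out
}

#' @rdname detect_events
#' @param trace A raw (unsmoothed) `cp_trace` for one well and strategy.
#' @export
detect_trace_events <- function(trace, window_fraction = 0.05,
                                flatten_fraction = 0.10,
                                noise_floor_mult = 5) {
  sm <- smooth_trace(trace, window_fraction)
  geo <- smooth_geometry(sm)
  strategy <- trace$strategy[1]
  is_twp <- grepl("^TWP", strategy)
  is_tid <- strategy == "TID"
  if (!is_twp && !is_tid) {
    return(detection_row(trace, "none"))
  }
  nuc <- detect_tnuc(sm, direction = if (is_twp) "auto" else "increase",
                     noise_floor_mult = noise_floor_mult)
  search_end <- if (is.na(nuc$t_nuc_C)) {
    NA_integer_
  } else {
    # keep the smoothing window clear of the freeze step
    nuc$max_gradient_frame - as.integer(geo$window)
  }
  cloud <- if (is_tid) {
    detect_tcloud_tid(sm, search_end = search_end,
                      flatten_fraction = flatten_fraction,
                      noise_floor_mult = noise_floor_mult)
  } else {
    detect_tcloud_twp(sm, search_end = search_end,
                      noise_floor_mult = noise_floor_mult)
  }
  out <- cloud
  out$method <- paste0(cloud$method, "+", nuc$method)
  out$t_nuc_C <- nuc$t_nuc_C
  out$max_gradient_frame <- nuc$max_gradient_frame
  out$direction <- if (!is.null(nuc$direction)) nuc$direction else NA_character_
  out
}

#' Write detections to CSV
#'
#' @param detections Output of [detect_events()].
#' @param path Output file.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
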