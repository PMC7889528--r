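#' Build a trace tibble
#'
#' A trace is one scalar per frame aligned to a temperature grid; this
#' constructor is the common route for user-supplied series and for tests.
#' Traces extracted from image sequences come from [extract_trace()].
#'
#' @param values Numeric, one per frame.
#' @param temp_C Temperature per frame (degC).
#' @param time_s Optional time per frame (s).
#' @param well_id,strategy Labels.
#' @return A `cp_trace` tibble with columns `well_id`, `frame`, `time_s`,
#'   `temp_C`, `strategy`, `value`.
#' @export
new_trace <- function(values, temp_C, time_s = NULL, well_id = "W1",
                      strategy = "trace") {
  stopifnot(length(values) == length(temp_C))
  out <- tibble(
    well_id = well_id, frame = seq_along(values),
    time_s = time_s %||% rep(NA_real_, length(values)),
    temp_C = temp_C, strategy = strategy, value = as.numeric(values)
  )
  class(out) <- c("cp_trace", class(out))
  out
}

# canonical strategy parsing -------------------------------------------------

parse_strategy <- function(strategy) {
  if (strategy == "TID") {
    return(list(type = "TID", label = "TID"))
  }
  ch <- c(MGL = "gray", MRL = "red", MGrL = "green", MBL = "blue")
  if (strategy %in% names(ch)) {
    return(list(type = "mean_level", channel = ch[[strategy]],
                label = strategy))
  }
  if (grepl("^TWP(:|$)", strategy)) {
    arg <- sub("^TWP:?", "", strategy)
    if (arg == "") {
      return(list(type = "TWP", wl = NULL, label = "TWP"))
    }
    if (arg %in% c("otsu_t0", "mean_gray_t0")) {
      return(list(type = "TWP", wl = white_level_spec(arg),
                  label = paste0("TWP:", arg)))
    }
    val <- suppressWarnings(as.numeric(arg))
    if (!is.na(val)) {
      return(list(type = "TWP", wl = white_level_spec("fixed", val),
                  label = sprintf("TWP:%.2f", val)))
    }
  }
  abort(sprintf("Unknown strategy '%s'.", strategy))
}

#' Extract a per-frame scalar trace from a well image sequence
#'
#' Applies one image-analysis strategy to every frame of a sequence:
#'
#' * `"TID"` - total intensity difference versus the first (t0) frame;
#' * `"TWP:<level>"` - white-pixel count of the gray image binarized at a
#'   fixed level (`"TWP:0.50"`, `"TWP:0.75"`, `"TWP:0.85"`) or at a
#'   data-dependent level resolved once from the t0 frame
#'   (`"TWP:otsu_t0"`, `"TWP:mean_gray_t0"`);
#' * `"MGL"`, `"MRL"`, `"MGrL"`, `"MBL"` - mean gray/red/green/blue level.
#'
#' @param sequence A `frame_sequence`.
#' @param strategy Strategy label (see above).
#' @param white_level Optional [white_level_spec()] (or fixed numeric
#'   level) overriding the level encoded in the label; required when the
#'   label is plain `"TWP"`.
#' @param temperature Which logged temperature the trace is aligned to.
#'   Detected event temperatures are reported on this grid; the instrument
#'   convention is `"device"`, which is precisely what makes detected cloud
#'   points apparent. `"sample"` is available for synthetic sequences.
#' @param tid_variant Passed to [total_intensity_difference()].
#' @return A `cp_trace` tibble; for TWP strategies the resolved level is in
#'   `attr(, "white_level")`.
#' @export
extract_trace <- function(sequence, strategy, white_level = NULL,
                          temperature = c("device", "sample"),
                          tid_variant = "abs_rgb") {
  stopifnot(inherits(sequence, "frame_sequence"))
  if (!length(sequence$frames)) abort("Empty frame sequence.")
  temperature <- match.arg(temperature)
  temps <- if (temperature == "device") {
    sequence$device_temp_C
  } else {
    if (is.null(sequence$sample_temp_C)) {
      abort("This sequence has no sample-temperature log.")
    }
    sequence$sample_temp_C
  }
  ps <- parse_strategy(strategy)
  frames <- sequence$frames
  resolved_level <- NA_real_
  values <- switch(ps$type,
    TID = {
      ref <- frames[[1]]
      vapply(frames, total_intensity_difference, numeric(1),
             reference_frame = ref, variant = tid_variant)
    },
    mean_level = vapply(frames, mean_level, numeric(1), channel = ps$channel),
    TWP = {
      wl <- white_level %||% ps$wl
      if (is.numeric(wl)) wl <- white_level_spec("fixed", wl)
      if (is.null(wl)) abort("TWP traces need a white level.")
      resolved_level <- resolve_white_level(wl, frames[[1]])
      if (wl$mode == "fixed") ps$label <- sprintf("TWP:%.2f", resolved_level)
      vapply(frames, function(f) {
        total_white_pixels(binarize(to_gray(f), resolved_level))
      }, integer(1))
    }
  )
  out <- new_trace(values, temps, time_s = sequence$time_s,
                   well_id = sequence$well_id, strategy = ps$label)
  attr(out, "white_level") <- resolved_level
  attr(out, "temperature") <- temperature
  out
}

#' Extract several strategies from a plate or sequence
#'
#' @param x A `well_plate` or a single `frame_sequence`.
#' @param strategies Character vector of strategy labels.
#' @param ... Passed to [extract_trace()].
#' @return A long tibble of traces (`well_id`, `frame`, `time_s`, `temp_C`,
#'   `strategy`, `value`).
#' @export
extract_traces <- function(x, strategies = c("TID", "TWP:0.50"), ...) {
  seqs <- if (inherits(x, "well_plate")) x$wells else list(x)
  purrr::map_dfr(seqs, function(sq) {
    purrr::map_dfr(strategies, function(s) extract_trace(sq, s, ...))
  })
}

#' Write traces to a tidy CSV
#'
#' Columns `well_id`, `frame_index`, `time_s`, `device_temp_C`, `strategy`,
#' `value`.
#'
#' @param traces Long trace tibble.
#' @param path Output file.
#' @export
write_traces <- function(traces, path) {
  out <- dplyr::transmute(traces,
    well_id = .data$well_id, frame_index = .data$frame,
    time_s = .data$time_s, device_temp_C = .data$temp_C,
    strategy = .data$strategy, value = .data$value)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
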