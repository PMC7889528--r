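#' Tukey-fence outlier mask
#'
#' Flags values outside `[Q1 - whisker * IQR, Q3 + whisker * IQR]` with the
#' conventional short whisker of 0.75 interquartile ranges used for
#' technical replicates. Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7) - at n = 6 the fences shift
#' materially between quartile conventions, so the convention is fixed and
#' recorded here. With fewer than 4 values the fences are meaningless; a
#' warning is raised and nothing is flagged.
#'
#' @param values Numeric.
#' @param whisker Whisker length in IQR units (default 0.75).
#' @return Logical mask, TRUE = outlier.
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 5, 100))
#' @export
tukey_outliers <- function(values, whisker = 0.75) {
  if (length(values) < 4) {
    warn("Fewer than 4 values: Tukey fences not applied, nothing flagged.")
    return(rep(FALSE, length(values)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values < q[1] - whisker * iqr | values > q[2] + whisker * iqr
}

#' Median and median absolute deviation
#'
#' The replicate summary of this pipeline: the median as central tendency
#' and the *unscaled* MAD, `median(|x - median(x)|)`, as raw spread (no
#' 1.4826 normal-consistency factor).
#'
#' @param values Numeric, non-empty.
#' @return One-row tibble with columns `median` and `mad`.
#' @examples
#' median_mad(c(1, 2, 3, 4, 5)) # median 3, mad 1
#' @export
median_mad <- function(values) {
  if (!length(values)) abort("`values` must be non-empty.")
  m <- median(values)
  tibble(median = m, mad = median(abs(values - m)))
}

#' Min-max normalization
#'
#' `(x - min) / (max - min)`: the minimum maps to 0 and the maximum to 1.
#' Used to put cloud-point series from different setups on a common scale
#' before RMSE comparison against reference data. Constant input has no
#' defined normalization and errors.
#'
#' @param values Numeric with at least two distinct values.
#' @return Values in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) {
    abort("Min-max normalization is undefined for constant input.")
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Aggregate replicate detections
#'
#' The filter-then-summarize pipeline for technical replicates: within each
#' group, Tukey-fence outliers are removed and the median and unscaled MAD
#' of the remainder reported.
#'
#' @param detections Tibble of per-well results.
#' @param value Name of the value column (string), e.g. `"t_cloud_app_C"`.
#' @param ... Grouping columns (tidy-select), e.g. `strategy, kind`.
#' @param whisker Tukey whisker length.
#' @return Tibble with grouping columns plus `median`, `mad`, `n_used`,
#'   `n_total`.
#' @export
aggregate_replicates <- function(detections, value = "t_cloud_app_C", ...,
                                 whisker = 0.75) {
  detections |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      res = {
        v <- .data[[value]]
        keep <- !tukey_outliers(v, whisker)
        dplyr::mutate(median_mad(v[keep]), n_used = sum(keep))
      },
      .groups = "drop"
    ) |>
    tidyr::unnest("res") |>
    dplyr::relocate("n_total", .after = "n_used")
}

#' Average difference between matched condition series
#'
#' Quantifies, e.g., the cloud-point depression of one cooling rate
#' relative to the reference rate: for every condition label shared by the
#' two series (typically the pH value), the difference `data - baseline`
#' is formed and its mean and standard deviation returned. Labels present
#' in only one series are dropped with a message; no shared labels is an
#' error.
#'
#' @param data,baseline Tibbles with a label column and a value column.
#' @param by Label column name (default `"label"`).
#' @param value Value column name (default `"value"`).
#' @return One-row tibble: `mean_diff`, `sd_diff`, `n_matched`.
#' @export
average_difference <- function(data, baseline, by = "label",
                               value = "value") {
  shared <- intersect(data[[by]], baseline[[by]])
  if (!length(shared)) abort("No shared condition labels.")
  dropped <- length(union(data[[by]], baseline[[by]])) - length(shared)
  if (dropped > 0) {
    message(dropped, " unmatched label(s) dropped.")
  }
  a <- data[[value]][match(shared, data[[by]])]
  b <- baseline[[value]][match(shared, baseline[[by]])]
  d <- a - b
  tibble(mean_diff = mean(d),
         sd_diff = if (length(d) > 1) sd(d) else 0,
         n_matched = length(d))
}
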