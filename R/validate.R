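#' Root-mean-squared error
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  sqrt(mean((a - b)^2))
}

#' Total and average RMSE over several series pairs
#'
#' Computes the per-series RMSEs, their sum ("total RMSE" in the
#' convention of this pipeline's method-comparison reports) and their
#' mean ("average RMSE").
#'
#' @param pairs A list of `list(a, b)` pairs, or a data frame with columns
#'   `series`, `a`, `b`.
#' @return One-row tibble: `total_rmse`, `average_rmse`, `n_series`.
#' @export
series_rmse_sum <- function(pairs) {
  if (is.data.frame(pairs)) {
    pairs <- lapply(split(pairs, pairs$series),
                    function(d) list(a = d$a, b = d$b))
  }
  per <- vapply(pairs, function(p) rmse(p[[1]], p[[2]]), numeric(1))
  tibble(total_rmse = sum(per), average_rmse = mean(per),
         n_series = length(per))
}

#' Squared Pearson correlation
#'
#' @param a,b Numeric vectors of equal length >= 2; either being constant
#'   (zero variance) is an error.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("`a` and `b` must have equal length >= 2.")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("R-squared is undefined for zero-variance input.")
  }
  stats::cor(a, b)^2
}

#' One-way ANOVA F statistic
#'
#' Classical between/within mean-square ratio with the p value from the F
#' distribution on (k - 1, N - k) degrees of freedom, via
#' `stats::oneway.test(var.equal = TRUE)`. Degenerate inputs are defined
#' rather than errors: zero between-group and zero within-group variance
#' gives F = 0, p = 1; zero within-group variance with distinct means
#' gives F = Inf, p = 0.
#'
#' @param ... Two or more numeric vectors (each of length >= 2), or a
#'   single list of them.
#' @return One-row tibble: `f`, `p`, `df_between`, `df_within`.
#' @examples
#' oneway_anova_f(c(1, 2, 3), c(1.5, 2.5, 3.5))
#' @export
oneway_anova_f <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]]) &&
      !is.numeric(groups[[1]])) {
    groups <- groups[[1]]
  }
  if (length(groups) < 2) abort("At least two groups are required.")
  if (any(lengths(groups) < 2)) abort("Each group needs >= 2 values.")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  n <- length(values)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - mean(values))^2)
  if (ssw == 0) {
    if (ssb == 0) {
      return(tibble(f = 0, p = 1, df_between = k - 1L, df_within = n - k))
    }
    return(tibble(f = Inf, p = 0, df_between = k - 1L, df_within = n - k))
  }
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  tibble(f = unname(ft$statistic), p = unname(ft$p.value),
         df_between = unname(ft$parameter[1]),
         df_within = unname(ft$parameter[2]))
}

#' Compare cloud-point detections between two strategies
#'
#' Pairs the detections of two image-analysis strategies by well and
#' quantifies their similarity: overall RMSE and R-squared of the paired
#' values (NA when either side is constant, as for technical replicates
#' quantized to a single grid temperature), a one-way ANOVA between the
#' two sets, and - when a `series`
#' column groups wells into data series (condition labels) - the summed
#' ("total") and mean ("average") per-series RMSEs.
#'
#' @param detections Tibble with columns `well_id`, `strategy`, the value
#'   column, and optionally `series`.
#' @param strategies The two strategy labels to pair (default TID vs
#'   TWP:0.50).
#' @param value Value column name (default `"t_cloud_app_C"`).
#' @return A `strategy_comparison` object; see [tidy.strategy_comparison()]
#'   and [glance.strategy_comparison()].
#' @export
compare_strategies <- function(detections,
                               strategies = c("TID", "TWP:0.50"),
                               value = "t_cloud_app_C") {
  stopifnot(length(strategies) == 2)
  keep <- detections$strategy %in% strategies & !is.na(detections[[value]])
  d <- detections[keep, , drop = FALSE]
  has_series <- "series" %in% names(d)
  cols <- c("well_id", if (has_series) "series", "strategy", value)
  wide <- d[, cols] |>
    tidyr::pivot_wider(names_from = "strategy", values_from = dplyr::all_of(value)) |>
    dplyr::filter(!is.na(.data[[strategies[1]]]),
                  !is.na(.data[[strategies[2]]]))
  if (!nrow(wide)) abort("No wells with matched detections for both strategies.")
  a <- wide[[strategies[1]]]
  b <- wide[[strategies[2]]]
  per_series <- if (has_series) {
    wide |>
      dplyr::group_by(.data$series) |>
      dplyr::summarise(rmse = rmse(.data[[strategies[1]]],
                                   .data[[strategies[2]]]),
                       n = dplyr::n(), .groups = "drop")
  } else {
    tibble(series = "all", rmse = rmse(a, b), n = length(a))
  }
  anova <- oneway_anova_f(a, b)
  structure(
    list(strategies = strategies, value = value, data = wide,
         per_series = per_series,
         rmse = rmse(a, b),
         total_rmse = sum(per_series$rmse),
         average_rmse = mean(per_series$rmse),
         # undefined when either strategy's detections are constant (e.g.
         # technical replicates quantized to one temperature-grid value)
         r_squared = if (sd(a) == 0 || sd(b) == 0) NA_real_
                     else r_squared(a, b),
         anova_f = anova$f, anova_p = anova$p,
         n_pairs = length(a)),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf(
    "<strategy_comparison> %s vs %s on %d wells\n  total RMSE %.3g, average RMSE %.3g, R^2 %.4g, ANOVA F %.3g (p %.3g)\n",
    x$strategies[1], x$strategies[2], x$n_pairs, x$total_rmse,
    x$average_rmse, x$r_squared, x$anova_f, x$anova_p))
  invisible(x)
}

#' Tidy a strategy comparison
#'
#' @param x A [compare_strategies()] result.
#' @param ... Unused.
#' @return Per-series tibble of RMSEs.
#' @export
tidy.strategy_comparison <- function(x, ...) {
  x$per_series
}

#' One-row summary of a strategy comparison
#'
#' @param x A [compare_strategies()] result.
#' @param ... Unused.
#' @return One-row tibble with `rmse`, `total_rmse`, `average_rmse`,
#'   `r_squared`, `anova_f`, `anova_p`, `n_pairs`.
#' @export
glance.strategy_comparison <- function(x, ...) {
  tibble(rmse = x$rmse, total_rmse = x$total_rmse,
         average_rmse = x$average_rmse, r_squared = x$r_squared,
         anova_f = x$anova_f, anova_p = x$anova_p, n_pairs = x$n_pairs)
}

#' Normalized-RMSE validation against a reference table
#'
#' Puts each data series and the reference on a common min-max-normalized
#' scale over their shared condition labels and reports the per-series
#' RMSE - low values mean the series reproduces the reference's variation
#' with condition (typically pH), whatever the absolute offsets.
#'
#' @param aggregates Tibble with a label column, a value column and a
#'   series column.
#' @param reference Tibble with the label column and a value column.
#' @param by Label column (default `"pH"`).
#' @param value Value column in `aggregates` (default `"median"`).
#' @param ref_value Value column in `reference` (default `"t_cloud_C"`).
#' @param series Series column in `aggregates` (default `"series"`).
#' @return Tibble with one row per series: `series`, `rmse`, `n`.
#' @export
validate_against_reference <- function(aggregates, reference, by = "pH",
                                       value = "median",
                                       ref_value = "t_cloud_C",
                                       series = "series") {
  stopifnot(by %in% names(aggregates), by %in% names(reference))
  split(aggregates, aggregates[[series]]) |>
    purrr::imap_dfr(function(d, s) {
      shared <- intersect(d[[by]], reference[[by]])
      if (length(shared) < 2) {
        abort(sprintf("Series '%s' shares fewer than 2 labels with the reference.", s))
      }
      a <- minmax_normalize(d[[value]][match(shared, d[[by]])])
      b <- minmax_normalize(reference[[ref_value]][match(shared, reference[[by]])])
      tibble(series = s, rmse = rmse(a, b), n = length(shared))
    })
}
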