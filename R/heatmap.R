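#' Univariate 0--10 scaling per parameter
#'
#' Linearly rescales values so that, within each parameter (across all
#' surface x condition x time cells supplied — the comparison set), the
#' minimum maps to 0 and the maximum to 10. Constant parameters map to
#' all-zero and are flagged. The original min/max are kept in the scaling
#' record so the transform is invertible.
#'
#' @param df Tibble with at least a `parameter` column and the value column.
#' @param value Name of the value column (default `"value"`).
#' @param by Grouping column(s) defining a row of the scaled matrix
#'   (default `"parameter"`).
#' @return `df` with an added `scaled` column and attribute `"scaling"` (a
#'   tibble of per-parameter `min`, `max`, `constant`); retrieve it with
#'   [scaling_record()].
#' @examples
#' scale_parameters(tibble::tibble(parameter = "P1", value = c(1, 3, 5)))$scaled
#' @export
scale_parameters <- function(df, value = "value", by = "parameter") {
  if (nrow(df) == 0) abort("empty table")
  v <- df[[value]]
  if (is.null(v)) abort(sprintf("no column '%s'", value))
  out <- df |>
    mutate(
      .min = min(.data[[value]], na.rm = TRUE),
      .max = max(.data[[value]], na.rm = TRUE),
      .by = all_of(by)
    ) |>
    mutate(scaled = ifelse(.data$.max > .data$.min,
                           10 * (.data[[value]] - .data$.min) /
                             (.data$.max - .data$.min),
                           0))
  rec <- out |>
    distinct(across(all_of(by)), min = .data$.min, max = .data$.max) |>
    mutate(constant = .data$max == .data$min)
  out$.min <- NULL; out$.max <- NULL
  attr(out, "scaling") <- rec
  out
}

#' @rdname scale_parameters
#' @param x A tibble returned by [scale_parameters()].
#' @export
scaling_record <- function(x) {
  rec <- attr(x, "scaling")
  if (is.null(rec)) abort("no scaling record attached; was this scaled?")
  rec
}

#' Invert the 0--10 scaling
#'
#' @param x Scaled tibble (with a `scaled` column).
#' @param record Scaling record; defaults to the one attached to `x`.
#' @param by Row-identifier column(s) used when scaling.
#' @return `x` with an `unscaled` column reproducing the original values
#'   (constant rows recover their constant).
#' @export
inverse_scale <- function(x, record = scaling_record(x), by = "parameter") {
  x |>
    left_join(record, by = by) |>
    mutate(unscaled = ifelse(.data$constant, .data$min,
                             .data$scaled / 10 * (.data$max - .data$min) +
                               .data$min)) |>
    select(-min, -max, -constant)
}

#' Subtraction heatmap with mean +/- SD relevance filtering
#'
#' Cellwise difference of two matched scaled tables; only differences
#' falling outside the relevance band (centred on `band_mean`, half-width
#' one `band_sd`) are retained, all other cells are set to 0. The default
#' band centre of 0 encodes "no effect"; per-cell bands (e.g. from replicate
#' control runs) can be supplied as columns.
#'
#' @param a,b Scaled tibbles (with a `scaled` column) sharing the key
#'   columns in `by`.
#' @param by Key columns to join on; defaults to all shared columns except
#'   value-like ones.
#' @param band_mean,band_sd Scalars, or a tibble keyed by (a subset of)
#'   `by` with columns `band_mean` and `band_sd`.
#' @return Tibble of the keys plus `delta` (raw difference), `retained`, and
#'   `value` (the filtered difference, 0 inside the band).
#' @export
subtraction_heatmap <- function(a, b, by = NULL, band_mean = 0, band_sd = 1) {
  drop_cols <- c("value", "scaled", "provenance")
  if (is.null(by)) by <- setdiff(intersect(names(a), names(b)), drop_cols)
  aa <- a |> select(all_of(by), scaled_a = "scaled")
  bb <- b |> select(all_of(by), scaled_b = "scaled")
  if (nrow(aa) != nrow(bb)) abort("shape mismatch between the two tables")
  d <- inner_join(aa, bb, by = by)
  if (nrow(d) != nrow(aa)) abort("tables do not align on the key columns")
  if (is.data.frame(band_mean)) {
    d <- d |> left_join(band_mean, by = intersect(by, names(band_mean)))
  } else {
    d$band_mean <- band_mean
    d$band_sd <- band_sd
  }
  d |>
    mutate(
      delta = .data$scaled_a - .data$scaled_b,
      retained = abs(.data$delta - .data$band_mean) > .data$band_sd,
      value = ifelse(.data$retained, .data$delta, 0)
    ) |>
    select(all_of(by), delta, retained, value)
}

#' Early- and late-interval parameter increases
#'
#' Increases over the first and second 4-minute intervals of a flow run:
#' `dt1 = v(4) - v(0)` and `dt2 = v(8) - v(4)`, computed on the 0--10
#' scaled values. Cells missing an anchor time are absent from the output.
#'
#' @param df Tibble with a `time` column and the value column.
#' @param value Column to difference (default `"scaled"`).
#' @param anchors The three anchor times.
#' @return Tibble of the grouping columns plus `dt1`, `dt2`.
#' @export
interval_deltas <- function(df, value = "scaled", anchors = c(0, 4, 8)) {
  keys <- setdiff(names(df), c("time", value, "value", "scaled", "provenance"))
  df |>
    filter(.data$time %in% anchors) |>
    select(all_of(keys), time, v = all_of(value)) |>
    pivot_wider(names_from = "time", values_from = "v", names_prefix = "t") |>
    filter(stats::complete.cases(across(all_of(paste0("t", anchors))))) |>
    mutate(
      dt1 = .data[[paste0("t", anchors[2])]] - .data[[paste0("t", anchors[1])]],
      dt2 = .data[[paste0("t", anchors[3])]] - .data[[paste0("t", anchors[2])]]
    ) |>
    select(all_of(keys), dt1, dt2)
}

#' Summed scaled effect over a scope
#'
#' Sum of the retained (relevance-filtered) signed differences of a
#' subtraction heatmap over an explicit scope of parameters / surfaces /
#' time points. The scope is an explicit argument because the summation set
#' defines the statistic.
#'
#' @param diff Output of [subtraction_heatmap()].
#' @param parameters,surfaces,times Optional scope filters (default: all).
#' @return Scalar sum.
#' @export
summed_scaled_effect <- function(diff, parameters = NULL, surfaces = NULL,
                                 times = NULL) {
  d <- diff
  if (!is.null(parameters)) d <- d |> filter(.data$parameter %in% parameters)
  if (!is.null(surfaces)) d <- d |> filter(.data$surface %in% surfaces)
  if (!is.null(times)) d <- d |> filter(.data$time %in% times | is.na(.data$time))
  if (nrow(d) == 0) abort("empty scope")
  sum(d$value)
}

#' Hierarchical clustering of matrix rows
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (ties broken deterministically by lowest merge index, as in
#' [stats::hclust()]).
#'
#' @param x Numeric matrix with rownames, or a data frame whose first
#'   column holds row identifiers.
#' @return List with `tree` (an `hclust`) and `order` (row labels in
#'   dendrogram order).
#' @export
cluster_rows <- function(x) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- as.character(x[[1]])
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) < 2) abort("need at least 2 rows")
  if (anyNA(m)) abort("rows contain missing values; impute first")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  list(tree = hc, order = hc$labels[hc$order])
}

#' Cross-surface correlation of the thrombus signature
#'
#' Pearson correlation, pairing subjects across two surfaces, of the scaled
#' parameter values per parameter x time cell — the donor-consistency
#' analysis between the two strongly GPVI-activating surfaces.
#'
#' @param df Scaled tibble with columns `subject`, `surface`, `parameter`,
#'   `time` and the value column.
#' @param surface_a,surface_b The two surfaces to pair.
#' @param value Value column (default `"scaled"`).
#' @return Tibble per parameter x time: `r`, `p`, `n` (r and p are `NA`
#'   where either vector has zero variance).
#' @export
correlate_surfaces <- function(df, surface_a, surface_b, value = "scaled") {
  wide <- df |>
    filter(.data$surface %in% c(surface_a, surface_b)) |>
    select(subject, surface, parameter, time, v = all_of(value)) |>
    pivot_wider(names_from = "surface", values_from = "v") |>
    filter(!is.na(.data[[surface_a]]), !is.na(.data[[surface_b]]))
  res <- wide |>
    summarise(
      n = n(),
      r = if (n() >= 3 && sd(.data[[surface_a]]) > 0 &&
              sd(.data[[surface_b]]) > 0) {
        cor(.data[[surface_a]], .data[[surface_b]])
      } else NA_real_,
      p = if (n() >= 3 && sd(.data[[surface_a]]) > 0 &&
              sd(.data[[surface_b]]) > 0) {
        cor.test(.data[[surface_a]], .data[[surface_b]])$p.value
      } else NA_real_,
      .by = c("parameter", "time")
    )
  if (any(res$n < 3)) abort("need at least 3 paired subjects per cell")
  res
}
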