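#' Control reference ranges
#'
#' Per-cell (surface x condition x parameter x time) mean and sample SD of
#' the scaled values across control subjects — the normal range used by the
#' relevance filter when comparing patients to controls.
#'
#' @param controls Scaled control tibble (with a `scaled` column and a
#'   `subject` column).
#' @param keys Cell-defining columns; defaults to everything except subject,
#'   group and value-like columns.
#' @return Tibble of the keys plus `ctrl_mean`, `ctrl_sd`, `n_controls`.
#' @export
build_reference <- function(controls, keys = NULL) {
  if (is.null(keys)) {
    keys <- setdiff(names(controls),
                    c("subject", "group", "value", "scaled", "provenance"))
  }
  ref <- controls |>
    summarise(
      ctrl_mean = mean(.data$scaled),
      ctrl_sd = sd(.data$scaled),
      n_controls = n(),
      .by = all_of(keys)
    )
  if (any(ref$n_controls < 2)) {
    abort("need at least 2 control subjects per cell for a reference range")
  }
  ref
}

#' Relevant changes of one patient versus the control reference
#'
#' Signed deviations of the patient's scaled values from the control mean,
#' retained only where they fall outside the control mean +/- SD band
#' (everything inside the normal range is set to 0). Negative retained
#' values are relevant decreases (rendered green), positive ones relevant
#' increases (red).
#'
#' @param patient Scaled tibble for one (or more) patients.
#' @param reference Output of [build_reference()].
#' @return Tibble of patient rows with `delta`, `retained`, `value` (the
#'   filtered deviation). Cells without a reference are dropped with a
#'   warning.
#' @export
patient_changes <- function(patient, reference) {
  keys <- setdiff(names(reference), c("ctrl_mean", "ctrl_sd", "n_controls"))
  joined <- patient |> left_join(reference, by = keys)
  n_miss <- sum(is.na(joined$ctrl_mean))
  if (n_miss > 0) {
    warn(sprintf("%d cell(s) missing from the reference; excluded", n_miss))
    joined <- joined |> filter(!is.na(.data$ctrl_mean))
  }
  joined |>
    mutate(
      delta = .data$scaled - .data$ctrl_mean,
      retained = abs(.data$delta) > .data$ctrl_sd,
      value = ifelse(.data$retained, .data$delta, 0)
    ) |>
    select(-any_of(c("ctrl_mean", "ctrl_sd", "n_controls")))
}

#' Integrate relevant changes by parameter group
#'
#' Cumulative signed sums of the relevance-filtered deviations over all time
#' points and the selected surfaces, per parameter group (platelet P1--P2,
#' thrombus P3--P6, fibrin P7--P9) and per TF stratum.
#'
#' @param changes Output of [patient_changes()].
#' @param groups Disjoint parameter grouping covering P1--P9; see
#'   [parameter_groups()].
#' @param surfaces Optional surface filter.
#' @param by Identifier columns kept in the output (default
#'   `c("subject", "group")`).
#' @return Tibble: identifiers, `param_group`, `tf_present`, `change_sum`.
#' @export
integrate_changes <- function(changes, groups = parameter_groups(),
                              surfaces = NULL,
                              by = c("subject", "group")) {
  all_p <- sort(unname(unlist(groups)))
  if (!identical(all_p, paste0("P", 1:9)) || anyDuplicated(unlist(groups))) {
    abort("groups must cover P1-P9 disjointly")
  }
  map <- tibble(
    parameter = unlist(groups),
    param_group = rep(names(groups), lengths(groups))
  )
  d <- changes
  if (!is.null(surfaces)) d <- d |> filter(.data$surface %in% surfaces)
  by <- intersect(by, names(d))
  d |>
    left_join(map, by = "parameter") |>
    mutate(tf_present = .data$tf > 0) |>
    summarise(change_sum = sum(.data$value),
              .by = all_of(c(by, "param_group", "tf_present"))) |>
    arrange(across(all_of(by)))
}

#' Mean thrombomodulin effect on the fibrin parameters
#'
#' For paired runs on the TM-co-coated collagen surface (TF in the
#' recalcification medium, with and without the TM co-coat), computes per
#' subject the mean over the fibrin parameters and time points of the
#' relevance-filtered scaled difference (no TM minus TM). The relevance band
#' is one per-cell SD of the control subjects' paired differences, centred
#' on zero. Positive values mean TM suppresses fibrin formation; a value
#' near zero for a factor V-Leiden carrier reflects the abolished TM
#' response.
#'
#' @param scaled Scaled tibble containing paired runs distinguished by a
#'   logical `tm` column, with `subject`, `group`, `parameter`, `time`.
#' @param fibrin_parameters Parameters to integrate (default P7--P9).
#' @param control_group Value of `group` identifying controls.
#' @return Tibble: `subject`, `group`, `tm_effect`.
#' @export
tm_effect <- function(scaled, fibrin_parameters = c("P7", "P8", "P9"),
                      control_group = "control") {
  if (!"tm" %in% names(scaled)) abort("need a logical 'tm' column (paired runs)")
  keys <- setdiff(names(scaled),
                  c("tm", "value", "scaled", "provenance", "group"))
  d <- scaled |>
    filter(.data$parameter %in% fibrin_parameters) |>
    select(all_of(keys), group, tm, scaled) |>
    pivot_wider(names_from = "tm", values_from = "scaled",
                names_prefix = "tm_")
  if (!all(c("tm_FALSE", "tm_TRUE") %in% names(d)) ||
      anyNA(d$tm_FALSE) || anyNA(d$tm_TRUE)) {
    abort("unpaired runs: every cell needs both a TM and a no-TM value")
  }
  d <- d |> mutate(diff = .data$tm_FALSE - .data$tm_TRUE)
  cell_keys <- setdiff(keys, "subject")
  band <- d |>
    filter(.data$group == control_group) |>
    summarise(band_sd = sd(.data$diff), .by = all_of(cell_keys))
  if (nrow(band) == 0) abort("no control subjects to build the relevance band")
  d |>
    left_join(band, by = cell_keys) |>
    mutate(value = ifelse(abs(.data$diff) > .data$band_sd, .data$diff, 0)) |>
    summarise(tm_effect = mean(.data$value), .by = c("subject", "group"))
}

#' Two-group comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact for small
#' tie-free samples, normal approximation with tie correction otherwise.
#' Degenerate all-tied data return p = 1.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 3).
#' @return Two-sided p-value.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 3, length(values_b) >= 3)
  if (length(unique(c(values_a, values_b))) == 1) return(1)
  suppressWarnings(wilcox.test(values_a, values_b,
                               alternative = "two.sided")$p.value)
}
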