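#' Scoring rubric thresholds
#'
#' The ordinal scores P4--P6 and P8 were, in the original assay, assigned by
#' blinded observers against reference images. This package substitutes
#' automated surrogates with explicit, configurable rubric thresholds; that
#' substitution is recorded in all outputs via the `provenance` column.
#' Area cutoffs are in px^2 at the default pixel scale and are scaled by
#' `(um_per_px / 0.108)^-2` when a different pixel size is supplied
#' downstream.
#'
#' @param sac_eps %SAC below which a field counts as blank.
#' @param single_max,small_max,medium_max Object-area tier cutoffs, px^2
#'   (single platelet < `single_max`; small aggregate < `small_max`; medium
#'   < `medium_max`; large otherwise).
#' @param singles_extensive %SAC above which single-platelet coverage counts
#'   as extensive.
#' @param p5_frac Tier cutpoints for the fraction of foreground held in
#'   aggregates.
#' @param p6_shrink Tier cutpoints for the relative footprint shrinkage.
#' @param p8_length Tier cutpoints for total fibre length, px.
#' @param p8_sac_top Fibrin %SAC at/above which the fibre mat scores 3.
#' @return Named list of thresholds.
#' @export
score_cutoffs <- function(sac_eps = 0.5, single_max = 80, small_max = 500,
                          medium_max = 2000, singles_extensive = 10,
                          p5_frac = c(0.1, 0.35, 0.6),
                          p6_shrink = c(0.05, 0.15, 0.30),
                          p8_length = c(1, 100, 300),
                          p8_sac_top = 15) {
  list(sac_eps = sac_eps, single_max = single_max, small_max = small_max,
       medium_max = medium_max, singles_extensive = singles_extensive,
       p5_frac = p5_frac, p6_shrink = p6_shrink, p8_length = p8_length,
       p8_sac_top = p8_sac_top)
}

#' Thrombus morphology score (P4, 0--5)
#'
#' Rubric: 0 blank field; 1 multiple single adhered platelets; 2 extensive
#' coverage of single platelets; 3 small aggregates; 4 medium aggregates and
#' thrombi; 5 large aggregates and thrombi. Driven by coverage and the
#' largest object's area; monotone non-decreasing in both.
#'
#' @param sac %SAC of the platelet/thrombus mask.
#' @param areas Numeric vector of object areas, px^2.
#' @param cutoffs A [score_cutoffs()] list.
#' @return Integer score 0--5.
#' @export
score_morphology <- function(sac, areas, cutoffs = score_cutoffs()) {
  if (sac < cutoffs$sac_eps || length(areas) == 0) return(0L)
  max_a <- max(areas)
  if (max_a >= cutoffs$medium_max) return(5L)
  if (max_a >= cutoffs$small_max) return(4L)
  if (max_a >= cutoffs$single_max) return(3L)
  if (sac >= cutoffs$singles_extensive) return(2L)
  1L
}

#' Thrombus aggregation score (P5, 0--3)
#'
#' Tiered on the fraction of foreground held in objects at or above the
#' single-platelet area cutoff.
#'
#' @inheritParams score_morphology
#' @return Integer score 0--3.
#' @export
score_aggregation <- function(areas, cutoffs = score_cutoffs()) {
  if (length(areas) == 0 || sum(areas) == 0) return(0L)
  frac <- sum(areas[areas >= cutoffs$single_max]) / sum(areas)
  sum(frac >= cutoffs$p5_frac)
}

#' Thrombus contraction score (P6, 0--3)
#'
#' Contraction shows as densification: the aggregate footprint shrinks while
#' the mean foreground intensity does not decrease. Tiered on the relative
#' shrinkage of the aggregate footprint from its running maximum, gated on
#' non-decreasing intensity.
#'
#' @param footprints Aggregate footprint (px^2 in objects at/above the
#'   single-platelet cutoff) per time point, ordered in time, up to and
#'   including the scored time.
#' @param intensities Mean foreground intensity per time point (same order);
#'   `NA`s are treated as non-decreasing.
#' @param cutoffs A [score_cutoffs()] list.
#' @return Integer score 0--3.
#' @export
score_contraction <- function(footprints, intensities = NULL,
                              cutoffs = score_cutoffs()) {
  stopifnot(length(footprints) >= 1)
  peak <- max(footprints)
  if (peak == 0) return(0L)
  i_peak <- which.max(footprints)
  shrink <- 1 - footprints[length(footprints)] / peak
  if (!is.null(intensities) && length(intensities) == length(footprints)) {
    seg <- intensities[i_peak:length(intensities)]
    seg <- seg[!is.na(seg)]
    if (length(seg) >= 2 && seg[length(seg)] < seg[1]) return(0L)
  }
  sum(shrink >= cutoffs$p6_shrink)
}

#' Fibrin score (P8, 0--3)
#'
#' Tiered on total fibre length of fibre-like objects; a dense fibre mat
#' (fibrin coverage at/above `p8_sac_top`) scores the top tier regardless.
#'
#' @param n_fibres Number of fibre-like objects.
#' @param fibre_length Total fibre length, px.
#' @param sac Fibrin-channel %SAC.
#' @param cutoffs A [score_cutoffs()] list.
#' @return Integer score 0--3.
#' @export
score_fibrin <- function(n_fibres, fibre_length, sac = 0,
                         cutoffs = score_cutoffs()) {
  if (n_fibres == 0 && sac < cutoffs$p8_sac_top) return(0L)
  if (sac >= cutoffs$p8_sac_top) return(3L)
  max(sum(fibre_length >= cutoffs$p8_length), 1L)
}

#' Time to first fibrin formation and the P9 statistic
#'
#' The onset is the earliest capture time at which fibre-like objects appear
#' and persist at the next frame (single-frame blips are treated as noise;
#' an appearance at the final frame cannot be checked for persistence and is
#' accepted with a flag). If no fibrin appears within the observation limit,
#' the default onset of 11 min applies, giving P9 = 0; otherwise
#' P9 = 11 - t_fib.
#'
#' @param n_fibres Integer vector of fibre counts per capture time.
#' @param times Capture times, min (same length, >= 2 time points).
#' @param limit Observation limit, min.
#' @param default Default onset when no fibrin is seen, min.
#' @param sac Optional fibrin-channel %SAC per capture time; a dense fibrin
#'   mat (coverage >= `sac_floor`) counts as fibrin present even when merged
#'   fibres no longer classify as elongated objects.
#' @param sac_floor Coverage treated as an unambiguous fibrin mat, %SAC.
#' @return List: `t_fib`, `p9`, `last_frame_onset` flag.
#' @export
detect_time_to_fibrin <- function(n_fibres, times, limit = 10, default = 11,
                                  sac = NULL, sac_floor = 15) {
  if (length(times) < 2) abort("persistence unverifiable on a single frame")
  stopifnot(length(n_fibres) == length(times), !is.unsorted(times))
  obs <- times <= limit
  n_fibres <- n_fibres[obs]
  if (is.null(sac)) sac <- rep(0, length(times))
  sac <- sac[obs]; times <- times[obs]
  present <- n_fibres > 0 | sac >= sac_floor
  persists <- c(present[-1], TRUE)  # last frame: no next frame to refute
  hit <- which(present & persists)
  if (length(hit) == 0) {
    list(t_fib = default, p9 = 0, last_frame_onset = FALSE)
  } else {
    t_fib <- times[hit[1]]
    list(
      t_fib = t_fib,
      p9 = clamp(default - t_fib, 0, default),
      last_frame_onset = hit[1] == length(times) && !present[length(times) - 1]
    )
  }
}

#' Derive the nine-parameter record from run quantification
#'
#' Maps per-channel, per-time quantification onto the kinetic readouts:
#' platelet adhesion P1 (platelet channel %SAC), PS exposure P2 (PS
#' channel), thrombus coverage P3 (bright-field), morphology P4,
#' aggregation P5 and contraction P6 (bright-field object statistics),
#' fibrin deposition P7 (fibrin channel), fibrin score P8 and the
#' time-to-fibrin statistic P9 (fibrin fibre statistics).
#'
#' @param quant Tidy quantification as returned by [quantify_run()].
#' @param cutoffs A [score_cutoffs()] list.
#' @param limit,default Observation limit and default onset for P9, min.
#' @return Long tibble `parameter`, `time`, `value` (41 rows when all five
#'   capture times are present), with `provenance = "automated_rubric"`.
#' @export
run_parameters <- function(quant, cutoffs = score_cutoffs(), limit = 10,
                           default = 11) {
  get_ch <- function(ch) quant |> filter(.data$channel == ch) |> arrange(time)
  plat <- get_ch("platelet"); ps <- get_ch("ps")
  fib <- get_ch("fibrin"); bf <- get_ch("brightfield")
  if (nrow(bf) == 0) bf <- plat  # fall back when no bright-field proxy
  sac_rows <- bind_rows(
    plat |> mutate(parameter = "P1") |> select(parameter, time, value = sac),
    ps |> mutate(parameter = "P2") |> select(parameter, time, value = sac),
    bf |> mutate(parameter = "P3") |> select(parameter, time, value = sac),
    fib |> mutate(parameter = "P7") |> select(parameter, time, value = sac)
  )
  agg_foot <- vapply(bf$areas, function(a) sum(a[a >= cutoffs$single_max]),
                     numeric(1))
  score_rows <- purrr::map(seq_len(nrow(bf)), function(i) {
    tibble(
      parameter = c("P4", "P5", "P6", "P8"),
      time = bf$time[i],
      value = c(
        score_morphology(bf$sac[i], bf$areas[[i]], cutoffs),
        score_aggregation(bf$areas[[i]], cutoffs),
        score_contraction(agg_foot[seq_len(i)], bf$mean_intensity[seq_len(i)],
                          cutoffs),
        score_fibrin(fib$n_fibres[i], fib$fibre_length[i], fib$sac[i], cutoffs)
      )
    )
  }) |> list_rbind()
  p9 <- detect_time_to_fibrin(fib$n_fibres, fib$time, limit, default,
                              sac = fib$sac)
  bind_rows(
    sac_rows, score_rows,
    tibble(parameter = "P9", time = NA_real_, value = p9$p9)
  ) |>
    mutate(provenance = "automated_rubric") |>
    arrange(parameter, time)
}

#' Assemble and validate a complete parameter record
#'
#' Combines the per-time values of P1--P8 with the scalar P9 into a 41-value
#' record, validated against the registry ranges.
#'
#' @param values Tibble `parameter`, `time`, `value` for P1--P8 at the five
#'   capture times.
#' @param p9 Scalar P9 value.
#' @param ... Metadata columns to attach (e.g. `subject`, `surface`).
#' @return Validated 41-row record tibble.
#' @export
assemble_record <- function(values, p9, ...) {
  rec <- bind_rows(
    values |> select(parameter, time, value),
    tibble(parameter = "P9", time = NA_real_, value = p9)
  )
  meta <- list(...)
  for (nm in names(meta)) rec[[nm]] <- meta[[nm]]
  missing <- setdiff(paste0("P", 1:9), unique(rec$parameter))
  if (length(missing) > 0) {
    abort(sprintf("record incomplete: missing %s", paste(missing, collapse = ", ")))
  }
  validate_records(rec, complete = TRUE)
  rec
}
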