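#' Logistic coverage profile of one channel
#'
#' The generator models every coverage-type readout as a saturating logistic
#' in time: plateau `c_max` (%SAC), half-time `t50` (min) and steepness `tau`
#' (min), anchored so coverage is exactly 0 at t = 0 and non-decreasing.
#' Fibrin channels additionally carry an onset time `t_fib` before which
#' coverage is exactly zero.
#'
#' @param c_max Plateau coverage, %SAC in \[0, 100\].
#' @param t50 Half-time, min (> 0).
#' @param tau Steepness, min (> 0).
#' @param t_fib Fibrin onset time in min; `Inf` when no fibrin forms.
#' @return An object of class `kinetic_profile`.
#' @export
kinetic_profile <- function(c_max, t50, tau, t_fib = Inf) {
  stopifnot(c_max >= 0, c_max <= 100, t50 > 0, tau > 0)
  structure(list(c_max = c_max, t50 = t50, tau = tau, t_fib = t_fib),
            class = "kinetic_profile")
}

# normalised logistic rise: 0 at t = 0, -> 1 as t -> Inf
logistic_rise <- function(t, t50, tau) {
  g0 <- stats::plogis(-t50 / tau)
  (stats::plogis((t - t50) / tau) - g0) / (1 - g0)
}

# fibrin accumulation after onset; exactly zero before t_fib
fibrin_rise <- function(t, t_fib, tau = 1.2) {
  ifelse(is.finite(t_fib) & t >= t_fib, 1 - exp(-(t - t_fib) / tau), 0)
}

#' Evaluate a kinetic profile
#'
#' @param profile A [kinetic_profile()].
#' @param t Times in min.
#' @return Coverage values (%SAC) at `t`.
#' @export
profile_coverage <- function(profile, t) {
  stopifnot(inherits(profile, "kinetic_profile"))
  base <- profile$c_max * logistic_rise(t, profile$t50, profile$tau)
  if (is.finite(profile$t_fib)) {
    base <- profile$c_max * fibrin_rise(t, profile$t_fib)
  }
  base
}

#' Named effect template modifying the generative kinetics
#'
#' Templates express conditions and subject groups as multiplicative /
#' additive modifiers of the baseline kinetic profiles: plateau multipliers
#' for the platelet, phosphatidylserine, thrombus and fibrin channels, a shift
#' of the fibrin onset time, and a scaling of the thrombomodulin / APC
#' response (`tm_scale = 0` models the APC resistance of factor V-Leiden
#' carriers, whose TM response is abolished). The control template is the
#' identity.
#'
#' @param name Template name.
#' @param platelet,ps,thrombus,fibrin Plateau multipliers (>= 0).
#' @param tfib_shift Additive shift of the fibrin onset time, min.
#' @param tm_scale Scaling of the TM/APC anticoagulant response in \[0, 1\].
#' @return An object of class `effect_template`.
#' @export
effect_template <- function(name = "control", platelet = 1, ps = 1,
                            thrombus = 1, fibrin = 1, tfib_shift = 0,
                            tm_scale = 1) {
  stopifnot(platelet >= 0, ps >= 0, thrombus >= 0, fibrin >= 0,
            tm_scale >= 0, tm_scale <= 1)
  structure(
    list(name = name, platelet = platelet, ps = ps, thrombus = thrombus,
         fibrin = fibrin, tfib_shift = tfib_shift, tm_scale = tm_scale),
    class = "effect_template"
  )
}

#' Built-in patient effect templates
#'
#' Four coagulation-disorder archetypes: severe factor XII deficiency
#' (reduced thrombus and fibrin parameters when TF is present), factor XI
#' deficiency (milder version of the same), severe factor V deficiency
#' (profound fibrin impairment preceded by reduced thrombus build-up), and
#' heterozygous factor V-Leiden (gain of function: raised PS exposure and
#' fibrin parameters, earlier fibrin onset, abolished TM response).
#'
#' @return Named list of [effect_template()] objects.
#' @export
patient_templates <- function() {
  list(
    fxii_def = effect_template("fxii_def", thrombus = 0.65, fibrin = 0.55,
                               tfib_shift = 1.5),
    fxi_def = effect_template("fxi_def", thrombus = 0.75, fibrin = 0.7,
                              tfib_shift = 1.0),
    fv_def = effect_template("fv_def", platelet = 0.85, thrombus = 0.7,
                             fibrin = 0.15, tfib_shift = 4.0),
    fv_leiden = effect_template("fv_leiden", ps = 1.3, fibrin = 1.3,
                                tfib_shift = -1.5, tm_scale = 0)
  )
}

#' Baseline surface reactivity ladder
#'
#' Per-surface platelet plateau (%SAC, the driver for all platelet and
#' thrombus readouts) and fibrin onset time without tissue factor. The ladder
#' respects the reactivity ordering M1 < M2, M3 < M4, M5 < M6 <= M7; without
#' TF only the most GPVI-reactive surfaces develop fibrin within the
#' observation window. Values are generator defaults chosen as a plausible
#' ladder, not measurements.
#'
#' @return Tibble with `surface`, `p1_plateau`, `tfib0`.
#' @export
surface_profiles <- function() {
  tibble(
    surface = c("M1", "M2", "M3", "M4", "M5", "M6", "M7", "M8", "M9"),
    p1_plateau = c(3, 20, 22, 32, 34, 50, 53, 50, 50),
    tfib0 = c(Inf, Inf, Inf, 10, 9.5, 9, 7, 9, 9)
  )
}

#' Default generator settings
#'
#' Kinetic constants, condition effect sizes and noise amplitudes used by
#' [generate_parameter_cohort()]. All tunables live here so alternative
#' scenarios can be expressed without touching code.
#'
#' @return Named list of defaults.
#' @export
cohort_defaults <- function() {
  list(
    # logistic half-times / steepness per readout (min)
    t50 = c(P1 = 1.8, P2 = 2.8, P3 = 2.0, P4 = 1.5, P5 = 1.8, P6 = 2.6),
    tau = c(P1 = 0.9, P2 = 1.0, P3 = 0.9, P4 = 0.7, P5 = 0.8, P6 = 0.9),
    fib_tau = 1.5,          # fibrin accumulation time constant after onset
    tf_k = 25,              # half-effect TF dose on fibrin onset (pM)
    tfib_min = 4.0,         # fastest attainable fibrin onset (min)
    tfib_cap = 12,          # virtual onset for non-fibrin surfaces once TF present
    cti_delay = c(no_tf = 1.0, tf = 2.0),   # intrinsic-pathway block (min)
    cti_fibrin = c(no_tf = 0.85, tf = 0.6), # fibrin plateau multipliers
    cti_thrombus_tf = 0.9,
    ifviia_neutralise = 0.05,  # residual effective TF dose fraction
    ifviia_thrombus = 0.9,
    tm_delay = 2.0,            # TM/APC fibrin onset delay (min)
    tm_ps = 0.6, tm_fibrin = 0.7,
    low_shear_plateau = 0.65,  # platelet deposition factor at 150/s
    low_shear_tf_gain = 0.35,  # TF enhancement factor at 150/s
    # platelet-primed fibrin: weakly activating surfaces (large headroom)
    # support less and later fibrin at low shear
    low_shear_fib_penalty = 0.4,
    low_shear_fib_delay = 2.0,
    tf_gain = c(platelet = 0.25, ps = 0.5, thrombus = 0.4),
    headroom_ref = 55,         # surfaces near this plateau gain little from TF
    fib_base = 10, fib_slope = 0.55,  # fibrin plateau = base + slope * reactivity
    noise = list(between_subject = 0.12, residual_sac = 1.2,
                 residual_score = 0.2, tfib_sd = 0.35),
    n_replicates = 2   # duplicate flow runs per blood sample, averaged
  )
}

#' Noiseless run profile for a surface under a condition and template
#'
#' The analytic ground truth behind the cohort generator: plateau levels per
#' readout and the fibrin onset time, before any between-subject or residual
#' noise is applied. Useful as the oracle for dose-response and template
#' tests.
#'
#' @param surface Surface id (`M1`--`M9`).
#' @param shear Wall shear rate, 150 or 1000 (1/s).
#' @param tf TF dose in pM (co-coated for M1--M7; in-medium for M8--M9).
#' @param ifviia,cti Logical intervention flags.
#' @param tm Logical; apply the surface's TM/APC co-coat (M8/M9 only).
#' @param template An [effect_template()].
#' @param defaults Settings list, see [cohort_defaults()].
#' @return Named list: plateaus per readout family, score caps, `t_fib`.
#' @export
expected_profile <- function(surface, shear = 1000, tf = 0, ifviia = FALSE,
                             cti = FALSE, tm = FALSE,
                             template = effect_template(),
                             defaults = cohort_defaults()) {
  sp <- surface_profiles()
  row <- sp[sp$surface == surface, ]
  if (nrow(row) == 0) abort(sprintf("unknown surface '%s'", surface))
  .run_profile(
    base = row$p1_plateau, tfib0 = row$tfib0, surface = surface,
    shear = shear, tf = tf, ifviia = ifviia, cti = cti, tm = tm,
    template = template, d = defaults
  )
}

# vectorised over the run grid; all arguments same length (or scalar template)
.run_profile <- function(base, tfib0, surface, shear, tf, ifviia, cti, tm,
                         template, d) {
  if (inherits(template, "effect_template")) template <- list(template)
  tpl <- function(field) vapply(template, `[[`, numeric(1), field)
  stopifnot(all(shear %in% c(150, 1000)), all(tf >= 0))

  tm_on <- tm & surface %in% c("M8", "M9")
  tm_eff <- ifelse(tm_on, tpl("tm_scale"), 0)

  shear_plat <- ifelse(shear == 150, d$low_shear_plateau, 1)
  g_shear <- ifelse(shear == 150, d$low_shear_tf_gain, 1)

  d_eff <- ifelse(ifviia, tf * d$ifviia_neutralise, tf)
  tf_frac <- d_eff / (d_eff + d$tf_k)
  headroom <- pmax(0, 1 - base / d$headroom_ref)

  plat_mult <- shear_plat * (1 + d$tf_gain[["platelet"]] * tf_frac * g_shear * headroom) *
    tpl("platelet")
  ps_mult <- shear_plat * (1 + d$tf_gain[["ps"]] * tf_frac * g_shear * headroom) *
    tpl("ps") * ifelse(tm_on, 1 - (1 - d$tm_ps) * tm_eff, 1)
  thr_mult <- shear_plat * (1 + d$tf_gain[["thrombus"]] * tf_frac * g_shear * headroom) *
    tpl("thrombus") *
    ifelse(ifviia, d$ifviia_thrombus, 1) *
    ifelse(cti & tf > 0, d$cti_thrombus_tf, 1)
  fib_mult <- tpl("fibrin") *
    ifelse(cti, ifelse(tf > 0, d$cti_fibrin[["tf"]], d$cti_fibrin[["no_tf"]]), 1) *
    ifelse(tm_on, 1 - (1 - d$tm_fibrin) * tm_eff, 1) *
    ifelse(shear == 150, 1 - d$low_shear_fib_penalty * headroom, 1)

  # fibrin onset: TF dose pulls the onset from the surface baseline towards
  # the floor; interventions and templates then shift it
  t0_eff <- ifelse(tf_frac > 0, pmin(tfib0, d$tfib_cap), tfib0)
  t_fib <- ifelse(tf_frac > 0, t0_eff - (t0_eff - d$tfib_min) * tf_frac, t0_eff)
  t_fib <- t_fib +
    ifelse(cti, ifelse(tf > 0, d$cti_delay[["tf"]], d$cti_delay[["no_tf"]]), 0) +
    ifelse(tm_on, d$tm_delay * tm_eff, 0) +
    ifelse(shear == 150, d$low_shear_fib_delay * headroom, 0) +
    tpl("tfib_shift")
  t_fib <- pmax(t_fib, 1.5)
  fibrin_on <- is.finite(t_fib)

  list(
    p1_plateau = clamp(base * plat_mult, 0, 100),
    p2_plateau = clamp(0.35 * base * ps_mult, 0, 100),
    p3_plateau = clamp(1.15 * base * thr_mult, 0, 100),
    p4_cap = 5 * pmin(base * thr_mult / d$headroom_ref, 1),
    p5_cap = 3 * pmin(base * thr_mult / d$headroom_ref, 1),
    p6_cap = 3 * pmin(base * thr_mult / (d$headroom_ref + 5), 1),
    p7_plateau = ifelse(
      fibrin_on,
      clamp((d$fib_base + d$fib_slope * base) * fib_mult, 0, 100), 0
    ),
    t_fib = t_fib
  )
}

#' Generate a synthetic parameter cohort
#'
#' Draws complete 41-value parameter records (P1--P8 at t = 0, 2, 4, 6, 8 min
#' plus the scalar P9) for control subjects and template-defined patients
#' across surfaces and flow conditions, bypassing image synthesis. The
#' generative model is the logistic-coverage kinetics of
#' [expected_profile()]: early platelet/thrombus accumulation, late
#' onset-gated fibrin, TF dose-dependent shortening of the time to fibrin,
#' TM/APC-induced fibrin delay, and the surface reactivity ladder. A
#' subject-level lognormal reactivity factor (shared across all of a
#' subject's runs) plus residual measurement noise give realistic
#' between-subject structure.
#'
#' @param n_controls Number of healthy control subjects (>= 2).
#' @param patients Named list of [effect_template()]s, one per patient; may be
#'   empty.
#' @param surfaces Character vector of surface ids.
#' @param conditions Tibble with columns `shear`, `tf`, `ifviia`, `cti`, `tm`
#'   (one row per condition); see [default_conditions()].
#' @param seed Integer seed; all randomness flows from it.
#' @param defaults Settings list, see [cohort_defaults()].
#' @return Long tibble of parameter records: `subject`, `group`, `surface`,
#'   `shear`, `tf`, `ifviia`, `cti`, `tm`, `parameter`, `time`, `value`,
#'   `provenance`. `P9` rows carry `time = NA`.
#' @examples
#' rec <- generate_parameter_cohort(n_controls = 3, seed = 1)
#' dplyr::count(rec, subject, surface, tf)  # 41 values per record
#' @export
generate_parameter_cohort <- function(n_controls = 10, patients = list(),
                                      surfaces = c("M6", "M7"),
                                      conditions = default_conditions(),
                                      seed = 1L,
                                      defaults = cohort_defaults()) {
  if (n_controls < 2) abort("need at least 2 control subjects")
  if (length(surfaces) == 0) abort("empty surface list")
  sp <- surface_profiles()
  if (!all(surfaces %in% sp$surface)) {
    abort(sprintf("unknown surface(s): %s",
                  paste(setdiff(surfaces, sp$surface), collapse = ", ")))
  }
  d <- defaults
  subjects <- tibble(
    subject = c(
      sprintf("ctrl_%02d", seq_len(n_controls)),
      if (length(patients)) sprintf("pat_%02d", seq_along(patients))
    ),
    group = c(
      rep("control", n_controls),
      vapply(patients, `[[`, character(1), "name")
    ),
    template = c(
      rep(list(effect_template()), n_controls),
      unname(patients)
    )
  )

  withr::with_seed(seed, {
    subjects$reactivity <- rlnorm(nrow(subjects), 0, d$noise$between_subject)

    runs <- tidyr::expand_grid(subjects, surface = surfaces, conditions) |>
      left_join(sp, by = "surface")

    prof <- .run_profile(
      base = runs$p1_plateau * runs$reactivity, tfib0 = runs$tfib0,
      surface = runs$surface, shear = runs$shear, tf = runs$tf,
      ifviia = runs$ifviia, cti = runs$cti, tm = runs$tm,
      template = runs$template, d = d
    )
    runs$template <- NULL
    for (nm in setdiff(names(prof), "t_fib")) runs[[nm]] <- prof[[nm]]
    rep_f <- 1 / sqrt(max(d$n_replicates %||% 1, 1))
    runs$t_fib <- prof$t_fib + rnorm(nrow(runs), 0, d$noise$tfib_sd * rep_f)
    runs$run_id <- seq_len(nrow(runs))

    times <- c(0, 2, 4, 6, 8)
    long <- tidyr::expand_grid(runs, time = times)

    val <- function(plateau, p, t) plateau * logistic_rise(t, d$t50[[p]], d$tau[[p]])
    noise_sac <- function(x, t) {
      clamp(x + ifelse(t > 0, rnorm(length(x), 0, d$noise$residual_sac * rep_f), 0), 0, 100)
    }
    noise_score <- function(latent, t, top) {
      raw <- latent + ifelse(t > 0, rnorm(length(latent), 0, d$noise$residual_score * rep_f), 0)
      as.numeric(clamp(round(raw), 0, top))
    }

    per_time <- long |>
      mutate(
        P1 = noise_sac(val(p1_plateau, "P1", time), time),
        P2 = noise_sac(val(p2_plateau, "P2", time), time),
        P3 = noise_sac(val(p3_plateau, "P3", time), time),
        P4 = noise_score(p4_cap * logistic_rise(time, d$t50[["P4"]], d$tau[["P4"]]), time, 5),
        P5 = noise_score(p5_cap * logistic_rise(time, d$t50[["P5"]], d$tau[["P5"]]), time, 3),
        P6 = noise_score(p6_cap * logistic_rise(time, d$t50[["P6"]], d$tau[["P6"]]), time, 3),
        P7 = ifelse(
          time < t_fib | p7_plateau == 0, 0,
          noise_sac(p7_plateau * fibrin_rise(time, t_fib, d$fib_tau), time)
        ),
        P8 = ifelse(
          time < t_fib | p7_plateau == 0, 0,
          noise_score(3 * pmin(p7_plateau * fibrin_rise(time, t_fib, d$fib_tau) / 25, 1),
                      time, 3)
        )
      ) |>
      select(run_id, subject, group, surface, shear, tf, ifviia, cti, tm,
             time, P1:P8) |>
      pivot_longer(P1:P8, names_to = "parameter", values_to = "value")

    p9 <- runs |>
      mutate(
        parameter = "P9", time = NA_real_,
        value = ifelse(
          is.finite(t_fib) & t_fib <= 10 & p7_plateau > 0,
          clamp(11 - t_fib, 1, 11), 0
        )
      ) |>
      select(run_id, subject, group, surface, shear, tf, ifviia, cti, tm,
             time, parameter, value)

    bind_rows(per_time, p9) |>
      arrange(run_id, parameter, time) |>
      select(-run_id) |>
      mutate(provenance = "synthetic") |>
      as_tibble()
  })
}

#' Default flow conditions
#'
#' High-shear (1000/s) runs with and without co-coated TF (500 pM), no
#' pathway blockers, no anticoagulant co-coat.
#'
#' @return Condition tibble for [generate_parameter_cohort()].
#' @export
default_conditions <- function() {
  tibble(shear = 1000, tf = c(0, 500), ifviia = FALSE, cti = FALSE, tm = FALSE)
}

#' Flow conditions for the anticoagulant surfaces
#'
#' Paired runs with TF (10 pM) in the recalcification medium, with and
#' without the TM/APC co-coat active, as used for the TM-effect analysis.
#'
#' @return Condition tibble.
#' @export
anticoagulant_conditions <- function() {
  tibble(shear = 1000, tf = 10, ifviia = FALSE, cti = FALSE, tm = c(FALSE, TRUE))
}

#' All eight intervention classes
#'
#' The combinations of TF (dose `tf_dose` when present), iFVIIa and CTI,
#' indexed by [condition_class()].
#'
#' @param tf_dose TF dose in pM for TF-present classes.
#' @param shear Wall shear rate.
#' @return Condition tibble with a `class` column (0..7).
#' @export
intervention_conditions <- function(tf_dose = 500, shear = 1000) {
  crossing(tf_present = c(FALSE, TRUE), ifviia = c(FALSE, TRUE),
           cti = c(FALSE, TRUE)) |>
    mutate(
      shear = shear,
      tf = ifelse(tf_present, tf_dose, 0),
      tm = FALSE,
      class = condition_class(tf_present, ifviia, cti)
    ) |>
    select(shear, tf, ifviia, cti, tm, class)
}

#' Generate a synthetic thrombin-generation curve
#'
#' A smooth unimodal thrombin pulse after a lag phase, either a gamma-like
#' pulse (default) or a triangle. The exact area (endogenous thrombin
#' potential) of the noiseless curve over the sampled window is attached as
#' attribute `etp_analytic`, for use as an oracle.
#'
#' @param lag Lag time before thrombin appears, min.
#' @param peak Peak thrombin concentration, nM (>= 0).
#' @param width Time from onset to peak (gamma) or rise/fall half-width
#'   (triangle), min (> 0).
#' @param grid Sampling step, min (> 0).
#' @param duration Assay duration, min.
#' @param shape `"gamma"` or `"triangle"`.
#' @param noise_sd Additive Gaussian noise SD, nM.
#' @param seed Optional integer seed for the noise.
#' @return Tibble `time`, `thrombin` with attributes `etp_analytic`,
#'   `peak_analytic`, `lag_true`.
#' @examples
#' tc <- generate_thrombin_curve(lag = 3, peak = 100, width = 5,
#'                               shape = "triangle", grid = 0.5)
#' attr(tc, "etp_analytic")  # 500 nM min
#' @export
generate_thrombin_curve <- function(lag = 3, peak = 150, width = 8,
                                    grid = 0.25, duration = 60,
                                    shape = c("gamma", "triangle"),
                                    noise_sd = 0, seed = NULL) {
  shape <- arg_match(shape)
  if (grid <= 0) abort("grid step must be > 0")
  if (peak < 0) abort("peak must be >= 0")
  if (width <= 0) abort("width must be > 0")
  t <- seq(0, duration, by = grid)
  u <- pmax(t - lag, 0)
  if (shape == "gamma") {
    a <- 2  # shape - 1; mode at u = width, height = peak
    y <- peak * (u / width)^a * exp(a * (1 - u / width))
    y[u == 0] <- 0
    # closed-form truncated area of the pulse
    ulim <- max(duration - lag, 0)
    etp <- peak * exp(a) * width * gamma(a + 1) / a^(a + 1) *
      stats::pgamma(ulim, shape = a + 1, rate = a / width)
  } else {
    y <- ifelse(u <= width, peak * u / width,
                pmax(peak * (1 - (u - width) / width), 0))
    etp <- peak * width  # full triangle area, assuming duration covers it
  }
  if (noise_sd > 0) {
    draw <- function() pmax(y + rnorm(length(y), 0, noise_sd), 0)
    y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  out <- tibble(time = t, thrombin = y)
  attr(out, "etp_analytic") <- etp
  attr(out, "peak_analytic") <- if (peak > 0 && max(u) >= width) peak else max(y)
  attr(out, "lag_true") <- lag
  out
}
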