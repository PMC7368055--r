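test_that("cohort generator is deterministic and respects degenerate noise", {
  a <- generate_parameter_cohort(n_controls = 3, surfaces = "M6", seed = 11)
  b <- generate_parameter_cohort(n_controls = 3, surfaces = "M6", seed = 11)
  expect_identical(a, b)
  c <- generate_parameter_cohort(n_controls = 3, surfaces = "M6", seed = 12)
  expect_false(identical(a, c))

  quiet <- cohort_defaults()
  quiet$noise <- list(between_subject = 0, residual_sac = 0,
                      residual_score = 0, tfib_sd = 0)
  rec <- generate_parameter_cohort(n_controls = 3, surfaces = "M6", seed = 1,
                                   defaults = quiet)
  per_subject <- rec |>
    tidyr::pivot_wider(names_from = "subject", values_from = "value")
  expect_equal(per_subject$ctrl_01, per_subject$ctrl_02)
  expect_equal(per_subject$ctrl_01, per_subject$ctrl_03)
})

test_that("all values vanish at t = 0 and respect registry ranges", {
  rec <- generate_parameter_cohort(n_controls = 4, patients = patient_templates(),
                                   surfaces = c("M1", "M6"), seed = 2)
  expect_true(all(rec$value[!is.na(rec$time) & rec$time == 0] == 0))
  expect_silent(validate_records(rec))
})

test_that("surface reactivity ladder is reproduced in mean platelet adhesion", {
  rec <- generate_parameter_cohort(
    n_controls = 8, surfaces = paste0("M", 1:7),
    conditions = dplyr::tibble(shear = 1000, tf = 0, ifviia = FALSE,
                               cti = FALSE, tm = FALSE),
    seed = 3
  )
  m <- rec |>
    dplyr::filter(parameter == "P1", time == 8) |>
    dplyr::summarise(v = mean(value), .by = surface)
  v <- setNames(m$v, m$surface)
  expect_lt(v[["M1"]], min(v[["M2"]], v[["M3"]]))
  expect_lt(max(v[["M2"]], v[["M3"]]), min(v[["M4"]], v[["M5"]]))
  expect_lt(max(v[["M4"]], v[["M5"]]), v[["M6"]])
  expect_lte(v[["M6"]], v[["M7"]] + 3)  # M6 <= M7 within noise
})

test_that("TF dose sweep shortens the analytic fibrin onset strictly", {
  doses <- c(0, 10, 50, 150, 500)
  tfib <- vapply(doses, function(d) expected_profile("M6", tf = d)$t_fib,
                 numeric(1))
  expect_true(all(diff(tfib) < 0))
  # a surface without intrinsic fibrin gains an onset only once TF is present
  expect_identical(expected_profile("M2", tf = 0)$t_fib, Inf)
  expect_true(is.finite(expected_profile("M2", tf = 500)$t_fib))
})

test_that("a null-fibrin template forces P7 and P9 to zero", {
  null_fib <- effect_template("null_fibrin", fibrin = 0)
  rec <- generate_parameter_cohort(n_controls = 2,
                                   patients = list(p = null_fib),
                                   surfaces = "M6", seed = 4)
  pat <- rec |> dplyr::filter(group == "null_fibrin",
                              parameter %in% c("P7", "P9"))
  expect_true(all(pat$value == 0))
})

test_that("generator rejects degenerate cohort requests", {
  expect_error(generate_parameter_cohort(n_controls = 1), "at least 2")
  expect_error(generate_parameter_cohort(surfaces = character(0)), "empty")
  expect_error(generate_parameter_cohort(surfaces = "M77"), "unknown")
})

test_that("image runs are deterministic with exact ground truth", {
  a <- generate_run_images(seed = 5, dim = c(96, 96))
  b <- generate_run_images(seed = 5, dim = c(96, 96))
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)

  # truth %SAC equals the mask foreground fraction exactly
  for (ch in c("platelet", "ps", "fibrin")) {
    sac <- a$truth$sac |> dplyr::filter(channel == ch)
    frac <- vapply(a$truth$masks[[ch]], mean, numeric(1)) * 100
    expect_equal(sac$sac_true, unname(frac))
    expect_true(all(diff(sac$sac_true) >= 0))  # accretion is monotone
  }
})

test_that("empty scenes and absent fibrin render as pure background", {
  run <- generate_run_images(
    profiles = list(platelet = kinetic_profile(0, 1, 1),
                    ps = kinetic_profile(0, 1, 1),
                    fibrin = kinetic_profile(0, 1, 1, t_fib = Inf)),
    seed = 6, dim = c(96, 96)
  )
  expect_true(all(run$truth$sac$sac_true == 0))

  no_fib <- generate_run_images(
    profiles = list(platelet = kinetic_profile(30, 1.8, 0.9),
                    ps = kinetic_profile(8, 2.8, 1),
                    fibrin = kinetic_profile(25, 2, 1, t_fib = Inf)),
    seed = 6, dim = c(96, 96)
  )
  fib <- no_fib$truth$sac |> dplyr::filter(channel == "fibrin")
  expect_true(all(fib$sac_true == 0))
})

test_that("fibrin ground truth is zero before the onset time", {
  run <- generate_run_images(seed = 8, dim = c(96, 96))  # t_fib = 4
  fib <- run$truth$sac |> dplyr::filter(channel == "fibrin")
  expect_true(all(fib$sac_true[fib$time < 4] == 0))
})

test_that("undersized frames are rejected", {
  expect_error(generate_run_images(dim = c(32, 32)), "below minimum")
})

test_that("synthetic thrombin curves carry exact analytic areas", {
  tri <- generate_thrombin_curve(lag = 3, peak = 100, width = 5,
                                 shape = "triangle", grid = 0.5)
  expect_equal(attr(tri, "etp_analytic"), 500)

  flat <- generate_thrombin_curve(peak = 0, shape = "gamma")
  expect_true(all(flat$thrombin == 0))
  expect_equal(attr(flat, "etp_analytic"), 0)

  # closed form against a high-resolution quadrature oracle
  g <- generate_thrombin_curve(lag = 4, peak = 180, width = 7, grid = 0.001,
                               duration = 90)
  quad <- pracma::trapz(g$time, g$thrombin)
  expect_equal(attr(g, "etp_analytic"), quad, tolerance = 1e-5)

  expect_error(generate_thrombin_curve(grid = 0), "grid")
  expect_error(generate_thrombin_curve(width = -1), "width")
})
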