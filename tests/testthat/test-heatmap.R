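test_that("row scaling maps endpoints to 0/10 and round-trips", {
  d <- tibble::tibble(parameter = "P1", value = c(1, 3, 5))
  s <- scale_parameters(d)
  expect_equal(s$scaled, c(0, 5, 10))

  const <- tibble::tibble(parameter = "P2", value = c(4, 4, 4))
  sc <- scale_parameters(const)
  expect_equal(sc$scaled, c(0, 0, 0))
  expect_true(scaling_record(sc)$constant)

  rec <- generate_parameter_cohort(n_controls = 3, surfaces = "M6", seed = 1)
  s2 <- scale_parameters(rec)
  back <- inverse_scale(s2)
  expect_lt(max(abs(back$unscaled - back$value)), 1e-9)
  rng <- s2 |> dplyr::summarise(lo = min(scaled), hi = max(scaled),
                                .by = parameter)
  expect_true(all(rng$lo == 0 & (rng$hi == 10 | rng$hi == 0)))

  expect_error(scale_parameters(tibble::tibble(parameter = character(0),
                                               value = numeric(0))), "empty")
})

test_that("scaling is invariant to affine transforms of the raw units", {
  withr::local_seed(2)
  d <- tibble::tibble(parameter = rep(c("P1", "P2"), each = 6),
                      value = runif(12, 0, 50))
  d2 <- d |> dplyr::mutate(value = 3.2 * value - 7)
  expect_equal(scale_parameters(d)$scaled, scale_parameters(d2)$scaled)
})

test_that("the subtraction heatmap retains exactly the out-of-band cells", {
  key <- tibble::tibble(parameter = rep(paste0("P", 1:3), each = 2),
                        time = rep(c(4, 8), 3))
  a <- key |> dplyr::mutate(scaled = c(5, 5, 7, 2, 4, 9))
  b <- key |> dplyr::mutate(scaled = c(5, 5, 5, 2.5, 3.5, 4))
  d <- subtraction_heatmap(a, b, band_mean = 0, band_sd = 1)
  expect_equal(d$value, c(0, 0, 2, 0, 0, 5))
  expect_equal(d$retained, abs(d$delta) > 1)

  # SD 0 retains every nonzero difference; an infinite band retains none
  d0 <- subtraction_heatmap(a, b, band_sd = 0)
  expect_equal(d0$retained, d0$delta != 0)
  dInf <- subtraction_heatmap(a, b, band_sd = Inf)
  expect_true(all(dInf$value == 0))

  expect_error(subtraction_heatmap(a, b[-1, ]), "mismatch|align")
})

test_that("interval deltas split early and late accumulation", {
  lin <- tibble::tibble(parameter = "P1", time = c(0, 4, 8),
                        scaled = c(0, 5, 10))
  d <- interval_deltas(lin)
  expect_equal(c(d$dt1, d$dt2), c(5, 5))

  sat <- tibble::tibble(parameter = "P4", time = c(0, 4, 8),
                        scaled = c(0, 8, 8))
  d2 <- interval_deltas(sat)
  expect_equal(d2$dt2, 0)

  # generator fibrin kinetics: late interval dominates
  rec <- generate_parameter_cohort(
    n_controls = 2, surfaces = "M6",
    conditions = tibble::tibble(shear = 1000, tf = 500, ifviia = FALSE,
                                cti = FALSE, tm = FALSE),
    seed = 3
  )
  d3 <- interval_deltas(scale_parameters(rec)) |>
    dplyr::summarise(dt1 = mean(dt1), dt2 = mean(dt2), .by = parameter)
  expect_lt(d3$dt1[d3$parameter == "P7"], 0.5)
  expect_gt(d3$dt2[d3$parameter == "P7"], d3$dt1[d3$parameter == "P7"])
})

test_that("summed scaled effect is a plain signed sum over the scope", {
  d <- tibble::tibble(parameter = c("P1", "P7"), surface = "M3",
                      time = c(4, 8), delta = c(2, -0.5),
                      retained = TRUE, value = c(2, -0.5))
  expect_equal(summed_scaled_effect(d), 1.5)
  filtered <- d |> dplyr::mutate(value = 0)
  expect_equal(summed_scaled_effect(filtered), 0)
  expect_error(summed_scaled_effect(d, surfaces = "M9"), "empty")
})

test_that("the TF effect on a weakly activating surface is shear-dependent", {
  # per shear rate: scale across the surface panel, then sum the TF-vs-no-TF
  # subtraction over the weakly GPVI-activating laminin surface only
  tf_sum <- function(sh, defaults) {
    rec <- generate_parameter_cohort(
      n_controls = 5, surfaces = c("M3", "M6"),
      conditions = tibble::tibble(shear = sh, tf = c(0, 500), ifviia = FALSE,
                                  cti = FALSE, tm = FALSE),
      seed = 7, defaults = defaults
    )
    m <- scale_parameters(rec) |>
      dplyr::summarise(scaled = mean(scaled),
                       .by = c(parameter, time, surface, tf))
    d <- subtraction_heatmap(m |> dplyr::filter(tf == 500) |> dplyr::select(-tf),
                             m |> dplyr::filter(tf == 0) |> dplyr::select(-tf),
                             band_sd = 0.5)
    summed_scaled_effect(d, surfaces = "M3")
  }
  # default physics: the TF effect is larger at high shear
  expect_gt(tf_sum(1000, cohort_defaults()), tf_sum(150, cohort_defaults()))
  # a template programmed with a TF response at high shear only
  high_only <- cohort_defaults()
  high_only$low_shear_tf_gain <- 0
  high_only$low_shear_fib_penalty <- 1
  high_only$low_shear_fib_delay <- 12
  expect_gt(tf_sum(1000, high_only), 4 * tf_sum(150, high_only))
})

test_that("complete-linkage clustering matches the brute-force oracle", {
  two <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 2, byrow = TRUE)
  rownames(two) <- c("a", "b")
  cl <- cluster_rows(two)
  expect_equal(cl$tree$height, 0)

  three <- matrix(c(0, 0, 1, 0, 10, 0), ncol = 2, byrow = TRUE)
  rownames(three) <- c("a", "b", "c")
  cl3 <- cluster_rows(three)
  expect_equal(sort(cl3$tree$merge[1, ]), c(-2, -1))  # close pair first

  withr::local_seed(4)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * 4), n, 4)
    rownames(m) <- paste0("r", seq_len(n))
    hc <- cluster_rows(m)$tree
    coph <- as.matrix(stats::cophenetic(hc))[rownames(m), rownames(m)]
    expect_equal(unname(coph), oracle_complete_linkage(m), tolerance = 1e-10)
  }

  expect_error(cluster_rows(matrix(1, 1, 3)), "2 rows")
  bad <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(cluster_rows(bad), "missing")
})

test_that("cross-surface correlation tracks the shared donor signature", {
  rec <- generate_parameter_cohort(n_controls = 10,
                                   surfaces = c("M6", "M7"), seed = 5)
  sc <- scale_parameters(rec) |> dplyr::filter(tf == 500)
  res <- correlate_surfaces(sc, "M6", "M7")
  late <- res |> dplyr::filter(!is.na(r),
                               parameter %in% c("P1", "P2", "P3", "P7"),
                               is.na(time) | time >= 4)
  expect_gt(mean(late$r > 0.5), 0.8)

  # independent noise, no shared subject effect: mean r near zero
  withr::local_seed(6)
  noise <- tidyr::expand_grid(subject = sprintf("s%02d", 1:10),
                              surface = c("A", "B"),
                              parameter = "P1", time = c(2, 4, 6, 8))
  noise$scaled <- rnorm(nrow(noise))
  r0 <- correlate_surfaces(noise, "A", "B")
  expect_lt(abs(mean(r0$r)), 0.35)
})
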