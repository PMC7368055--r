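test_that("background suppression flattens gradients but keeps objects", {
  withr::local_seed(1)
  H <- 128
  # constant image: residual amplitude below 1% of range
  const <- matrix(120, H, H)
  out <- suppress_background(const)
  expect_lt(diff(range(out)), 0.01 * 255)

  # disc on a strong linear illumination ramp
  ramp <- outer(seq_len(H), seq_len(H), function(i, j) 40 * (i + j) / (2 * H))
  disc <- matrix(0, H, H)
  cx <- 64; cy <- 64
  disc[(row(disc) - cx)^2 + (col(disc) - cy)^2 <= 12^2] <- 100
  img <- 20 + ramp + disc
  filt <- suppress_background(img, low_period_px = 100, high_period_px = 3)
  # plane-fit amplitude attenuated at least 10x more than the disc contrast
  in_disc <- (row(disc) - cx)^2 + (col(disc) - cy)^2 <= 8^2
  bg <- disc == 0 & !in_disc
  contrast_before <- mean(img[in_disc]) - mean(img[bg])
  contrast_after <- mean(filt[in_disc]) - mean(filt[bg])
  plane_after <- plane_amplitude(replace(filt, in_disc, mean(filt[bg])))
  plane_before <- plane_amplitude(replace(img, in_disc, mean(img[bg])))
  att_plane <- plane_before / max(plane_after, 1e-9)
  att_disc <- contrast_before / max(contrast_after, 1e-9)
  expect_gt(att_plane, 10 * att_disc)

  expect_error(suppress_background(array(0, c(4, 4, 2))), "matrix")
})

test_that("background suppression is idempotent", {
  withr::local_seed(2)
  img <- matrix(runif(96 * 96, 0, 255), 96, 96)
  img <- img + outer(seq_len(96), seq_len(96), function(i, j) i / 3)
  once <- suppress_background(img, 100, 3)
  twice <- suppress_background(once, 100, 3)
  expect_lt(max(abs(twice - once)), 2)
})

test_that("thresholding is referenced to the t = 0 baseline", {
  withr::local_seed(3)
  H <- 96
  t0 <- matrix(20 + rnorm(H * H, 0, 3), H, H)
  # frame identical to baseline: (near-)empty mask
  mk <- threshold_channel(t0, t0)
  mk <- clean_mask(mk)
  expect_lt(mean(mk$mask) * 100, 0.3)

  # a bright disc is recovered within 5% of its true area
  frame <- t0
  disc <- (row(frame) - 48)^2 + (col(frame) - 48)^2 <= 20^2
  frame[disc] <- 200 + rnorm(sum(disc), 0, 3)
  mk2 <- threshold_channel(frame, t0)
  expect_lt(abs(sum(mk2$mask) - sum(disc)) / sum(disc), 0.05)
  expect_true(mk2$threshold > mean(t0))

  # all-foreground frame reads 100 %SAC (only the t0 floor applies)
  full <- matrix(200, H, H)
  mk3 <- threshold_channel(full, t0)
  expect_equal(mean(mk3$mask) * 100, 100)

  # saturated frames raise a QC flag
  sat <- matrix(255, H, H)
  expect_true("saturated" %in% threshold_channel(sat, t0)$qc)
})

test_that("mask cleanup removes speckle and preserves structures", {
  H <- 100
  speckle <- matrix(FALSE, H, H)
  withr::with_seed(4, speckle[sample(H * H, 40)] <- TRUE)
  # isolated single pixels vanish (sampled points are almost surely isolated)
  expect_lt(sum(clean_mask(speckle)), 5)

  square <- matrix(FALSE, H, H)
  square[26:75, 26:75] <- TRUE
  cleaned <- clean_mask(square)
  expect_lte(sum(xor(cleaned, square)), 4 * 50 * 2)  # within a 1-px border
  expect_true(all(cleaned[28:73, 28:73]))

  # a width-3 fibre polyline stays connected
  run <- withr::with_seed(5, {
    m <- matrix(FALSE, H, H)
    m[thrombospot:::.fibre_idx(H, H, 60, width = 3)] <- TRUE
    m
  })
  kept <- clean_mask(run)
  expect_gt(sum(kept), 0.7 * sum(run))
  expect_equal(max(label_components(kept)), 1)
})

test_that("component labelling is 8-connected and matches a flood-fill oracle", {
  diag2 <- matrix(FALSE, 5, 5)
  diag2[cbind(1:4, 1:4)] <- TRUE
  expect_equal(max(label_components(diag2)), 1)

  for (s in 1:5) {
    m <- withr::with_seed(s, matrix(runif(24 * 24) < 0.3, 24, 24))
    expect_equal(max(label_components(m)), oracle_component_count(m))
  }
})

test_that("%SAC quantification is exact on constructed masks", {
  H <- 64
  empty <- list(`0` = matrix(FALSE, H, H))
  q <- quantify_masks(empty)
  expect_equal(q$sac, 0)
  expect_equal(q$n_objects, 0)

  checker <- matrix(rep(c(TRUE, FALSE), length.out = H * H), H, H)
  expect_equal(quantify_masks(list(`2` = checker))$sac, 50)

  expect_error(quantify_masks(list(a = checker)), "named by capture time")
})

test_that("qc verification flags bad thresholds and respects the retry cap", {
  withr::local_seed(6)
  H <- 96
  t0 <- matrix(20 + rnorm(H * H, 0, 3), H, H)
  frame <- t0
  disc <- (row(frame) - 48)^2 + (col(frame) - 48)^2 <= 18^2
  frame[disc] <- 200
  good <- threshold_channel(frame, t0)
  res <- qc_verify(good, frame, t0)
  expect_gte(res$agreement, 0.9)
  expect_equal(res$retried, 0L)
  expect_false(res$flagged)

  wrong <- good
  wrong$mask <- matrix(rep(c(TRUE, FALSE), length.out = H * H), H, H)
  res2 <- qc_verify(wrong, frame, t0, retries = 1)
  expect_true(res2$flagged)
  expect_lte(res2$retried, 1L)
  expect_gt(res2$agreement, 0.5)  # the single re-run recovers the disc
})

test_that("segmentation recovers generator coverage within tolerance", {
  run <- generate_run_images(seed = 9, dim = c(192, 192))
  q <- quantify_run(run)
  cmp <- q |>
    dplyr::select(channel, time, sac) |>
    dplyr::left_join(run$truth$sac |> dplyr::select(channel, time, sac_true),
                     by = c("channel", "time")) |>
    dplyr::filter(channel %in% c("platelet", "ps", "fibrin"))
  expect_lt(mean(abs(cmp$sac - cmp$sac_true)), 2)
  # monotone scene: measured coverage non-decreasing within 1 %SAC
  mono <- cmp |> dplyr::summarise(ok = all(diff(sac) > -1), .by = channel)
  expect_true(all(mono$ok))
})
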