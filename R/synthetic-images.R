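#' Noise specification for synthetic microscopy frames
#'
#' Additive Gaussian background with a low-frequency illumination plane and
#' optional Poisson shot noise, on an 8-bit gray scale.
#'
#' @param background Mean background gray level.
#' @param illumination Peak-to-peak amplitude of the illumination gradient.
#' @param gaussian_sd SD of the additive Gaussian read noise.
#' @param shot Apply Poisson shot noise to the mean image.
#' @param signal Named per-channel foreground gray levels.
#' @return Named list.
#' @export
noise_spec <- function(background = 20, illumination = 10, gaussian_sd = 5,
                       shot = TRUE,
                       signal = c(platelet = 170, ps = 150, fibrin = 160)) {
  list(background = background, illumination = illumination,
       gaussian_sd = gaussian_sd, shot = shot, signal = signal)
}

# pixel indices of a filled disc, clipped to the frame
.disc_idx <- function(cx, cy, r, H, W) {
  rows <- max(1L, floor(cx - r)):min(H, ceiling(cx + r))
  cols <- max(1L, floor(cy - r)):min(W, ceiling(cy + r))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  keep <- (rr - cx)^2 + (cc - cy)^2 <= r^2
  (cc[keep] - 1L) * H + rr[keep]
}

# pixel indices of a random-walk fibre polyline, thickened to `width`
.fibre_idx <- function(H, W, len, width = 3) {
  x <- runif(1, width + 2, H - width - 2)
  y <- runif(1, width + 2, W - width - 2)
  theta <- runif(1, 0, 2 * pi)
  half <- floor(width / 2)
  off <- as.matrix(expand.grid(dr = -half:half, dc = -half:half))
  pts <- matrix(NA_real_, nrow = len, ncol = 2)
  for (i in seq_len(len)) {
    pts[i, ] <- c(x, y)
    theta <- theta + rnorm(1, 0, 0.15)
    x <- clamp(x + cos(theta), 2, H - 1)
    y <- clamp(y + sin(theta), 2, W - 1)
  }
  r <- pmin(pmax(round(rep(pts[, 1], each = nrow(off)) + off[, 1]), 1L), H)
  c <- pmin(pmax(round(rep(pts[, 2], each = nrow(off)) + off[, 2]), 1L), W)
  unique((c - 1L) * H + r)
}

#' Generate a synthetic multicolour flow-run image series
#'
#' Renders 8-bit frames at the capture times for four channels: a platelet
#' membrane-label channel (disc-shaped platelets accreting into aggregates),
#' a phosphatidylserine channel (a subset of the platelet objects), a fibrin
#' channel (fibre-like elongated random-walk structures appearing only once
#' the onset time `t_fib` has passed), and a bright-field proxy (inverted
#' composite). Exact ground-truth masks and %SAC accompany the frames, and
#' everything is deterministic given `seed`.
#'
#' @param profiles Named list with elements `platelet`, `ps`, `fibrin`, each
#'   a [kinetic_profile()] (the fibrin profile carries `t_fib`).
#' @param times Capture times, min.
#' @param dim Frame size `c(H, W)`; at least 64 px per side (4x the largest
#'   platelet radius).
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param disc_radius Range of platelet disc radii, px.
#' @param fibre_len Range of fibre lengths, px.
#' @return List with `frames` (per channel, per time, integer matrices),
#'   `truth` (`masks` per fluorescence channel and `sac` tibble of exact
#'   coverages plus object statistics), and `manifest` (times, channels,
#'   seed, pixel size).
#' @examples
#' run <- generate_run_images(seed = 7, dim = c(96, 96))
#' run$truth$sac
#' @export
generate_run_images <- function(profiles = list(
                                  platelet = kinetic_profile(40, 1.8, 0.9),
                                  ps = kinetic_profile(12, 2.8, 1.0),
                                  fibrin = kinetic_profile(25, 2, 1, t_fib = 4)
                                ),
                                times = c(0, 2, 4, 6, 8),
                                dim = c(256, 256),
                                noise = noise_spec(),
                                seed = 1L,
                                disc_radius = c(5, 15),
                                fibre_len = c(40, 80)) {
  H <- dim[1]; W <- dim[2]
  if (min(H, W) < 4 * max(disc_radius)) {
    abort(sprintf("frame size %dx%d below minimum (4x max object radius = %d px)",
                  H, W, 4 * max(disc_radius)))
  }
  stopifnot(all(c("platelet", "ps", "fibrin") %in% names(profiles)))

  withr::with_seed(seed, {
    plane <- noise$illumination *
      (outer(seq_len(H) / H, seq_len(W) / W, `+`) / 2 - 0.5)

    plat_mask <- matrix(FALSE, H, W)
    ps_mask <- matrix(FALSE, H, W)
    fib_mask <- matrix(FALSE, H, W)
    discs <- list()  # accreted platelet discs, reused for the PS subset
    n_ps <- 0L

    frames <- list(platelet = list(), ps = list(), fibrin = list(),
                   brightfield = list())
    masks <- list(platelet = list(), ps = list(), fibrin = list(),
                  brightfield = list())
    sac <- list()

    render <- function(mask, channel) {
      img <- if (channel == "brightfield") {
        235 - plane - 150 * mask
      } else {
        noise$background + plane + noise$signal[[channel]] * mask
      }
      if (noise$shot) img <- rpois(length(img), pmax(img, 0))
      img <- img + rnorm(length(img), 0, noise$gaussian_sd)
      matrix(as.integer(clamp(round(img), 0, 255)), H, W)
    }

    for (t in times) {
      # platelet accretion towards the profile's target coverage
      target <- profile_coverage(profiles$platelet, t)
      while (mean(plat_mask) * 100 < target) {
        d <- list(cx = runif(1, 1, H), cy = runif(1, 1, W),
                  r = runif(1, disc_radius[1], disc_radius[2]))
        discs[[length(discs) + 1L]] <- d
        plat_mask[.disc_idx(d$cx, d$cy, d$r, H, W)] <- TRUE
      }
      # PS channel: shrunken discs at a growing prefix of platelet objects
      target_ps <- min(profile_coverage(profiles$ps, t),
                       profile_coverage(profiles$platelet, t))
      while (mean(ps_mask) * 100 < target_ps && n_ps < length(discs)) {
        n_ps <- n_ps + 1L
        d <- discs[[n_ps]]
        ps_mask[.disc_idx(d$cx, d$cy, 0.65 * d$r, H, W)] <- TRUE
      }
      # fibrin fibres only once the onset has passed
      target_fib <- profile_coverage(profiles$fibrin, t)
      if (is.finite(profiles$fibrin$t_fib) && t >= profiles$fibrin$t_fib) {
        while (mean(fib_mask) * 100 < target_fib) {
          fib_mask[.fibre_idx(H, W, round(runif(1, fibre_len[1], fibre_len[2])))] <- TRUE
        }
      }
      bf_mask <- plat_mask | fib_mask
      key <- as.character(t)
      cur <- list(platelet = plat_mask, ps = ps_mask, fibrin = fib_mask,
                  brightfield = bf_mask)
      for (ch in names(cur)) {
        frames[[ch]][[key]] <- render(cur[[ch]], ch)
        masks[[ch]][[key]] <- cur[[ch]]
      }
      for (ch in c("platelet", "ps", "fibrin", "brightfield")) {
        lab_areas <- if (any(cur[[ch]])) {
          tabulate(label_components(cur[[ch]]))
        } else numeric(0)
        sac[[length(sac) + 1L]] <- tibble(
          channel = ch, time = t, sac_true = mean(cur[[ch]]) * 100,
          n_objects = length(lab_areas), areas = list(lab_areas)
        )
      }
    }

    list(
      frames = frames,
      truth = list(masks = masks, sac = list_rbind(sac)),
      manifest = list(
        times = times, channels = names(frames), seed = seed,
        dim = c(H, W), bit_depth = 8L, pixel_size_um = 0.108
      )
    )
  })
}
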