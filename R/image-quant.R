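#' Frequency-domain background suppression
#'
#' Band-pass filtering of an 8-bit grayscale frame: structures larger than
#' `low_period_px` (illumination gradients, image-wide trends) and noise
#' finer than `high_period_px` are removed in the Fourier domain. The frame
#' is mirror-padded before the transform so non-periodic gradients do not
#' leak across the boundary, the pass band is an ideal (0/1) radial mask —
#' which makes the operator exactly idempotent — and the output is linearly
#' mapped back onto the input's gray scale (matching mean and spread).
#'
#' @param frame Numeric matrix (grayscale).
#' @param low_period_px Structures with period above this are removed.
#' @param high_period_px Structures with period below this are removed.
#' @return Filtered matrix, same shape, same gray range as the input.
#' @export
suppress_background <- function(frame, low_period_px = 200, high_period_px = 3) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    abort("frame must be a numeric (grayscale) matrix")
  }
  H <- nrow(frame); W <- ncol(frame)
  if (!(high_period_px > 0 && high_period_px < low_period_px &&
        low_period_px <= 2 * min(H, W))) {
    abort("require 0 < high_period_px < low_period_px <= 2*min(dim)")
  }
  frame_range <- range(frame)
  if (diff(frame_range) == 0) return(matrix(mean(frame), H, W))

  # even (mirror) extension to 2H x 2W
  pad <- rbind(cbind(frame, frame[, W:1]), cbind(frame[H:1, ], frame[H:1, W:1]))
  H2 <- 2L * H; W2 <- 2L * W
  fr <- (seq_len(H2) - 1L); fr <- ifelse(fr > H2 / 2, fr - H2, fr) / H2
  fc <- (seq_len(W2) - 1L); fc <- ifelse(fc > W2 / 2, fc - W2, fc) / W2
  rho <- sqrt(outer(fr^2, fc^2, `+`))
  keep <- rho >= 1 / low_period_px & rho <= 1 / high_period_px

  Fhat <- stats::fft(pad) * keep
  out <- Re(stats::fft(Fhat, inverse = TRUE)) / (H2 * W2)
  out <- out[seq_len(H), seq_len(W)]

  # map back onto the input's gray scale by matching mean and spread; an
  # affine map keeps the ideal-mask filter exactly idempotent, and moment
  # matching (unlike min/max) is robust to clipped-pixel outliers
  s_out <- stats::sd(out)
  if (s_out == 0) return(matrix(mean(frame), H, W))
  (out - mean(out)) / s_out * stats::sd(frame) + mean(frame)
}

#' Threshold a filtered frame against its t = 0 baseline
#'
#' The binarisation threshold is the maximum of an automatic (Otsu)
#' threshold computed on the filtered frame and a floor derived from the
#' t = 0 frame of the same run and channel: mean(t0) + k * SD(t0). For the
#' fibrin channel the floor constant is larger so that the threshold sits
#' above the baseline fibrinogen-binding signal.
#'
#' @param filtered Filtered frame (numeric matrix).
#' @param t0_frame Filtered t = 0 frame from the same run/channel.
#' @param channel Channel id; `"fibrin"` selects the larger floor constant.
#' @param k Floor constant for non-fibrin channels.
#' @param fibrin_k Floor constant for the fibrin channel.
#' @return A `binary_mask`: list with `mask` (logical matrix), `channel`,
#'   `threshold`, and `qc` flags (`saturated` when >= 99% of pixels sit at
#'   the maximum gray level).
#' @export
threshold_channel <- function(filtered, t0_frame, channel = "platelet",
                              k = 3, fibrin_k = 5) {
  stopifnot(is.matrix(filtered), is.matrix(t0_frame),
            all(dim(filtered) == dim(t0_frame)))
  qc <- character(0)
  if (mean(filtered >= max(filtered)) >= 0.99 && max(filtered) >= 254) {
    qc <- c(qc, "saturated")
  }
  kk <- if (identical(channel, "fibrin")) fibrin_k else k
  floor_thr <- mean(t0_frame) + kk * stats::sd(t0_frame)
  rng <- range(filtered)
  # a constant frame carries no contrast for Otsu; only the t0 floor applies
  auto <- if (diff(rng) == 0) -Inf else {
    EBImage::otsu(EBImage::Image((filtered - rng[1]) / diff(rng)),
                  range = c(0, 1), levels = 256) * diff(rng) + rng[1]
  }
  thr <- max(auto, floor_thr)
  structure(
    list(mask = filtered > thr, channel = channel, threshold = thr, qc = qc),
    class = "binary_mask"
  )
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$mask else mask
}

#' Directional morphological cleanup of a binary mask
#'
#' Horizontal-then-vertical closing followed by horizontal-then-vertical
#' opening with line structuring elements of length `2 * radius_px + 1`.
#' Removes isolated noise pixels while preserving objects larger than the
#' element (including fibres of at least the element's width).
#'
#' @param mask Logical matrix or a `binary_mask`.
#' @param radius_px Half-length of the line elements (>= 1).
#' @return Same type as the input, cleaned.
#' @export
clean_mask <- function(mask, radius_px = 1) {
  stopifnot(radius_px >= 1)
  m <- as_mask_matrix(mask)
  len <- 2L * as.integer(radius_px) + 1L
  img <- EBImage::Image(m * 1)
  kh <- EBImage::makeBrush(len, shape = "line", angle = 0)
  kv <- EBImage::makeBrush(len, shape = "line", angle = 90)
  img <- EBImage::erode(EBImage::dilate(img, kh), kh)  # close horizontally
  img <- EBImage::erode(EBImage::dilate(img, kv), kv)  # close vertically
  img <- EBImage::dilate(EBImage::erode(img, kh), kh)  # open horizontally
  img <- EBImage::dilate(EBImage::erode(img, kv), kv)  # open vertically
  out <- EBImage::imageData(img) > 0.5
  if (inherits(mask, "binary_mask")) {
    mask$mask <- out
    mask
  } else out
}

#' 8-connected component labelling
#'
#' Labels the foreground of a binary mask with 8-connectivity (diagonal
#' neighbours join). Implemented on the pixel adjacency graph.
#'
#' @param mask Logical matrix or a `binary_mask`.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- as_mask_matrix(mask)
  H <- nrow(m); W <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0) return(lab)
  id <- integer(H * W)
  id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 <= W
    idx2 <- (c2[ok] - 1L) * H + r2[ok]
    ok2 <- m[idx2]
    edges <- c(edges, rbind(id[idx[ok]][ok2], id[idx2][ok2]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Fibre-like object statistics
#'
#' Objects are fibre candidates when their major-axis length and elongation
#' (major / minor axis ratio) exceed the configured minima; elongation is
#' derived from second-order image moments.
#'
#' @param labels Integer label matrix, e.g. from [label_components()].
#' @param min_length Minimum major-axis length, px.
#' @param min_elongation Minimum major/minor axis ratio.
#' @return Tibble: one row per object with `area`, `length`, `elongation`,
#'   `is_fibre`.
#' @export
fibre_stats <- function(labels, min_length = 20, min_elongation = 4) {
  n <- max(labels)
  if (n == 0) {
    return(tibble(object = integer(0), area = numeric(0), length = numeric(0),
                  elongation = numeric(0), is_fibre = logical(0)))
  }
  mom <- EBImage::computeFeatures.moment(labels)
  mom <- matrix(mom, nrow = n, dimnames = list(NULL, colnames(mom)))
  ecc <- pmin(mom[, "m.eccentricity"], 0.999999)
  elong <- 1 / sqrt(1 - ecc^2)
  tibble(
    object = seq_len(n),
    area = tabulate(labels[labels > 0], nbins = n),
    length = mom[, "m.majoraxis"],
    elongation = elong,
    is_fibre = mom[, "m.majoraxis"] >= min_length & elong >= min_elongation
  )
}

#' Quantify a series of binary masks
#'
#' Percent surface-area coverage is exact (100 x foreground / total pixels);
#' object statistics use 8-connected components.
#'
#' @param masks Named-by-time list of logical matrices or `binary_mask`
#'   objects for one channel.
#' @param frames Optional matching list of intensity frames (for mean
#'   foreground intensity).
#' @param channel Channel id recorded in the output.
#' @param fibre_config List with `min_length`, `min_elongation` for fibre
#'   candidate statistics.
#' @return Tibble per time point: `sac`, `n_objects`, `max_area`,
#'   `aggregate_area` (foreground in objects at/above the single-platelet
#'   cutoff is computed downstream from `areas`), `mean_intensity`,
#'   `n_fibres`, `fibre_length`, `areas` (list column), `threshold`, `qc`.
#' @export
quantify_masks <- function(masks, frames = NULL, channel = "platelet",
                           fibre_config = list(min_length = 20,
                                               min_elongation = 4)) {
  stopifnot(length(masks) >= 1)
  times <- suppressWarnings(as.numeric(names(masks)))
  if (anyNA(times)) abort("masks must be a list named by capture time")
  dims <- unique(lapply(masks, function(m) dim(as_mask_matrix(m))))
  if (length(dims) != 1) abort("masks must share one shape")
  purrr::imap(masks, function(mk, nm) {
    m <- as_mask_matrix(mk)
    lab <- label_components(m)
    n <- max(lab)
    areas <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else numeric(0)
    fs <- fibre_stats(lab, fibre_config$min_length, fibre_config$min_elongation)
    fr <- frames[[nm]]
    tibble(
      channel = channel,
      time = as.numeric(nm),
      sac = mean(m) * 100,
      n_objects = n,
      max_area = if (n > 0) max(areas) else 0,
      mean_intensity = if (!is.null(fr) && any(m)) mean(fr[m]) else NA_real_,
      n_fibres = sum(fs$is_fibre),
      fibre_length = sum(fs$length[fs$is_fibre]),
      areas = list(areas),
      threshold = if (inherits(mk, "binary_mask")) mk$threshold else NA_real_,
      qc = paste(if (inherits(mk, "binary_mask")) mk$qc else character(0),
                 collapse = ";")
    )
  }) |> list_rbind() |> arrange(time)
}

#' Verify a mask against its frame and re-threshold once if poor
#'
#' Agreement is the Jaccard overlap between the mask and the equally-sized
#' top-intensity pixel set of the frame. If agreement falls below `floor`,
#' thresholding is re-run once with a softened floor constant and the run is
#' flagged; at most `retries` re-runs happen.
#'
#' @param mask A `binary_mask` from [threshold_channel()].
#' @param frame The filtered frame the mask came from.
#' @param t0_frame The filtered baseline frame (for the re-run).
#' @param floor Minimum acceptable agreement.
#' @param k Floor constant used originally.
#' @param retries Maximum number of re-thresholding attempts.
#' @return List: `mask` (possibly re-thresholded), `agreement`, `retried`,
#'   `flagged`.
#' @export
qc_verify <- function(mask, frame, t0_frame, floor = 0.5, k = 3, retries = 1) {
  agree <- function(mk) {
    m <- as_mask_matrix(mk)
    f <- sum(m)
    if (f == 0) return(1)  # empty mask: nothing to contradict
    top <- frame >= stats::quantile(frame, 1 - f / length(frame))
    sum(m & top) / sum(m | top)
  }
  a <- agree(mask)
  retried <- 0L
  while (a < floor && retried < retries) {
    retried <- retried + 1L
    mask <- threshold_channel(frame, t0_frame, channel = mask$channel,
                              k = max(k - retried, 1),
                              fibrin_k = max(k + 2 - retried, 1))
    mask$qc <- union(mask$qc, "rethresholded")
    a <- agree(mask)
  }
  list(mask = mask, agreement = a, retried = retried,
       flagged = retried > 0 || a < floor)
}

#' Quantify one synthetic or loaded flow run end-to-end
#'
#' Applies background suppression, t = 0-referenced thresholding,
#' morphological cleanup, QC verification and coverage quantification to
#' every channel and time point of a run (the bright-field proxy is inverted
#' before filtering, so thrombi appear bright).
#'
#' @param run A run object as produced by [generate_run_images()] (elements
#'   `frames` and `manifest`), or a compatible list of frames.
#' @param low_period_px,high_period_px Band-pass periods for
#'   [suppress_background()].
#' @param k,fibrin_k Threshold floor constants.
#' @param clean_radius Line-element half-length for [clean_mask()].
#' @return Tidy tibble of per-channel, per-time statistics (see
#'   [quantify_masks()]), with the masks attached as attribute `"masks"`.
#' @export
quantify_run <- function(run, low_period_px = NULL, high_period_px = 3,
                         k = 3, fibrin_k = 5, clean_radius = 1) {
  frames <- run$frames
  stopifnot(is.list(frames), length(frames) >= 1)
  if (is.null(low_period_px)) {
    dims <- dim(frames[[1]][[1]])
    low_period_px <- min(200, 2 * min(dims))
  }
  out <- list()
  all_masks <- list()
  for (ch in names(frames)) {
    series <- frames[[ch]]
    prep <- function(f) {
      f <- if (ch == "brightfield") 255 - f else f
      suppress_background(f, low_period_px, high_period_px)
    }
    filt <- lapply(series, prep)
    t0 <- filt[[1]]
    masks <- purrr::imap(filt, function(f, nm) {
      mk <- threshold_channel(f, t0, channel = ch, k = k, fibrin_k = fibrin_k)
      mk <- clean_mask(mk, clean_radius)
      qc_verify(mk, f, t0, k = k)$mask
    })
    all_masks[[ch]] <- masks
    out[[ch]] <- quantify_masks(masks, frames = filt, channel = ch)
  }
  res <- list_rbind(out)
  attr(res, "masks") <- all_masks
  res
}
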