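# Independent brute-force oracles used to cross-check the implementation.

# Naive O(n^3) agglomerative complete-linkage clustering; returns the
# cophenetic distance matrix (tie-break: lowest-index pair merges first).
oracle_complete_linkage <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd; best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all group
# assignments of the pooled ranks (tie-free data only).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Flood-fill 8-connected component count (queue-based, intentionally naive).
oracle_component_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

# Least-squares plane amplitude (peak-to-peak of the fitted plane) of an image
plane_amplitude <- function(img) {
  H <- nrow(img); W <- ncol(img)
  x <- rep(seq_len(H), times = W); y <- rep(seq_len(W), each = H)
  fit <- lm(as.vector(img) ~ x + y)
  pred <- fitted(fit)
  max(pred) - min(pred)
}

# A small feature table with a known 8-class structure for prediction tests;
# the signal is a one-hot class code so separation survives per-feature
# standardization (sep = 0 gives pure noise, i.e. a chance-level problem)
make_class_fixture <- function(n_per_class = 2, n_features = 8, sep = 10,
                               noise_sd = 0.01, seed = 42) {
  withr::with_seed(seed, {
    cls <- rep(0:7, each = n_per_class)
    X <- matrix(rnorm(length(cls) * n_features, sd = noise_sd),
                ncol = n_features)
    for (j in seq_len(min(n_features, 8))) {
      X[, j] <- X[, j] + sep * as.integer(cls == (j - 1))
    }
    tb <- tibble::as_tibble(setNames(as.data.frame(X),
                                     paste0("P", 1:n_features, "_t2")))
    tb$surface <- "M6"
    tb$class <- factor(cls, levels = 0:7)
    tb
  })
}
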