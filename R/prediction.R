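#' Pivot parameter records to a per-run feature table
#'
#' One row per flow run with the 41 kinetic features (`P1_t0` ... `P8_t8`,
#' `P9`), run metadata, and the 8-way condition class label from
#' [condition_class()].
#'
#' @param records Long record tibble from [generate_parameter_cohort()] or
#'   [run_parameters()] plus metadata.
#' @return Wide tibble with a `class` column (factor, levels 0..7).
#' @export
records_to_features <- function(records) {
  meta <- intersect(c("subject", "group", "surface", "shear", "tf",
                      "ifviia", "cti", "tm"), names(records))
  wide <- records |>
    mutate(feature = ifelse(is.na(.data$time), .data$parameter,
                            sprintf("%s_t%g", .data$parameter, .data$time))) |>
    select(all_of(meta), feature, value) |>
    pivot_wider(names_from = "feature", values_from = "value")
  if (all(c("tf", "ifviia", "cti") %in% names(wide))) {
    wide$class <- factor(
      condition_class(wide$tf > 0, wide$ifviia, wide$cti),
      levels = 0:7
    )
  }
  wide
}

feature_columns <- function(table) {
  grep("^P[1-9](_t[0-9]+)?$", names(table), value = TRUE)
}

#' k-nearest-neighbour imputation of missing feature values
#'
#' Each missing cell is replaced by the mean of that feature over the `k`
#' nearest rows (root-mean-square Euclidean distance on the features both
#' rows observe; only rows observing the target feature are candidates).
#' Ties are broken deterministically towards the lowest row index, so
#' imputation is reproducible and idempotent.
#'
#' @param table Feature table (see [records_to_features()]); non-feature
#'   columns are passed through untouched.
#' @param k Number of neighbours (>= 1).
#' @return The table with every missing feature value filled in.
#' @export
impute_missing <- function(table, k = 3) {
  stopifnot(k >= 1)
  cols <- feature_columns(table)
  X <- as.matrix(table[, cols])
  if (any(colSums(!is.na(X)) == 0)) {
    abort("feature missing in all rows; cannot impute")
  }
  if (any(rowSums(!is.na(X)) == 0)) {
    abort("row with no observed features; cannot impute")
  }
  miss <- which(is.na(X), arr.ind = TRUE)
  if (nrow(miss) == 0) return(table)
  Xout <- X
  for (i in unique(miss[, "row"])) {
    need <- miss[miss[, "row"] == i, "col"]
    obs_i <- !is.na(X[i, ])
    cand <- setdiff(seq_len(nrow(X)), i)
    d <- vapply(cand, function(j) {
      co <- obs_i & !is.na(X[j, ])
      if (!any(co)) return(Inf)
      sqrt(mean((X[i, co] - X[j, co])^2))
    }, numeric(1))
    for (col in need) {
      ok <- cand[!is.na(X[cand, col]) & is.finite(d)]
      if (length(ok) == 0) abort("no donor rows observe the missing feature")
      dd <- d[match(ok, cand)]
      nb <- ok[order(dd, ok)][seq_len(min(k, length(ok)))]
      Xout[i, col] <- mean(X[nb, col])
    }
  }
  table[, cols] <- as_tibble(Xout)
  table
}

#' Contribution of the platelet parameters to thrombus and fibrin outcomes
#'
#' For every target parameter (P3--P9) and time point, fits the full linear
#' model on the two platelet parameters (P1, P2 at the same time; P9 uses
#' the final capture time) and the two single-predictor models; the
#' contribution of each platelet parameter is its single-predictor R^2 as a
#' percentage of the full model's R^2 ("% of maximal prediction").
#'
#' @param features Feature table (see [records_to_features()]).
#' @param by Grouping column(s) (default `"surface"`); each group needs at
#'   least 5 runs.
#' @param r2_floor Full-model R^2 below which contributions are flagged
#'   unstable.
#' @return Tibble: group columns, `target`, `time`, `r2_full`,
#'   `contribution_p1`, `contribution_p2`, `unstable`.
#' @export
platelet_contribution <- function(features, by = "surface", r2_floor = 0.05) {
  times <- sort(unique(as.numeric(
    sub("^P[12]_t", "", grep("^P1_t", names(features), value = TRUE))
  )))
  t_last <- max(times)
  targets <- c(paste0("P", 3:8), "P9")
  groups <- features |> distinct(across(all_of(by)))
  purrr::map(seq_len(nrow(groups)), function(gi) {
    g <- features |> semi_join(groups[gi, , drop = FALSE], by = by)
    if (nrow(g) < 5) abort("need at least 5 runs per group")
    purrr::map(targets, function(tp) {
      tts <- if (tp == "P9") NA_real_ else times[times > 0]
      purrr::map(tts, function(tt) {
        ycol <- if (tp == "P9") "P9" else sprintf("%s_t%g", tp, tt)
        pt <- if (tp == "P9") t_last else tt
        x1 <- g[[sprintf("P1_t%g", pt)]]
        x2 <- g[[sprintf("P2_t%g", pt)]]
        y <- g[[ycol]]
        if (is.null(y) || sd(y) == 0) {
          return(tibble(groups[gi, , drop = FALSE], target = tp, time = tt,
                        r2_full = NA_real_, contribution_p1 = NA_real_,
                        contribution_p2 = NA_real_, unstable = TRUE))
        }
        # perfect fits (r^2 = 1) are legitimate here, e.g. degenerate targets
        r2 <- function(fm) suppressWarnings(summary(fm)$r.squared)
        r2_full <- r2(lm(y ~ x1 + x2))
        c1 <- if (r2_full > 0) max(r2(lm(y ~ x1)) / r2_full * 100, 0) else NA_real_
        c2 <- if (r2_full > 0) max(r2(lm(y ~ x2)) / r2_full * 100, 0) else NA_real_
        tibble(groups[gi, , drop = FALSE], target = tp, time = tt,
               r2_full = r2_full, contribution_p1 = c1, contribution_p2 = c2,
               unstable = r2_full < r2_floor)
      }) |> list_rbind()
    }) |> list_rbind()
  }) |> list_rbind()
}

#' The default classifier roster
#'
#' Eight classifier families standing in for the original multi-program
#' roster: CART, random forest, naive Bayes, multinomial logistic
#' regression, linear and radial SVM, 1-nearest-neighbour, and LDA.
#' Distance/margin-based members (`scale = TRUE`) receive features z-scored
#' on the training fold only.
#'
#' @return Named list of classifier definitions (`fit`, `predict`, `scale`,
#'   `stochastic`).
#' @export
classifier_roster <- function() {
  list(
    cart = list(scale = FALSE, stochastic = FALSE,
      fit = function(X, y) rpart::rpart(y ~ ., data = data.frame(X, y = y),
                                        method = "class",
                                        control = rpart::rpart.control(minsplit = 2,
                                                                       cp = 0.001)),
      predict = function(m, X) predict(m, data.frame(X), type = "class")),
    random_forest = list(scale = FALSE, stochastic = TRUE,
      fit = function(X, y) randomForest::randomForest(X, y, ntree = 100),
      predict = function(m, X) predict(m, X)),
    naive_bayes = list(scale = FALSE, stochastic = FALSE,
      fit = function(X, y) e1071::naiveBayes(X, y),
      predict = function(m, X) predict(m, X)),
    logistic = list(scale = TRUE, stochastic = FALSE,
      fit = function(X, y) nnet::multinom(y ~ ., data = data.frame(X, y = y),
                                          trace = FALSE, MaxNWts = 5000),
      predict = function(m, X) predict(m, data.frame(X), type = "class")),
    svm_linear = list(scale = TRUE, stochastic = FALSE,
      fit = function(X, y) e1071::svm(X, y, kernel = "linear", scale = FALSE),
      predict = function(m, X) predict(m, X)),
    svm_radial = list(scale = TRUE, stochastic = FALSE,
      fit = function(X, y) e1071::svm(X, y, kernel = "radial", scale = FALSE),
      predict = function(m, X) predict(m, X)),
    knn1 = list(scale = TRUE, stochastic = FALSE,
      fit = function(X, y) list(X = X, y = y),
      predict = function(m, X) class::knn(m$X, X, m$y, k = 1)),
    lda = list(scale = FALSE, stochastic = FALSE,
      fit = function(X, y) MASS::lda(X, grouping = y),
      predict = function(m, X) predict(m, X)$class)
  )
}

#' Leave-one-out condition prediction across a classifier roster
#'
#' Per surface, predicts the 8-way intervention class (TF / iFVIIa / CTI
#' present or absent) from the 41 kinetic features with every classifier of
#' the roster, scoring by leave-one-out cross-validation: every fold
#' retrains from scratch on the remaining runs, zero-variance training
#' features are dropped per fold, scaling statistics come from the training
#' fold only, and stochastic classifiers get a fixed per-fold seed recorded
#' in the report.
#'
#' @param features Feature table with a `class` factor and a `surface`
#'   column (see [records_to_features()]); missing values must be imputed
#'   first.
#' @param roster Classifier roster (see [classifier_roster()]).
#' @param seed Base seed for stochastic classifiers.
#' @return A `prediction_report`: accuracies per surface x classifier, mean
#'   accuracy per surface, and flags (e.g. singleton classes, whose folds
#'   cannot be predicted and count as errors).
#' @export
classify_conditions <- function(features, roster = classifier_roster(),
                                seed = 1L) {
  stopifnot(length(roster) >= 2, "class" %in% names(features))
  cols <- feature_columns(features)
  if (anyNA(features[, cols])) abort("impute missing values first")
  surfaces <- unique(features$surface)
  flags <- character(0)
  acc <- purrr::map(surfaces, function(sf) {
    d <- features |> filter(.data$surface == sf)
    X <- as.matrix(d[, cols]); y <- droplevels(d$class)
    if (any(table(y) < 2)) {
      flags <<- c(flags, sprintf(
        "surface %s: singleton class(es) %s counted as unpredictable", sf,
        paste(names(which(table(y) < 2)), collapse = ",")))
    }
    n <- nrow(X)
    purrr::imap(roster, function(clf, nm) {
      ci <- match(nm, names(roster))
      pred <- factor(rep(NA_character_, n), levels = levels(y))
      for (i in seq_len(n)) {
        tr <- setdiff(seq_len(n), i)
        Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
        keep <- apply(Xtr, 2, function(v) sd(v) > 0)
        if (!any(keep)) {
          pred[i] <- names(which.max(table(ytr)))[1]
          next
        }
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- X[i, keep, drop = FALSE]
        if (isTRUE(clf$scale)) {
          mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd)
          sg[sg == 0] <- 1
          Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
          Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
        }
        fold_seed <- (abs(seed) * 1009L + i * 131L + ci) %% 2147483647L
        p <- withr::with_seed(fold_seed, tryCatch(suppressWarnings({
          m <- clf$fit(Xtr, ytr)
          as.character(clf$predict(m, Xte))
        }), error = function(e) names(which.max(table(ytr)))[1]))
        pred[i] <- p
      }
      tibble(surface = sf, classifier = nm, fold = seq_len(n),
             truth = as.character(y), predicted = as.character(pred))
    }) |> list_rbind()
  }) |> list_rbind()
  preds <- acc
  acc <- preds |>
    summarise(accuracy = mean(.data$predicted == .data$truth),
              n_runs = n(), .by = c("surface", "classifier"))
  structure(
    list(
      accuracies = acc,
      predictions = preds,
      mean_accuracy = acc |>
        summarise(mean_accuracy = mean(.data$accuracy), .by = "surface"),
      meta = list(seed = seed, roster = names(roster),
                  class_bits = c(TF = 4, iFVIIa = 2, CTI = 1)),
      flags = flags
    ),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Leave-one-out condition prediction\n")
  cat("Classifiers:", paste(x$meta$roster, collapse = ", "), "\n")
  print(x$mean_accuracy)
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.prediction_report <- function(x, ...) x$accuracies

#' @export
glance.prediction_report <- function(x, ...) {
  tibble(
    n_surfaces = nrow(x$mean_accuracy),
    n_classifiers = length(x$meta$roster),
    mean_accuracy = mean(x$accuracies$accuracy),
    min_accuracy = min(x$accuracies$accuracy),
    max_accuracy = max(x$accuracies$accuracy)
  )
}

#' Pairwise surface comparison of classifier performance
#'
#' For every pair of surfaces, a paired two-sided t-test across the roster's
#' accuracy vectors, with Benjamini-Hochberg false-discovery-rate adjustment
#' over all pairs. Identical accuracy vectors give an undefined t statistic
#' and report p = 1, flagged.
#'
#' @param report A `prediction_report` from [classify_conditions()].
#' @return Tibble: `surface_a`, `surface_b`, `mean_diff`, `p`, `p_adj`,
#'   `degenerate`.
#' @export
compare_classifiers <- function(report) {
  acc <- report$accuracies
  wide <- acc |>
    pivot_wider(id_cols = "classifier", names_from = "surface",
                values_from = "accuracy")
  surfaces <- setdiff(names(wide), "classifier")
  if (nrow(wide) < 2) abort("need at least 2 classifiers")
  if (length(surfaces) < 2) {
    return(tibble(surface_a = character(0), surface_b = character(0),
                  mean_diff = numeric(0), p = numeric(0),
                  p_adj = numeric(0), degenerate = logical(0)))
  }
  pairs <- utils::combn(surfaces, 2, simplify = FALSE)
  res <- purrr::map(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    degen <- sd(a - b) == 0
    p <- if (degen) 1 else t.test(a, b, paired = TRUE)$p.value
    tibble(surface_a = pr[1], surface_b = pr[2],
           mean_diff = mean(a - b), p = p, degenerate = degen)
  }) |> list_rbind()
  res$p_adj <- p.adjust(res$p, method = "BH")
  res |> select(surface_a, surface_b, mean_diff, p, p_adj, degenerate)
}
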