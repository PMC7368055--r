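test_that("kNN imputation follows the documented semantics", {
  rec <- generate_parameter_cohort(n_controls = 4, surfaces = "M6", seed = 1)
  feat <- records_to_features(rec)
  expect_identical(impute_missing(feat), feat)  # nothing missing: identity

  # an exact duplicate row donates its value at k = 1
  dup <- feat[c(1, 1, 2:4), ]
  dup$P1_t4[1] <- NA
  filled <- impute_missing(dup, k = 1)
  expect_equal(filled$P1_t4[1], feat$P1_t4[1])

  # idempotence
  holed <- feat
  holed$P3_t6[2] <- NA; holed$P7_t8[3] <- NA
  once <- impute_missing(holed, k = 3)
  expect_identical(impute_missing(once, k = 3), once)

  # mask-and-recover: imputation error stays below the feature spread
  big <- records_to_features(
    generate_parameter_cohort(n_controls = 12, surfaces = "M6", seed = 2)
  )
  cols <- grep("^P[1-7]_t[48]$", names(big), value = TRUE)
  withr::local_seed(3)
  masked <- big
  hit <- lapply(cols, function(cc) sample(nrow(big), 2))
  for (i in seq_along(cols)) masked[[cols[i]]][hit[[i]]] <- NA
  rec2 <- impute_missing(masked, k = 3)
  errs <- unlist(lapply(seq_along(cols), function(i) {
    rec2[[cols[i]]][hit[[i]]] - big[[cols[i]]][hit[[i]]]
  }))
  sds <- unlist(lapply(seq_along(cols), function(i) sd(big[[cols[i]]])))
  expect_lt(sqrt(mean(errs^2)), mean(sds))

  allna <- feat; allna$P2_t4 <- NA_real_
  expect_error(impute_missing(allna), "missing in all rows")
})

test_that("platelet contribution isolates the driving parameter", {
  withr::local_seed(4)
  n <- 40
  base <- records_to_features(
    generate_parameter_cohort(n_controls = 10, surfaces = "M6", seed = 4)
  )[rep(1:20, 2)[1:n], ]
  base$P1_t4 <- rnorm(n, 30, 8)
  base$P2_t4 <- rnorm(n, 10, 3)
  # target P3 at t = 4 is an exact copy of P1
  base$P3_t4 <- base$P1_t4
  contrib <- platelet_contribution(base)
  row <- contrib |> dplyr::filter(target == "P3", time == 4)
  expect_equal(row$contribution_p1, 100, tolerance = 1e-6)
  expect_lt(row$contribution_p2, 30)

  # a target independent of both platelet parameters is flagged unstable
  base$P5_t4 <- rnorm(n)
  c2 <- platelet_contribution(base)
  expect_true(c2$unstable[c2$target == "P5" & c2$time == 4])

  # programmed mixture: P1 dominates P2 across seeds
  wins <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      x1 <- rnorm(n, 0, 1); x2 <- rnorm(n, 0, 1)
      tb <- base
      tb$P1_t6 <- x1; tb$P2_t6 <- x2
      tb$P4_t6 <- 0.8 * x1 + 0.2 * x2 + rnorm(n, 0, 0.2)
      cc <- platelet_contribution(tb) |>
        dplyr::filter(target == "P4", time == 6)
      cc$contribution_p1 > cc$contribution_p2
    })
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("LOOCV accuracies equal a fold-by-fold brute-force oracle", {
  fix <- make_class_fixture(n_per_class = 2)  # 16 runs
  det <- classifier_roster()[c("cart", "naive_bayes", "knn1", "lda",
                               "svm_linear")]
  rep <- classify_conditions(fix, roster = det, seed = 1)

  cols <- grep("^P", names(fix), value = TRUE)
  X <- as.matrix(fix[, cols]); y <- droplevels(fix$class)
  for (nm in names(det)) {
    clf <- det[[nm]]
    manual <- vapply(seq_len(nrow(X)), function(i) {
      tr <- setdiff(seq_len(nrow(X)), i)
      Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
      keep <- apply(Xtr, 2, sd) > 0
      Xtr <- Xtr[, keep, drop = FALSE]; Xte <- X[i, keep, drop = FALSE]
      if (isTRUE(clf$scale)) {
        mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
        Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
        Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
      }
      suppressWarnings(
        as.character(clf$predict(clf$fit(Xtr, ytr), Xte)) == as.character(y[i])
      )
    }, logical(1))
    got <- rep$accuracies$accuracy[rep$accuracies$classifier == nm]
    expect_equal(got, mean(manual), info = nm)
  }
})

test_that("accuracy sits at chance under zero signal and 1 under separation", {
  noise <- make_class_fixture(n_per_class = 6, sep = 0, noise_sd = 1)  # 48 runs
  rep0 <- classify_conditions(noise, seed = 2)
  # binomial band around 1/8 across the roster mean
  expect_lt(glance(rep0)$mean_accuracy, 0.32)

  sepd <- make_class_fixture(n_per_class = 6, sep = 15, noise_sd = 1)
  repS <- classify_conditions(sepd, seed = 2)
  expect_true(all(repS$accuracies$accuracy == 1))
})

test_that("a test row's label never leaks into its own fold", {
  fix <- make_class_fixture(n_per_class = 2)
  det <- classifier_roster()[c("cart", "lda", "knn1")]
  rep1 <- classify_conditions(fix, roster = det, seed = 3)
  flipped <- fix
  flipped$class[1] <- factor((as.integer(as.character(fix$class[1])) + 1) %% 8,
                             levels = 0:7)
  rep2 <- classify_conditions(flipped, roster = det, seed = 3)
  p1 <- rep1$predictions |> dplyr::filter(fold == 1)
  p2 <- rep2$predictions |> dplyr::filter(fold == 1)
  expect_identical(p1$predicted, p2$predicted)
})

test_that("singleton classes are flagged as unpredictable", {
  fix <- make_class_fixture(n_per_class = 2)
  fix <- fix[-1, ]  # class 0 now has a single run
  rep <- classify_conditions(fix, roster = classifier_roster()[c("cart", "lda")],
                             seed = 4)
  expect_true(any(grepl("singleton", rep$flags)))
})

test_that("classifier comparison applies BH over all surface pairs", {
  mk_report <- function(acc_by_surface) {
    acc <- purrr::imap(acc_by_surface, function(a, sf) {
      tibble::tibble(surface = sf, classifier = paste0("c", seq_along(a)),
                     accuracy = a, n_runs = 16)
    }) |> purrr::list_rbind()
    structure(list(accuracies = acc,
                   mean_accuracy = dplyr::summarise(
                     acc, mean_accuracy = mean(accuracy), .by = surface),
                   meta = list(roster = unique(acc$classifier)),
                   flags = character(0)),
              class = "prediction_report")
  }
  # identical accuracy vectors: degenerate, p = 1
  same <- mk_report(list(A = c(0.5, 0.6, 0.7), B = c(0.5, 0.6, 0.7)))
  cmp <- compare_classifiers(same)
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_adj, 1)

  # BH closed form: equal raw p across m hypotheses stay at that p
  withr::local_seed(5)
  many <- mk_report(list(A = rnorm(8, 0.5, 0.05), B = rnorm(8, 0.55, 0.05),
                         C = rnorm(8, 0.6, 0.05), D = rnorm(8, 0.65, 0.05)))
  cmp2 <- compare_classifiers(many)
  expect_equal(cmp2$p_adj, p.adjust(cmp2$p, method = "BH"))
  expect_true(all(cmp2$p_adj >= cmp2$p))

  # null calibration: the BH false-positive rate stays near or below q
  fp <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      r <- mk_report(list(A = rnorm(8, 0.5, 0.05), B = rnorm(8, 0.5, 0.05),
                          C = rnorm(8, 0.5, 0.05)))
      any(compare_classifiers(r)$p_adj < 0.05)
    })
  }, logical(1))
  expect_lte(mean(fp), 0.1)
})
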