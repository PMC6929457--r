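test_that("confusion counts match hand tallies and validate inputs", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cc <- confusion_counts(y, p)
  expect_identical(unclass(cc)[c("TP", "FN", "FP", "TN")],
                   list(TP = 3L, FN = 1L, FP = 1L, TN = 5L))
  perfect <- confusion_counts(y, y)
  expect_identical(perfect$FP + perfect$FN, 0L)
  flipped <- confusion_counts(y, 1 - y)
  expect_identical(flipped$TP + flipped$TN, 0L)
  expect_error(confusion_counts(y, p[-1]), "length mismatch")
  expect_error(confusion_counts(y, replace(p, 2, 5)), "binary")
})

test_that("Sen/Spe/Acc/MCC reproduce their closed forms on a hand example", {
  cc <- confusion_counts(rep(c(1, 0), c(4, 6)),
                         c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(sen(cc), 0.75)
  expect_equal(spe(cc), 5 / 6)
  expect_equal(acc(cc), 0.8)
  expect_equal(mcc(cc), 14 / 24)
})

test_that("perfect prediction saturates all four metrics", {
  y <- rep(c(1, 0), c(7, 13))
  cc <- confusion_counts(y, y)
  expect_equal(c(sen(cc), spe(cc), acc(cc), mcc(cc)), c(1, 1, 1, 1))
})

test_that("zero-denominator conventions: NA for empty classes, 0 for MCC", {
  # all-positive predictor on balanced data
  y <- rep(c(1, 0), each = 5)
  cc <- confusion_counts(y, rep(1, 10))
  expect_equal(spe(cc), 0)
  expect_equal(mcc(cc), 0)   # zero factor under the root
  # a fold with no true positives leaves Sen undefined
  cc2 <- confusion_counts(rep(0, 6), rep(c(0, 1), 3))
  expect_true(is.na(sen(cc2)))
  expect_false(is.na(spe(cc2)))
})

test_that("metrics stay in bounds and match formulas on random tables", {
  set.seed(7)
  for (i in 1:300) {
    k <- random_counts()
    cc <- structure(k, class = "confusion_counts")
    denom <- as.numeric(k$TP + k$FN) * (k$TP + k$FP) * (k$TN + k$FN) * (k$TN + k$FP)
    expected_mcc <- if (denom == 0) 0 else
      (as.numeric(k$TP) * k$TN - as.numeric(k$FN) * k$FP) / sqrt(denom)
    expect_equal(mcc(cc), expected_mcc, tolerance = 1e-12)
    expect_true(mcc(cc) >= -1 - 1e-12 && mcc(cc) <= 1 + 1e-12)
    total <- k$TP + k$TN + k$FP + k$FN
    if (total > 0) expect_equal(acc(cc), (k$TP + k$TN) / total, tolerance = 1e-12)
  }
})

test_that("MCC is centered on zero for label-independent predictions", {
  set.seed(12)
  n <- 400
  y <- rep(c(1, 0), c(100, 300))
  vals <- vapply(1:200, function(i) mcc(confusion_counts(y, sample(y))), numeric(1))
  # permuted predictions are independent of truth: per-draw variance is about
  # 1/(n-1), so a 4-sigma CLT bound on the mean of 200 draws is
  expect_lt(abs(mean(vals)), 4 / sqrt((n - 1) * 200))
})

test_that("the registry resolves the four named learners and rejects others", {
  for (nm in c("DA", "RF", "NN", "AdaBoost")) {
    h <- classifier_registry(nm)
    expect_true(is.function(h$fit) && is.function(h$predict))
  }
  expect_error(classifier_registry("SVM"), "DA, RF, NN, AdaBoost")
})

test_that("AdaBoost separates a separable toy set via a signed weighted vote", {
  set.seed(5)
  x <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
  y <- rep(c(0L, 1L), each = 10)
  h <- classifier_registry("AdaBoost")
  fit <- h$fit(x, y)
  pred <- h$predict(fit, x)
  expect_identical(pred, y)
  # the prediction is exactly the sign of the weighted weak-learner sum
  expect_identical(pred, as.integer(adaboost_score(fit, x) > 0))
  expect_identical(length(fit$thetas), length(fit$stumps))
  expect_true(all(fit$thetas > 0))
})

test_that("cross-validation partitions samples and respects the trivial predictor", {
  d <- random_dataset(m = 15, n = 35, f = 4, seed = 91)
  rep_ <- cross_validate(d, NULL, "majority", folds = 5, seed = 3)
  # every sample is scored in exactly one test fold
  expect_identical(sum(rep_$per_fold$TP + rep_$per_fold$TN +
                         rep_$per_fold$FP + rep_$per_fold$FN), 50L)
  # the training majority is always negative here
  expect_equal(rep_$per_fold$Sen, rep(0, 5))
  expect_equal(rep_$per_fold$Spe, rep(1, 5))
  # test folds are exactly the complements of what the sampler saw, and those
  # complements partition the dataset
  complements <- lapply(rep_$sampler_seen_indices, function(s) setdiff(1:50, s))
  expect_identical(sort(unlist(complements)), 1:50)
  expect_identical(anyDuplicated(unlist(complements)), 0L)
})

test_that("aggregate metrics are fold means and recomputable from counts", {
  pd <- generate_planted(15, 60, 10, 6, 3, seed = 8)
  rep_ <- suppressWarnings(
    cross_validate(pd$dataset, cfg_l("MMPCC", 5), "DA", folds = 5, seed = 2))
  for (mname in c("Sen", "Spe", "Acc", "MCC")) {
    expect_equal(unname(rep_$aggregate[mname]), mean(rep_$per_fold[[mname]]))
  }
  recomputed <- apply(rep_$per_fold, 1, function(r) {
    cc <- structure(as.list(setNames(as.integer(r[c("TP", "TN", "FP", "FN")]),
                                     c("TP", "TN", "FP", "FN"))),
                    class = "confusion_counts")
    c(sen(cc), spe(cc), acc(cc), mcc(cc))
  })
  expect_equal(unname(t(recomputed)),
               unname(as.matrix(rep_$per_fold[, c("Sen", "Spe", "Acc", "MCC")])))
})

test_that("the sampler never sees test-fold rows under train_folds scope", {
  pd <- generate_planted(15, 60, 10, 6, 3, seed = 9)
  n_all <- length(pd$dataset$labels)
  rep_ <- suppressWarnings(
    cross_validate(pd$dataset, cfg_l("MMPCC", 5), "DA", folds = 5, seed = 4,
                   sample_scope = "train_folds"))
  test_sizes <- rep_$per_fold$TP + rep_$per_fold$TN + rep_$per_fold$FP + rep_$per_fold$FN
  for (f in 1:5) {
    seen <- rep_$sampler_seen_indices[[f]]
    expect_identical(length(seen) + test_sizes[f], n_all)
    test_fold <- setdiff(seq_len(n_all), seen)
    expect_identical(length(intersect(seen, test_fold)), 0L)
  }
  # whole-dataset scope, by contrast, exposes everything
  rep_w <- suppressWarnings(
    cross_validate(pd$dataset, cfg_l("MMPCC", 5), "DA", folds = 5, seed = 4,
                   sample_scope = "whole_dataset"))
  expect_identical(rep_w$sampler_seen_indices[[1]], seq_len(n_all))
})

test_that("cross-validation rejects unknown classifiers and tiny classes", {
  d <- random_dataset(m = 3, n = 30, f = 4, seed = 93)
  expect_error(cross_validate(d, NULL, "nope"), "unknown classifier")
  expect_error(cross_validate(d, NULL, "DA", folds = 5), "at least 5")
})

test_that("percentage_sweep tabulates percentage x classifier and nests 0%", {
  pd <- generate_planted(15, 60, 10, 6, 3, seed = 10)
  tab <- suppressWarnings(
    percentage_sweep(pd$dataset, "MMPCC", c("DA", "majority"),
                     percentages = c(0, 30), seed = 5))
  expect_identical(nrow(tab), 4L)
  expect_identical(names(tab), c("percentage", "classifier",
                                 "Sen", "Spe", "Acc", "MCC"))
  solo <- cross_validate(pd$dataset, NULL, "DA", seed = 5)
  expect_equal(tab$Sen[tab$percentage == 0 & tab$classifier == "DA"],
               unname(solo$aggregate["Sen"]))
})

test_that("resampling baselines plug into the harness", {
  pd <- generate_planted(15, 60, 10, 6, 3, seed = 11)
  rep_ <- cross_validate(pd$dataset,
                         baseline_config("SMOTE", percentage = 50, seed = 1),
                         "DA", folds = 5, seed = 6)
  expect_true(all(is.finite(rep_$aggregate)))
})
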