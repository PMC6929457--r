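#' Confusion counts for binary predictions
#'
#' Tallies TP/TN/FP/FN with the positive class being the original dataset's
#' minority class of interest. Predictions and truth are 0/1 vectors.
#'
#' @param y_true,y_pred Binary (0/1) vectors of equal length.
#' @return A `confusion_counts` object (list with TP, TN, FP, FN).
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("length mismatch: %d vs %d", length(y_true), length(y_pred)),
         call. = FALSE)
  }
  y_true <- coerce_labels(y_true)
  y_pred <- coerce_labels01(y_pred)
  structure(
    list(TP = sum(y_true == 1L & y_pred == 1L),
         TN = sum(y_true == 0L & y_pred == 0L),
         FP = sum(y_true == 0L & y_pred == 1L),
         FN = sum(y_true == 1L & y_pred == 0L)),
    class = "confusion_counts")
}

# like coerce_labels but tolerates single-class vectors (predictions)
coerce_labels01 <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  y <- as.integer(y)
  if (anyNA(y) || any(!y %in% c(0L, 1L))) {
    stop("predictions must be binary (0/1)", call. = FALSE)
  }
  y
}

#' Sensitivity, specificity, accuracy and Matthews correlation coefficient
#'
#' The four evaluation metrics, as closed forms of the confusion counts:
#' Sen = TP/(TP+FN), Spe = TN/(TN+FP), Acc = (TP+TN)/total and
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)).
#' Sen/Spe with an empty class are undefined and return `NA` (the harness
#' excludes them from fold means with a flag); MCC with a zero factor under
#' the root returns 0, the standard convention.
#'
#' @param counts A [confusion_counts()] object.
#' @return A scalar; Sen/Spe/Acc in \[0, 1\] (or NA), MCC in \[-1, 1\].
#' @export
sen <- function(counts) {
  with(counts, if (TP + FN == 0L) NA_real_ else TP / (TP + FN))
}

#' @rdname sen
#' @export
spe <- function(counts) {
  with(counts, if (TN + FP == 0L) NA_real_ else TN / (TN + FP))
}

#' @rdname sen
#' @export
acc <- function(counts) {
  with(counts, (TP + TN) / (TP + TN + FP + FN))
}

#' @rdname sen
#' @export
mcc <- function(counts) {
  with(counts, {
    denom <- as.numeric(TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
    if (denom == 0) 0 else (as.numeric(TP) * TN - as.numeric(FN) * FP) / sqrt(denom)
  })
}

metric_row <- function(counts) {
  data.frame(TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
             Sen = sen(counts), Spe = spe(counts),
             Acc = acc(counts), MCC = mcc(counts))
}

# ---- classifier registry ----------------------------------------------------

classifier_backends <- local({
  fit_stump <- function(x, y, w) {
    df <- data.frame(y = factor(y, levels = c(0, 1)), x)
    rpart::rpart(y ~ ., data = df, weights = w,
                 control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                minsplit = 2, xval = 0))
  }
  list(
    DA = list(
      fit = function(x, y) MASS::lda(x, grouping = factor(y, levels = c(0, 1))),
      predict = function(model, x) {
        as.integer(as.character(stats::predict(model, x)$class))
      }),
    RF = list(
      fit = function(x, y) {
        randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = 200)
      },
      predict = function(model, x) {
        as.integer(as.character(stats::predict(model, x)))
      }),
    NN = list(
      fit = function(x, y) {
        nnet::nnet(x, y, size = 5, decay = 1e-3, maxit = 300, trace = FALSE)
      },
      predict = function(model, x) {
        as.integer(stats::predict(model, x)[, 1] > 0.5)
      }),
    AdaBoost = list(
      # discrete AdaBoost.M1 with decision stumps: the strong classifier is
      # sign(sum_m theta_m f_m(x)) over M weak learners f_m in {-1, +1}
      fit = function(x, y, rounds = 50L) {
        n <- length(y)
        w <- rep(1 / n, n)
        y_pm <- ifelse(y == 1L, 1, -1)
        stumps <- list(); thetas <- numeric(0)
        for (m in seq_len(rounds)) {
          st <- fit_stump(x, y, w)
          pred <- as.integer(as.character(
            stats::predict(st, data.frame(x), type = "class")))
          pred_pm <- ifelse(pred == 1L, 1, -1)
          err <- sum(w[pred_pm != y_pm])
          if (err >= 0.5) break
          err <- max(err, 1e-10)
          theta <- 0.5 * log((1 - err) / err)
          stumps[[length(stumps) + 1L]] <- st
          thetas <- c(thetas, theta)
          w <- w * exp(-theta * y_pm * pred_pm)
          w <- w / sum(w)
          if (err < 1e-10) break
        }
        structure(list(stumps = stumps, thetas = thetas), class = "mmpcc_adaboost")
      },
      predict = function(model, x) {
        as.integer(adaboost_score(model, x) > 0)
      }),
    majority = list(
      # trivial baseline: always predicts the training majority class
      fit = function(x, y) {
        list(label = as.integer(sum(y == 1L) > sum(y == 0L)))
      },
      predict = function(model, x) rep(model$label, nrow(x)))
  )
})

#' Weighted weak-learner sum of a fitted AdaBoost model
#'
#' Exposes the raw decision value sum_m theta_m f_m(x) (weak-learner outputs
#' in \{-1, +1\}) whose sign is the AdaBoost prediction; useful for
#' verifying the weighted-vote semantics.
#'
#' @param model A model fitted by the `"AdaBoost"` registry entry.
#' @param x Feature matrix.
#' @return Numeric vector of decision values.
#' @export
adaboost_score <- function(model, x) {
  xdf <- data.frame(x)
  scores <- rep(0, nrow(xdf))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(
      stats::predict(model$stumps[[m]], xdf, type = "class")))
    scores <- scores + model$thetas[m] * ifelse(pred == 1L, 1, -1)
  }
  scores
}

#' Look up a classifier by name
#'
#' The registry exposes the four learners used by the evaluation protocol —
#' `"DA"` (linear discriminant analysis), `"RF"` (random forest), `"NN"`
#' (single-hidden-layer neural network), `"AdaBoost"` (decision-stump
#' boosting) — plus a trivial `"majority"` predictor. Each handle is a list
#' with `fit(x, y)` and `predict(model, x)` returning 0/1 predictions;
#' internals are delegated to standard backends.
#'
#' @param name Registered classifier name.
#' @return A classifier handle.
#' @export
#' @examples
#' h <- classifier_registry("DA")
#' x <- matrix(rnorm(40), 20, 2); y <- rep(c(0, 1), each = 10)
#' fit <- h$fit(x, y); table(h$predict(fit, x), y)
classifier_registry <- function(name) {
  if (!name %in% names(classifier_backends)) {
    stop(sprintf("unknown classifier %s; registered: %s", dQuote(name),
                 paste(names(classifier_backends), collapse = ", ")),
         call. = FALSE)
  }
  classifier_backends[[name]]
}

# ---- cross-validation harness ----------------------------------------------

stratified_folds <- function(labels, folds, seed) {
  if (min(sum(labels == 1L), sum(labels == 0L)) < folds) {
    stop(sprintf("each class needs at least %d members for %d-fold CV",
                 folds, folds), call. = FALSE)
  }
  set.seed(seed)
  assign <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

apply_sampler <- function(dataset, sampler_spec, seed) {
  if (is.null(sampler_spec)) return(dataset)
  if (inherits(sampler_spec, "baseline_config")) {
    cfg <- sampler_spec
    cfg$seed <- seed
    return(apply_baseline(dataset, cfg))
  }
  if (inherits(sampler_spec, "sampler_config")) {
    res <- select_pseudo_negatives(dataset, sampler_spec)
    return(relabel(dataset, res))
  }
  stop("`sampler_spec` must be NULL, a sampler_config or a baseline_config",
       call. = FALSE)
}

#' Stratified k-fold cross-validation with in-fold resampling
#'
#' The evaluation protocol: stratified fold assignment (class ratios
#' preserved per fold, seeded); for each fold the sampler is fitted on and
#' applied to the training portion only, the classifier is trained on the
#' resampled training data, and the untouched test fold is scored against
#' the ORIGINAL labels — pseudo-negative relabeling is a training construct
#' and never changes a test label. Setting
#' `sample_scope = "whole_dataset"` instead applies the sampler once to the
#' full dataset before splitting (the leakage-prone protocol, provided for
#' comparison; test folds are still scored against original labels).
#'
#' @param dataset A [labeled_dataset()].
#' @param sampler_spec `NULL` (no resampling), a [sampler_config()] (select
#'   + relabel pseudo-negatives) or a [baseline_config()] (SMOTE/ROS/RUS).
#' @param classifier Registered classifier name; see [classifier_registry()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment and stochastic samplers.
#' @param sample_scope `"train_folds"` (default) or `"whole_dataset"`.
#' @param standardize If `TRUE`, z-score each feature using training-fold
#'   means/sds before sampling and classification (default `FALSE`).
#' @return A `metrics_report`: list with `per_fold` (data frame of counts
#'   and metrics per fold), `aggregate` (means across folds; NA Sen/Spe
#'   excluded with `flags` noting it), `sampler_seen_indices` (per fold, the
#'   original row indices the sampler had access to — the no-leakage audit
#'   trail) and a config echo.
#' @export
cross_validate <- function(dataset, sampler_spec = NULL, classifier = "RF",
                           folds = 5L, seed = 1L,
                           sample_scope = c("train_folds", "whole_dataset"),
                           standardize = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  sample_scope <- match.arg(sample_scope)
  handle <- classifier_registry(classifier)
  fold_of <- stratified_folds(dataset$labels, folds, seed)
  y_orig <- dataset$labels

  whole <- dataset
  if (sample_scope == "whole_dataset") {
    whole <- apply_sampler(dataset, sampler_spec, seed)
    # samplers only relabel/append/remove; original rows keep their indices
  }

  per_fold <- NULL
  seen <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    x_test <- dataset$features[test_idx, , drop = FALSE]

    if (sample_scope == "train_folds") {
      train <- labeled_dataset(dataset$features[train_idx, , drop = FALSE],
                               y_orig[train_idx],
                               feature_names = dataset$feature_names)
      if (standardize) {
        mu <- colMeans(train$features)
        sd_ <- pmax(apply(train$features, 2L, stats::sd), 1e-12)
        train$features <- scale(train$features, mu, sd_)
        x_test <- scale(x_test, mu, sd_)
      }
      seen[[f]] <- train_idx
      train <- apply_sampler(train, sampler_spec, seed + f)
    } else {
      origin <- attr(whole, "origin")
      if (is.null(origin)) origin <- seq_along(whole$labels)
      keep <- is.na(origin) | origin %in% train_idx
      train <- labeled_dataset(whole$features[keep, , drop = FALSE],
                               whole$labels[keep],
                               feature_names = dataset$feature_names)
      seen[[f]] <- seq_along(y_orig)
      if (standardize) {
        mu <- colMeans(train$features)
        sd_ <- pmax(apply(train$features, 2L, stats::sd), 1e-12)
        train$features <- scale(train$features, mu, sd_)
        x_test <- scale(x_test, mu, sd_)
      }
    }

    model <- handle$fit(train$features, train$labels)
    pred <- handle$predict(model, x_test)
    counts <- confusion_counts(y_orig[test_idx], pred)
    per_fold <- rbind(per_fold, cbind(fold = f, metric_row(counts)))
  }

  flags <- character(0)
  agg <- vapply(c("Sen", "Spe", "Acc", "MCC"), function(mname) {
    v <- per_fold[[mname]]
    if (anyNA(v)) flags <<- c(flags, sprintf("%s undefined in %d fold(s), excluded from mean",
                                             mname, sum(is.na(v))))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  if (length(flags) > 0) warning(paste(flags, collapse = "; "), call. = FALSE)

  structure(
    list(per_fold = per_fold, aggregate = agg, flags = flags,
         sampler_seen_indices = seen,
         config = list(sampler = sampler_spec, classifier = classifier,
                       folds = folds, seed = seed,
                       sample_scope = sample_scope,
                       standardize = standardize)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d-fold CV%s\n", x$config$classifier,
              x$config$folds,
              if (is.null(x$config$sampler)) "" else
                sprintf(", sampler %s", x$config$sampler$method)))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Percentage sweep of a sampling method
#'
#' Runs [cross_validate()] at each pseudo-negative (or baseline resampling)
#' percentage — 0 means no sampling — for each requested classifier, and
#' tabulates the aggregate metrics. This reproduces the shape of the
#' standard comparison tables: one row per percentage x classifier with
#' Sen/Spe/Acc/MCC.
#'
#' @param dataset A [labeled_dataset()].
#' @param method Sampling method name (`"MMPCC"`, `"MAXR"`, `"MINR"`,
#'   `"SMOTE"`, `"ROS"`, `"RUS"`) or `"none"`.
#' @param classifiers Character vector of registered classifier names.
#' @param percentages Numeric vector of percentages (0–100).
#' @param folds,seed,sample_scope,standardize Passed to [cross_validate()].
#' @param percentage_base Base count for the percentage; see [resolve_l()].
#' @return A data frame with columns `percentage`, `classifier`, `Sen`,
#'   `Spe`, `Acc`, `MCC`.
#' @export
percentage_sweep <- function(dataset, method = "MMPCC", classifiers = "RF",
                             percentages = c(0, 10, 20, 30, 40, 50),
                             folds = 5L, seed = 1L,
                             sample_scope = "train_folds",
                             percentage_base = "positives",
                             standardize = FALSE) {
  out <- NULL
  for (p in percentages) {
    spec <- if (p == 0 || identical(method, "none")) NULL
      else if (method %in% c("MMPCC", "MAXR", "MINR")) {
        sampler_config(method = method, percentage = p,
                       percentage_base = percentage_base)
      } else {
        baseline_config(method = method, percentage = p,
                        percentage_base = percentage_base, seed = seed)
      }
    for (cl in classifiers) {
      rep_ <- suppressWarnings(
        cross_validate(dataset, spec, cl, folds = folds, seed = seed,
                       sample_scope = sample_scope, standardize = standardize))
      out <- rbind(out, data.frame(percentage = p, classifier = cl,
                                   t(rep_$aggregate)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a metrics report or sweep table to CSV or JSON
#'
#' CSV mirrors the comparison-table layout (Sen/Spe/Acc as percentages, MCC
#' as a value); JSON keeps raw proportions plus the config echo.
#'
#' @param report A `metrics_report` or a sweep data frame from
#'   [percentage_sweep()].
#' @param path Output file; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  to_table <- function(df) {
    data.frame(df[setdiff(names(df), c("Sen", "Spe", "Acc", "MCC"))],
               `Sen%` = round(df$Sen * 100, 2), `Spe%` = round(df$Spe * 100, 2),
               `Acc%` = round(df$Acc * 100, 2), MCC = round(df$MCC, 4),
               check.names = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (inherits(report, "metrics_report")) {
      payload <- list(per_fold = report$per_fold,
                      aggregate = as.list(report$aggregate),
                      flags = report$flags,
                      config = list(classifier = report$config$classifier,
                                    folds = report$config$folds,
                                    seed = report$config$seed,
                                    sample_scope = report$config$sample_scope))
    } else payload <- report
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- if (inherits(report, "metrics_report")) {
      data.frame(classifier = report$config$classifier,
                 Sen = report$aggregate[["Sen"]], Spe = report$aggregate[["Spe"]],
                 Acc = report$aggregate[["Acc"]], MCC = report$aggregate[["MCC"]])
    } else report
    utils::write.csv(to_table(df), path, row.names = FALSE)
  }
  invisible(path)
}
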