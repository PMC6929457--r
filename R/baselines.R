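#' Baseline resampler configuration
#'
#' Configures the classical comparators: SMOTE (synthetic minority
#' oversampling), ROS (random duplication of minority samples) and RUS
#' (random elimination of majority samples). `amount` counts the synthetic /
#' duplicated / removed samples; alternatively a `percentage` with the same
#' base semantics as [resolve_l()].
#'
#' @param method `"SMOTE"`, `"ROS"` or `"RUS"`.
#' @param amount Nonnegative integer number of samples to add (SMOTE, ROS)
#'   or remove (RUS).
#' @param percentage Alternative to `amount`; see [resolve_l()].
#' @param percentage_base `"positives"` (default) or `"negatives"`.
#' @param k_neighbors SMOTE only: number of minority nearest neighbors
#'   (Euclidean); default 5. Must be below the minority count.
#' @param seed Integer seed; all baselines are bit-reproducible given it.
#' @return A `baseline_config` object.
#' @export
baseline_config <- function(method = c("SMOTE", "ROS", "RUS"),
                            amount = NULL, percentage = NULL,
                            percentage_base = c("positives", "negatives"),
                            k_neighbors = 5L, seed = 1L) {
  method <- match.arg(method)
  percentage_base <- match.arg(percentage_base)
  if (is.null(amount) == is.null(percentage)) {
    stop("exactly one of `amount` or `percentage` must be set", call. = FALSE)
  }
  if (!is.null(amount) && (amount < 0 || amount != round(amount))) {
    stop("`amount` must be a nonnegative integer", call. = FALSE)
  }
  if (k_neighbors < 1) stop("`k_neighbors` must be positive", call. = FALSE)
  structure(
    list(method = method, l = amount, percentage = percentage,
         percentage_base = percentage_base, k_neighbors = as.integer(k_neighbors),
         seed = as.integer(seed)),
    class = "baseline_config")
}

resolve_amount <- function(config, dataset) {
  if (!is.null(config$l)) return(as.integer(config$l))
  base <- if (identical(config$percentage_base, "negatives"))
    negative_count(dataset) else positive_count(dataset)
  max(0L, as.integer(round_half_up(config$percentage / 100 * base, 0)))
}

append_rows <- function(dataset, rows, labels, tag) {
  prov <- dataset$provenance
  if (is.null(prov)) prov <- rep("original", length(dataset$labels))
  out <- labeled_dataset(rbind(dataset$features, rows),
                         c(dataset$labels, labels),
                         feature_names = dataset$feature_names,
                         provenance = c(prov, rep(tag, length(labels))))
  # map output rows back to input rows (NA = newly created); used by the
  # whole-dataset CV scope to keep test folds addressable
  attr(out, "origin") <- c(seq_along(dataset$labels), rep(NA_integer_, length(labels)))
  out
}

#' SMOTE oversampling
#'
#' Appends synthetic minority (positive) samples: each synthetic point is
#' x + g * (x_nn - x), where x is a uniformly drawn minority sample, x_nn
#' one of its k nearest minority neighbors under Euclidean distance on the
#' raw features, and g uniform on \[0, 1\]. Original rows are untouched;
#' appended rows carry provenance `"synthetic"`.
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [baseline_config()] with `method = "SMOTE"`.
#' @return A new `labeled_dataset` with m + amount positives.
#' @export
smote <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  amount <- resolve_amount(config, dataset)
  if (amount == 0L) return(dataset)
  pos <- positive_indices(dataset)
  m <- length(pos)
  k <- config$k_neighbors
  if (m < k + 1L) {
    stop(sprintf("SMOTE needs at least k_neighbors + 1 = %d minority samples, have %d",
                 k + 1L, m), call. = FALSE)
  }
  X <- dataset$features[pos, , drop = FALSE]
  dmat <- as.matrix(stats::dist(X))
  diag(dmat) <- Inf
  ord <- apply(dmat, 1L, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)

  set.seed(config$seed)
  base_i <- sample.int(m, amount, replace = TRUE)
  nn_pick <- sample.int(k, amount, replace = TRUE)
  g <- stats::runif(amount)
  synth <- X[base_i, , drop = FALSE] +
    g * (X[nn[cbind(base_i, nn_pick)], , drop = FALSE] - X[base_i, , drop = FALSE])
  append_rows(dataset, synth, rep(1L, amount), "synthetic")
}

#' Random oversampling (ROS)
#'
#' Appends `amount` exact duplicates of uniformly drawn (with replacement)
#' minority rows; provenance `"duplicate"`.
#'
#' @inheritParams smote
#' @param config A [baseline_config()] with `method = "ROS"`.
#' @return A new `labeled_dataset` with m + amount positives.
#' @export
random_oversample <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  amount <- resolve_amount(config, dataset)
  if (amount == 0L) return(dataset)
  pos <- positive_indices(dataset)
  set.seed(config$seed)
  picks <- pos[sample.int(length(pos), amount, replace = TRUE)]
  append_rows(dataset, dataset$features[picks, , drop = FALSE],
              rep(1L, amount), "duplicate")
}

#' Random undersampling (RUS)
#'
#' Removes `amount` uniformly drawn (without replacement) majority rows;
#' minority rows are untouched.
#'
#' @inheritParams smote
#' @param config A [baseline_config()] with `method = "RUS"`.
#' @return A new `labeled_dataset` with n - amount negatives.
#' @export
random_undersample <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  amount <- resolve_amount(config, dataset)
  if (amount == 0L) return(dataset)
  neg <- negative_indices(dataset)
  if (amount > length(neg)) {
    stop(sprintf("cannot remove %d of %d majority samples", amount, length(neg)),
         call. = FALSE)
  }
  set.seed(config$seed)
  drop <- neg[sample.int(length(neg), amount, replace = FALSE)]
  keep <- setdiff(seq_along(dataset$labels), drop)
  out <- labeled_dataset(dataset$features[keep, , drop = FALSE],
                         dataset$labels[keep],
                         feature_names = dataset$feature_names,
                         provenance = dataset$provenance[keep])
  attr(out, "origin") <- keep
  out
}

#' Apply the resampler named in a baseline config
#'
#' @inheritParams smote
#' @return A resampled `labeled_dataset`.
#' @export
apply_baseline <- function(dataset, config) {
  switch(config$method,
         SMOTE = smote(dataset, config),
         ROS = random_oversample(dataset, config),
         RUS = random_undersample(dataset, config))
}
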