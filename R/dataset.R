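#' Construct a labeled dataset
#'
#' Bundles a numeric feature matrix with a binary label per row. The positive
#' class is the (usually minority) class of interest; everything downstream —
#' relevance scoring, pseudo-negative selection, resampling baselines and the
#' evaluation harness — operates on this container.
#'
#' @param features Numeric matrix (or data frame coercible to one),
#'   `n_samples x n_features`. All values must be finite.
#' @param labels Vector of length `nrow(features)` coding the class of each
#'   row: `1`/`TRUE`/`"positive"` for positives, `0`/`FALSE`/`"negative"` for
#'   negatives.
#' @param feature_names Optional character vector of feature identifiers;
#'   defaults to the column names of `features`.
#' @param drop_degenerate Sample-wise Pearson correlation is undefined for a
#'   row whose features are all equal (zero variance). If `FALSE` (default)
#'   such rows raise an error listing the offending row indices; if `TRUE`
#'   they are dropped with a warning.
#' @param provenance Optional character vector tagging each row (e.g.
#'   `"original"`, `"synthetic"`, `"duplicate"`); used by the resampling
#'   baselines.
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `features` (matrix), `labels` (integer 0/1, 1 = positive),
#'   `feature_names`, and optionally `provenance`.
#' @export
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 5, 4), c(1, 1, 0, 0, 0))
#' positive_count(d)  # 2
#' negative_count(d)  # 3
labeled_dataset <- function(features, labels, feature_names = NULL,
                            drop_degenerate = FALSE, provenance = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(features) != length(labels)) {
    stop(sprintf("`labels` length (%d) must equal nrow(features) (%d)",
                 length(labels), nrow(features)), call. = FALSE)
  }
  bad <- which(!is.finite(features), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite feature values, first at row %d column %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  labels <- coerce_labels(labels)
  if (sum(labels == 1L) < 1L || sum(labels == 0L) < 1L) {
    stop("dataset must contain at least one positive and one negative sample",
         call. = FALSE)
  }
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (!is.null(feature_names)) colnames(features) <- feature_names

  degenerate <- which(apply(features, 1L, function(r) max(r) == min(r)))
  if (length(degenerate) > 0) {
    if (drop_degenerate) {
      warning(sprintf("dropping %d zero-variance sample row(s): %s",
                      length(degenerate),
                      paste(degenerate, collapse = ", ")), call. = FALSE)
      features <- features[-degenerate, , drop = FALSE]
      labels <- labels[-degenerate]
      if (!is.null(provenance)) provenance <- provenance[-degenerate]
    } else {
      stop(sprintf(paste0("zero-variance sample row(s) make sample-wise ",
                          "Pearson correlation undefined: %s ",
                          "(use drop_degenerate = TRUE to drop them)"),
                   paste(degenerate, collapse = ", ")), call. = FALSE)
    }
  }

  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, provenance = provenance),
    class = "labeled_dataset")
}

coerce_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("positive", "negative")
    if (!all(ok)) {
      stop(sprintf("unknown label value %s at row %d",
                   dQuote(labels[which(!ok)[1]]), which(!ok)[1]), call. = FALSE)
    }
    return(as.integer(labels == "positive"))
  }
  labels <- as.integer(labels)
  ok <- labels %in% c(0L, 1L)
  if (any(!ok) || anyNA(labels)) {
    bad <- which(!ok | is.na(labels))[1]
    stop(sprintf("labels must be binary (0/1); offending row %d", bad),
         call. = FALSE)
  }
  labels
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features (%d positive, %d negative, ratio %.1f)\n",
              nrow(x$features), ncol(x$features),
              positive_count(x), negative_count(x),
              negative_count(x) / positive_count(x)))
  invisible(x)
}

#' Class counts and index accessors
#'
#' @param dataset A [labeled_dataset()].
#' @return `positive_count()`/`negative_count()` return integers (the paper's
#'   m and n); `positive_indices()`/`negative_indices()` return row indices.
#' @export
positive_count <- function(dataset) sum(dataset$labels == 1L)

#' @rdname positive_count
#' @export
negative_count <- function(dataset) sum(dataset$labels == 0L)

#' @rdname positive_count
#' @export
positive_indices <- function(dataset) which(dataset$labels == 1L)

#' @rdname positive_count
#' @export
negative_indices <- function(dataset) which(dataset$labels == 0L)

#' Pearson correlation between two sample vectors
#'
#' The similarity primitive of the whole toolkit: the Pearson correlation
#' coefficient cov(u, v) / sqrt(var(u) var(v)) between two samples' feature
#' vectors. The value is invariant to the population-vs-sample variance
#' convention (the normalizer cancels) and to affine rescaling of either
#' vector with positive slope.
#'
#' @param u,v Numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return A scalar in \[-1, 1\].
#' @export
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))  # 0.98198...
pearson <- function(u, v) {
  if (length(u) != length(v)) {
    stop(sprintf("length mismatch: %d vs %d", length(u), length(v)),
         call. = FALSE)
  }
  if (length(u) < 2L) stop("vectors must have length >= 2", call. = FALSE)
  if (max(u) == min(u) || max(v) == min(v)) {
    stop("zero-variance input: Pearson correlation undefined", call. = FALSE)
  }
  stats::cor(u, v)
}

#' Negative-vs-positive relevance block
#'
#' Computes the full block of sample-wise Pearson correlations between every
#' negative sample (rows) and every positive sample (columns). This is the
#' max-relevance similarity matrix; its computation costs exactly n*m
#' pairwise correlation evaluations, which the returned object records for
#' complexity accounting.
#'
#' @param dataset A [labeled_dataset()].
#' @param use_abs If `TRUE`, take absolute values of the correlations
#'   (treats anticorrelated samples as relevant). Default `FALSE`: signed
#'   correlations.
#' @return A `similarity_block`: list with `values` (n x m matrix, entries in
#'   \[-1, 1\]), `row_index` (negative-sample row indices), `col_index`
#'   (positive-sample row indices), and `n_correlations` (= n*m).
#' @export
relevance_block <- function(dataset, use_abs = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  neg <- negative_indices(dataset)
  pos <- positive_indices(dataset)
  values <- stats::cor(t(dataset$features[neg, , drop = FALSE]),
                       t(dataset$features[pos, , drop = FALSE]))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("undefined correlation between sample rows %d and %d",
                 neg[bad[1]], pos[bad[2]]), call. = FALSE)
  }
  if (use_abs) values <- abs(values)
  structure(
    list(values = values, row_index = neg, col_index = pos,
         n_correlations = length(neg) * length(pos)),
    class = "similarity_block")
}

#' Aggregate per-negative relevance scores
#'
#' Reduces a relevance block over its positive-sample columns into one
#' relevance score D per negative sample. The mean over positives is the
#' default (self-consistent with the mean used by the redundancy term); the
#' max over positives is available as an alternative.
#'
#' @param block A `similarity_block` from [relevance_block()].
#' @param mode `"mean"` (default) or `"max"`.
#' @return Numeric vector of length n (one score per negative sample), named
#'   by the negative rows' dataset indices.
#' @export
aggregate_relevance <- function(block, mode = c("mean", "max")) {
  stopifnot(inherits(block, "similarity_block"))
  mode <- match.arg(mode)
  d <- switch(mode,
              mean = rowMeans(block$values),
              max = apply(block$values, 1L, max))
  names(d) <- block$row_index
  d
}
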