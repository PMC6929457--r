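#' Generate an imbalanced dataset with planted pseudo-negatives
#'
#' Emulates the pseudo-negative setting with known ground truth: a small
#' positive class, a large negative class, and `l_true` "negatives" actually
#' drawn from the positive-class distribution (the planted pseudo-negatives
#' a selector should find). Both classes are spherical Gaussians with
#' within-class standard deviation `sd`; the class-mean profiles differ by a
#' random direction scaled so that the per-feature root-mean-square offset
#' is `delta * sd` (i.e. the Euclidean distance between the class means is
#' `delta * sd * sqrt(f)`) — `delta` is the separation in within-class
#' standard deviations per feature, the single knob that moves the problem
#' from indistinguishable (`delta = 0`) to cleanly separated. The positive
#' mean profile itself is drawn with spread `profile_sd * sd` across
#' features, which is what gives samples of the same class correlated
#' profile shapes and makes sample-wise Pearson relevance informative.
#' Negative rows (true and planted) are shuffled together so plantedness is
#' not encoded in row order. Fully determined by `seed`.
#'
#' @param m Number of positive samples.
#' @param n_true_neg Number of genuine negative samples.
#' @param l_true Number of planted pseudo-negatives (may be 0).
#' @param f Number of features.
#' @param delta Class-mean separation per feature, in units of `sd`.
#' @param sd Within-class standard deviation (default 1).
#' @param seed Integer seed.
#' @param profile_sd Spread of the class mean profile across features, in
#'   units of `sd` (default 3).
#' @return A `planted_dataset`: list with `dataset` (a [labeled_dataset()]),
#'   `planted_indices` (row indices of the planted samples) and
#'   `generator_params`.
#' @export
#' @examples
#' pd <- generate_planted(m = 20, n_true_neg = 180, l_true = 20, f = 10,
#'                        delta = 4, seed = 1)
#' pd$dataset
generate_planted <- function(m, n_true_neg, l_true, f, delta, sd = 1,
                             seed = 1L, profile_sd = 3) {
  if (m < 1 || n_true_neg < 1 || f < 1 || l_true < 0 || delta < 0 || sd <= 0) {
    stop("invalid generator sizes: need m, n_true_neg, f >= 1, l_true >= 0, delta >= 0, sd > 0",
         call. = FALSE)
  }
  set.seed(seed)
  mu_pos <- stats::rnorm(f, 0, profile_sd * sd)
  u <- stats::rnorm(f)
  u <- u / sqrt(sum(u^2))
  mu_neg <- mu_pos + delta * sd * sqrt(f) * u

  draw <- function(k, mu) {
    matrix(stats::rnorm(k * f, 0, sd), k, f) + matrix(mu, k, f, byrow = TRUE)
  }
  pos <- draw(m, mu_pos)
  true_neg <- draw(n_true_neg, mu_neg)
  planted <- if (l_true > 0) draw(l_true, mu_pos) else NULL

  neg_rows <- rbind(true_neg, planted)
  perm <- sample.int(nrow(neg_rows))
  neg_rows <- neg_rows[perm, , drop = FALSE]
  planted_pos_in_neg <- which(perm > n_true_neg)

  features <- rbind(pos, neg_rows)
  labels <- c(rep(1L, m), rep(0L, nrow(neg_rows)))
  dataset <- labeled_dataset(features, labels,
                             feature_names = paste0("f", seq_len(f)))
  structure(
    list(dataset = dataset,
         planted_indices = as.integer(m + planted_pos_in_neg),
         generator_params = list(m = m, n_true_neg = n_true_neg,
                                 l_true = l_true, f = f, delta = delta,
                                 sd = sd, profile_sd = profile_sd,
                                 seed = seed)),
    class = "planted_dataset")
}

#' @export
print.planted_dataset <- function(x, ...) {
  p <- x$generator_params
  cat(sprintf("<planted_dataset> m=%d, n=%d (%d planted), f=%d, delta=%g, seed=%d\n",
              p$m, p$n_true_neg + p$l_true, p$l_true, p$f, p$delta, p$seed))
  invisible(x)
}

#' Precision and recall of a selection against planted ground truth
#'
#' Compares a selector's output with the known planted pseudo-negatives:
#' precision = |selected intersect planted| / |selected| and
#' recall = |selected intersect planted| / |planted|. Recall of an empty
#' planted set is 1 by convention (flagged); precision of an empty selection
#' is NA (flagged). The selection must have been produced on the same
#' dataset (checked by fingerprint).
#'
#' @param result A `selection_result` produced on `truth$dataset`.
#' @param truth A `planted_dataset`.
#' @return A list with `precision`, `recall` and `flags`.
#' @export
recovery_score <- function(result, truth) {
  stopifnot(inherits(result, "selection_result"),
            inherits(truth, "planted_dataset"))
  if (!identical(result$dataset_fingerprint,
                 dataset_fingerprint(truth$dataset))) {
    stop("selection result was not produced on this planted dataset (fingerprint mismatch)",
         call. = FALSE)
  }
  hits <- length(intersect(result$selected, truth$planted_indices))
  flags <- character(0)
  if (length(result$selected) == 0L) {
    precision <- NA_real_
    flags <- c(flags, "empty selection: precision undefined")
  } else precision <- hits / length(result$selected)
  if (length(truth$planted_indices) == 0L) {
    recall <- 1
    flags <- c(flags, "empty planted set: recall 1 by convention")
  } else recall <- hits / length(truth$planted_indices)
  list(precision = precision, recall = recall, flags = flags)
}
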