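#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the display convention
#' used for imbalance ratios and percentage-resolved sample counts. Base R's
#' `round()` rounds ties to even, which would turn 166.5 into 166.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a labeled dataset from delimited text
#'
#' Loads a CSV/TSV file (header row required) with numeric feature columns
#' and one label column, validating that every feature cell is numeric and
#' finite. Rows whose label equals `positive_label` become positives; if
#' `negative_label` is `NULL` the remaining single label value becomes the
#' negatives (more than two distinct values is an error). A warning is
#' issued when the positive class is the majority, since the pseudo-negative
#' setting assumes minority positives.
#'
#' @param path File path; tab-separated when the extension is `.tsv`/`.tab`,
#'   comma-separated otherwise.
#' @param label_column Name of the label column (default `"label"`).
#' @param positive_label Value in the label column marking positives.
#' @param negative_label Optional explicit negative value.
#' @param drop_degenerate Passed to [labeled_dataset()].
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, label_column = "label", positive_label = 1,
                         negative_label = NULL, drop_degenerate = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column %s not found (columns: %s)",
                 dQuote(label_column), paste(names(df), collapse = ", ")),
         call. = FALSE)
  }
  raw_labels <- df[[label_column]]
  feat_df <- df[setdiff(names(df), label_column)]
  for (j in seq_along(feat_df)) {
    v <- feat_df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric feature value %s at row %d, column %s",
                     dQuote(v[bad[1]]), bad[1], dQuote(names(feat_df)[j])),
             call. = FALSE)
      }
      feat_df[[j]] <- vn
    }
    miss <- which(is.na(feat_df[[j]]))
    if (length(miss) > 0) {
      stop(sprintf("missing feature value at row %d, column %s",
                   miss[1], dQuote(names(feat_df)[j])), call. = FALSE)
    }
  }
  uniq <- unique(raw_labels)
  if (!positive_label %in% uniq) {
    stop(sprintf("positive label %s not present in column %s",
                 dQuote(positive_label), dQuote(label_column)), call. = FALSE)
  }
  if (is.null(negative_label)) {
    others <- setdiff(uniq, positive_label)
    if (length(others) != 1L) {
      stop(sprintf("expected exactly one non-positive label value, found: %s",
                   paste(dQuote(others), collapse = ", ")), call. = FALSE)
    }
    negative_label <- others
  } else if (!all(uniq %in% c(positive_label, negative_label))) {
    bad <- setdiff(uniq, c(positive_label, negative_label))[1]
    stop(sprintf("unknown label value %s at row %d", dQuote(bad),
                 which(raw_labels == bad)[1]), call. = FALSE)
  }
  labels <- as.integer(raw_labels == positive_label)
  d <- labeled_dataset(as.matrix(feat_df), labels,
                       feature_names = names(feat_df),
                       drop_degenerate = drop_degenerate)
  if (positive_count(d) > negative_count(d)) {
    warning("the positive class is the majority; pseudo-negative sampling assumes minority positives",
            call. = FALSE)
  }
  d
}

#' Write a labeled dataset to delimited text
#'
#' Inverse of [read_dataset()]: features plus a 0/1 `label` column, and a
#' `provenance` column when the dataset carries one (appended synthetic or
#' duplicated rows are tagged by the resampling baselines).
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output path; `.tsv`/`.tab` writes tab-separated.
#' @param label_column Name for the label column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, label_column = "label") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(dataset$features)
  if (is.null(dataset$feature_names)) {
    names(df) <- paste0("f", seq_len(ncol(df)))
  }
  df[[label_column]] <- dataset$labels
  if (!is.null(dataset$provenance)) df$provenance <- dataset$provenance
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dataset descriptor with imbalance ratio
#'
#' Summarizes a dataset the way benchmark tables do: class counts, feature
#' count, and the imbalance ratio (negatives / positives) displayed to one
#' decimal, rounded half-up.
#'
#' @param dataset A [labeled_dataset()], or use [dataset_descriptor()] to
#'   build one directly from printed counts.
#' @param name Dataset name for display.
#' @return A `dataset_descriptor`: list with `name`, `positives`,
#'   `negatives`, `attributes`, `ratio` (one-decimal) and `ratio_exact`.
#' @export
#' @examples
#' describe(labeled_dataset(matrix(rnorm(40), 10, 4), rep(c(1, 0), c(3, 7))))
describe <- function(dataset, name = "dataset") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dataset_descriptor(name, positive_count(dataset), negative_count(dataset),
                     ncol(dataset$features))
}

#' @rdname describe
#' @param positives,negatives,attributes Class and feature counts.
#' @export
dataset_descriptor <- function(name, positives, negatives, attributes) {
  if (positives < 1 || negatives < 1 || attributes < 1) {
    stop("positives, negatives and attributes must all be >= 1", call. = FALSE)
  }
  structure(
    list(name = name, positives = as.integer(positives),
         negatives = as.integer(negatives), attributes = as.integer(attributes),
         ratio = round_half_up(negatives / positives, 1),
         ratio_exact = negatives / positives),
    class = "dataset_descriptor")
}

#' @export
print.dataset_descriptor <- function(x, ...) {
  cat(sprintf("%s: %d positive / %d negative, %d attributes, ratio %.1f\n",
              x$name, x$positives, x$negatives, x$attributes, x$ratio))
  invisible(x)
}

#' Per-residue scoring profile
#'
#' Container for a protein chain's position-specific scoring matrix (PSSM):
#' 20 conservation scores per residue (one per amino-acid type, assumed
#' pre-scaled) plus a binary per-residue label (e.g. DNA-binding vs not).
#'
#' @param scores Numeric matrix, `n_residues x 20`.
#' @param labels Binary vector of length `n_residues`.
#' @param sequence_id Identifier for the chain.
#' @return A `residue_profile` object.
#' @export
residue_profile <- function(scores, labels, sequence_id = "seq") {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    stop(sprintf("PSSM profiles must have exactly 20 score columns, got %d",
                 ncol(scores)), call. = FALSE)
  }
  if (nrow(scores) != length(labels)) {
    stop("labels length must equal the number of residues", call. = FALSE)
  }
  structure(list(scores = scores, labels = coerce_labels01(labels),
                 sequence_id = sequence_id),
            class = "residue_profile")
}

#' Sliding-window PSSM features
#'
#' Turns a per-residue profile into one sample per residue: the PSSM score
#' rows of a window of `window` consecutive residues centered on the target,
#' flattened row-major (each position's 20 scores contiguous, positions
#' left to right). Positions falling outside the sequence are zero-padded,
#' so every sample has exactly `window * 20` features — 180 at the default
#' window of 9. The residue's binding label becomes the sample label.
#'
#' @param profile A [residue_profile()] or list of them.
#' @param window Odd window length (default 9).
#' @return A [labeled_dataset()] with `window * 20` feature columns.
#' @export
pssm_window_features <- function(profile, window = 9L) {
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  profiles <- if (inherits(profile, "residue_profile")) list(profile) else profile
  half <- (window - 1L) %/% 2L
  feats <- NULL; labs <- integer(0)
  for (pr in profiles) {
    stopifnot(inherits(pr, "residue_profile"))
    nres <- nrow(pr$scores)
    rows <- matrix(0, nres, window * 20L)
    for (i in seq_len(nres)) {
      offs <- (i - half):(i + half)
      inside <- offs >= 1L & offs <= nres
      block <- matrix(0, window, 20L)
      block[inside, ] <- pr$scores[offs[inside], , drop = FALSE]
      rows[i, ] <- as.vector(t(block))
    }
    feats <- rbind(feats, rows)
    labs <- c(labs, pr$labels)
  }
  fn <- as.vector(t(outer(seq_len(window), seq_len(20L),
                          function(p, s) sprintf("w%02d_s%02d", p, s))))
  labeled_dataset(feats, labs, feature_names = fn, drop_degenerate = TRUE)
}
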