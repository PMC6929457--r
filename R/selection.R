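#' Sampler configuration
#'
#' Configures a pseudo-negative selector. Exactly one of `l` (an explicit
#' number of samples to select) or `percentage` must be given; a percentage
#' is resolved against the positive count m (default) or the negative count n
#' via [resolve_l()]. The number of pseudo-negatives is an expert choice; the
#' usual regime keeps l below m, and a warning is issued otherwise.
#'
#' @param method `"MMPCC"` (joint max-relevance min-redundancy, the default),
#'   `"MAXR"` (relevance only) or `"MINR"` (redundancy only).
#' @param l Positive integer count of pseudo-negatives to select.
#' @param percentage Alternative to `l`: a value in (0, 100\] (0 is accepted
#'   and means no sampling).
#' @param percentage_base `"positives"` (default) or `"negatives"`: the count
#'   the percentage is taken of.
#' @param aggregation How per-negative relevance is aggregated over the
#'   positive set: `"mean"` (default) or `"max"`. See [aggregate_relevance()].
#' @param use_abs Use absolute correlations for relevance/redundancy.
#' @param seed Integer recorded in the result for audit; selection itself is
#'   deterministic (ties break to the lowest original sample index).
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(method = c("MMPCC", "MAXR", "MINR"),
                           l = NULL, percentage = NULL,
                           percentage_base = c("positives", "negatives"),
                           aggregation = c("mean", "max"),
                           use_abs = FALSE, seed = NULL) {
  method <- match.arg(method)
  percentage_base <- match.arg(percentage_base)
  aggregation <- match.arg(aggregation)
  if (is.null(l) == is.null(percentage)) {
    stop("exactly one of `l` or `percentage` must be set", call. = FALSE)
  }
  if (!is.null(l) && (length(l) != 1L || l < 1 || l != round(l))) {
    stop("`l` must be a single positive integer", call. = FALSE)
  }
  if (!is.null(percentage) &&
      (length(percentage) != 1L || percentage < 0 || percentage > 100)) {
    stop("`percentage` must lie in [0, 100]", call. = FALSE)
  }
  structure(
    list(method = method, l = l, percentage = percentage,
         percentage_base = percentage_base, aggregation = aggregation,
         use_abs = use_abs, seed = seed),
    class = "sampler_config")
}

#' Resolve the number of pseudo-negatives to select
#'
#' Turns a config's `l` or `percentage` into an integer count. Percentages
#' are rounded half-up against the chosen base count and clamped to
#' \[0, n\]. A resolved l of 0 (the 0% sweep point) means "no sampling" and
#' triggers a warning only when a nonzero percentage collapsed to 0.
#'
#' @param config A [sampler_config()] (or baseline config with the same
#'   `amount`/`percentage` semantics).
#' @param dataset The [labeled_dataset()] the config will be applied to.
#' @return A single integer in \[0, n\].
#' @export
resolve_l <- function(config, dataset) {
  m <- positive_count(dataset)
  n <- negative_count(dataset)
  if (!is.null(config$l)) {
    l <- as.integer(config$l)
    if (l > n) {
      stop(sprintf("l = %d exceeds the negative count n = %d", l, n),
           call. = FALSE)
    }
  } else {
    base <- if (identical(config$percentage_base, "negatives")) n else m
    l <- as.integer(round_half_up(config$percentage / 100 * base, 0))
    if (l == 0L && config$percentage > 0) {
      warning(sprintf("percentage %g of %d resolves to l = 0 (no sampling)",
                      config$percentage, base), call. = FALSE)
    }
    l <- max(0L, min(l, n))
  }
  if (l >= m) {
    warning(sprintf("resolved l = %d is not below the positive count m = %d; the usual regime keeps l < m",
                    l, m), call. = FALSE)
  }
  l
}

new_selection_result <- function(selected, d, r, method, config, dataset,
                                 n_correlations) {
  structure(
    list(selected = as.integer(selected),
         d_scores = as.numeric(d), r_scores = as.numeric(r),
         psi_scores = as.numeric(d) - as.numeric(r),
         method = method, l = length(selected), config = config,
         n_correlations = n_correlations,
         dataset_fingerprint = dataset_fingerprint(dataset)),
    class = "selection_result")
}

dataset_fingerprint <- function(dataset) {
  paste(nrow(dataset$features), ncol(dataset$features),
        sum(dataset$labels), signif(sum(dataset$features), 12), sep = "/")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d pseudo-negatives (%d correlation evaluations)\n",
              x$method, x$l, x$n_correlations))
  if (x$l > 0) {
    utils::head(as.data.frame(x), 5L) |> print(row.names = FALSE)
    if (x$l > 5) cat(sprintf("... %d more steps\n", x$l - 5L))
  }
  invisible(x)
}

#' @export
as.data.frame.selection_result <- function(x, ...) {
  data.frame(step = seq_len(x$l), sample_index = x$selected,
             D = x$d_scores, R = x$r_scores, Psi = x$psi_scores)
}

#' Select pseudo-negatives with the MMPCC criterion
#'
#' Greedy forward selection over the negative class starting from the empty
#' set. At step k each remaining candidate i is scored by
#' Psi_i = D_i - R_i, where D_i is the candidate's aggregated Pearson
#' relevance to the positive class and R_i is its mean correlation to the
#' k-1 samples already selected (0 at the first step); the candidate with
#' maximal Psi wins, ties going to the lowest sample index. The relevance
#' block is computed once (n*m correlations) and the redundancy sums are
#' updated incrementally (at most n per step), so the total correlation
#' count is at most n*m + n*l.
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [sampler_config()]; its `method` is ignored here.
#' @return A `selection_result` with the ordered selected indices and the
#'   winning candidate's D, R and Psi at every step.
#' @seealso [select_maxr()], [select_minr()], [relabel()]
#' @export
select_mmpcc <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "sampler_config"))
  l <- resolve_l(config, dataset)
  block <- relevance_block(dataset, use_abs = config$use_abs)
  d_all <- aggregate_relevance(block, config$aggregation)
  neg <- block$row_index
  n_cor <- block$n_correlations

  sel <- integer(0); d_win <- numeric(0); r_win <- numeric(0)
  r_sum <- rep(0, length(neg))
  avail <- rep(TRUE, length(neg))
  tneg <- t(dataset$features[neg, , drop = FALSE])
  for (k in seq_len(l)) {
    r_cur <- if (k == 1L) rep(0, length(neg)) else r_sum / (k - 1L)
    psi <- d_all - r_cur
    psi[!avail] <- -Inf
    w <- which.max(psi)  # first max = lowest original index among ties
    sel <- c(sel, neg[w]); d_win <- c(d_win, d_all[[w]]); r_win <- c(r_win, r_cur[[w]])
    avail[w] <- FALSE
    if (k < l) {
      cor_new <- as.numeric(stats::cor(tneg, dataset$features[neg[w], ]))
      if (config$use_abs) cor_new <- abs(cor_new)
      r_sum <- r_sum + cor_new
      n_cor <- n_cor + sum(avail)  # only remaining candidates need the update
    }
  }
  new_selection_result(sel, d_win, r_win, "MMPCC", config, dataset, n_cor)
}

#' Select pseudo-negatives by max-relevance only (MAXR)
#'
#' The relevance-only ablation: the l negatives with the largest aggregated
#' Pearson correlation to the positive class, in descending-relevance order.
#' Redundancy scores are all zero.
#'
#' @inheritParams select_mmpcc
#' @return A `selection_result`.
#' @export
select_maxr <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "sampler_config"))
  l <- resolve_l(config, dataset)
  block <- relevance_block(dataset, use_abs = config$use_abs)
  d_all <- aggregate_relevance(block, config$aggregation)
  ord <- order(-d_all)[seq_len(l)]  # stable: ties keep ascending index
  new_selection_result(block$row_index[ord], d_all[ord], rep(0, l),
                       "MAXR", config, dataset, block$n_correlations)
}

#' Select pseudo-negatives by min-redundancy only (MINR)
#'
#' The redundancy-only ablation. The first pick is the negative with minimal
#' mean correlation to all other negatives (a pure-redundancy rule for the
#' otherwise-undefined empty-set step); each later step picks the remaining
#' candidate with minimal mean correlation to the already-selected set.
#' Relevance scores are all zero, so Psi = -R.
#'
#' @inheritParams select_mmpcc
#' @return A `selection_result`.
#' @export
select_minr <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "sampler_config"))
  l <- resolve_l(config, dataset)
  neg <- negative_indices(dataset)
  n <- length(neg)
  sel <- integer(0); r_win <- numeric(0)
  avail <- rep(TRUE, n)
  tneg <- t(dataset$features[neg, , drop = FALSE])
  n_cor <- 0L
  r_sum <- rep(0, n)
  for (k in seq_len(l)) {
    if (k == 1L) {
      cmat <- stats::cor(tneg)
      if (config$use_abs) cmat <- abs(cmat)
      n_cor <- n_cor + n * (n - 1L) / 2L
      r_cur <- (rowSums(cmat) - diag(cmat)) / (n - 1L)
    } else {
      r_cur <- r_sum / (k - 1L)
    }
    r_cur[!avail] <- Inf
    w <- which.min(r_cur)
    sel <- c(sel, neg[w]); r_win <- c(r_win, if (k == 1L) r_cur[[w]] else r_cur[[w]])
    avail[w] <- FALSE
    if (k < l) {
      cor_new <- as.numeric(stats::cor(tneg, dataset$features[neg[w], ]))
      if (config$use_abs) cor_new <- abs(cor_new)
      r_sum <- r_sum + cor_new
      n_cor <- n_cor + sum(avail)
    }
  }
  new_selection_result(sel, rep(0, l), r_win, "MINR", config, dataset, n_cor)
}

#' Run the selector named in a config
#'
#' Dispatches to [select_mmpcc()], [select_maxr()] or [select_minr()]
#' according to `config$method`.
#'
#' @inheritParams select_mmpcc
#' @return A `selection_result`.
#' @export
select_pseudo_negatives <- function(dataset, config) {
  switch(config$method,
         MMPCC = select_mmpcc(dataset, config),
         MAXR = select_maxr(dataset, config),
         MINR = select_minr(dataset, config))
}

#' Brute-force single greedy step (test oracle)
#'
#' Evaluates one greedy step of MMPCC, MAXR or MINR with naive loops over
#' scalar [pearson()] calls and no caching. Intended as an independent
#' oracle for the optimized selectors, not for production use.
#'
#' @param dataset A [labeled_dataset()].
#' @param selected_so_far Integer vector of already-selected dataset row
#'   indices (possibly empty).
#' @param config A [sampler_config()]; `method` decides the scored criterion.
#' @return A list with `winner` (dataset row index), `D`, `R` and `Psi` of
#'   the winning candidate.
#' @export
brute_force_step <- function(dataset, selected_so_far, config) {
  neg <- negative_indices(dataset)
  pos <- positive_indices(dataset)
  cand <- setdiff(neg, selected_so_far)
  if (length(cand) == 0L) stop("no remaining candidates", call. = FALSE)
  pcc <- function(i, j) {
    v <- pearson(dataset$features[i, ], dataset$features[j, ])
    if (config$use_abs) abs(v) else v
  }
  k_minus_1 <- length(selected_so_far)
  best <- NULL
  for (i in cand) {
    if (config$method %in% c("MMPCC", "MAXR")) {
      per_pos <- vapply(pos, function(j) pcc(i, j), numeric(1))
      D <- if (identical(config$aggregation, "max")) max(per_pos) else mean(per_pos)
    } else D <- 0
    if (config$method == "MAXR") {
      R <- 0
    } else if (k_minus_1 == 0L) {
      if (config$method == "MINR") {
        others <- setdiff(neg, i)
        R <- mean(vapply(others, function(s) pcc(i, s), numeric(1)))
      } else R <- 0
    } else {
      R <- sum(vapply(selected_so_far, function(s) pcc(i, s),
                      numeric(1))) / k_minus_1
    }
    score <- if (config$method == "MINR") -R else D - R
    if (is.null(best) || score > best$score) {
      best <- list(winner = i, D = D, R = R, Psi = D - R, score = score)
    }
  }
  best$score <- NULL
  best
}

#' Relabel selected pseudo-negatives as positive
#'
#' Flips the labels of the selected samples from negative to positive — the
#' samples move between classes (no duplication), so the new class counts
#' are m + l positives and n - l negatives. The feature matrix and the input
#' dataset are untouched.
#'
#' @param dataset The [labeled_dataset()] the selection was made on.
#' @param result A `selection_result` (or integer vector of negative row
#'   indices).
#' @return A new `labeled_dataset` with flipped labels.
#' @export
relabel <- function(dataset, result) {
  idx <- if (inherits(result, "selection_result")) result$selected else as.integer(result)
  if (length(idx) == 0L) return(dataset)
  if (any(dataset$labels[idx] != 0L)) {
    stop(sprintf("index %d is not a negative sample",
                 idx[which(dataset$labels[idx] != 0L)[1]]), call. = FALSE)
  }
  out <- dataset
  out$labels[idx] <- 1L
  out
}

#' Write a selection result to CSV or JSON
#'
#' CSV has one row per greedy step (`step, sample_index, D, R, Psi`); JSON
#' additionally echoes the resolved configuration.
#'
#' @param result A `selection_result`.
#' @param path Output file; format chosen by extension (`.json` vs anything
#'   else, written as CSV).
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- result$config
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    jsonlite::write_json(
      list(method = result$method, l = result$l,
           config = cfg, steps = as.data.frame(result),
           n_correlations = result$n_correlations),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  }
  invisible(path)
}
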