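# Random fixture builders used across the suite.

random_dataset <- function(m = 5, n = 12, f = 6, seed = 1) {
  set.seed(seed)
  labeled_dataset(matrix(rnorm((m + n) * f), m + n, f),
                  rep(c(1L, 0L), c(m, n)))
}

# Selection config with explicit l and default everything else.
cfg_l <- function(method, l, ...) {
  suppressWarnings(sampler_config(method = method, l = l, ...))
}

# Run a selector and verify every greedy step against brute_force_step.
expect_matches_oracle <- function(dataset, config) {
  res <- suppressWarnings(select_pseudo_negatives(dataset, config))
  sel <- integer(0)
  for (k in seq_len(res$l)) {
    bf <- brute_force_step(dataset, sel, config)
    expect_identical(bf$winner, res$selected[k])
    sel <- c(sel, res$selected[k])
  }
  invisible(res)
}

random_counts <- function() {
  as.list(structure(sample(0:40, 4, replace = TRUE),
                    names = c("TP", "TN", "FP", "FN")))
}
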