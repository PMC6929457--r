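test_that("resolve_l handles explicit counts, percentages and edge cases", {
  d <- random_dataset(m = 333, n = 400, f = 3, seed = 3)
  expect_identical(resolve_l(cfg_l("MMPCC", 7), d), 7L)
  expect_identical(resolve_l(sampler_config(percentage = 0), d), 0L)
  # round-half-up: 50% of 333 positives is 166.5 -> 167
  expect_identical(resolve_l(sampler_config(percentage = 50), d), 167L)
  expect_identical(
    resolve_l(sampler_config(percentage = 10, percentage_base = "negatives"), d),
    40L)
  expect_error(resolve_l(cfg_l("MMPCC", 500), d), "exceeds the negative count")
  small <- random_dataset(m = 4, n = 10, f = 3, seed = 4)
  expect_warning(resolve_l(sampler_config(l = 5), small), "l < m")
})

test_that("sampler_config requires exactly one of l and percentage", {
  expect_error(sampler_config(), "exactly one")
  expect_error(sampler_config(l = 3, percentage = 10), "exactly one")
  expect_error(sampler_config(l = 0), "positive integer")
  expect_error(sampler_config(percentage = 150), "\\[0, 100\\]")
})

test_that("all three selectors agree with the brute-force oracle per step", {
  set.seed(99)
  for (i in 1:12) {
    m <- sample(2:6, 1); n <- sample(6:18, 1); f <- sample(3:8, 1)
    d <- random_dataset(m, n, f, seed = 1000 + i)
    l <- sample(1:min(6, n), 1)
    for (meth in c("MMPCC", "MAXR", "MINR")) {
      expect_matches_oracle(d, cfg_l(meth, l))
    }
  }
})

test_that("selection results are deterministic and internally consistent", {
  d <- random_dataset(m = 5, n = 20, f = 6, seed = 21)
  for (meth in c("MMPCC", "MAXR", "MINR")) {
    r1 <- select_pseudo_negatives(d, cfg_l(meth, 4))
    r2 <- select_pseudo_negatives(d, cfg_l(meth, 4))
    expect_identical(r1, r2)
    expect_identical(anyDuplicated(r1$selected), 0L)
    expect_true(all(d$labels[r1$selected] == 0L))
    expect_equal(r1$psi_scores, r1$d_scores - r1$r_scores)
  }
  rm_ <- select_mmpcc(d, cfg_l("MMPCC", 4))
  expect_identical(rm_$r_scores[1], 0)
})

test_that("MMPCC with l = 1 reduces to MAXR's top pick", {
  d <- random_dataset(m = 4, n = 15, f = 5, seed = 31)
  expect_identical(select_mmpcc(d, cfg_l("MMPCC", 1))$selected,
                   select_maxr(d, cfg_l("MAXR", 1))$selected)
})

test_that("MAXR equals sorting the relevance vector and is prefix-monotone", {
  d <- random_dataset(m = 5, n = 30, f = 6, seed = 41)
  d_scores <- aggregate_relevance(relevance_block(d), "mean")
  expected <- as.integer(names(sort(d_scores, decreasing = TRUE)))
  full <- suppressWarnings(select_maxr(d, cfg_l("MAXR", 30)))
  expect_identical(full$selected, expected)
  for (l in c(3, 7, 15)) {
    part <- suppressWarnings(select_maxr(d, cfg_l("MAXR", l)))
    expect_identical(part$selected, expected[1:l])
  }
})

test_that("an exact copy of a positive is MAXR's first pick with D = 1", {
  pos_row <- c(1, 4, 2, 8)
  X <- rbind(pos_row, pos_row,                 # identical positives
             pos_row, c(8, 1, 3, 2), c(0, 2, 9, 1))
  d <- labeled_dataset(X, c(1, 1, 0, 0, 0))
  for (agg in c("mean", "max")) {
    r <- select_maxr(d, cfg_l("MAXR", 1, aggregation = agg))
    expect_identical(r$selected, 3L)
    expect_equal(r$d_scores, 1)
  }
})

test_that("MINR's pure-redundancy rule picks the anticorrelated sample first", {
  v <- c(1, 2, 3); w <- c(3, 2, 1)   # pearson(v, w) = -1
  d <- labeled_dataset(rbind(c(5, 1, 2), v, v, w), c(1, 0, 0, 0))
  r <- suppressWarnings(select_minr(d, cfg_l("MINR", 2)))
  # step 1: w has mean correlation -1 to the other negatives, the copies of v
  # have mean 0; step 2: both copies tie at cor -1, lowest index wins
  expect_identical(r$selected, c(4L, 2L))
  expect_equal(r$d_scores, c(0, 0))
})

test_that("MMPCC's correlation count respects the n*m + n*l budget", {
  d <- random_dataset(m = 8, n = 40, f = 6, seed = 51)
  r <- select_mmpcc(d, cfg_l("MMPCC", 6))
  expect_lte(r$n_correlations, 40 * 8 + 40 * 6)
  expect_gte(r$n_correlations, 40 * 8)  # the relevance block is always paid
})

test_that("relabel flips selected negatives to positive without copying", {
  d <- random_dataset(m = 10, n = 100, f = 4, seed = 61)
  r <- suppressWarnings(select_mmpcc(d, cfg_l("MMPCC", 25)))
  d2 <- relabel(d, r)
  expect_identical(positive_count(d2), 35L)
  expect_identical(negative_count(d2), 75L)
  expect_identical(d2$features, d$features)
  expect_identical(positive_count(d), 10L)  # input untouched
  # involution: flipping the same indices back restores the labels
  d3 <- d2; d3$labels[r$selected] <- 0L
  expect_identical(d3$labels, d$labels)
  # l = 0 is the identity
  expect_identical(relabel(d, integer(0)), d)
  expect_error(relabel(d, 1L), "not a negative")
})

test_that("selection results serialize to CSV and JSON", {
  d <- random_dataset(m = 4, n = 12, f = 5, seed = 71)
  r <- select_mmpcc(d, cfg_l("MMPCC", 3))
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_selection(r, csv); write_selection(r, json)
  back <- read.csv(csv)
  expect_identical(names(back), c("step", "sample_index", "D", "R", "Psi"))
  expect_equal(back$sample_index, r$selected)
  payload <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_identical(payload$method, "MMPCC")
  expect_equal(payload$steps$Psi, r$psi_scores)
  unlink(c(csv, json))
})
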