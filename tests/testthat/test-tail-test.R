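test_that("quantile thresholds give equal occupancy on their own values", {
  th <- quantile_thresholds(1:20, k = 4)
  expect_equal(th$thresholds, c(0, 5, 10, 15, 20))
  F <- bin_count_prefixes(1:20, th)
  expect_equal(F, c(5L, 10L, 15L, 20L))

  # continuous values: every bin holds n/k +- 1
  set.seed(3)
  for (rep in 1:5) {
    vals <- stats::rexp(100 + rep)
    th <- quantile_thresholds(vals, k = 20)
    F <- bin_count_prefixes(vals, th)
    occ <- diff(c(0L, F))
    expect_true(all(abs(occ - length(vals) / 20) <= 1))
    expect_equal(F[20], length(vals))  # real values never overflow
  }

  expect_equal(quantile_thresholds(runif(30), k = 1)$k, 1)
  expect_error(quantile_thresholds(1:5, k = 10), "at least k")
  expect_warning(quantile_thresholds(rep(c(1, 1, 1, 2), 10), k = 4), "ties")
})

test_that("prefix counts match a naive counting oracle and handle overflow", {
  th <- quantile_thresholds(1:20, k = 4)
  expect_equal(bin_count_prefixes(c(1, 2, 3), th), c(3L, 3L, 3L, 3L))
  expect_equal(bin_count_prefixes(numeric(0), th), rep(0L, 4))
  set.seed(10)
  for (rep in 1:10) {
    vals <- runif(50, 0, 30)  # some values overflow past t_k = 20
    F <- bin_count_prefixes(vals, th)
    t <- th$thresholds
    oracle <- vapply(1:4, function(j) sum(vals >= t[1] & vals <= t[j + 1]), 0L)
    expect_equal(F, oracle)
    expect_true(all(diff(F) >= 0))
    expect_equal(F[4], sum(vals <= 20))  # overflow excluded everywhere
  }
})

test_that("an extreme first bin forces j* = 1 with corrected p = 0.001", {
  th <- quantile_thresholds(1:20, k = 4)
  real <- runif(40, 0, 5)  # everything in bin 1
  reps <- lapply(1:999, function(i) {
    set.seed(i); runif(40, 0, 20)
  })
  res <- distribution_tail_test(real, reps, thresholds = th)
  expect_equal(res$j_star, 1L)
  expect_equal(res$p_corrected, 1 * (0 + 1) / (999 + 1))
})

test_that("alpha = 0 never finds a significant prefix; alpha is monotone", {
  set.seed(5)
  real <- rexp(60, 3)
  reps <- lapply(1:99, function(i) rexp(60))
  none <- distribution_tail_test(real, reps, k = 5, alpha = 0)
  expect_true(is.na(none$j_star))

  a1 <- distribution_tail_test(real, reps, k = 5, alpha = 0.05)
  a2 <- distribution_tail_test(real, reps, k = 5, alpha = 0.2)
  if (!is.na(a1$j_star)) {
    expect_false(is.na(a2$j_star))
    expect_lte(a2$j_star, a1$j_star)
  }
})

test_that("minimal-j search agrees with a brute-force prefix scan", {
  set.seed(14)
  for (rep in 1:10) {
    real <- rexp(50, 2)
    reps <- lapply(1:49, function(i) rexp(50))
    res <- distribution_tail_test(real, reps, k = 10, alpha = 0.3)
    # brute force: recompute every prefix p-value by direct counting
    th <- res$thresholds
    Freal <- bin_count_prefixes(real, th)
    scan <- vapply(seq_len(th$k), function(j) {
      k <- sum(vapply(reps, function(v) {
        sum(v >= th$thresholds[1] & v <= th$thresholds[j + 1]) >= Freal[j]
      }, TRUE))
      (k + 1) / (49 + 1)
    }, 0)
    expect_equal(res$p_j, scan)
    hits <- which(seq_len(th$k) * scan <= 0.3)
    expect_equal(res$j_star,
                 if (length(hits)) hits[1] else NA_integer_)
    if (!is.na(res$j_star)) {
      expect_equal(res$p_corrected, res$j_star * scan[res$j_star])
    }
    expect_true(all(res$p_j >= 1 / 50))
  }
})

test_that("lexicographic extremeness follows first-difference ordering", {
  expect_true(lexicographic_refinement(c(5, 8, 2), c(5, 9, 0)))
  expect_false(lexicographic_refinement(c(5, 8, 2), c(4, 99, 99)))
  expect_true(lexicographic_refinement(c(5, 8, 2), c(5, 8, 2)))  # tie counts

  # string-padding oracle on random vector pairs
  set.seed(27)
  for (i in 1:100) {
    a <- sample(0:99, 4, replace = TRUE)
    b <- sample(0:99, 4, replace = TRUE)
    pad <- function(v) paste(sprintf("%03d", v), collapse = "")
    expect_equal(unname(lexicographic_refinement(a, b)), pad(b) >= pad(a))
  }
})

test_that("the tail test on null replicates is seldom significant", {
  # replicates from the same distribution as the real values: the minimal-j
  # search at alpha = 0.05 should almost always come up empty
  set.seed(33)
  found <- 0L
  for (rep in 1:40) {
    real <- rexp(60)
    reps <- lapply(1:99, function(i) rexp(60))
    res <- distribution_tail_test(real, reps, k = 10, alpha = 0.05)
    found <- found + !is.na(res$j_star)
  }
  expect_lte(found, 40 * 0.05 + 3 * sqrt(40 * 0.05 * 0.95) + 1)
})

test_that("integer chromosome-count thresholds reproduce the at-most-c curve", {
  cfg <- synthetic_config(n_chromosomes = 3,
                          genes_per_chromosome = c(15, 15, 15),
                          n_groups = 20, seed = 73)
  lay <- generate_genome(cfg)
  col <- generate_groups(lay, cfg, "null")
  tt <- run_tail_test(lay, col, "chrom_counts", scheme = "global",
                      n = 49, seed = 4)
  h <- chromosome_count_histogram(col, lay)
  expect_equal(tt$real_prefix, h$cumulative)
  expect_equal(tt$real_prefix[3], 20)
})
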