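test_that("coo entries are mirrored and conflicts rejected", {
  f <- tmpfile(c("seg_i\tseg_j\tvalue",
                 "chr1:0-1000000\tchr1:1000000-2000000\t5.0"))
  map <- load_contact_map(f, "coo_tsv", 1e6)
  expect_equal(map$matrix[2, 1], 5.0)
  expect_equal(map$matrix[1, 2], 5.0)
  expect_true(is.na(map$matrix[1, 1]))  # unlisted entries missing, not zero

  bad <- tmpfile(c("seg_i\tseg_j\tvalue",
                   "chr1:0-1000000\tchr1:1000000-2000000\t5",
                   "chr1:1000000-2000000\tchr1:0-1000000\t7"))
  expect_error(load_contact_map(bad, "coo_tsv", 1e6), "conflicting")
})

test_that("dense maps round-trip through write and load", {
  map <- toy_map(n = 5, chromosomes = c(3, 2))
  dir <- tempfile()
  paths <- write_fixture_bundle(toy_layout(), map = map, out_dir = dir)
  back <- load_contact_map(paths[["contact_map"]], "dense_tsv", 1e6)
  expect_equal(back$matrix, map$matrix, tolerance = 0)
  expect_equal(back$segments$chromosome, map$segments$chromosome)
  expect_equal(back$segments$start, map$segments$start)
})

test_that("genes map to the segment containing their midpoint, half-open", {
  segs <- data.frame(chromosome = "chr1", start = c(0, 1e6, 2e6),
                     end = c(1e6, 2e6, 3e6))
  map <- contact_map(diag(3) + 1, segs, 1e6)
  g <- function(s, e) list(chromosome = "chr1", start = s, end = e)
  expect_equal(gene_to_segment(g(1.4e6, 1.6e6), map), 2)  # ordinal 1, 0-based
  expect_equal(gene_to_segment(g(999999, 1000001 + 1), map), 2)  # mid = 1e6
  expect_equal(gene_to_segment(g(0, 1), map), 1)          # mid = 0
  expect_error(gene_to_segment(g(5e6, 5.1e6), map), "no segment")
})

test_that("segment distance is 1 - Pearson r on shared non-self columns", {
  # rows 1 and 2 proportional (r = 1) on their three shared columns
  M <- matrix(NA_real_, 5, 5)
  M[1, 3:5] <- c(1, 2, 3); M[3:5, 1] <- c(1, 2, 3)
  M[2, 3:5] <- c(2, 4, 6); M[3:5, 2] <- c(2, 4, 6)
  M[1, 2] <- 9; M[2, 1] <- 9
  diag(M) <- 1
  M[3, 4] <- M[4, 3] <- 1; M[3, 5] <- M[5, 3] <- 1; M[4, 5] <- M[5, 4] <- 1
  segs <- data.frame(chromosome = "chr1", start = (0:4) * 1e6,
                     end = (1:5) * 1e6)
  map <- contact_map(M, segs, 1e6)
  expect_equal(segment_distance(1, 2, map, min_overlap = 3), 0)

  # hand-computed Pearson oracle on an arbitrary pair of profiles
  x <- c(1, 5, 2); y <- c(4, 1, 7)
  M[1, 3:5] <- x; M[3:5, 1] <- x
  M[2, 3:5] <- y; M[3:5, 2] <- y
  map2 <- contact_map(M, segs, 1e6)
  expect_equal(segment_distance(1, 2, map2, min_overlap = 3),
               1 - sum((x - mean(x)) * (y - mean(y))) /
                 (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2))))

  # anti-proportional profiles give the maximum distance 2
  M[2, 3:5] <- c(3, -1, 2.5); M[3:5, 2] <- c(3, -1, 2.5)
  M[1, 3:5] <- -2 * c(3, -1, 2.5) + 1; M[3:5, 1] <- M[1, 3:5]
  map3 <- contact_map(M, segs, 1e6)
  expect_equal(segment_distance(1, 2, map3, min_overlap = 3), 2)

  # identical profile with itself: distance 0
  expect_equal(segment_distance(2, 2, map3), 0)
})

test_that("min_overlap and zero variance yield undefined distances", {
  map <- toy_map(n = 6)
  expect_true(is.na(segment_distance(1, 2, map, min_overlap = 10)))
  M <- map$matrix
  M[1, ] <- 1; M[, 1] <- 1  # constant profile
  flat <- contact_map(M, map$segments, map$segment_size)
  expect_true(is.na(segment_distance(1, 2, flat, min_overlap = 3)))
})

test_that("closed-form distance matrix matches the per-pair definition", {
  map <- toy_map(n = 12, chromosomes = c(6, 6), seed = 3)
  Dfast <- spatial_distance_matrix(map, min_overlap = 5)
  n <- nrow(map$matrix)
  for (i in 1:n) for (j in 1:n) {
    expect_equal(Dfast[i, j],
                 segment_distance(i, j, map, min_overlap = 5),
                 tolerance = 1e-10)
  }
  # defined distances live in [0, 2] and the matrix is symmetric
  expect_true(all(Dfast >= 0 & Dfast <= 2, na.rm = TRUE))
  expect_equal(Dfast, t(Dfast))
  expect_true(all(diag(Dfast) == 0))
})

test_that("distance grows with linear separation on a noise-free decay map", {
  cfg <- synthetic_config(n_chromosomes = 2, genes_per_chromosome = 40,
                          noise = 0, decay_exponent = 1, seed = 8)
  lay <- generate_genome(cfg)
  map <- generate_contact_map(lay, cfg)
  D <- spatial_distance_matrix(map, min_overlap = 5)
  ch1 <- which(map$segments$chromosome == "chr1")
  d_by_sep <- sapply(1:(length(ch1) - 1), function(s) {
    mean(D[cbind(ch1[1:(length(ch1) - s)], ch1[(1 + s):length(ch1)])],
         na.rm = TRUE)
  })
  expect_true(all(diff(d_by_sep[1:10]) > 0))

  # gene pairs in adjacent segments are closer than far-apart pairs
  g_at <- function(seg) {
    s <- map$segments$start[seg] + 1000
    list(chromosome = map$segments$chromosome[seg], start = s, end = s + 100)
  }
  near <- gene_pair_distance(g_at(ch1[1]), g_at(ch1[2]), map, min_overlap = 5)
  far <- gene_pair_distance(g_at(ch1[1]), g_at(ch1[15]), map, min_overlap = 5)
  expect_equal(near$pair_class, "intra")
  expect_lt(near$distance, far$distance)
})

test_that("gene pair distances classify intra vs inter and same-segment as 0", {
  map <- toy_map(n = 40, chromosomes = c(20, 20), seed = 12)
  a <- list(chromosome = "chr1", start = 100, end = 200)
  b <- list(chromosome = "chr1", start = 300, end = 400)  # same segment
  r <- gene_pair_distance(a, b, map)
  expect_equal(r$distance, 0)
  expect_equal(r$pair_class, "intra")
  x <- list(chromosome = "chr2", start = 100, end = 200)
  expect_equal(gene_pair_distance(a, x, map)$pair_class, "inter")
})
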