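test_that("chromosomes_involved counts distinct chromosomes with members", {
  lay <- toy_layout()
  expect_equal(chromosomes_involved(c("a1", "a2", "a3"), lay), 1)
  expect_equal(chromosomes_involved(c("a1", "b1"), lay), 2)
  expect_error(chromosomes_involved(c("zz"), lay), "no members")
  # a group on 5 of 23 chromosomes counts 5, however many genes it has
  big <- funcoloc:::new_genome_layout(data.frame(
    gene_id = paste0("g", 1:23), chromosome = paste0("chr", 1:23),
    start = 0, end = 100, stringsAsFactors = FALSE))
  expect_equal(chromosomes_involved(paste0("g", c(1, 1, 4, 9, 12, 20)), big), 5)
})

test_that("mean chromosome count and histogram agree with direct recounts", {
  lay <- toy_layout()
  col <- toy_collection(list(c("a1", "a2"), c("a3", "b1", "b2")))
  expect_equal(mean_chromosome_count(col, lay), mean(c(1, 2)))

  h <- chromosome_count_histogram(
    toy_collection(list(c("a1", "a2"), c("a2", "a3"), c("a1", "b1"))), lay)
  expect_equal(h$f, c(2, 1))
  expect_equal(h$cumulative[2], 3)

  # brute-force oracle on a random collection
  cfg <- synthetic_config(n_chromosomes = 3,
                          genes_per_chromosome = c(10, 8, 6),
                          n_groups = 10, seed = 61)
  rlay <- generate_genome(cfg)
  rcol <- generate_groups(rlay, cfg, "null")
  counts <- vapply(rcol$groups, function(g) {
    length(unique(rlay$genes$chromosome[rlay$genes$gene_id %in% g$members]))
  }, 0L)
  expect_equal(mean_chromosome_count(rcol, rlay), sum(counts) / 10)
  expect_equal(chromosome_count_histogram(rcol, rlay)$f,
               tabulate(counts, 3))
  expect_equal(sum(chromosome_count_histogram(rcol, rlay)$f), 10)
})

test_that("per-group linear means average midpoint distances of eligible pairs", {
  lay <- funcoloc:::new_genome_layout(data.frame(
    gene_id = c("x", "y", "z"), chromosome = "chr1",
    start = c(50, 250, 650), end = c(150, 350, 750),
    stringsAsFactors = FALSE))  # midpoints 100, 300, 700
  col <- toy_collection(list(c("x", "y", "z")))
  rec <- group_mean_distances(col, lay, "linear", "intra_only")
  expect_equal(rec$d_i, mean(c(200, 600, 400)))
  expect_equal(rec$d_i, 400)
  expect_equal(rec$n_pairs, 3)
})

test_that("cross-chromosome groups are omitted under the intra filter", {
  lay <- toy_layout()
  col <- toy_collection(list(G1 = c("a1", "b1"), G2 = c("a1", "a2")))
  rec <- group_mean_distances(col, lay, "linear", "intra_only")
  expect_equal(rec$group_id, "G2")
  expect_error(
    group_mean_distances(toy_collection(list(c("a1", "b1"))), lay,
                         "linear", "intra_only"),
    "all groups omitted")
})

test_that("spatial group means equal hand-averaged segment distances", {
  map <- toy_map(n = 8, chromosomes = c(4, 4), segment_size = 1e6, seed = 44)
  # genes placed mid-segment on segments 1, 3 (chr1) and 5 (chr2)
  lay <- funcoloc:::new_genome_layout(data.frame(
    gene_id = c("u", "v", "w"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(0.4e6, 2.4e6, 0.4e6), end = c(0.6e6, 2.6e6, 0.6e6),
    stringsAsFactors = FALSE))
  col <- toy_collection(list(c("u", "v", "w")))
  rec <- group_mean_distances(col, lay, "spatial", "all", map = map,
                              min_overlap = 3)
  d <- function(i, j) segment_distance(i, j, map, min_overlap = 3)
  expect_equal(rec$d_i, mean(c(d(1, 3), d(1, 5), d(3, 5))))

  inter <- group_mean_distances(col, lay, "spatial", "inter_only", map = map,
                                min_overlap = 3)
  expect_equal(inter$d_i, mean(c(d(1, 5), d(3, 5))))
  expect_equal(inter$n_pairs, 2)
})

test_that("unweighted mean of group means ignores pair counts", {
  rec <- data.frame(group_id = c("A", "B"), d_i = c(100, 300),
                    n_pairs = c(1, 45))
  expect_equal(mean_of_group_means(rec), 200)
  expect_equal(mean_of_group_means(rec[1, ]), 100)
  expect_error(mean_of_group_means(rec[0, ]), "no group")
})

test_that("pair tables enumerate one row per eligible pair per group", {
  lay <- toy_layout()
  col <- toy_collection(list(G1 = c("a1", "a2", "b1"),
                             G2 = c("a1", "a2")))
  tab <- pair_distances(col, lay, "linear", "all")
  # linear distance undefined on inter pairs, so they are excluded
  expect_equal(nrow(tab), 1 + 1)
  expect_equal(sum(tab$group_id == "G1"), 1)
  # the same gene pair in two groups appears once per group
  expect_equal(sum(tab$gene_a == "a1" & tab$gene_b == "a2"), 2)

  # enumeration oracle on the spatial metric, where inter pairs are defined
  map <- toy_map(n = 10, chromosomes = c(5, 5), segment_size = 1e6, seed = 9)
  lay2 <- funcoloc:::new_genome_layout(data.frame(
    gene_id = c("p", "q", "r"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(0.1e6, 1.1e6, 2.1e6), end = c(0.2e6, 1.2e6, 2.2e6),
    stringsAsFactors = FALSE))
  col2 <- toy_collection(list(c("p", "q", "r")))
  tab2 <- pair_distances(col2, lay2, "spatial", "all", map = map,
                         min_overlap = 3)
  expect_equal(nrow(tab2), choose(3, 2))
  expect_setequal(tab2$pair_class[tab2$gene_b == "r" | tab2$gene_a == "r"],
                  "inter")
})

test_that("fast context statistics agree with the public reference functions", {
  cfg <- synthetic_config(n_chromosomes = 3,
                          genes_per_chromosome = c(20, 15, 10),
                          n_groups = 12, seed = 88)
  lay <- generate_genome(cfg)
  col <- generate_groups(lay, cfg, "null")
  map <- generate_contact_map(lay, cfg)
  ctx <- funcoloc:::statistic_context(lay, col, map, min_overlap = 5)
  id <- seq_len(ctx$n)
  v <- funcoloc:::ctx_eval_stats(ctx, id, names(statistic_registry()))

  expect_equal(v[["mean_chrom_count"]], mean_chromosome_count(col, lay))
  expect_equal(v[["single_chrom_enrichment"]],
               chromosome_count_histogram(col, lay)$f[1])
  expect_equal(v[["intra_linear_group_mean"]],
               mean_of_group_means(
                 group_mean_distances(col, lay, "linear", "intra_only")))
  expect_equal(v[["spatial_all_group_mean"]],
               mean_of_group_means(
                 group_mean_distances(col, lay, "spatial", "all", map = map,
                                      min_overlap = 5)))
  expect_equal(v[["spatial_inter_group_mean"]],
               mean_of_group_means(
                 group_mean_distances(col, lay, "spatial", "inter_only",
                                      map = map, min_overlap = 5)))
  expect_equal(v[["spatial_inter_pairs"]],
               mean(pair_distances(col, lay, "spatial", "inter_only",
                                   map = map, min_overlap = 5)$distance))
})

test_that("within-chromosome permutation preserves per-group intra pair counts", {
  cfg <- synthetic_config(n_chromosomes = 2, genes_per_chromosome = 25,
                          n_groups = 10, seed = 19)
  lay <- generate_genome(cfg)
  col <- generate_groups(lay, cfg, "null")
  real <- group_mean_distances(col, lay, "linear", "intra_only")
  for (i in 1:10) {
    perm <- permute_layout(lay, "within_chromosome", seed = 700 + i)
    pr <- group_mean_distances(col, perm, "linear", "intra_only")
    expect_equal(pr$group_id, real$group_id)
    expect_equal(pr$n_pairs, real$n_pairs)
  }
})
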