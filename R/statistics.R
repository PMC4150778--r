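#' @title Concentration statistics on gene groups
#'
#' @description Three families of test statistics, each a pure function of
#' (layout, collection, contact map): chromosome dispersal (how many
#' chromosomes a group's genes occupy), linear intra-chromosomal distance
#' (mean base-pair distance between same-chromosome member pairs), and
#' spatial 1-correlation distance between members' contact-map segments.
#' Groups with no eligible pair under a metric/filter are omitted from the
#' statistic rather than scored with a sentinel.
#'
#' @name concentration_stats
NULL

group_member_rows <- function(layout, members) {
  match(unique(resolve_gene_ids(layout, members)), layout$genes$gene_id)
}

#' Number of chromosomes involved in a group
#'
#' @param group a single group (list with `members`) or a character vector of
#'   gene ids
#' @param layout a `genome_layout`
#' @return count of distinct chromosomes holding at least one mapped member
#' @export
chromosomes_involved <- function(group, layout) {
  members <- if (is.list(group)) group$members else group
  rows <- group_member_rows(layout, members)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0) stop("group has no members mapped to the layout")
  length(unique(layout$genes$chromosome[rows]))
}

#' Mean number of chromosomes involved per group
#'
#' The first dispersal statistic: the average of [chromosomes_involved] over
#' all groups of a collection. Small observed values relative to permuted
#' genomes indicate concentration of groups on few chromosomes
#' (direction `"le"`).
#'
#' @param collection a `group_collection`
#' @param layout a `genome_layout`
#' @return numeric mean
#' @export
mean_chromosome_count <- function(collection, layout) {
  if (n_groups(collection) == 0) stop("empty group collection")
  mean(vapply(collection$groups, chromosomes_involved, 0L, layout = layout))
}

#' Histogram of chromosomes-involved counts
#'
#' `f[i]` is the number of groups whose genes occupy exactly `i`
#' chromosomes; `cumulative[c]` is the number of groups represented on at
#' most `c` chromosomes -- the curve used to display dispersal against the
#' permutation null.
#'
#' @param collection a `group_collection`
#' @param layout a `genome_layout`
#' @return list with `f` and `cumulative`, both indexed 1..C where C is the
#'   number of chromosomes in the layout
#' @export
chromosome_count_histogram <- function(collection, layout) {
  counts <- vapply(collection$groups, chromosomes_involved, 0L,
                   layout = layout)
  C <- length(unique(layout$genes$chromosome))
  f <- tabulate(counts, nbins = C)
  list(f = f, cumulative = cumsum(f))
}

#' Per-group mean pairwise distances
#'
#' For each group, the mean distance `d_i` over its eligible unordered member
#' pairs. With `metric = "linear"` the distance is midpoint base-pair
#' distance (defined only within a chromosome); with `metric = "spatial"` it
#' is the 1-correlation segment distance from a contact map. The pair filter
#' selects which pairs are eligible: `intra_only` (same chromosome),
#' `inter_only` (different chromosomes) or `all`. Pairs with undefined
#' distance are excluded; groups left with no eligible pair are omitted.
#'
#' @param collection a `group_collection`
#' @param layout a `genome_layout`
#' @param metric `"linear"` or `"spatial"`
#' @param pair_filter `"all"`, `"intra_only"` or `"inter_only"`
#' @param map a `contact_map`, required for the spatial metric
#' @param min_overlap spatial distance overlap guard
#' @return data frame with columns `group_id`, `d_i`, `n_pairs`,
#'   `pair_filter`; one row per non-omitted group
#' @export
group_mean_distances <- function(collection, layout,
                                 metric = c("linear", "spatial"),
                                 pair_filter = c("all", "intra_only",
                                                 "inter_only"),
                                 map = NULL, min_overlap = 10) {
  metric <- match.arg(metric)
  pair_filter <- match.arg(pair_filter)
  tab <- pair_distances(collection, layout, metric = metric,
                        pair_filter = pair_filter, map = map,
                        min_overlap = min_overlap)
  if (nrow(tab) == 0) stop("all groups omitted: no eligible pairs under ",
                           metric, "/", pair_filter)
  agg <- stats::aggregate(distance ~ group_id, data = tab,
                          FUN = mean, na.action = stats::na.omit)
  cnt <- stats::aggregate(distance ~ group_id, data = tab, FUN = length)
  out <- data.frame(
    group_id = agg$group_id,
    d_i = agg$distance,
    n_pairs = cnt$distance,
    pair_filter = pair_filter,
    stringsAsFactors = FALSE
  )
  # keep original group order
  ord <- match(vapply(collection$groups, `[[`, "", "group_id"), out$group_id)
  out <- out[ord[!is.na(ord)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean of per-group mean distances
#'
#' The unweighted mean of `d_i` over groups -- every group counts once
#' regardless of its pair count.
#'
#' @param records data frame from [group_mean_distances]
#' @return numeric mean
#' @export
mean_of_group_means <- function(records) {
  if (NROW(records) == 0) stop("no group distance records")
  mean(records$d_i)
}

#' Table of individual pair distances
#'
#' One row per eligible unordered member pair per group; a gene pair shared
#' by several groups appears once per group. Pairs failing the filter or
#' with undefined distance are excluded.
#'
#' @inheritParams group_mean_distances
#' @return data frame with columns `group_id`, `gene_a`, `gene_b`,
#'   `distance`, `pair_class`
#' @export
pair_distances <- function(collection, layout,
                           metric = c("linear", "spatial"),
                           pair_filter = c("all", "intra_only", "inter_only"),
                           map = NULL, min_overlap = 10) {
  metric <- match.arg(metric)
  pair_filter <- match.arg(pair_filter)
  if (metric == "spatial" && is.null(map)) {
    stop("spatial metric requires a contact map")
  }
  genes <- layout$genes
  mids <- gene_midpoints(layout)
  segs <- if (metric == "spatial") genes_to_segments(layout, map) else NULL
  D <- if (metric == "spatial") {
    spatial_distance_matrix(map, min_overlap = min_overlap)
  } else NULL

  rows <- list()
  for (g in collection$groups) {
    idx <- group_member_rows(layout, g$members)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2) next
    pr <- utils::combn(idx, 2)
    for (p in seq_len(ncol(pr))) {
      i <- pr[1, p]; j <- pr[2, p]
      same <- genes$chromosome[i] == genes$chromosome[j]
      cls <- if (same) "intra" else "inter"
      if (pair_filter == "intra_only" && !same) next
      if (pair_filter == "inter_only" && same) next
      d <- if (metric == "linear") {
        if (same) abs(mids[i] - mids[j]) else NA_real_
      } else {
        si <- segs[i]; sj <- segs[j]
        if (is.na(si) || is.na(sj)) NA_real_ else D[si, sj]
      }
      if (is.na(d)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g$group_id,
        gene_a = genes$gene_id[i], gene_b = genes$gene_id[j],
        distance = d, pair_class = cls, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(group_id = character(0), gene_a = character(0),
                      gene_b = character(0), distance = numeric(0),
                      pair_class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Fast evaluation context: precomputes everything that is invariant under
# permutation (loci, group membership indices, flattened pair indices, the
# segment spatial distance matrix) so each replicate costs a handful of
# vectorized operations. Gene g sits at locus pi[g]; the real genome is the
# identity permutation.

statistic_context <- function(layout, collection, map = NULL,
                              min_overlap = 10) {
  genes <- layout$genes
  n <- nrow(genes)
  chrom <- as.integer(factor(genes$chromosome))
  mids <- gene_midpoints(layout)

  gid <- vapply(collection$groups, `[[`, "", "group_id")
  mlist <- lapply(collection$groups, function(g) {
    idx <- group_member_rows(layout, g$members)
    idx[!is.na(idx)]
  })
  keep <- vapply(mlist, length, 0L) >= 2L
  mlist <- mlist[keep]
  gid <- gid[keep]
  if (length(mlist) == 0) stop("no groups with >= 2 mapped members")

  g_of_member <- rep(seq_along(mlist), vapply(mlist, length, 0L))
  midx <- unlist(mlist)
  pairs <- lapply(seq_along(mlist), function(k) {
    p <- utils::combn(mlist[[k]], 2)
    rbind(p, rep(k, ncol(p)))
  })
  pairs <- do.call(cbind, pairs)

  seg <- NULL; D <- NULL
  if (!is.null(map)) {
    seg <- genes_to_segments(layout, map)
    D <- spatial_distance_matrix(map, min_overlap = min_overlap)
  }
  list(
    n = n, n_chrom = max(chrom), chrom = chrom, mids = mids,
    blocks = layout_blocks(layout),
    n_groups = length(mlist), group_ids = gid,
    g_of_member = g_of_member, midx = midx,
    pa = pairs[1, ], pb = pairs[2, ], pg = pairs[3, ],
    seg = seg, D = D
  )
}

# distinct-chromosome count per group under permutation pi
ctx_chrom_counts <- function(ctx, pi) {
  ch <- ctx$chrom[pi[ctx$midx]]
  key <- ctx$g_of_member * (ctx$n_chrom + 1L) + ch
  tabulate(ctx$g_of_member[!duplicated(key)], ctx$n_groups)
}

# per-group mean over masked pair values; NA for groups with no pair
ctx_group_means <- function(ctx, vals, mask) {
  v <- vals[mask]
  g <- ctx$pg[mask]
  cnt <- tabulate(g, ctx$n_groups)
  s <- numeric(ctx$n_groups)
  if (length(v)) {
    rs <- rowsum(v, g)
    s[as.integer(rownames(rs))] <- rs
  }
  out <- s / cnt
  out[cnt == 0] <- NA_real_
  out
}

# per-group d_i for the linear intra-chromosomal metric
ctx_linear_di <- function(ctx, pi) {
  la <- pi[ctx$pa]; lb <- pi[ctx$pb]
  mask <- ctx$chrom[la] == ctx$chrom[lb]
  ctx_group_means(ctx, abs(ctx$mids[la] - ctx$mids[lb]), mask)
}

ctx_spatial_pair_values <- function(ctx, pi) {
  if (is.null(ctx$D)) stop("spatial statistic requires a contact map")
  la <- pi[ctx$pa]; lb <- pi[ctx$pb]
  sa <- ctx$seg[la]; sb <- ctx$seg[lb]
  d <- ifelse(is.na(sa) | is.na(sb), NA_real_, ctx$D[cbind(sa, sb)])
  list(d = d, inter = ctx$chrom[la] != ctx$chrom[lb])
}

mean_defined <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

# evaluate a set of registered statistics for one permutation, computing
# shared intermediates (chromosome counts, spatial pair values) only once
ctx_eval_stats <- function(ctx, pi, stats) {
  out <- stats::setNames(numeric(length(stats)), stats)
  need_counts <- any(stats %in% c("mean_chrom_count",
                                  "single_chrom_enrichment"))
  need_spatial <- any(grepl("^spatial", stats))
  if (need_counts) counts <- ctx_chrom_counts(ctx, pi)
  if (need_spatial) sp <- ctx_spatial_pair_values(ctx, pi)
  for (s in stats) {
    out[s] <- switch(s,
      mean_chrom_count = mean(counts),
      single_chrom_enrichment = sum(counts == 1L),
      intra_linear_group_mean = mean_defined(ctx_linear_di(ctx, pi)),
      spatial_all_group_mean =
        mean_defined(ctx_group_means(ctx, sp$d, !is.na(sp$d))),
      spatial_inter_group_mean =
        mean_defined(ctx_group_means(ctx, sp$d, sp$inter & !is.na(sp$d))),
      spatial_inter_pairs = mean_defined(sp$d[sp$inter])
    )
  }
  out
}

#' The statistic registry
#'
#' Named scalar statistics usable with [run_permutation_test] and
#' [run_test_battery], with their default extremeness direction:
#' \describe{
#'   \item{mean_chrom_count}{mean chromosomes involved per group (`le`)}
#'   \item{single_chrom_enrichment}{number of groups confined to one
#'     chromosome (`ge`)}
#'   \item{intra_linear_group_mean}{mean over groups of mean linear
#'     same-chromosome pair distance (`le`)}
#'   \item{spatial_all_group_mean}{mean over groups of mean spatial distance,
#'     all pairs (`le`)}
#'   \item{spatial_inter_group_mean}{as above, inter-chromosomal pairs
#'     only (`le`)}
#'   \item{spatial_inter_pairs}{mean spatial distance over individual
#'     inter-chromosomal pairs, pooled across groups (`le`)}
#' }
#'
#' @return named list; each entry has `fun(ctx, pi)` and `direction`
#' @export
statistic_registry <- function() {
  list(
    mean_chrom_count = list(
      direction = "le",
      fun = function(ctx, pi) mean(ctx_chrom_counts(ctx, pi))
    ),
    single_chrom_enrichment = list(
      direction = "ge",
      fun = function(ctx, pi) sum(ctx_chrom_counts(ctx, pi) == 1L)
    ),
    intra_linear_group_mean = list(
      direction = "le",
      fun = function(ctx, pi) mean_defined(ctx_linear_di(ctx, pi))
    ),
    spatial_all_group_mean = list(
      direction = "le",
      fun = function(ctx, pi) {
        sp <- ctx_spatial_pair_values(ctx, pi)
        mean_defined(ctx_group_means(ctx, sp$d, !is.na(sp$d)))
      }
    ),
    spatial_inter_group_mean = list(
      direction = "le",
      fun = function(ctx, pi) {
        sp <- ctx_spatial_pair_values(ctx, pi)
        mean_defined(ctx_group_means(ctx, sp$d, sp$inter & !is.na(sp$d)))
      }
    ),
    spatial_inter_pairs = list(
      direction = "le",
      fun = function(ctx, pi) {
        sp <- ctx_spatial_pair_values(ctx, pi)
        mean_defined(sp$d[sp$inter])
      }
    )
  )
}
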