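#' @title Distribution tail test
#'
#' @description A sensitive alternative to moment statistics when the signal
#' lives in the tail of a value distribution (the closest pairs, the most
#' concentrated groups). Real values are partitioned into k equal-occupancy
#' bins by their own quantile thresholds; the same thresholds then bin the
#' values from each permuted genome. For each prefix length j the cumulative
#' count F_j = f_1 + ... + f_j of the real genome is compared with the
#' permutation replicates by empirical p-value, and the minimal j whose
#' Bonferroni-corrected p-value (j * p_j) clears alpha is reported.
#'
#' @name tail_test
NULL

#' Equal-occupancy bin thresholds
#'
#' Thresholds `t_0 < t_1 < ... < t_k` such that each bin `(t_{i-1}, t_i]`
#' (first bin `[t_0, t_1]`) holds as close to `1/k` of the real values as
#' ties permit. `t_i` is the `i/k` empirical quantile taken as an order
#' statistic (inverse ECDF, quantile type 1): with n distinct values,
#' `t_i` is the `ceiling(i*n/k)`-th smallest value, so the cumulative count
#' at `t_i` is exactly that order index. `t_0` is the lower bound of the
#' value domain (0 for distances).
#'
#' @param real_values numeric vector (length >= k)
#' @param k number of bins (default 20)
#' @param lower_bound domain minimum used as `t_0`
#' @return object of class `bin_thresholds`: list with `k`, `thresholds`
#' @export
quantile_thresholds <- function(real_values, k = 20, lower_bound = 0) {
  real_values <- real_values[!is.na(real_values)]
  if (length(real_values) < k) {
    stop("need at least k = ", k, " values to form ", k, " bins")
  }
  if (any(real_values < lower_bound)) {
    stop("values below the stated lower bound ", lower_bound)
  }
  q <- stats::quantile(real_values, probs = seq_len(k) / k, type = 1,
                       names = FALSE)
  thresholds <- c(lower_bound, q)
  if (any(diff(thresholds) <= 0)) {
    # heavy ties (common for segment-level spatial distances, where many
    # gene pairs share one segment pair) collapse adjacent quantiles; merge
    # the tied thresholds into fewer, wider bins instead of failing
    merged <- unique(thresholds)
    warning(sprintf(
      "ties collapse %d of %d quantile thresholds; using %d bins",
      length(thresholds) - length(merged), k, length(merged) - 1))
    thresholds <- merged
    k <- length(thresholds) - 1
    if (k < 1) stop("all values equal the lower bound; no bins can be formed")
  }
  structure(list(k = k, thresholds = thresholds), class = "bin_thresholds")
}

#' Cumulative prefix bin counts
#'
#' `F_j` counts values in bins 1..j, i.e. values in `[t_0, t_j]`. Values
#' above `t_k` fall in an overflow bin and are counted in no prefix; for
#' replicate genomes this deflates every replicate `F_j`, which is the
#' conservative direction for an enrichment test. Values below `t_0` cannot
#' occur for distances and are likewise left uncounted.
#'
#' @param values numeric vector (possibly empty; `NA` ignored)
#' @param thresholds a `bin_thresholds`
#' @return integer vector `F_1..F_k`, non-decreasing
#' @export
bin_count_prefixes <- function(values, thresholds) {
  stopifnot(inherits(thresholds, "bin_thresholds"))
  values <- values[!is.na(values)]
  t <- thresholds$thresholds
  vapply(seq_len(thresholds$k),
         function(j) sum(values >= t[1] & values <= t[j + 1]), 0L)
}

#' Lexicographic extremeness of prefix vectors
#'
#' Alternative extremeness order for the tail test: a replicate counts as
#' "at least as extreme" as the real genome iff its prefix-count vector
#' `(F_1, ..., F_k)` is greater than or equal to the real vector in
#' lexicographic order. This refines the single-prefix comparison when many
#' replicates tie with the real genome on the first bins.
#'
#' @param real_prefix integer vector `F_1..F_k` of the real genome
#' @param replicate_prefixes matrix with one replicate per row (k columns),
#'   or a single vector
#' @return logical vector: is each replicate lexicographically >= real?
#' @export
lexicographic_refinement <- function(real_prefix, replicate_prefixes) {
  if (is.vector(replicate_prefixes)) {
    replicate_prefixes <- matrix(replicate_prefixes, nrow = 1)
  }
  stopifnot(ncol(replicate_prefixes) == length(real_prefix))
  apply(replicate_prefixes, 1, function(v) {
    diff <- v - real_prefix
    nz <- which(diff != 0)
    if (length(nz) == 0) TRUE else diff[nz[1]] > 0
  })
}

#' The distribution tail test
#'
#' Bins the real values by their own equal-occupancy thresholds (or by
#' thresholds supplied explicitly, e.g. integer chromosome counts), bins each
#' replicate value set by the same thresholds, and tests every cumulative
#' prefix `F_j` for enrichment. The minimal significant prefix `j*` is the
#' smallest `j` with `j * p_j <= alpha`; its corrected p-value is `j* * p_j*`
#' capped at 1. The full prefix p-value vector is retained so significance
#' over ranges of bins can be reported.
#'
#' @param real_values numeric vector of real-genome values
#' @param replicate_value_sets list of numeric vectors, one per permuted
#'   genome, produced under the appropriate permutation scheme
#' @param k number of bins (ignored when `thresholds` given)
#' @param alpha significance level for the minimal-j search
#' @param thresholds optional `bin_thresholds` overriding the quantile
#'   construction
#' @param lexicographic also compute the lexicographic-order p-value
#' @param lower_bound passed to [quantile_thresholds]
#' @param seed recorded for provenance
#' @return a `tail_test` object: `thresholds`, `real_prefix` (F_1..F_k),
#'   `replicate_prefix` (n x k matrix), `p_j` (raw prefix p-values),
#'   `j_star` (NA if none), `p_corrected`, `n`, `alpha`, `p_lex` (optional)
#' @export
distribution_tail_test <- function(real_values, replicate_value_sets,
                                   k = 20, alpha = 0.05, thresholds = NULL,
                                   lexicographic = FALSE, lower_bound = 0,
                                   seed = NA_integer_) {
  if (is.null(thresholds)) {
    thresholds <- quantile_thresholds(real_values, k = k,
                                      lower_bound = lower_bound)
  }
  k <- thresholds$k
  n <- length(replicate_value_sets)
  if (n < 1) stop("no replicate value sets")

  real_prefix <- bin_count_prefixes(real_values, thresholds)
  rep_prefix <- t(vapply(replicate_value_sets, bin_count_prefixes,
                         integer(k), thresholds = thresholds))
  if (k == 1) rep_prefix <- matrix(rep_prefix, ncol = 1)

  p_j <- vapply(seq_len(k), function(j) {
    empirical_p(real_prefix[j], rep_prefix[, j], "ge")$p_value
  }, 0)
  corrected <- bonferroni(p_j, seq_len(k))
  hits <- which(corrected <= alpha)
  j_star <- if (length(hits)) hits[1] else NA_integer_

  out <- structure(
    list(thresholds = thresholds, real_prefix = real_prefix,
         replicate_prefix = rep_prefix, p_j = p_j,
         p_j_corrected = corrected,
         j_star = j_star,
         p_corrected = if (is.na(j_star)) NA_real_ else corrected[j_star],
         n = n, alpha = alpha, seed = seed),
    class = "tail_test"
  )
  if (lexicographic) {
    extreme <- lexicographic_refinement(real_prefix, rep_prefix)
    out$p_lex <- (sum(extreme) + 1) / (n + 1)
  }
  out
}

#' @export
print.tail_test <- function(x, ...) {
  cat(sprintf("<tail_test> k=%d bins, n=%d replicates\n",
              x$thresholds$k, x$n))
  if (is.na(x$j_star)) {
    cat(sprintf("  no significant prefix at alpha=%g\n", x$alpha))
  } else {
    cat(sprintf("  minimal significant prefix j*=%d, corrected p=%.3g\n",
                x$j_star, x$p_corrected))
  }
  if (!is.null(x$p_lex)) cat(sprintf("  lexicographic p=%.3g\n", x$p_lex))
  invisible(x)
}

#' Run a permutation tail test on a per-group or per-pair value function
#'
#' Computes the real value vector, draws `n` permuted layouts under the
#' scheme (sharing the seed-derivation rule of [run_permutation_test]),
#' recomputes the values on each, and applies [distribution_tail_test].
#' Available value functions: `"chrom_counts"` (chromosomes involved per
#' group; binned by integer thresholds 0..C), `"linear_di"` (per-group mean
#' linear intra-chromosomal distance), `"spatial_inter_pairs"` (individual
#' inter-chromosomal pair spatial distances).
#'
#' @param layout a `genome_layout`
#' @param collection a restricted `group_collection`
#' @param values one of `"chrom_counts"`, `"linear_di"`,
#'   `"spatial_inter_pairs"`
#' @param scheme permutation scheme
#' @param n replicate count
#' @param k bin count (quantile bins; ignored for `chrom_counts`)
#' @param alpha significance level
#' @param seed base seed
#' @param map optional `contact_map`
#' @param min_overlap spatial overlap guard
#' @param lexicographic also compute the lexicographic p-value
#' @return a `tail_test` object
#' @export
run_tail_test <- function(layout, collection,
                          values = c("chrom_counts", "linear_di",
                                     "spatial_inter_pairs"),
                          scheme = c("within_chromosome", "global"),
                          n = 999, k = 20, alpha = 0.05, seed = 1,
                          map = NULL, min_overlap = 10,
                          lexicographic = FALSE) {
  values <- match.arg(values)
  scheme <- match.arg(scheme)
  ctx <- statistic_context(layout, collection, map, min_overlap = min_overlap)

  value_fun <- switch(values,
    chrom_counts = function(pi) ctx_chrom_counts(ctx, pi),
    linear_di = function(pi) {
      d <- ctx_linear_di(ctx, pi)
      d[!is.na(d)]
    },
    spatial_inter_pairs = function(pi) {
      sp <- ctx_spatial_pair_values(ctx, pi)
      sp$d[sp$inter & !is.na(sp$d)]
    }
  )

  id <- seq_len(ctx$n)
  real <- value_fun(id)
  if (length(real) == 0) stop("tail test value function '", values,
                              "' yields no values on the real layout")
  thresholds <- if (values == "chrom_counts") {
    structure(list(k = ctx$n_chrom,
                   thresholds = as.numeric(0:ctx$n_chrom)),
              class = "bin_thresholds")
  } else NULL

  reps <- vector("list", n)
  for (r in seq_len(n)) {
    set.seed(replicate_seed(seed, r))
    pi <- draw_permutation(ctx$n, ctx$blocks, scheme)
    reps[[r]] <- value_fun(pi)
  }
  out <- distribution_tail_test(real, reps, k = k, alpha = alpha,
                                thresholds = thresholds,
                                lexicographic = lexicographic, seed = seed)
  out$values <- values
  out$scheme <- scheme
  out
}
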