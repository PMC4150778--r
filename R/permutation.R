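#' @title Permutation null models and empirical p-values
#'
#' @description The null model fixes everything about the genome except gene
#' order: genes are reassigned uniformly at random to the loci occupied in
#' the real genome, so the locus multiset and the per-chromosome gene counts
#' never change, and group composition is untouched. Two schemes are
#' available: `global` shuffles gene labels over all loci genome-wide;
#' `within_chromosome` shuffles independently inside each chromosome, so
#' every gene additionally keeps its chromosome. The second scheme is the
#' right control when chromosome-level concentration has already been
#' established and only the arrangement along chromosomes is in question.
#'
#' @name permutation_testing
NULL

PERMUTATION_SCHEMES <- c("global", "within_chromosome")

# chromosome block index list for a layout (genes sorted by chromosome)
layout_blocks <- function(layout) {
  split(seq_len(nrow(layout$genes)), layout$genes$chromosome)
}

# draw a permutation vector: gene g moves to locus pi[g]
draw_permutation <- function(n, blocks, scheme) {
  if (scheme == "global") {
    sample.int(n)
  } else {
    pi <- integer(n)
    for (b in blocks) {
      pi[b] <- if (length(b) == 1L) b else b[sample.int(length(b))]
    }
    pi
  }
}

#' Permute gene locations in a layout
#'
#' Returns a new layout in which gene identifiers are reassigned uniformly at
#' random to the fixed loci under the chosen scheme. The input layout is
#' untouched; the sorted multiset of (chromosome, start, end) loci is
#' identical before and after.
#'
#' @param layout a `genome_layout`
#' @param scheme `"global"` or `"within_chromosome"`
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a `genome_layout`
#' @export
permute_layout <- function(layout, scheme = c("global", "within_chromosome"),
                           seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(layout$genes)
  pi <- draw_permutation(n, layout_blocks(layout), scheme)
  apply_permutation(layout, pi)
}

# gene g takes over locus pi[g]: locus pi[g] gets gene g's identifier
apply_permutation <- function(layout, pi) {
  genes <- layout$genes
  genes$gene_id[pi] <- layout$genes$gene_id
  new_genome_layout(genes, layout$aliases)
}

#' Empirical p-value from permutation replicates
#'
#' `p = (k + 1) / (n + 1)` where `k` counts replicates at least as extreme as
#' the observed statistic `v0` -- `v >= v0` for direction `"ge"`, `v <= v0`
#' for `"le"`; ties count toward `k`. The +1 correction counts the observed
#' genome among the permutations, giving a valid p-value with floor
#' `1/(n + 1)`.
#'
#' @param v0 observed statistic
#' @param replicates numeric vector of replicate statistics (length n >= 1)
#' @param direction `"ge"` when large values are extreme, `"le"` when small
#'   values are
#' @param seed optional seed recorded for provenance
#' @return an `empirical_test` object with fields `v0`, `replicates`, `k`,
#'   `n`, `direction`, `p_value`, `seed`
#' @export
empirical_p <- function(v0, replicates, direction = c("ge", "le"),
                        seed = NA_integer_) {
  direction <- match.arg(direction)
  if (length(replicates) < 1L) stop("empirical_p: no replicates")
  if (is.na(v0)) stop("empirical_p: observed statistic is NA")
  k <- if (direction == "ge") sum(replicates >= v0, na.rm = TRUE)
       else sum(replicates <= v0, na.rm = TRUE)
  n <- length(replicates)
  structure(
    list(v0 = v0, replicates = replicates, k = k, n = n,
         direction = direction, p_value = (k + 1) / (n + 1), seed = seed),
    class = "empirical_test"
  )
}

#' @export
print.empirical_test <- function(x, ...) {
  cat(sprintf("<empirical_test> v0=%.6g, n=%d, direction=%s, p=%.3g\n",
              x$v0, x$n, x$direction, x$p_value))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p p-value(s)
#' @param m number of tests (>= 1)
#' @return `min(1, m * p)`, vectorized over `p`
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

# deterministic per-replicate seed stream: results do not depend on the
# order replicates are evaluated in
replicate_seed <- function(seed, r) {
  (as.numeric(seed) + r * 48271) %% 2147483647
}

#' Run a permutation test
#'
#' Computes the observed statistic on the real layout, then `n` replicate
#' values on independently permuted layouts, and converts them to an
#' empirical p-value. Statistics may be given by registry name (see
#' [statistic_registry]), which uses a fast vectorized evaluation path, or as
#' a function `function(layout, collection, map)` returning a scalar.
#' Fully reproducible from `seed`; replicate r draws from a seed derived
#' deterministically from (`seed`, r), so both paths produce identical
#' permutations.
#'
#' @param layout a `genome_layout`
#' @param collection a `group_collection` (already restricted to the layout)
#' @param statistic registry name or function
#' @param scheme permutation scheme
#' @param n number of replicates
#' @param direction `"ge"` or `"le"` (defaults to the registry direction for
#'   named statistics)
#' @param seed integer base seed
#' @param map optional `contact_map` for spatial statistics
#' @param min_overlap passed to the spatial distance computation
#' @return an `empirical_test`
#' @export
run_permutation_test <- function(layout, collection, statistic,
                                 scheme = c("global", "within_chromosome"),
                                 n = 999, direction = NULL, seed = 1,
                                 map = NULL, min_overlap = 10) {
  scheme <- match.arg(scheme)
  if (is.character(statistic)) {
    res <- run_test_battery(layout, collection, statistic, scheme = scheme,
                            n = n, directions = direction, seed = seed,
                            map = map, min_overlap = min_overlap)
    return(res[[1]])
  }
  if (is.null(direction)) stop("direction must be given for function statistics")
  v0 <- statistic(layout, collection, map)
  if (is.na(v0)) stop("statistic undefined on the real layout")
  reps <- numeric(n)
  for (r in seq_len(n)) {
    set.seed(replicate_seed(seed, r))
    perm <- permute_layout(layout, scheme)
    reps[r] <- statistic(perm, collection, map)
  }
  empirical_p(v0, reps, direction, seed = seed)
}

#' Run several statistics on shared permutations
#'
#' Evaluates a battery of registered statistics on one stream of permuted
#' layouts, sharing every permutation draw across statistics. Each
#' statistic's p-value is marginally identical to running it alone with the
#' same seed.
#'
#' @param layout,collection,scheme,n,seed,map,min_overlap as in
#'   [run_permutation_test]
#' @param statistics character vector of registry names
#' @param directions optional character vector overriding registry directions
#' @return named list of `empirical_test` objects
#' @export
run_test_battery <- function(layout, collection, statistics,
                             scheme = c("global", "within_chromosome"),
                             n = 999, directions = NULL, seed = 1,
                             map = NULL, min_overlap = 10) {
  scheme <- match.arg(scheme)
  reg <- statistic_registry()
  unknown <- setdiff(statistics, names(reg))
  if (length(unknown)) stop("unknown statistic(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(directions)) {
    directions <- vapply(reg[statistics], `[[`, "", "direction")
  }
  ctx <- statistic_context(layout, collection, map, min_overlap = min_overlap)

  id <- seq_len(ctx$n)
  v0 <- ctx_eval_stats(ctx, id, statistics)
  bad <- names(v0)[is.na(v0)]
  if (length(bad)) {
    stop("statistic undefined on the real layout: ",
         paste(bad, collapse = ", "))
  }
  reps <- matrix(NA_real_, n, length(statistics))
  for (r in seq_len(n)) {
    set.seed(replicate_seed(seed, r))
    pi <- draw_permutation(ctx$n, ctx$blocks, scheme)
    reps[r, ] <- ctx_eval_stats(ctx, pi, statistics)
  }
  out <- vector("list", length(statistics))
  names(out) <- statistics
  for (s in seq_along(statistics)) {
    out[[s]] <- empirical_p(unname(v0[s]), reps[, s], directions[s],
                            seed = seed)
    out[[s]]$statistic <- statistics[s]
    out[[s]]$scheme <- scheme
  }
  out
}
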