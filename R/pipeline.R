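#' @title End-to-end analysis pipeline
#'
#' @description Orchestrates the full battery of concentration tests on one
#' genome and one or more group collections: chromosome dispersal (mean
#' chromosomes-involved, global permutations; single-chromosome and
#' at-most-c enrichment via the tail test on integer chromosome counts),
#' linear intra-chromosomal concentration (group-mean distance and 20-bin
#' tail test, within-chromosome permutations), and spatial concentration
#' from a contact map (all-pairs group mean with global permutations;
#' inter-chromosomal-only group mean and individual-pair tail test with
#' within-chromosome permutations, which holds each group's inter-pair count
#' fixed in the null).
#'
#' @name pipeline
NULL

#' Build an analysis configuration
#'
#' @param genome path to the gene position file
#' @param genome_format `"bed"` or `"tsv"`
#' @param families optional path to the gene-family TSV (enables tandem
#'   duplicate merging)
#' @param groups list of lists, each with `path`, `format`
#'   (`"pairs"`/`"gmt"`) and `type` (`"ppi"`/`"complex"`/`"pathway"`)
#' @param contact_map optional path to a contact map
#' @param contact_map_format `"dense_tsv"` or `"coo_tsv"`
#' @param segment_size contact-map segment size in bases
#' @param tests which tests to run (subset of `inter_mean`, `inter_tail`,
#'   `intra_mean`, `intra_tail`, `spatial_all_mean`, `spatial_inter_mean`,
#'   `spatial_inter_tail`); spatial tests require a contact map
#' @param n_permutations replicates per test
#' @param k_bins tail-test bin count
#' @param alpha significance level for minimal-j searches
#' @param min_overlap spatial correlation overlap guard
#' @param seed global seed
#' @param out_dir optional directory; when set, [run_analysis] writes report
#'   files there
#' @return an `analysis_config` list
#' @export
analysis_config <- function(genome, genome_format = "bed", families = NULL,
                            groups = list(), contact_map = NULL,
                            contact_map_format = "dense_tsv",
                            segment_size = NULL,
                            tests = c("inter_mean", "inter_tail",
                                      "intra_mean", "intra_tail",
                                      "spatial_all_mean",
                                      "spatial_inter_mean",
                                      "spatial_inter_tail"),
                            n_permutations = 999, k_bins = 20, alpha = 0.05,
                            min_overlap = 10, seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  spatial <- grepl("^spatial", tests)
  if (any(spatial) && is.null(contact_map)) {
    cfg$tests <- tests[!spatial]
    message("no contact map supplied; spatial tests skipped")
  }
  if (!is.null(contact_map) && is.null(segment_size)) {
    stop("segment_size is required with a contact map")
  }
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path
#' @return an `analysis_config`
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  y$genome <- rel(y$genome)
  y$families <- rel(y$families)
  y$contact_map <- rel(y$contact_map)
  if (!is.null(y$groups)) {
    y$groups <- lapply(y$groups, function(g) { g$path <- rel(g$path); g })
  }
  do.call(analysis_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis
#'
#' Loads inputs, merges tandem duplicates when a family table is given,
#' restricts each collection to the layout, runs the selected tests per
#' collection, and assembles (and optionally writes) the report, including
#' the per-group table.
#'
#' @param config an `analysis_config`
#' @return an `analysis_report`: list with `tests` (per type, per test),
#'   `per_group` (data frame), `summaries`, `seed`, `config`
#' @export
run_analysis <- function(config) {
  layout <- stage("load_genome",
                  load_gene_positions(config$genome, config$genome_format))
  if (!is.null(config$families)) {
    fams <- stage("load_families", load_gene_families(config$families))
    layout <- stage("merge_tandem", merge_tandem_duplicates(layout, fams))
  }
  map <- NULL
  if (!is.null(config$contact_map)) {
    map <- stage("load_contact_map",
                 load_contact_map(config$contact_map,
                                  config$contact_map_format,
                                  config$segment_size))
  }
  collections <- stage("load_groups", lapply(config$groups, function(g) {
    restrict_to_layout(load_groups(g$path, g$format, g$type), layout)
  }))
  names(collections) <- vapply(config$groups, `[[`, "", "type")

  n <- config$n_permutations
  alpha <- config$alpha
  k <- config$k_bins
  results <- list()
  for (type in names(collections)) {
    col <- collections[[type]]
    res <- list()
    t <- config$tests
    glob <- intersect(
      c(if ("inter_mean" %in% t) "mean_chrom_count",
        if ("spatial_all_mean" %in% t) "spatial_all_group_mean"),
      names(statistic_registry()))
    within <- intersect(
      c(if ("intra_mean" %in% t) "intra_linear_group_mean",
        if ("spatial_inter_mean" %in% t) "spatial_inter_group_mean"),
      names(statistic_registry()))
    if (length(glob)) {
      res <- c(res, stage(paste0(type, ":global_battery"),
        run_test_battery(layout, col, glob, scheme = "global", n = n,
                         seed = config$seed, map = map,
                         min_overlap = config$min_overlap)))
    }
    if (length(within)) {
      res <- c(res, stage(paste0(type, ":within_battery"),
        run_test_battery(layout, col, within, scheme = "within_chromosome",
                         n = n, seed = config$seed, map = map,
                         min_overlap = config$min_overlap)))
    }
    if ("inter_tail" %in% t) {
      res$inter_tail <- stage(paste0(type, ":inter_tail"),
        run_tail_test(layout, col, "chrom_counts", scheme = "global",
                      n = n, alpha = alpha, seed = config$seed))
    }
    if ("intra_tail" %in% t) {
      res$intra_tail <- stage(paste0(type, ":intra_tail"),
        run_tail_test(layout, col, "linear_di",
                      scheme = "within_chromosome", n = n, k = k,
                      alpha = alpha, seed = config$seed))
    }
    if ("spatial_inter_tail" %in% t && !is.null(map)) {
      res$spatial_inter_tail <- stage(paste0(type, ":spatial_inter_tail"),
        run_tail_test(layout, col, "spatial_inter_pairs",
                      scheme = "within_chromosome", n = n, k = k,
                      alpha = alpha, seed = config$seed, map = map,
                      min_overlap = config$min_overlap))
    }
    results[[type]] <- res
  }

  report <- structure(
    list(
      tests = results,
      per_group = per_group_report(layout, collections, map,
                                   min_overlap = config$min_overlap),
      summaries = lapply(collections, summarize_groups),
      layout_n_genes = nrow(layout$genes),
      seed = config$seed,
      n_permutations = n,
      config = config
    ),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Per-group results table
#'
#' One row per group with its three per-group quantities: chromosomes
#' involved, mean linear intra-chromosomal distance, and mean spatial
#' distance (all pairs and inter-chromosomal only). Undefined quantities
#' (e.g. linear distance for a group with no same-chromosome pair) are `NA`,
#' never zero.
#'
#' @param layout a `genome_layout`
#' @param collections named list of restricted `group_collection`s
#' @param map optional `contact_map`
#' @param min_overlap spatial overlap guard
#' @return data frame
#' @export
per_group_report <- function(layout, collections, map = NULL,
                             min_overlap = 10) {
  rows <- list()
  for (type in names(collections)) {
    col <- collections[[type]]
    if (n_groups(col) == 0) next
    ids <- vapply(col$groups, `[[`, "", "group_id")
    sizes <- group_sizes(col)
    chroms <- vapply(col$groups, chromosomes_involved, 0L, layout = layout)

    lin <- tryCatch(
      group_mean_distances(col, layout, "linear", "intra_only"),
      error = function(e) NULL)
    spa <- spi <- NULL
    if (!is.null(map)) {
      spa <- tryCatch(
        group_mean_distances(col, layout, "spatial", "all", map = map,
                             min_overlap = min_overlap),
        error = function(e) NULL)
      spi <- tryCatch(
        group_mean_distances(col, layout, "spatial", "inter_only", map = map,
                             min_overlap = min_overlap),
        error = function(e) NULL)
    }
    pick <- function(tab, id) {
      if (is.null(tab)) NA_real_
      else { i <- match(id, tab$group_id); if (is.na(i)) NA_real_ else tab$d_i[i] }
    }
    rows[[type]] <- data.frame(
      group_type = type,
      group_id = ids,
      n_members = sizes,
      chromosomes_involved = chroms,
      d_linear = vapply(ids, pick, 0, tab = lin),
      d_spatial_all = vapply(ids, pick, 0, tab = spa),
      d_spatial_inter = vapply(ids, pick, 0, tab = spi),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(group_type = character(0), group_id = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an analysis report to disk
#'
#' Emits `per_group.tsv`, `tests.tsv` (one row per type x test with observed
#' statistic and p-values) and `summary.json`. Output is byte-identical for
#' identical config and seed.
#'
#' @param report an `analysis_report`
#' @param out_dir output directory (created if needed)
#' @return invisible vector of file paths
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  pg <- file.path(out_dir, "per_group.tsv")
  utils::write.table(report$per_group, pg, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  rows <- list()
  json <- list()
  for (type in names(report$tests)) {
    for (test in names(report$tests[[type]])) {
      r <- report$tests[[type]][[test]]
      if (inherits(r, "empirical_test")) {
        rows[[length(rows) + 1L]] <- data.frame(
          group_type = type, test = test, kind = "scalar",
          statistic = r$v0, p_value = r$p_value,
          p_corrected = NA_real_, j_star = NA_integer_,
          n = r$n, scheme = r$scheme %||% NA_character_,
          seed = r$seed, stringsAsFactors = FALSE)
        json[[type]][[test]] <- list(v0 = r$v0, p = r$p_value, n = r$n)
      } else if (inherits(r, "tail_test")) {
        rows[[length(rows) + 1L]] <- data.frame(
          group_type = type, test = test, kind = "tail",
          statistic = r$real_prefix[max(1, r$j_star, na.rm = TRUE)],
          p_value = if (is.na(r$j_star)) min(r$p_j) else r$p_j[r$j_star],
          p_corrected = r$p_corrected, j_star = r$j_star,
          n = r$n, scheme = r$scheme %||% NA_character_,
          seed = r$seed, stringsAsFactors = FALSE)
        json[[type]][[test]] <- list(
          j_star = r$j_star, p_corrected = r$p_corrected,
          prefix_p = r$p_j, real_prefix = r$real_prefix, n = r$n)
      }
    }
  }
  tt <- file.path(out_dir, "tests.tsv")
  utils::write.table(do.call(rbind, rows), tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(seed = report$seed, n_permutations = report$n_permutations,
         n_genes = report$layout_n_genes,
         collections = lapply(report$summaries, function(s) as.list(s)),
         tests = json),
    sj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(per_group = pg, tests = tt, summary = sj))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete fixture bundle
#'
#' Convenience wrapper chaining the synthetic generators: genome, families,
#' one collection per requested mode, contact map with planted pairs, all
#' written to `out_dir`.
#'
#' @param config a `synthetic_config`
#' @param out_dir output directory
#' @param modes group generation modes (one collection per mode)
#' @param n_planted_pairs planted inter-chromosomal segment pairs
#' @return list with the generated objects and `paths`
#' @export
simulate_bundle <- function(config, out_dir,
                            modes = "null", n_planted_pairs = 0) {
  layout <- generate_genome(config)
  families <- generate_families(layout, config)
  base_map <- generate_contact_map(layout, config)
  planted <- NULL
  map <- base_map
  if (n_planted_pairs > 0) {
    planted <- sample_planted_pairs(layout, base_map, n_planted_pairs,
                                    seed = config$seed + 4)
    map <- generate_contact_map(layout, config, planted_pairs = planted)
  }
  collections <- lapply(modes, function(m) {
    generate_groups(layout, config, mode = m,
                    group_type = if (m == "spatial_colocalized") "ppi"
                                 else "pathway",
                    planted_pairs = planted, map = map)
  })
  paths <- write_fixture_bundle(layout, families, collections, map, out_dir)
  list(layout = layout, families = families, collections = collections,
       map = map, planted_pairs = planted, paths = paths)
}
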