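#' @title Synthetic genomes, groups and contact maps with planted signal
#'
#' @description Generators for every input the pipeline consumes, with
#' tunable planted structure so calibration (no signal) and power (strong
#' signal) are both testable against ground truth. Gene layouts draw gene
#' lengths and intergenic gaps from exponential distributions, so chromosome
#' lengths and gene densities vary as they do across real chromosomes.
#' Group collections are sampled under a null mode or with planted
#' chromosome concentration, linear clustering, or spatial co-localization.
#' Contact maps combine intra-chromosomal distance decay, a weak
#' inter-chromosomal background, optional noise, and planted correlated
#' segment pairs.
#'
#' @name synthetic_data
NULL

#' Synthetic data configuration
#'
#' @param n_chromosomes number of chromosomes
#' @param genes_per_chromosome genes per chromosome (scalar or vector)
#' @param gene_length_mean mean gene length in bases (exponential draw,
#'   floor 200)
#' @param gap_mean mean intergenic gap in bases (exponential draw)
#' @param n_groups number of groups per collection
#' @param group_size_lambda group sizes are `2 + Poisson(lambda)`
#' @param rho clustering strength in [0, 1]: probability a member is placed
#'   near the group anchor (its chromosome, window or planted segment)
#'   rather than uniformly
#' @param sigma spatial co-localization strength in [0, 1] of planted
#'   contact-map segment pairs
#' @param decay_exponent intra-chromosomal contact decay exponent alpha:
#'   expected contact between segments at ordinal distance d is
#'   `(1 + d)^(-alpha)`
#' @param inter_background expected inter-chromosomal contact level
#' @param noise additive half-normal noise scale on contact entries
#' @param cluster_window linear-clustering window as a fraction of
#'   chromosome length
#' @param segment_size contact-map segment size in bases
#' @param tandem_runs planted tandem-duplicate runs per chromosome in the
#'   family table
#' @param seed base RNG seed; generators derive their own sub-streams
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_chromosomes = 2,
                             genes_per_chromosome = 100,
                             gene_length_mean = 10000,
                             gap_mean = 40000,
                             n_groups = 50,
                             group_size_lambda = 2,
                             rho = 0,
                             sigma = 0,
                             decay_exponent = 1,
                             inter_background = 0.05,
                             noise = 0.1,
                             cluster_window = 0.05,
                             segment_size = 100000,
                             tandem_runs = 0,
                             seed = 1) {
  stopifnot(rho >= 0, rho <= 1, sigma >= 0, sigma <= 1,
            n_chromosomes >= 1, all(genes_per_chromosome >= 1))
  if (length(genes_per_chromosome) == 1) {
    genes_per_chromosome <- rep(genes_per_chromosome, n_chromosomes)
  }
  stopifnot(length(genes_per_chromosome) == n_chromosomes)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic genome layout
#'
#' Per chromosome, gene lengths and intergenic gaps are drawn from
#' exponential distributions and laid end to end, giving strictly increasing
#' non-overlapping genes and an emergent chromosome length. Deterministic
#' under the seed.
#'
#' @param config a `synthetic_config`
#' @param seed override of `config$seed`
#' @return a `genome_layout` with gene ids `g<chrom>_<index>`
#' @export
generate_genome <- function(config, seed = config$seed) {
  set.seed(seed)
  rows <- list()
  for (c in seq_len(config$n_chromosomes)) {
    ng <- config$genes_per_chromosome[c]
    lens <- pmax(200, round(stats::rexp(ng, 1 / config$gene_length_mean)))
    gaps <- pmax(1, round(stats::rexp(ng, 1 / config$gap_mean)))
    starts <- cumsum(gaps) + c(0, cumsum(lens))[seq_len(ng)]
    rows[[c]] <- data.frame(
      gene_id = sprintf("g%d_%03d", c, seq_len(ng)),
      chromosome = sprintf("chr%d", c),
      start = starts,
      end = starts + lens,
      stringsAsFactors = FALSE
    )
  }
  validate_genome_layout(new_genome_layout(do.call(rbind, rows)))
}

#' Generate a synthetic gene-family table
#'
#' Every gene is its own family except `config$tandem_runs` planted runs per
#' chromosome: each run makes 2-3 adjacent genes share a family, emulating
#' tandem duplications for the merging step.
#'
#' @param layout a `genome_layout`
#' @param config a `synthetic_config`
#' @param seed override of `config$seed`
#' @return named character vector `gene_id -> family_id`
#' @export
generate_families <- function(layout, config, seed = config$seed + 1) {
  set.seed(seed)
  fam <- stats::setNames(paste0("fam_", layout$genes$gene_id),
                         layout$genes$gene_id)
  if (config$tandem_runs > 0) {
    run_id <- 0L
    for (ch in unique(layout$genes$chromosome)) {
      idx <- which(layout$genes$chromosome == ch)
      if (length(idx) < 3) next
      for (r in seq_len(config$tandem_runs)) {
        run_id <- run_id + 1L
        len <- sample(2:3, 1)
        at <- sample(seq_len(length(idx) - len + 1), 1)
        fam[layout$genes$gene_id[idx[at:(at + len - 1)]]] <-
          sprintf("tandemfam_%d", run_id)
      }
    }
  }
  fam
}

#' Generate a synthetic group collection
#'
#' Modes: `null` samples members uniformly without replacement;
#' `chrom_concentrated` draws each member from the group's anchor chromosome
#' with probability `rho`, uniformly otherwise; `linear_clustered` draws
#' members from a window of `cluster_window` times the chromosome length
#' around an anchor gene with probability `rho` (falling back to a uniform
#' draw if the window holds no unused gene); `spatial_colocalized`
#' places, with probability `rho` per group, a size-2 group into the two
#' segments of a randomly chosen planted inter-chromosomal segment pair
#' (requires `planted_pairs` and `map`).
#'
#' @param layout a `genome_layout`
#' @param config a `synthetic_config`
#' @param mode generation mode
#' @param group_type type label for the collection (`spatial_colocalized`
#'   forces size-2 groups, matching `ppi`)
#' @param planted_pairs 2-column matrix of segment indices (for
#'   `spatial_colocalized`)
#' @param map a `contact_map` (for `spatial_colocalized`)
#' @param seed override of `config$seed`
#' @return a `group_collection`
#' @export
generate_groups <- function(layout, config,
                            mode = c("null", "chrom_concentrated",
                                     "linear_clustered",
                                     "spatial_colocalized"),
                            group_type = "pathway",
                            planted_pairs = NULL, map = NULL,
                            seed = config$seed + 2) {
  mode <- match.arg(mode)
  set.seed(seed)
  genes <- layout$genes
  ngene <- nrow(genes)
  mids <- gene_midpoints(layout)
  chrom_len <- tapply(genes$end, genes$chromosome, max)

  # grow a member set: with probability rho draw from the anchor pool,
  # uniformly otherwise; fall back to uniform when the pool is exhausted
  grow_mixture <- function(picked, size, pool, ngene, rho) {
    while (length(picked) < size) {
      avail <- setdiff(pool, picked)
      cand <- if (stats::runif(1) < rho && length(avail)) {
        avail[sample.int(length(avail), 1)]
      } else {
        rest <- setdiff(seq_len(ngene), picked)
        rest[sample.int(length(rest), 1)]
      }
      picked <- c(picked, cand)
    }
    picked
  }

  sizes <- if (mode == "spatial_colocalized") {
    rep(2L, config$n_groups)
  } else {
    2L + stats::rpois(config$n_groups, config$group_size_lambda)
  }
  if (any(sizes > ngene)) stop("group size exceeds gene count")

  draw_group <- function(size) {
    switch(mode,
      null = sample.int(ngene, size),
      chrom_concentrated = {
        anchor <- sample(unique(genes$chromosome), 1)
        pool_anchor <- which(genes$chromosome == anchor)
        grow_mixture(integer(0), size, pool_anchor, ngene, config$rho)
      },
      linear_clustered = {
        anchor <- sample.int(ngene, 1)
        ch <- genes$chromosome[anchor]
        # window w of the chromosome length: members within w/2 of the
        # anchor midpoint, so intra-group pair distances are bounded by w
        w <- config$cluster_window * chrom_len[[ch]]
        near <- which(genes$chromosome == ch &
                      abs(mids - mids[anchor]) <= w / 2)
        grow_mixture(anchor, size, near, ngene, config$rho)
      },
      spatial_colocalized = {
        stopifnot(!is.null(planted_pairs), !is.null(map))
        if (stats::runif(1) < config$rho) {
          pr <- planted_pairs[sample.int(nrow(planted_pairs), 1), ]
          seg <- genes_to_segments(layout, map)
          a_pool <- which(seg == pr[1])
          b_pool <- which(seg == pr[2])
          if (length(a_pool) && length(b_pool)) {
            c(a_pool[sample.int(length(a_pool), 1)],
              b_pool[sample.int(length(b_pool), 1)])
          } else sample.int(ngene, 2)
        } else sample.int(ngene, 2)
      }
    )
  }

  groups <- lapply(seq_len(config$n_groups), function(i) {
    list(group_id = sprintf("%s_%03d", mode, i),
         members = genes$gene_id[draw_group(sizes[i])])
  })
  new_group_collection(group_type, groups,
                       provenance = sprintf("synthetic:%s", mode))
}

# segment table tiling each chromosome of a layout
layout_segments <- function(layout, segment_size) {
  rows <- lapply(unique(layout$genes$chromosome), function(ch) {
    len <- max(layout$genes$end[layout$genes$chromosome == ch])
    nseg <- ceiling(len / segment_size)
    data.frame(
      chromosome = ch,
      start = (seq_len(nseg) - 1) * segment_size,
      end = seq_len(nseg) * segment_size,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Sample inter-chromosomal segment pairs for planting
#'
#' Picks `n_pairs` disjoint inter-chromosomal segment pairs, preferring
#' segments that contain at least one gene (so planted spatial signal can be
#' carried by groups).
#'
#' @param layout a `genome_layout`
#' @param map a `contact_map`
#' @param n_pairs number of pairs
#' @param seed RNG seed
#' @return 2-column integer matrix of segment row indices
#' @export
sample_planted_pairs <- function(layout, map, n_pairs, seed = 1) {
  set.seed(seed)
  seg <- genes_to_segments(layout, map)
  occupied <- sort(unique(seg[!is.na(seg)]))
  ch <- map$segments$chromosome[occupied]
  pool <- occupied[ch %in% names(which(table(ch) >= 1))]
  pairs <- matrix(NA_integer_, 0, 2)
  used <- integer(0)
  tries <- 0
  while (nrow(pairs) < n_pairs && tries < 1000 * n_pairs) {
    tries <- tries + 1
    cand <- sample(setdiff(pool, used), 2)
    if (map$segments$chromosome[cand[1]] != map$segments$chromosome[cand[2]]) {
      pairs <- rbind(pairs, cand)
      used <- c(used, cand)
    }
  }
  if (nrow(pairs) < n_pairs) {
    stop("could not place ", n_pairs, " disjoint inter-chromosomal pairs")
  }
  unname(pairs)
}

#' Generate a synthetic contact map
#'
#' Intra-chromosomal entries decay as `(1 + d)^(-alpha)` in the ordinal
#' segment separation d; inter-chromosomal entries sit at a low constant
#' background; half-normal noise is added symmetrically. Each planted
#' inter-chromosomal pair (s, t) then has t's contact profile blended toward
#' s's with weight `sigma`, making the two segments' profiles correlated --
#' at `sigma = 1` with zero noise they are identical and their 1-correlation
#' distance is exactly 0, the map's minimum.
#'
#' @param layout a `genome_layout`
#' @param config a `synthetic_config`
#' @param planted_pairs optional 2-column matrix of segment row indices
#' @param seed override of `config$seed`
#' @return a `contact_map`
#' @export
generate_contact_map <- function(layout, config, planted_pairs = NULL,
                                 seed = config$seed + 3) {
  set.seed(seed)
  segs <- layout_segments(layout, config$segment_size)
  n <- nrow(segs)
  ord <- segs$start %/% config$segment_size
  same <- outer(segs$chromosome, segs$chromosome, "==")
  dsep <- abs(outer(ord, ord, "-"))
  M <- ifelse(same, (1 + dsep)^(-config$decay_exponent),
              config$inter_background)
  if (config$noise > 0) {
    noise <- matrix(0, n, n)
    up <- upper.tri(noise, diag = TRUE)
    noise[up] <- abs(stats::rnorm(sum(up), 0, config$noise))
    noise <- noise + t(noise) - diag(diag(noise))
    M <- M + noise
  }
  diag(M) <- max(M) + 1  # self-contact dominates; never enters correlations
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0 &&
      config$sigma > 0) {
    s <- config$sigma
    for (p in seq_len(nrow(planted_pairs))) {
      i <- planted_pairs[p, 1]; j <- planted_pairs[p, 2]
      blended <- (1 - s) * M[j, ] + s * M[i, ]
      M[j, ] <- blended
      M[, j] <- blended
      M[j, j] <- max(M)
      hi <- max(M[i, -c(i, j)])
      M[i, j] <- hi; M[j, i] <- hi  # planted contact enrichment
    }
  }
  M <- (M + t(M)) / 2
  contact_map(M, segs, config$segment_size)
}

#' Write a fixture bundle to disk
#'
#' Writes a layout (BED), family table (TSV), group collections (pairs TSV
#' for ppi, GMT otherwise), and contact map (dense TSV) in exactly the
#' formats the loaders consume, plus a small JSON manifest. Round-trips
#' losslessly through the loaders.
#'
#' @param layout a `genome_layout`
#' @param families named character vector, or `NULL`
#' @param collections list of `group_collection`s (possibly empty)
#' @param map a `contact_map`, or `NULL`
#' @param out_dir output directory (created if needed)
#' @return named character vector of file paths (invisibly)
#' @export
write_fixture_bundle <- function(layout, families = NULL,
                                 collections = list(), map = NULL,
                                 out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  paths <- c()

  bed <- file.path(out_dir, "genome.bed")
  g <- layout$genes
  writeLines(sprintf("%s\t%d\t%d\t%s", g$chromosome, as.integer(g$start),
                     as.integer(g$end), g$gene_id), bed)
  paths["genome"] <- bed

  if (!is.null(families)) {
    fp <- file.path(out_dir, "families.tsv")
    utils::write.table(
      data.frame(gene_id = names(families), family_id = unname(families)),
      fp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["families"] <- fp
  }

  tags <- make.unique(vapply(collections, `[[`, "", "group_type"), sep = "_")
  for (ci in seq_along(collections)) {
    col <- collections[[ci]]
    if (col$group_type == "ppi") {
      fp <- file.path(out_dir, sprintf("groups_%s.pairs.tsv", tags[ci]))
      writeLines(vapply(col$groups, function(g) {
        paste(g$members[1], g$members[2], sep = "\t")
      }, ""), fp)
    } else {
      fp <- file.path(out_dir, sprintf("groups_%s.gmt", tags[ci]))
      writeLines(vapply(col$groups, function(g) {
        paste(c(g$group_id, "synthetic", g$members), collapse = "\t")
      }, ""), fp)
    }
    paths[paste0("groups_", tags[ci])] <- fp
  }

  if (!is.null(map)) {
    fp <- file.path(out_dir, "contact_map.tsv")
    mat <- map$matrix
    labels <- segment_labels(map)
    lines <- c(paste(c("segment", labels), collapse = "\t"),
               vapply(seq_len(nrow(mat)), function(i) {
                 paste(c(labels[i],
                         formatC(mat[i, ], format = "g", digits = 17)),
                       collapse = "\t")
               }, ""))
    writeLines(lines, fp)
    paths["contact_map"] <- fp
  }

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(files = as.list(paths),
         n_genes = nrow(layout$genes),
         n_collections = length(collections),
         note = if (length(collections) == 0) "no group files" else ""),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  paths["manifest"] <- manifest
  invisible(paths)
}
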