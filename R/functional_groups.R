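#' @title Collections of functional gene groups
#'
#' @description A group collection holds named gene sets of one functional
#' type: interacting protein pairs (`ppi`, always size 2), protein complexes
#' (`complex`) or pathways (`pathway`). Groups are the units the concentration
#' tests score; the permutation null keeps group composition fixed and only
#' shuffles gene locations.
#'
#' @name group_collection
NULL

GROUP_TYPES <- c("ppi", "complex", "pathway")

new_group_collection <- function(group_type, groups, provenance = "") {
  structure(
    list(group_type = group_type, groups = groups, provenance = provenance),
    class = "group_collection"
  )
}

#' @export
print.group_collection <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$members), 0L)
  cat(sprintf("<group_collection> type=%s, %d groups, sizes %s..%s\n",
              x$group_type, length(x$groups),
              if (length(sizes)) min(sizes) else "-",
              if (length(sizes)) max(sizes) else "-"))
  invisible(x)
}

#' Number of groups in a collection
#' @param collection a `group_collection`
#' @return integer
#' @export
n_groups <- function(collection) length(collection$groups)

group_sizes <- function(collection) {
  vapply(collection$groups, function(g) length(g$members), 0L)
}

#' Load a group collection from a pair list or GMT file
#'
#' Pair lists (two tab-separated gene ids per line) are the native format for
#' PPIs; GMT (id, description, then members, tab-separated) is the native
#' format for complexes and pathways. Duplicate members within a group are
#' collapsed; identical groups appearing twice are kept as distinct database
#' records. Self-interaction pairs and groups with fewer than 2 distinct
#' members are dropped with a warning.
#'
#' @param path path to the file
#' @param format `"pairs"` or `"gmt"`
#' @param group_type one of `"ppi"`, `"complex"`, `"pathway"`
#' @return a `group_collection`
#' @export
load_groups <- function(path, format = c("pairs", "gmt"),
                        group_type = c("ppi", "complex", "pathway")) {
  format <- match.arg(format)
  group_type <- match.arg(group_type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]

  groups <- list()
  if (format == "pairs") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(fields, length, 0L)
    if (any(nf != 2L)) {
      stop("malformed pair line ", which(nf != 2L)[1], ": expected 2 fields")
    }
    dropped <- 0L
    for (i in seq_along(fields)) {
      a <- fields[[i]][1]; b <- fields[[i]][2]
      if (a == b) { dropped <- dropped + 1L; next }
      groups[[length(groups) + 1L]] <-
        list(group_id = paste(a, b, sep = "--"), members = c(a, b))
    }
    if (dropped > 0) warning(dropped, " self-interaction pairs dropped")
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    rejected <- 0L
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 2L) stop("malformed GMT line ", i, ": need id and description")
      members <- unique(f[-(1:2)])
      members <- members[nzchar(members)]
      if (length(members) < 2L) { rejected <- rejected + 1L; next }
      if (group_type == "ppi" && length(members) > 2L) {
        stop("GMT group ", f[1], " has ", length(members),
             " members; ppi groups must have exactly 2")
      }
      groups[[length(groups) + 1L]] <- list(group_id = f[1], members = members)
    }
    if (rejected > 0) {
      warning(rejected, " groups rejected with fewer than 2 distinct members")
    }
  }

  # identical database records are kept; disambiguate their ids for reporting
  ids <- vapply(groups, `[[`, "", "group_id")
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "#")
    for (i in seq_along(groups)) groups[[i]]$group_id <- ids[i]
  }
  new_group_collection(group_type, groups, provenance = path)
}

#' Restrict a group collection to genes present in a layout
#'
#' Group members are resolved through merged-gene aliases, members absent
#' from the layout are removed, members collapsing onto one merged gene are
#' deduplicated, and groups reduced below 2 members are dropped. The result
#' is what every downstream statistic consumes.
#'
#' @param collection a `group_collection`
#' @param layout a `genome_layout`
#' @return a `group_collection`; idempotent
#' @export
restrict_to_layout <- function(collection, layout) {
  present <- layout$genes$gene_id
  kept <- list()
  lost_members <- 0L
  for (g in collection$groups) {
    m <- unique(resolve_gene_ids(layout, g$members))
    m2 <- m[m %in% present]
    lost_members <- lost_members + (length(g$members) - length(m2))
    if (length(m2) >= 2L) {
      kept[[length(kept) + 1L]] <- list(group_id = g$group_id, members = m2)
    }
  }
  if (length(kept) < length(collection$groups) || lost_members > 0) {
    message(sprintf(
      "restrict_to_layout: %d/%d groups kept (%d member references removed)",
      length(kept), length(collection$groups), lost_members))
  }
  new_group_collection(collection$group_type, kept, collection$provenance)
}

#' Summarize a group collection
#'
#' @param collection a non-empty `group_collection`
#' @return data frame with one row: `n_groups`, `min_size`, `median_size`,
#'   `max_size`, `n_genes` (distinct genes across all groups). The median of
#'   an even-length size list is the mean of the two central values.
#' @export
summarize_groups <- function(collection) {
  if (n_groups(collection) == 0) stop("empty group collection")
  sizes <- group_sizes(collection)
  genes <- unique(unlist(lapply(collection$groups, `[[`, "members")))
  data.frame(
    group_type = collection$group_type,
    n_groups = length(sizes),
    min_size = min(sizes),
    median_size = stats::median(sizes),
    max_size = max(sizes),
    n_genes = length(genes),
    stringsAsFactors = FALSE
  )
}
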