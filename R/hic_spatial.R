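#' @title Binned contact maps and 1-correlation spatial distances
#'
#' @description A contact map is a symmetric segment-by-segment matrix of
#' normalized contact scores at a fixed segment size (e.g. 1 Mb bins of a
#' Hi-C experiment). Spatial proximity between two segments is measured as
#' one minus the Pearson correlation of their contact profiles (their matrix
#' rows), computed over columns where both profiles are defined and excluding
#' the two segments' own columns so the dominant near-diagonal entries cannot
#' drive the correlation. Values lie in [0, 2]; small values mean the two
#' segments see the rest of the genome alike, i.e. are close in nuclear space.
#'
#' @name contact_map
NULL

#' Construct a contact map
#'
#' @param mat square numeric matrix of contact scores; `NA` marks missing
#'   entries. Must be symmetric where defined.
#' @param segments data frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open), one row per matrix row, in matrix order
#' @param segment_size nominal segment size in bases
#' @return a `contact_map`
#' @export
contact_map <- function(mat, segments, segment_size) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            nrow(segments) == nrow(mat),
            all(c("chromosome", "start", "end") %in% names(segments)))
  both <- !is.na(mat) & !is.na(t(mat))
  if (any(abs(mat[both] - t(mat)[both]) > 1e-9)) {
    stop("contact matrix is asymmetric beyond tolerance 1e-9")
  }
  # mirror entries defined on one side only
  miss <- is.na(mat) & !is.na(t(mat))
  mat[miss] <- t(mat)[miss]
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  segments$ordinal <- segments$start %/% segment_size
  structure(
    list(matrix = mat, segments = segments, segment_size = segment_size),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %d segments of %g bp on %d chromosomes (%.1f%% entries defined)\n",
    nrow(x$matrix), x$segment_size,
    length(unique(x$segments$chromosome)),
    100 * mean(!is.na(x$matrix))))
  invisible(x)
}

segment_labels <- function(map) {
  sprintf("%s:%d-%d", map$segments$chromosome,
          as.integer(map$segments$start), as.integer(map$segments$end))
}

parse_segment_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- which(vapply(m, length, 0L) != 4L)
  if (length(bad)) stop("malformed segment label: ", labels[bad[1]])
  data.frame(
    chromosome = vapply(m, `[[`, "", 2L),
    start = as.numeric(vapply(m, `[[`, "", 3L)),
    end = as.numeric(vapply(m, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Load a contact map from disk
#'
#' Two plain-text formats are supported. `dense_tsv`: a tab-separated matrix
#' with segment labels `chrom:start-end` as both header and first column;
#' empty cells or `NA` mark missing entries. `coo_tsv`: a headered triple
#' list with columns `seg_i`, `seg_j`, `value` using the same labels;
#' unlisted pairs are missing (not zero), and each listed entry is mirrored.
#' Conflicting symmetric entries (difference above 1e-9) are an error.
#'
#' @param path path to the file
#' @param format `"dense_tsv"` or `"coo_tsv"`
#' @param segment_size segment size in bases
#' @return a `contact_map`
#' @export
load_contact_map <- function(path, format = c("dense_tsv", "coo_tsv"),
                             segment_size) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as.matrix(tab)
    if (!identical(rownames(mat), colnames(mat))) {
      stop("dense contact map row and column labels differ")
    }
    segs <- parse_segment_labels(rownames(mat))
    dimnames(mat) <- NULL
    contact_map(mat, segs, segment_size)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("seg_i", "seg_j", "value")
    if (!all(need %in% names(tab))) {
      stop("coo contact map must have columns seg_i, seg_j, value")
    }
    labels <- sort(unique(c(tab$seg_i, tab$seg_j)))
    segs <- parse_segment_labels(labels)
    ord <- order(segs$chromosome, segs$start)
    segs <- segs[ord, , drop = FALSE]
    labels <- labels[ord]
    n <- length(labels)
    mat <- matrix(NA_real_, n, n)
    i <- match(tab$seg_i, labels)
    j <- match(tab$seg_j, labels)
    for (r in seq_len(nrow(tab))) {
      v <- tab$value[r]
      old <- mat[i[r], j[r]]
      if (!is.na(old) && abs(old - v) > 1e-9) {
        stop(sprintf("conflicting contact entries for (%s, %s): %g vs %g",
                     tab$seg_i[r], tab$seg_j[r], old, v))
      }
      mat[i[r], j[r]] <- v
      mat[j[r], i[r]] <- v
    }
    contact_map(mat, segs, segment_size)
  }
}

#' Map a gene to its contact-map segment
#'
#' A gene belongs to exactly one segment: the one containing its midpoint
#' under half-open segment intervals. Genes spanning a segment boundary are
#' therefore assigned unambiguously.
#'
#' @param gene a single gene record (list or one-row data frame with
#'   `chromosome`, `start`, `end`)
#' @param map a `contact_map`
#' @return integer row index into `map$segments`
#' @export
gene_to_segment <- function(gene, map) {
  mid <- floor((gene$start + gene$end) / 2)
  hit <- which(map$segments$chromosome == gene$chromosome &
               map$segments$start <= mid & mid < map$segments$end)
  if (length(hit) != 1L) {
    stop(sprintf("gene midpoint %s:%d falls in no segment of the contact map",
                 gene$chromosome, as.integer(mid)))
  }
  hit
}

# Vectorized gene -> segment lookup; NA where unmappable.
genes_to_segments <- function(layout, map) {
  mids <- gene_midpoints(layout)
  key <- paste(map$segments$chromosome, map$segments$ordinal)
  gkey <- paste(layout$genes$chromosome, mids %/% map$segment_size)
  idx <- match(gkey, key)
  # guard against partial terminal segments: midpoint must lie inside
  bad <- !is.na(idx) &
    !(map$segments$start[idx] <= mids & mids < map$segments$end[idx])
  idx[bad] <- NA_integer_
  idx
}

#' Spatial distance between two segments
#'
#' One minus the Pearson correlation of the two segments' contact profiles,
#' computed over the columns where both profiles are defined, excluding
#' columns `i` and `j` themselves. `NA` when fewer than `min_overlap`
#' columns remain or either profile is constant on the overlap. The
#' self-distance of a segment with a defined profile is 0 by definition.
#'
#' @param i,j segment row indices
#' @param map a `contact_map`
#' @param min_overlap minimum number of shared defined columns (default 10)
#' @param method correlation method, `"pearson"` (default) or `"spearman"`
#' @return distance in [0, 2], or `NA`
#' @export
segment_distance <- function(i, j, map, min_overlap = 10,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (i == j) {
    return(if (any(!is.na(map$matrix[i, -i]))) 0 else NA_real_)
  }
  x <- map$matrix[i, ]
  y <- map$matrix[j, ]
  keep <- !is.na(x) & !is.na(y)
  keep[c(i, j)] <- FALSE
  if (sum(keep) < min_overlap) return(NA_real_)
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  1 - stats::cor(x, y, method = method)
}

#' All-pairs spatial distance matrix of a contact map
#'
#' Precomputes [segment_distance] for every segment pair. Because the
#' contact map is fixed while permutation tests shuffle only gene locations,
#' this matrix is computed once and reused across all replicates. For maps
#' with no missing entries a closed-form sufficient-statistics path is used;
#' it is numerically identical to the per-pair definition.
#'
#' @param map a `contact_map`
#' @param min_overlap minimum shared defined columns per pair
#' @param method correlation method
#' @return symmetric numeric matrix with zero diagonal and `NA` where
#'   undefined
#' @export
spatial_distance_matrix <- function(map, min_overlap = 10,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  M <- map$matrix
  n <- nrow(M)
  if (method == "pearson" && !anyNA(M) && n - 2 >= min_overlap) {
    # per-pair sufficient statistics over all columns, then subtract the two
    # excluded columns i and j (M is symmetric, so M[j,i] = M[i,j])
    di <- diag(M)
    SX <- matrix(rowSums(M), n, n)        # SX[i,j]  = sum_k M[i,k]
    SXX <- matrix(rowSums(M^2), n, n)
    DI <- matrix(di, n, n)                # DI[i,j]  = M[i,i]
    C <- tcrossprod(M)                    # C[i,j]   = sum_k M[i,k] M[j,k]
    m <- n - 2
    sx <- SX - DI - M
    sy <- t(SX) - t(DI) - M
    sxx <- SXX - DI^2 - M^2
    syy <- t(SXX) - t(DI)^2 - M^2
    sxy <- C - M * (DI + t(DI))
    num <- m * sxy - sx * sy
    den <- sqrt(pmax(m * sxx - sx^2, 0)) * sqrt(pmax(m * syy - sy^2, 0))
    D <- 1 - num / den
    D[den == 0] <- NA_real_
    diag(D) <- 0
    # clamp tiny floating-point excursions outside [0, 2]
    D[!is.na(D)] <- pmin(pmax(D[!is.na(D)], 0), 2)
    return(D)
  }
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    D[i, i] <- if (any(!is.na(M[i, -i]))) 0 else NA_real_
    for (j in seq_len(n)[-seq_len(i)]) {
      d <- segment_distance(i, j, map, min_overlap = min_overlap,
                            method = method)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Spatial distance between a gene pair
#'
#' Distance between the two genes' segments, with the pair classified as
#' intra- or inter-chromosomal. Two genes in the same segment have distance 0.
#'
#' @param a,b single gene records
#' @param map a `contact_map`
#' @param min_overlap,method passed to [segment_distance]
#' @return list with `distance` (may be `NA`) and `pair_class`
#'   (`"intra"` or `"inter"`)
#' @export
gene_pair_distance <- function(a, b, map, min_overlap = 10,
                               method = "pearson") {
  cls <- if (a$chromosome == b$chromosome) "intra" else "inter"
  d <- tryCatch({
    i <- gene_to_segment(a, map)
    j <- gene_to_segment(b, map)
    segment_distance(i, j, map, min_overlap = min_overlap, method = method)
  }, error = function(e) {
    message("gene_pair_distance: ", conditionMessage(e))
    NA_real_
  })
  list(distance = d, pair_class = cls)
}
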