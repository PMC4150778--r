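#' @title Genome layouts: gene positions on chromosomes
#'
#' @description A genome layout is the fixed scaffold every permutation test
#' operates on: an ordered table of gene loci per chromosome. Coordinates are
#' 0-based half-open throughout the package; 1-based inclusive TSV input is
#' converted on load. Permutations reassign gene identifiers to the fixed
#' loci, so the locus multiset is immutable.
#'
#' @name genome_layout
NULL

new_genome_layout <- function(genes, aliases = character(0)) {
  genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(genes = genes, aliases = aliases),
    class = "genome_layout"
  )
}

validate_genome_layout <- function(layout) {
  g <- layout$genes
  stopifnot(
    all(c("gene_id", "chromosome", "start", "end") %in% names(g)),
    !anyDuplicated(g$gene_id),
    all(g$start >= 0),
    all(g$end > g$start)
  )
  # starts strictly increase within each chromosome
  for (ch in unique(g$chromosome)) {
    s <- g$start[g$chromosome == ch]
    if (length(s) > 1 && any(diff(s) <= 0)) {
      stop("gene starts are not strictly increasing on chromosome ", ch)
    }
  }
  invisible(layout)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "<genome_layout> %d genes on %d chromosomes (%d merged-gene aliases)\n",
    nrow(x$genes), length(unique(x$genes$chromosome)), length(x$aliases)
  ))
  invisible(x)
}

#' Number of genes in a layout
#' @param layout a `genome_layout`
#' @return integer gene count
#' @export
n_genes <- function(layout) nrow(layout$genes)

#' Chromosome names of a layout
#' @param layout a `genome_layout`
#' @return character vector of chromosome names, sorted
#' @export
layout_chromosomes <- function(layout) sort(unique(layout$genes$chromosome))

#' Gene midpoints
#'
#' Midpoint of the gene interval, `floor((start + end) / 2)`. Midpoints anchor
#' both linear distances and the assignment of genes to contact-map segments;
#' they remain well defined for merged tandem-duplicate genes, which span the
#' full run of genes they replace.
#'
#' @param layout a `genome_layout`
#' @return numeric vector aligned with `layout$genes`
#' @export
gene_midpoints <- function(layout) {
  floor((layout$genes$start + layout$genes$end) / 2)
}

#' Load gene positions from a BED or TSV file
#'
#' Reads a gene position table and builds a [genome_layout]. Genes whose
#' identifier occurs more than once (ambiguous position) are dropped
#' entirely -- none of the copies is kept, so only genes with a unique
#' position enter the analysis. Strand columns, if present, are ignored.
#'
#' @param path path to the file
#' @param format `"bed"` for BED4+ (chrom, start, end, name; 0-based
#'   half-open) or `"tsv"` for a headered table with columns
#'   `gene_id`, `chromosome`, `start`, `end` (1-based inclusive, converted
#'   to the internal 0-based half-open convention).
#' @return a `genome_layout`
#' @export
load_gene_positions <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty gene position file: ", path)

  if (format == "bed") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 0L) < 4L)
    if (length(bad)) {
      stop("malformed BED line ", bad[1], ": fewer than 4 columns")
    }
    genes <- data.frame(
      gene_id = vapply(fields, `[[`, "", 4L),
      chromosome = vapply(fields, `[[`, "", 1L),
      start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
      end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
      stringsAsFactors = FALSE
    )
    bad <- which(is.na(genes$start) | is.na(genes$end))
    if (length(bad)) stop("malformed BED line ", bad[1], ": non-numeric coordinate")
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chromosome", "start", "end")
    if (!all(need %in% names(tab))) {
      stop("TSV gene table must have columns: ", paste(need, collapse = ", "))
    }
    genes <- data.frame(
      gene_id = as.character(tab$gene_id),
      chromosome = as.character(tab$chromosome),
      # 1-based inclusive -> 0-based half-open
      start = as.numeric(tab$start) - 1,
      end = as.numeric(tab$end),
      stringsAsFactors = FALSE
    )
  }

  bad <- which(genes$start < 0 | genes$end <= genes$start)
  if (length(bad)) {
    stop("malformed record at line ", bad[1], ": need 0 <= start < end")
  }

  dup <- genes$gene_id %in% genes$gene_id[duplicated(genes$gene_id)]
  if (any(dup)) {
    message(sum(dup), " records dropped for non-unique gene ids (",
            length(unique(genes$gene_id[dup])), " genes)")
    genes <- genes[!dup, , drop = FALSE]
  }
  if (nrow(genes) == 0) stop("no genes with a unique position in ", path)
  validate_genome_layout(new_genome_layout(genes))
}

#' Load a gene-family assignment table
#'
#' Reads a two-column TSV (`gene_id`, `family_id`). Families are consumed as
#' input (e.g. produced upstream by all-against-all protein similarity search
#' plus Markov clustering); genes absent from the table are treated as
#' singleton families.
#'
#' @param path path to the TSV file (with header)
#' @return named character vector mapping gene_id to family_id
#' @export
load_gene_families <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "family_id") %in% names(tab))) {
    stop("family table must have columns gene_id, family_id")
  }
  stats::setNames(as.character(tab$family_id), as.character(tab$gene_id))
}

#' Merge tandem duplicate genes
#'
#' Tandemly duplicated genes share a family by ancestry and sit adjacently on
#' the chromosome; left in place they create trivial clustering signal. This
#' merges every maximal run of genes that are consecutive in the
#' per-chromosome gene order and share a family into a single gene spanning
#' the run's full interval. Member identifiers alias to the merged gene so
#' functional-group lookups still resolve.
#'
#' @param layout a `genome_layout`
#' @param families named character vector `gene_id -> family_id` (genes not
#'   named are singleton families and never merge)
#' @return a `genome_layout` with merged genes and an alias map; idempotent
#' @export
merge_tandem_duplicates <- function(layout, families = character(0)) {
  g <- layout$genes
  fam <- families[g$gene_id]
  # unmapped genes get a unique singleton family so they never join a run
  singleton <- is.na(fam)
  fam[singleton] <- paste0(".singleton.", g$gene_id[singleton])

  # run id changes whenever chromosome or family changes along the sorted order
  brk <- c(TRUE, g$chromosome[-1] != g$chromosome[-nrow(g)] |
                  fam[-1] != fam[-nrow(g)])
  run <- cumsum(brk)

  ord <- seq_len(nrow(g))
  starts <- tapply(g$start, run, min)
  ends <- tapply(g$end, run, max)
  chroms <- tapply(g$chromosome, run, `[[`, 1L)
  sizes <- tabulate(run)
  ids <- tapply(ord, run, function(i) paste(g$gene_id[i], collapse = "|"))

  merged <- data.frame(
    gene_id = as.character(ids),
    chromosome = as.character(chroms),
    start = as.numeric(starts),
    end = as.numeric(ends),
    stringsAsFactors = FALSE
  )

  aliases <- layout$aliases
  multi <- which(sizes > 1)
  if (length(multi)) {
    for (r in multi) {
      members <- g$gene_id[run == r]
      new <- stats::setNames(rep(merged$gene_id[r], length(members)), members)
      aliases <- c(aliases, new)
    }
    # re-point any pre-existing aliases whose target was itself merged
    tgt <- aliases[aliases]
    aliases[!is.na(tgt)] <- tgt[!is.na(tgt)]
  }
  validate_genome_layout(new_genome_layout(merged, aliases))
}

#' Resolve gene identifiers through merged-gene aliases
#'
#' @param layout a `genome_layout`
#' @param ids character vector of gene identifiers
#' @return character vector: the merged-gene id where the input was absorbed
#'   by a tandem merge, the input id otherwise
#' @export
resolve_gene_ids <- function(layout, ids) {
  hit <- layout$aliases[ids]
  unname(ifelse(is.na(hit), ids, hit))
}

#' Linear distance between two genes
#'
#' Midpoint-to-midpoint distance in bases; `NA` when the genes are on
#' different chromosomes (linear distance is undefined across chromosomes).
#'
#' @param a,b single gene records: lists or one-row data frames with
#'   `chromosome`, `start`, `end`
#' @return non-negative number of bases, or `NA`
#' @export
linear_distance <- function(a, b) {
  if (a$chromosome != b$chromosome) return(NA_real_)
  abs(floor((a$start + a$end) / 2) - floor((b$start + b$end) / 2))
}
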