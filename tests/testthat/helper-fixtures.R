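# Small deterministic fixtures, built in code.

# 5-gene layout on two chromosomes with round coordinates
toy_layout <- function() {
  funcoloc:::new_genome_layout(data.frame(
    gene_id = c("a1", "a2", "a3", "b1", "b2"),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(50, 250, 650, 100, 900),
    end = c(150, 350, 750, 300, 1100),
    stringsAsFactors = FALSE
  ))
}

toy_collection <- function(groups, type = "pathway") {
  funcoloc:::new_group_collection(type, lapply(seq_along(groups), function(i) {
    list(group_id = names(groups)[i] %||% paste0("G", i),
         members = groups[[i]])
  }), provenance = "test")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || a == "") b else a

# complete symmetric toy contact map: n segments on the given chromosomes
toy_map <- function(n = 6, chromosomes = c(3, 3), segment_size = 1e6,
                    seed = 99) {
  set.seed(seed)
  stopifnot(sum(chromosomes) == n)
  chrom <- rep(paste0("chr", seq_along(chromosomes)), chromosomes)
  ord <- unlist(lapply(chromosomes, seq_len)) - 1
  segs <- data.frame(chromosome = chrom,
                     start = ord * segment_size,
                     end = (ord + 1) * segment_size,
                     stringsAsFactors = FALSE)
  M <- matrix(stats::runif(n * n, 0.1, 1), n, n)
  M <- (M + t(M)) / 2
  contact_map(M, segs, segment_size)
}

# write lines to a temp file, return path
tmpfile <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# enumerate all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# all scheme-consistent permutation vectors for a layout
all_scheme_perms <- function(layout, scheme) {
  n <- nrow(layout$genes)
  blocks <- funcoloc:::layout_blocks(layout)
  if (scheme == "global") return(all_perms(n))
  per_block <- lapply(blocks, function(b) {
    lapply(all_perms(length(b)), function(p) b[p])
  })
  grids <- expand.grid(lapply(per_block, seq_along))
  lapply(seq_len(nrow(grids)), function(r) {
    pi <- integer(n)
    for (k in seq_along(per_block)) {
      pi[blocks[[k]]] <- per_block[[k]][[grids[r, k]]]
    }
    pi
  })
}
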