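# shared fixtures: all built in code at test time

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tmp_fasta <- function(lines) write_tmp(lines, ".fasta")

# hit table for a raw score matrix (rows = genome A genes, cols = genome B)
mat_to_hits <- function(M, dir = c("ab", "ba")) {
  dir <- match.arg(dir)
  an <- sprintf("a%02d", seq_len(nrow(M)))
  bn <- sprintf("b%02d", seq_len(ncol(M)))
  if (dir == "ab") {
    tibble::tibble(query_genome = "A", query_id = rep(an, ncol(M)),
                   subject_genome = "B", subject_id = rep(bn, each = nrow(M)),
                   score = as.vector(M), evalue = NA_real_)
  } else {
    tibble::tibble(query_genome = "B", query_id = rep(bn, each = nrow(M)),
                   subject_genome = "A", subject_id = rep(an, ncol(M)),
                   score = as.vector(M), evalue = NA_real_)
  }
}

# independent brute-force BBH oracle on a score matrix: for every (i, j),
# scan row i and column j exhaustively and apply the tie rules directly
bbh_oracle <- function(M) {
  an <- sprintf("a%02d", seq_len(nrow(M)))
  bn <- sprintf("b%02d", seq_len(ncol(M)))
  pairs <- character(0)
  for (i in seq_len(nrow(M))) {
    # best subject for query i: max score, tie -> lexicographically smallest
    # subject id (bn are same-width so lexicographic = numeric index order)
    bests_i <- which(M[i, ] == max(M[i, ]))[1]
    bests_j <- which(M[, bests_i] == max(M[, bests_i]))[1]
    if (bests_j == i) pairs <- c(pairs, paste(an[i], bn[bests_i]))
  }
  sort(pairs)
}

# random unrooted binary tree with positive branch lengths and its exact
# path-length (additive) distance matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# standard 3-genome community used by the binning study conditions:
# GC 45/55/63 %, abundances 0.6/0.3/0.1, ~500 contigs
study_genomes <- function() {
  tibble::tibble(
    genome_id = c("gA", "gB", "gC"),
    length_bp = c(4.2e6, 4.1e6, 3.9e6),
    gc_percent = c(45, 55, 63),
    abundance = c(0.6, 0.3, 0.1)
  )
}

# truth-guided rectangle around one genome's contig cluster
region_around <- function(stats, truth, genome) {
  ids <- truth$contig_id[truth$genome_id == genome]
  sub <- stats[stats$contig_id %in% ids, ]
  selection_region(
    gc_min = min(sub$gc_percent) - 0.2, gc_max = max(sub$gc_percent) + 0.2,
    rpkm_min = max(0, min(sub$rpkm) * 0.8), rpkm_max = max(sub$rpkm) * 1.2
  )
}
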