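# Comparative genomics by bidirectional best hits (BBH): all-vs-all protein
# scoring (Smith-Waterman, affine gaps), paralog de-duplication, BBH ortholog
# pairing and the three-genome Venn partition of shared and peculiar CDSs.

aa_matrix <- function(matrix_name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(matrix_name, envir = e)) {
    abort(paste0("unknown substitution matrix: ", matrix_name))
  }
  get(matrix_name, envir = e)
}

#' Local alignment score of two proteins
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of length
#' L costs `gap_open + gap_extend * L`) under a named substitution matrix.
#' Stands in for BLASTP bit scores when no external hit table is imported;
#' symmetric in its arguments.
#'
#' @param a,b Protein sequence strings.
#' @param matrix_name Substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1).
#' @return The alignment score (numeric scalar).
#' @export
#' @examples
#' align_score("A", "A") # 4 under BLOSUM62
align_score <- function(a, b, matrix_name = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  m <- aa_matrix(matrix_name)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
}

# score every query against one subject set; returns a full numeric matrix
score_matrix <- function(queries, subjects, matrix_name = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  m <- aa_matrix(matrix_name)
  qs <- Biostrings::AAStringSet(queries)
  out <- matrix(NA_real_, nrow = length(queries), ncol = length(subjects),
                dimnames = list(names(queries), names(subjects)))
  for (j in seq_along(subjects)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      qs, Biostrings::AAString(subjects[[j]]),
      type = "local", substitutionMatrix = m,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
  }
  out
}

#' All-vs-all protein hits between two genomes
#'
#' Scores every query/subject pair with [align_score()] and keeps rows at or
#' above `min_score`. For genuine BLASTP/DIAMOND results use
#' [read_blast_tab()] instead; both produce the same hit-table shape.
#'
#' @param a,b Protein tibbles (`id`, `sequence`) for the query and subject
#'   genomes, e.g. from [read_fasta()].
#' @param genome_a,genome_b Genome ids recorded in the output.
#' @param min_score Score threshold; pairs scoring below it are dropped
#'   (default 60, a conservative floor well above what unrelated proteins of
#'   typical length reach under BLOSUM62).
#' @param matrix_name,gap_open,gap_extend Passed to the aligner.
#' @return Hit tibble `(query_genome, query_id, subject_genome, subject_id,
#'   score, evalue)`; `evalue` is `NA` in internal-scoring mode.
#' @export
all_vs_all <- function(a, b, genome_a = "A", genome_b = "B", min_score = 60,
                       matrix_name = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (nrow(a) == 0 || nrow(b) == 0) abort("protein sets must be non-empty")
  sm <- score_matrix(setNames(a$sequence, a$id), setNames(b$sequence, b$id),
                     matrix_name, gap_open, gap_extend)
  hits <- tibble(
    query_genome = genome_a,
    query_id = rep(a$id, times = nrow(b)),
    subject_genome = genome_b,
    subject_id = rep(b$id, each = nrow(a)),
    score = as.vector(sm),
    evalue = NA_real_
  )
  filter(hits, .data$score >= min_score)
}

#' Import a 12-column tabular hit file (BLAST/DIAMOND `-outfmt 6`)
#'
#' The escape hatch for real data: supply pre-computed BLASTP hits instead of
#' internal alignment. Rows above the E-value threshold of 1e-5 (the standard
#' cutoff for BBH surveys) are dropped; the bit score fills the `score`
#' column.
#'
#' @param path Path to the tabular file (no header; columns query, subject,
#'   pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore).
#' @param genome_a,genome_b Genome ids recorded in the output.
#' @param max_evalue E-value threshold (default `1e-5`).
#' @return Hit tibble as in [all_vs_all()].
#' @export
read_blast_tab <- function(path, genome_a = "A", genome_b = "B", max_evalue = 1e-5) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- readr::read_tsv(path, col_names = cols,
                         col_types = "ccdddddddddd", comment = "#")
  tab %>%
    filter(.data$evalue <= max_evalue) %>%
    mutate(query_genome = genome_a, subject_genome = genome_b,
           score = .data$bitscore) %>%
    select("query_genome", "query_id", "subject_genome", "subject_id",
           "score", "evalue")
}

#' Remove redundant (duplicate) genes within a genome
#'
#' BBH ortholog counting assumes each function is represented once per
#' genome, so near-identical within-genome duplicates are collapsed first:
#' proteins whose mutual local-alignment identity (matches over the shorter
#' sequence length) reaches `min_identity` are clustered by single linkage
#' and only the longest member of each cluster is kept (ties: smallest id).
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param min_identity Percent-identity threshold (default 90).
#' @param matrix_name,gap_open,gap_extend Passed to the aligner.
#' @return The reduced protein tibble, input order preserved.
#' @export
dedup_paralogs <- function(proteins, min_identity = 90,
                           matrix_name = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  n <- nrow(proteins)
  if (n < 2) return(proteins)
  m <- aa_matrix(matrix_name)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  lens <- nchar(proteins$sequence)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins$sequence[i]),
        Biostrings::AAString(proteins$sequence[j]),
        type = "local", substitutionMatrix = m,
        gapOpening = gap_open, gapExtension = gap_extend
      )
      ident <- 100 * Biostrings::nmatch(aln) / min(lens[i], lens[j])
      if (ident >= min_identity) {
        a <- find(i); b <- find(j)
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- proteins %>%
    mutate(.cluster = root, .len = lens, .row = row_number()) %>%
    group_by(.data$.cluster) %>%
    arrange(dplyr::desc(.data$.len), .data$id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    pull(".row")
  proteins[sort(keep), , drop = FALSE]
}

# best subject per query under the tie rules: score desc, evalue asc,
# subject id lexicographic
best_hits <- function(hits) {
  ev <- hits$evalue
  ev[is.na(ev)] <- Inf
  o <- order(hits$query_id, -hits$score, ev, hits$subject_id, method = "radix")
  keep <- o[!duplicated(hits$query_id[o])]
  list(query_id = hits$query_id[keep], subject_id = hits$subject_id[keep])
}

#' Bidirectional best-hit ortholog pairs
#'
#' `(x, y)` is a BBH pair iff `y` is `x`'s best hit among genome B and `x` is
#' `y`'s best hit among genome A, both hit tables having been thresholded
#' identically. Best = highest score, ties broken by lower E-value then
#' lexicographic subject id; each gene appears in at most one pair.
#'
#' @param ab Hit table with genome A queries against genome B.
#' @param ba Hit table with genome B queries against genome A.
#' @return Tibble `(genome_a, id_a, genome_b, id_b)`.
#' @export
bbh_pairs <- function(ab, ba) {
  ga <- if (nrow(ab) > 0) ab$query_genome[[1]] else if (nrow(ba) > 0) ba$subject_genome[[1]] else "A"
  gb <- if (nrow(ab) > 0) ab$subject_genome[[1]] else if (nrow(ba) > 0) ba$query_genome[[1]] else "B"
  if (nrow(ab) == 0 || nrow(ba) == 0) {
    return(tibble(genome_a = character(0), id_a = character(0),
                  genome_b = character(0), id_b = character(0)))
  }
  fwd <- best_hits(ab)
  bwd <- best_hits(ba)
  idx <- match(fwd$subject_id, bwd$query_id)
  mutual <- !is.na(idx) & bwd$subject_id[idx] == fwd$query_id
  o <- order(fwd$query_id[mutual], method = "radix")
  tibble(genome_a = ga, id_a = fwd$query_id[mutual][o],
         genome_b = gb, id_b = fwd$subject_id[mutual][o])
}

#' Venn partition of three genomes' gene sets from pairwise BBHs
#'
#' Assigns each (non-redundant) gene of each genome to the Venn region named
#' by its own genome plus every genome where it has a BBH partner. Assignment
#' is per gene from its own BBH edges, so non-transitive BBH triangles cannot
#' corrupt the partition. Region labels are the sorted genome ids joined by
#' `"&"`.
#'
#' @param proteins Named list of three protein tibbles (`id`, `sequence`);
#'   names are the genome ids. Apply [dedup_paralogs()] first.
#' @param pairs List of the three pairwise BBH tibbles from [bbh_pairs()].
#' @return Tibble `(genome_id, protein_id, region)`.
#' @export
venn_partition <- function(proteins, pairs) {
  if (length(proteins) != 3 || is.null(names(proteins))) {
    abort("proteins must be a named list of three genomes")
  }
  genomes <- names(proteins)
  edges <- purrr::map_dfr(pairs, function(p) {
    bind_rows(
      tibble(genome = p$genome_a, id = p$id_a, partner = p$genome_b),
      tibble(genome = p$genome_b, id = p$id_b, partner = p$genome_a)
    )
  })
  purrr::map_dfr(genomes, function(g) {
    ids <- proteins[[g]]$id
    part <- edges %>% filter(.data$genome == g)
    region <- vapply(ids, function(i) {
      with_part <- sort(unique(c(g, part$partner[part$id == i])))
      paste(with_part, collapse = "&")
    }, character(1))
    tibble(genome_id = g, protein_id = ids, region = unname(region))
  })
}

#' Region counts of a Venn partition
#'
#' Counts genes per Venn region. For the focal-versus-two-references layout
#' the interesting regions are the focal-only genes (peculiar CDSs) and the
#' genes shared by both references but absent from the focal genome (missing
#' functions).
#'
#' @param partition Tibble from [venn_partition()].
#' @return Tibble `(region, n_genes)` sorted by region label.
#' @export
venn_counts <- function(partition) {
  partition %>% count(.data$region, name = "n_genes") %>% arrange(.data$region)
}
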