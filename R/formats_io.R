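#' Read a FASTA file into a sequence tibble
#'
#' Parses nucleotide or protein FASTA into a tibble with one row per record.
#' The record id is the header token before the first whitespace; any
#' remainder is kept as `description` but is never used for joins. Sequences
#' are normalized to uppercase and validated against the declared alphabet
#' (`ACGTN` for nucleotide; the 20 canonical amino acids plus `X`, with `*`
#' stripped if it terminates a protein).
#'
#' @param path Path to a FASTA file.
#' @param kind `"nucleotide"` or `"protein"`.
#' @return A tibble with columns `id`, `description`, `sequence` and
#'   attribute `kind`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 a contig", "acgt"), tf)
#' read_fasta(tf, "nucleotide")
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate id ", dup[[1]], " in ", path))
  }
  seqs <- toupper(as.character(set))
  if (kind == "protein") seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for id ", ids[!nzchar(seqs)][[1]]))
  }
  ok <- if (kind == "nucleotide") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX"
  bad <- regexpr(paste0("[^", ok, "]"), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[[1]]
    abort(sprintf(
      "illegal character '%s' at position %d of sequence %s",
      substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]
    ))
  }
  out <- tibble(id = unname(ids), description = unname(desc), sequence = unname(seqs))
  attr(out, "kind") <- kind
  out
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `sequence` and optionally
#'   `description` (appended to the header after a space when non-empty).
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  hdr <- seqs$id
  if ("description" %in% names(seqs)) {
    has <- nzchar(seqs$description %||% "")
    hdr[has] <- paste(seqs$id[has], seqs$description[has])
  }
  set <- Biostrings::BStringSet(setNames(seqs$sequence, hdr))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a per-contig mapped-read count table
#'
#' Reads a TSV with header columns `contig_id` and `mapped_reads`. The
#' metagenome-wide total used for RPKM and relative abundance defaults to the
#' column sum; when the table is a subset of all contigs, the true total can
#' be supplied as a `#total=<int>` comment line before the header.
#'
#' @param path Path to the TSV.
#' @return Tibble `(contig_id, mapped_reads)` with attribute
#'   `total_mapped_reads`.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) abort(paste0("coverage file not found: ", path))
  lines <- readLines(path)
  total <- NA_real_
  tl <- grep("^#total=", lines, value = TRUE)
  if (length(tl) > 0) total <- as.numeric(sub("^#total=", "", tl[[1]]))
  body <- lines[!startsWith(lines, "#")]
  tab <- readr::read_tsv(I(body), col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("contig_id", "mapped_reads") %in% names(tab))) {
    abort("coverage table must have columns contig_id and mapped_reads")
  }
  reads <- suppressWarnings(as.numeric(tab$mapped_reads))
  if (anyNA(reads)) abort("non-numeric mapped_reads value in coverage table")
  if (any(reads < 0)) abort("negative mapped_reads value in coverage table")
  if (any(reads != floor(reads))) abort("mapped_reads must be integers")
  if (anyDuplicated(tab$contig_id)) {
    abort(paste0("duplicate contig_id in coverage table: ",
                 tab$contig_id[duplicated(tab$contig_id)][[1]]))
  }
  if (is.na(total)) total <- sum(reads)
  if (total < sum(reads)) abort("#total= is smaller than the sum of listed counts")
  if (total <= 0) abort("total mapped reads must be positive")
  out <- tibble(contig_id = tab$contig_id, mapped_reads = reads)
  attr(out, "total_mapped_reads") <- total
  out
}

#' Total mapped reads of a coverage table
#' @param coverage A tibble from [read_coverage()] or with a
#'   `total_mapped_reads` attribute; falls back to the column sum.
#' @return A single number.
#' @export
coverage_total <- function(coverage) {
  attr(coverage, "total_mapped_reads") %||% sum(coverage$mapped_reads)
}

#' Write a coverage table (round-trips through [read_coverage()])
#' @param coverage Tibble `(contig_id, mapped_reads)`; a `total_mapped_reads`
#'   attribute is preserved as a `#total=` line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  lines <- character(0)
  tot <- attr(coverage, "total_mapped_reads")
  if (!is.null(tot)) lines <- sprintf("#total=%.0f", tot)
  lines <- c(lines, "contig_id\tmapped_reads",
             sprintf("%s\t%.0f", coverage$contig_id, coverage$mapped_reads))
  writeLines(lines, path)
  invisible(path)
}

#' Default universal single-copy marker universe
#'
#' Bacterial completeness estimation here uses a configurable universe of 105
#' universal single-copy genes; marker detection itself (HMM searches) is out
#' of scope, so markers enter the pipeline as annotations. This helper names
#' the default 105-marker universe.
#'
#' @param n Number of markers (default 105).
#' @return Character vector of marker ids.
#' @export
default_marker_universe <- function(n = 105L) sprintf("USCG_%03d", seq_len(n))

#' Read a contig-to-marker annotation table
#'
#' TSV with header columns `contig_id` and `marker_id`. A `(contig_id,
#' marker_id)` pair may repeat only when the contig genuinely carries two
#' copies of the marker.
#'
#' @param path Path to the TSV.
#' @param marker_universe Character vector of valid marker ids; rows outside
#'   it are an error.
#' @return Tibble `(contig_id, marker_id)` with attribute `marker_universe`.
#' @export
read_markers <- function(path, marker_universe = default_marker_universe()) {
  if (!file.exists(path)) abort(paste0("marker file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#")
  if (!all(c("contig_id", "marker_id") %in% names(tab))) {
    abort("marker table must have columns contig_id and marker_id")
  }
  bad <- setdiff(tab$marker_id, marker_universe)
  if (length(bad) > 0) {
    abort(paste0("marker id outside the marker universe: ", bad[[1]]))
  }
  out <- tibble(contig_id = tab$contig_id, marker_id = tab$marker_id)
  attr(out, "marker_universe") <- marker_universe
  out
}

#' Marker universe of a marker table
#' @param markers Tibble from [read_markers()]; falls back to the distinct
#'   marker ids present.
#' @return Character vector of marker ids.
#' @export
marker_universe <- function(markers) {
  attr(markers, "marker_universe") %||% sort(unique(markers$marker_id))
}

#' Write a Newick tree file
#'
#' Serializes an `ape` `phylo` tree to standard Newick with branch lengths
#' printed to 6 decimal places and any `node.label` values (e.g. bootstrap
#' supports) as internal-node labels. Reading the file back preserves
#' topology, branch lengths to 1e-6 and supports exactly.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' Render a `phylo` tree as a Newick string (6-decimal branch lengths)
#' @param tree A `phylo` object.
#' @return A single Newick string, terminated by `;`.
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    nl <- tree$node.label
    if (is.null(nl)) return("")
    l <- nl[node - ntip]
    if (is.na(l)) "" else as.character(l)
  }
  render <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(lab(node))
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      len <- if (is.null(tree$edge.length)) NULL else tree$edge.length[r]
      s <- render(child)
      if (!is.null(len)) s <- sprintf("%s:%.6f", s, len)
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  paste0(render(root), ";")
}

#' Read a Newick tree file
#' @param path Path to a Newick file.
#' @return A `phylo` object (node labels retained as character supports).
#' @export
read_newick <- function(path) ape::read.tree(path)
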