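# Per-contig statistics: length, G+C, RPKM and canonical tetranucleotide
# profiles -- the coordinates of bubble-chart binning and tetra refinement.

BASES <- c("A", "C", "G", "T")

# integer codes 0..3 per base, NA for N; used by gc and tetra routines
seq_to_int <- function(seq) {
  v <- match(strsplit(seq, "", fixed = TRUE)[[1]], BASES) - 1L
  v
}

#' G+C content of nucleotide sequences, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`. Ambiguous bases (`N`) are excluded from
#' both numerator and denominator.
#'
#' @param seq Character vector of nucleotide sequences over `ACGTN`.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
#' @examples
#' gc_percent("ATGC") # 50
gc_percent <- function(seq) {
  vapply(seq, function(s) {
    n <- nchar(s)
    gc <- n - nchar(gsub("[GC]", "", s))
    nn <- n - nchar(gsub("N", "", s))
    if (n - nn == 0) abort("no unambiguous bases in sequence")
    100 * gc / (n - nn)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Reads per kilobase per million mapped reads
#'
#' The depth- and length-normalized coverage proxy used as the y axis of the
#' bubble chart: `mapped_reads / (length_bp/1000) / (total_mapped_reads/1e6)`.
#' The total is the metagenome-wide number of mapped reads, not a per-bin
#' total.
#'
#' @param mapped_reads Non-negative read counts (vectorized).
#' @param length_bp Positive contig lengths in bp (vectorized).
#' @param total_mapped_reads Positive total mapped reads (scalar).
#' @return Numeric vector of RPKM values.
#' @export
#' @examples
#' rpkm(10, 1000, 1e6) # 10
rpkm <- function(mapped_reads, length_bp, total_mapped_reads) {
  if (length(total_mapped_reads) != 1 || is.na(total_mapped_reads) ||
      total_mapped_reads <= 0) {
    abort("total_mapped_reads must be a positive scalar")
  }
  if (any(length_bp <= 0)) abort("length_bp must be positive")
  if (any(mapped_reads < 0)) abort("mapped_reads must be non-negative")
  mapped_reads / (length_bp / 1000) / (total_mapped_reads / 1e6)
}

# 256 -> 136 canonical 4-mer classes: each 4-mer is merged with its reverse
# complement; the lexicographically smaller of the pair names the class.
tetra_space <- local({
  env <- new.env()
  function() {
    if (is.null(env$map)) {
      codes <- 0:255
      d1 <- codes %/% 64; d2 <- (codes %/% 16) %% 4
      d3 <- (codes %/% 4) %% 4; d4 <- codes %% 4
      rc <- (3 - d4) * 64 + (3 - d3) * 16 + (3 - d2) * 4 + (3 - d1)
      canon <- pmin(codes, rc)
      classes <- sort(unique(canon))
      kmer_name <- paste0(BASES[d1 + 1], BASES[d2 + 1], BASES[d3 + 1], BASES[d4 + 1])
      env$map <- match(canon, classes)        # 256 -> 1..136
      env$names <- kmer_name[classes + 1]
    }
    env
  }
})

#' Names of the 136 canonical tetranucleotide classes
#' @return Character vector of length 136 (lexicographically smaller member of
#'   each 4-mer / reverse-complement pair).
#' @export
tetra_class_names <- function() tetra_space()$names

#' Canonical tetranucleotide frequency profile
#'
#' Slides a 4-bp window (step 1) over the sequence, skips windows containing
#' `N`, merges each 4-mer with its reverse complement into one of 136
#' strand-canonical classes, and normalizes counts to frequencies summing
#' to 1. Contig strand is arbitrary after assembly, so the profile is
#' invariant under reverse complementation. A sequence with no valid window
#' yields an all-zero vector (not an error), which downstream refinement
#' treats as exempt.
#'
#' @param seq A single nucleotide sequence over `ACGTN`.
#' @return Named numeric vector of length 136.
#' @export
tetra_profile <- function(seq) {
  ts <- tetra_space()
  out <- setNames(numeric(136), ts$names)
  v <- seq_to_int(seq)
  n <- length(v)
  if (n < 4) return(out)
  codes <- v[1:(n - 3)] * 64L + v[2:(n - 2)] * 16L + v[3:(n - 1)] * 4L + v[4:n]
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) return(out)
  counts <- tabulate(ts$map[codes + 1L], nbins = 136L)
  out[] <- counts / sum(counts)
  out
}

#' Reverse complement of a nucleotide string
#' @param seq Character vector over `ACGTN`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Per-contig statistics table
#'
#' Joins contig sequences with mapped-read counts and computes, per contig:
#' length, G+C percent, RPKM and the canonical tetranucleotide profile
#' (list-column `tetra`). Contigs absent from the coverage table get zero
#' reads; a coverage row naming an unknown contig is an error. Rows keep the
#' input FASTA order.
#'
#' @param contigs Sequence tibble from [read_fasta()] (nucleotide).
#' @param coverage Coverage tibble from [read_coverage()]; its
#'   `total_mapped_reads` attribute sets the RPKM denominator.
#' @return Tibble `(contig_id, length_bp, gc_percent, mapped_reads, rpkm,
#'   tetra)` with attribute `total_mapped_reads`.
#' @export
contig_stats <- function(contigs, coverage) {
  unknown <- setdiff(coverage$contig_id, contigs$id)
  if (length(unknown) > 0) {
    abort(paste0("coverage row references unknown contig: ", unknown[[1]]))
  }
  total <- coverage_total(coverage)
  reads <- coverage$mapped_reads[match(contigs$id, coverage$contig_id)]
  reads[is.na(reads)] <- 0
  out <- tibble(
    contig_id = contigs$id,
    length_bp = nchar(contigs$sequence),
    gc_percent = gc_percent(contigs$sequence),
    mapped_reads = reads,
    rpkm = rpkm(reads, nchar(contigs$sequence), total),
    tetra = lapply(contigs$sequence, tetra_profile)
  )
  attr(out, "total_mapped_reads") <- total
  out
}

#' Write the per-contig stats table (without the tetra list-column)
#' @param stats Tibble from [contig_stats()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contig_stats <- function(stats, path) {
  readr::write_tsv(select(stats, -"tetra"), path)
  invisible(path)
}
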