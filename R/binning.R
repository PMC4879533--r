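# Bin reconstruction: bubble-chart region selection, tetranucleotide-coherence
# refinement, and single-copy-marker de-duplication. The manual "circled"
# selections of a bubble chart are formalized as closed axis-aligned
# rectangles in (G+C %, RPKM) space, optionally with a contig-length floor.

#' Define a bubble-chart selection region
#'
#' @param gc_min,gc_max Closed G+C bounds in percent, within `[0, 100]`.
#' @param rpkm_min,rpkm_max Closed RPKM bounds; `rpkm_max` may be `Inf`.
#' @param min_contig_length Minimum contig length in bp (default 0).
#' @return A `selection_region` object.
#' @export
selection_region <- function(gc_min, gc_max, rpkm_min = 0, rpkm_max = Inf,
                             min_contig_length = 0) {
  if (gc_min > gc_max) abort("gc_min must be <= gc_max")
  if (rpkm_min > rpkm_max) abort("rpkm_min must be <= rpkm_max")
  if (gc_min < 0 || gc_max > 100) abort("gc bounds must lie in [0, 100]")
  if (rpkm_min < 0) abort("rpkm_min must be >= 0")
  structure(
    list(gc_min = gc_min, gc_max = gc_max, rpkm_min = rpkm_min,
         rpkm_max = rpkm_max, min_contig_length = min_contig_length),
    class = "selection_region"
  )
}

#' @export
print.selection_region <- function(x, ...) {
  cat(sprintf("<selection_region> GC [%g, %g]%%, RPKM [%g, %g], length >= %g bp\n",
              x$gc_min, x$gc_max, x$rpkm_min, x$rpkm_max, x$min_contig_length))
  invisible(x)
}

#' Construct a bin from explicit contig membership
#'
#' Bins normally come from [select_contigs()]; this constructor builds one
#' directly, e.g. when replaying a membership table produced elsewhere.
#'
#' @param bin_id Bin name.
#' @param contig_ids Character vector of member contig ids.
#' @return A `mag_bin` object.
#' @export
mag_bin <- function(bin_id, contig_ids) {
  if (length(contig_ids) == 0) abort("a bin must contain at least one contig")
  if (anyDuplicated(contig_ids)) abort("duplicate contig ids in bin")
  new_bin(bin_id, contig_ids)
}

new_bin <- function(bin_id, contig_ids, refinement_log = NULL) {
  structure(
    list(
      bin_id = bin_id,
      contig_ids = contig_ids,
      refinement_log = refinement_log %||%
        tibble(contig_id = character(0), reason = character(0))
    ),
    class = "mag_bin"
  )
}

#' @export
print.mag_bin <- function(x, ...) {
  cat(sprintf("<mag_bin> %s: %d contigs, %d removed during refinement\n",
              x$bin_id, length(x$contig_ids), nrow(x$refinement_log)))
  invisible(x)
}

#' Tidy a bin into a membership tibble
#' @param x A `mag_bin`.
#' @param ... Unused.
#' @return Tibble `(bin_id, contig_id)`.
#' @export
tidy.mag_bin <- function(x, ...) {
  tibble(bin_id = x$bin_id, contig_id = x$contig_ids)
}

#' One-row summary of a bin
#' @param x A `mag_bin`.
#' @param ... Unused.
#' @return Tibble with bin id, contig count and refinement-removal count.
#' @export
glance.mag_bin <- function(x, ...) {
  tibble(bin_id = x$bin_id, n_contigs = length(x$contig_ids),
         n_removed = nrow(x$refinement_log))
}

#' Select contigs falling in a bubble-chart region
#'
#' Takes the contigs whose `(gc_percent, rpkm, length_bp)` lie inside the
#' closed region (boundary values included). Input order is preserved.
#'
#' @param stats Per-contig stats tibble from [contig_stats()].
#' @param region A [selection_region()].
#' @param bin_id Name for the resulting bin.
#' @return A `mag_bin`.
#' @export
select_contigs <- function(stats, region, bin_id = "bin1") {
  stopifnot(inherits(region, "selection_region"))
  if (nrow(stats) == 0) abort("stats table is empty")
  keep <- stats$gc_percent >= region$gc_min & stats$gc_percent <= region$gc_max &
    stats$rpkm >= region$rpkm_min & stats$rpkm <= region$rpkm_max &
    stats$length_bp >= region$min_contig_length
  if (!any(keep)) abort("region selects no contigs")
  new_bin(bin_id, stats$contig_id[keep])
}

# Pearson correlation of each member profile to the length-weighted mean
# profile of the bin; all-zero profiles get NA (exempt from removal).
bin_tetra_cor <- function(contig_ids, stats) {
  idx <- match(contig_ids, stats$contig_id)
  if (anyNA(idx)) {
    abort(paste0("bin contig missing from stats: ", contig_ids[is.na(idx)][[1]]))
  }
  prof <- do.call(rbind, stats$tetra[idx])
  w <- stats$length_bp[idx]
  nz <- rowSums(prof) > 0
  if (!any(nz)) return(setNames(rep(NA_real_, length(idx)), contig_ids))
  centroid <- colSums(prof[nz, , drop = FALSE] * w[nz]) / sum(w[nz])
  r <- rep(NA_real_, length(idx))
  r[nz] <- suppressWarnings(apply(prof[nz, , drop = FALSE], 1, cor, y = centroid))
  setNames(r, contig_ids)
}

#' Refine a bin by tetranucleotide coherence
#'
#' Iteratively computes the length-weighted mean tetranucleotide profile of
#' the bin and removes the single member with the lowest Pearson correlation
#' to it, provided that correlation falls below `min_correlation`; then
#' recomputes. Stops when no member falls below the threshold, after
#' `max_rounds` removals, or when one contig remains. Contigs with all-zero
#' profiles (no valid 4-bp window) are exempt. Removals are logged with
#' reason `"tetra"`.
#'
#' @param bin A `mag_bin`.
#' @param stats Per-contig stats tibble ([contig_stats()]).
#' @param min_correlation Coherence threshold (default 0.9).
#' @param max_rounds Maximum number of removals (default 10).
#' @return The refined `mag_bin`.
#' @export
refine_by_tetra <- function(bin, stats, min_correlation = 0.9, max_rounds = 10) {
  stopifnot(inherits(bin, "mag_bin"))
  ids <- bin$contig_ids
  log <- bin$refinement_log
  rounds <- 0
  while (length(ids) > 1 && rounds < max_rounds) {
    r <- bin_tetra_cor(ids, stats)
    cand <- which(!is.na(r) & r < min_correlation)
    if (length(cand) == 0) break
    worst <- cand[which.min(r[cand])]
    log <- bind_rows(log, tibble(contig_id = ids[worst], reason = "tetra"))
    ids <- ids[-worst]
    rounds <- rounds + 1
  }
  new_bin(bin$bin_id, ids, log)
}

#' Enforce the single-copy marker rule on a bin
#'
#' A reconstructed bin genome must not carry the same universal single-copy
#' marker on two distinct contigs. While any marker occurs on two or more
#' distinct member contigs, the contig (among those carrying that marker)
#' whose tetranucleotide correlation to the bin's length-weighted mean
#' profile is lowest is removed (ties: shorter contig first, then
#' lexicographically larger contig id). Duplication of a marker within a
#' single contig does not trigger removal but is reported as a warning.
#' Removals are logged with reason `"marker-dup"`.
#'
#' @param bin A `mag_bin`.
#' @param markers Marker tibble ([read_markers()]).
#' @param stats Per-contig stats tibble ([contig_stats()]).
#' @return The de-duplicated `mag_bin`.
#' @export
dedup_markers <- function(bin, markers, stats) {
  stopifnot(inherits(bin, "mag_bin"))
  ids <- bin$contig_ids
  log <- bin$refinement_log
  within_dup <- markers %>%
    filter(.data$contig_id %in% ids) %>%
    count(.data$contig_id, .data$marker_id) %>%
    filter(.data$n > 1)
  if (nrow(within_dup) > 0) {
    warn(sprintf("marker %s occurs %d times within contig %s",
                 within_dup$marker_id[[1]], within_dup$n[[1]],
                 within_dup$contig_id[[1]]))
  }
  repeat {
    mk <- markers %>%
      filter(.data$contig_id %in% ids) %>%
      distinct(.data$contig_id, .data$marker_id)
    dup <- mk %>% count(.data$marker_id) %>% filter(.data$n > 1)
    if (nrow(dup) == 0) break
    r <- bin_tetra_cor(ids, stats)
    m <- dup$marker_id[[1]]
    carriers <- mk$contig_id[mk$marker_id == m]
    ord <- order(
      replace(r[carriers], is.na(r[carriers]), Inf),
      stats$length_bp[match(carriers, stats$contig_id)],
      rank(carriers) * -1
    )
    victim <- carriers[ord[[1]]]
    log <- bind_rows(log, tibble(contig_id = victim, reason = "marker-dup"))
    ids <- setdiff(ids, victim)
  }
  new_bin(bin$bin_id, ids, log)
}

#' Bin membership table for a list of bins
#' @param bins A list of `mag_bin` objects.
#' @return Tibble `(bin_id, contig_id)`.
#' @export
bin_membership <- function(bins) {
  purrr::map_dfr(bins, tidy.mag_bin)
}
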