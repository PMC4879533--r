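# Bin-genome quality metrics: marker completeness, predicted genome size,
# relative read abundance and the per-bin report table.

#' Marker-based completeness of a bin, in percent
#'
#' `100 * (distinct single-copy markers present on any bin contig) /
#' (marker universe size)`. Presence/absence of markers, not copy number,
#' is counted.
#'
#' @param bin A `mag_bin`.
#' @param markers Marker tibble ([read_markers()]); its `marker_universe`
#'   attribute sets the denominator (default 105 markers).
#' @return Completeness percentage in `[0, 100]`.
#' @export
completeness <- function(bin, markers) {
  stopifnot(inherits(bin, "mag_bin"))
  if (length(bin$contig_ids) == 0) abort("bin is empty")
  universe <- marker_universe(markers)
  if (length(universe) == 0) abort("marker universe is empty")
  found <- unique(markers$marker_id[markers$contig_id %in% bin$contig_ids])
  100 * length(found) / length(universe)
}

#' Predicted genome size from bin length and completeness
#'
#' Extrapolates the assembled bin length to full completeness:
#' `(total_length_bp / (completeness_percent/100)) / 1e6` megabases.
#'
#' @param total_length_bp Total bin length in bp.
#' @param completeness_percent Completeness in percent, `> 0`.
#' @return Predicted genome size in Mb (unrounded).
#' @export
#' @examples
#' round(predicted_genome_size(3302713, 98), 2) # 3.37
predicted_genome_size <- function(total_length_bp, completeness_percent) {
  if (any(completeness_percent <= 0)) abort("cannot extrapolate size from completeness 0")
  (total_length_bp / (completeness_percent / 100)) / 1e6
}

#' Relative read abundance of a bin, in percent
#'
#' `100 * (reads mapped to bin contigs) / (total mapped reads)`.
#'
#' @param bin A `mag_bin`.
#' @param coverage Coverage tibble ([read_coverage()]).
#' @return Abundance percentage.
#' @export
relative_abundance <- function(bin, coverage) {
  stopifnot(inherits(bin, "mag_bin"))
  total <- coverage_total(coverage)
  if (total <= 0) abort("total mapped reads must be positive")
  100 * sum(coverage$mapped_reads[coverage$contig_id %in% bin$contig_ids]) / total
}

#' Per-bin quality report
#'
#' Assembles one row per bin: contig count, total length, length-weighted
#' G+C, completeness, predicted genome size, relative abundance, marker
#' counts, and whether the bin passes the reporting threshold of
#' completeness above 70%.
#'
#' @param bins List of `mag_bin` objects.
#' @param stats Per-contig stats tibble ([contig_stats()]).
#' @param markers Marker tibble ([read_markers()]).
#' @param coverage Coverage tibble ([read_coverage()]).
#' @param completeness_threshold Reporting threshold in percent (default 70).
#' @return Tibble `(bin_id, n_contigs, total_length_bp, gc_percent,
#'   completeness_percent, predicted_size_mb, relative_abundance_percent,
#'   n_markers_found, n_markers_duplicated, passes_70pct)`, unrounded;
#'   see [format_quality_report()] for display rounding.
#' @export
bin_quality <- function(bins, stats, markers, coverage,
                        completeness_threshold = 70) {
  purrr::map_dfr(bins, function(bin) {
    idx <- match(bin$contig_ids, stats$contig_id)
    if (anyNA(idx)) {
      abort(paste0("bin contig missing from stats: ",
                   bin$contig_ids[is.na(idx)][[1]]))
    }
    len <- stats$length_bp[idx]
    comp <- completeness(bin, markers)
    mk <- markers %>%
      filter(.data$contig_id %in% bin$contig_ids) %>%
      distinct(.data$contig_id, .data$marker_id) %>%
      count(.data$marker_id)
    tibble(
      bin_id = bin$bin_id,
      n_contigs = length(bin$contig_ids),
      total_length_bp = sum(len),
      gc_percent = sum(stats$gc_percent[idx] * len) / sum(len),
      completeness_percent = comp,
      predicted_size_mb = if (comp > 0) predicted_genome_size(sum(len), comp) else NA_real_,
      relative_abundance_percent = relative_abundance(bin, coverage),
      n_markers_found = nrow(mk),
      n_markers_duplicated = sum(mk$n > 1),
      passes_70pct = comp > completeness_threshold
    )
  })
}

#' Round a quality report for display
#'
#' Table-style display rounding: megabases to 2 decimals, percentages to 1.
#' Internal values stay unrounded in [bin_quality()].
#'
#' @param report Tibble from [bin_quality()].
#' @return The report with rounded display columns.
#' @export
format_quality_report <- function(report) {
  report %>%
    mutate(
      gc_percent = round(.data$gc_percent, 1),
      completeness_percent = round(.data$completeness_percent, 1),
      predicted_size_mb = round(.data$predicted_size_mb, 2),
      relative_abundance_percent = round(.data$relative_abundance_percent, 1)
    )
}
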