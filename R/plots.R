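# Plot helpers. Plots are never load-bearing: every figure's underlying data
# is available as a tibble or TSV.

#' Bubble chart of contigs in (G+C, RPKM) space
#'
#' The binning view: each contig is a bubble at its G+C percent and RPKM,
#' sized by length. Optionally colour by bin membership or truth labels, and
#' overlay selection rectangles.
#'
#' @param stats Per-contig stats tibble ([contig_stats()]).
#' @param groups Optional tibble `(contig_id, <group column>)`, e.g. bin
#'   membership from [bin_membership()] or simulation truth labels.
#' @param regions Optional named list of [selection_region()] objects drawn
#'   as rectangles.
#' @param log_rpkm Use a log10 y axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_bubble <- function(stats, groups = NULL, regions = NULL, log_rpkm = TRUE) {
  df <- select(stats, "contig_id", "gc_percent", "rpkm", "length_bp")
  if (!is.null(groups)) {
    grp_col <- setdiff(names(groups), "contig_id")[[1]]
    df <- left_join(df, groups, by = "contig_id") %>%
      rename(group = dplyr::all_of(grp_col))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gc_percent, y = .data$rpkm)) +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$length_bp,
                   colour = if (is.null(groups)) NULL else .data$group),
      alpha = 0.6
    ) +
    ggplot2::scale_size_area(name = "Contig length (bp)") +
    ggplot2::labs(x = "G+C content (%)", y = "RPKM",
                  colour = if (is.null(groups)) NULL else "Group") +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    rects <- purrr::imap_dfr(regions, function(r, id) {
      tibble(bin_id = id, xmin = r$gc_min, xmax = r$gc_max,
             ymin = max(r$rpkm_min, if (log_rpkm) 1e-3 else 0),
             ymax = if (is.finite(r$rpkm_max)) r$rpkm_max else max(df$rpkm) * 1.5)
    })
    p <- p + ggplot2::geom_rect(
      data = rects, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = NA, colour = "grey30", linetype = 2
    )
  }
  if (log_rpkm) p <- p + ggplot2::scale_y_log10()
  p
}

#' Bar chart of Venn region gene counts
#'
#' @param counts Tibble from [venn_counts()].
#' @return A ggplot object.
#' @export
plot_venn_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$region, -.data$n_genes),
                                       y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Venn region (genomes sharing the gene)", y = "CDS count") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrapped NJ tree
#'
#' Unrooted layout with bootstrap supports over 50 shown at branching points,
#' matching the usual display rule for such trees.
#'
#' @param x An `nj_boot` object.
#' @param show_threshold Only supports strictly greater than this are drawn
#'   (default 50).
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.nj_boot <- function(x, show_threshold = 50, ...) {
  tree <- x$tree
  lab <- suppressWarnings(as.numeric(tree$node.label))
  tree$node.label <- ifelse(!is.na(lab) & lab > show_threshold, tree$node.label, "")
  ape::plot.phylo(tree, type = "unrooted", ...)
  ape::nodelabels(tree$node.label, frame = "none", adj = c(1.1, -0.4))
  invisible(x)
}
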