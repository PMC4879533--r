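# Workflow entry points wiring the modules together. Each takes a run
# configuration (a YAML file path or an equivalent named list), writes plain
# TSV/FASTA/Newick outputs under `out_dir`, and returns its main result
# invisibly. A thin Rscript wrapper with subcommands lives at
# `system.file("cli", "magbinr.R", package = "magbinr")`.

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  config
}

need <- function(config, field) {
  if (is.null(config[[field]])) abort(paste0("config is missing required field: ", field))
  config[[field]]
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

#' Compute and write per-contig bubble-chart data
#'
#' Config fields: `contigs` (nucleotide FASTA), `coverage` (count TSV),
#' `out_dir`. Writes `contig_stats.tsv` with the bubble-chart coordinates
#' (G+C %, RPKM) plus length and read count per contig.
#'
#' @param config YAML path or named list.
#' @return The stats tibble, invisibly.
#' @export
run_stats <- function(config) {
  config <- load_config(config)
  contigs <- read_fasta(need(config, "contigs"), "nucleotide")
  if (nrow(contigs) == 0) abort("contig FASTA is empty")
  coverage <- read_coverage(need(config, "coverage"))
  stats <- contig_stats(contigs, coverage)
  out <- ensure_dir(need(config, "out_dir"))
  write_contig_stats(stats, file.path(out, "contig_stats.tsv"))
  invisible(stats)
}

parse_regions <- function(regions) {
  purrr::map(regions, function(r) {
    selection_region(
      gc_min = r$gc_min, gc_max = r$gc_max,
      rpkm_min = r$rpkm_min %||% 0, rpkm_max = r$rpkm_max %||% Inf,
      min_contig_length = r$min_contig_length %||% 0
    )
  })
}

#' Run binning: region selection, tetra refinement, marker dedup, quality
#'
#' Config fields: `contigs`, `coverage`, `markers` (TSVs), `out_dir`,
#' `regions` (a named list, one entry per bin, each with `gc_min`, `gc_max`
#' and optional `rpkm_min`, `rpkm_max`, `min_contig_length`), optional
#' `min_tetra_correlation` (default 0.9), `max_refine_rounds` (default 10),
#' `marker_universe_size` (default 105). Writes `bin_membership.tsv`,
#' `refinement_log.tsv` and `bin_quality.tsv`.
#'
#' @param config YAML path or named list.
#' @return List with `bins` and the `quality` tibble, invisibly.
#' @export
run_bin <- function(config) {
  config <- load_config(config)
  contigs <- read_fasta(need(config, "contigs"), "nucleotide")
  coverage <- read_coverage(need(config, "coverage"))
  universe <- default_marker_universe(config$marker_universe_size %||% 105L)
  markers <- read_markers(need(config, "markers"), universe)
  stats <- contig_stats(contigs, coverage)
  regions <- parse_regions(need(config, "regions"))
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    abort("each region must be named by its bin_id")
  }
  min_cor <- config$min_tetra_correlation %||% 0.9
  rounds <- config$max_refine_rounds %||% 10
  bins <- purrr::imap(regions, function(region, bin_id) {
    select_contigs(stats, region, bin_id) %>%
      refine_by_tetra(stats, min_correlation = min_cor, max_rounds = rounds) %>%
      dedup_markers(markers, stats)
  })
  quality <- bin_quality(bins, stats, markers, coverage)
  out <- ensure_dir(need(config, "out_dir"))
  readr::write_tsv(bin_membership(bins), file.path(out, "bin_membership.tsv"))
  readr::write_tsv(
    purrr::map_dfr(bins, ~ mutate(.x$refinement_log, bin_id = .x$bin_id, .before = 1)),
    file.path(out, "refinement_log.tsv")
  )
  readr::write_tsv(format_quality_report(quality), file.path(out, "bin_quality.tsv"))
  invisible(list(bins = bins, quality = quality))
}

#' Run the three-genome BBH / Venn comparison
#'
#' Config fields: `proteins` (named list of three protein FASTA paths, names
#' are genome ids), `out_dir`, optional `min_score` (internal-alignment score
#' threshold, default 60), `dedup_identity` (default 90), or `hits` (named
#' list of six tabular hit files `"A|B"`, `"B|A"`, ... to use import mode at
#' the 1e-5 E-value threshold instead of internal alignment; paralog dedup is
#' skipped in import mode as external pipelines de-duplicate upstream).
#' Writes `bbh_pairs.tsv`, `venn_membership.tsv` and `venn_counts.tsv`.
#'
#' @param config YAML path or named list.
#' @return List with `pairs`, `partition` and `counts`, invisibly.
#' @export
run_compare <- function(config) {
  config <- load_config(config)
  paths <- need(config, "proteins")
  if (length(paths) != 3 || is.null(names(paths))) {
    abort("config$proteins must name exactly three genomes")
  }
  genomes <- names(paths)
  prot <- purrr::map(paths, read_fasta, kind = "protein")
  empty <- purrr::map_int(prot, nrow) == 0
  if (any(empty)) abort(paste0("protein set is empty: ", genomes[empty][[1]]))
  combos <- utils::combn(genomes, 2, simplify = FALSE)
  if (!is.null(config$hits)) {
    max_e <- config$max_evalue %||% 1e-5
    pairs <- purrr::map(combos, function(gg) {
      ab <- read_blast_tab(config$hits[[paste(gg[1], gg[2], sep = "|")]],
                           gg[1], gg[2], max_e)
      ba <- read_blast_tab(config$hits[[paste(gg[2], gg[1], sep = "|")]],
                           gg[2], gg[1], max_e)
      bbh_pairs(ab, ba)
    })
  } else {
    min_score <- config$min_score %||% 60
    ident <- config$dedup_identity %||% 90
    prot <- purrr::map(prot, dedup_paralogs, min_identity = ident)
    pairs <- purrr::map(combos, function(gg) {
      a <- prot[[gg[1]]]; b <- prot[[gg[2]]]
      bbh_pairs(
        all_vs_all(a, b, gg[1], gg[2], min_score = min_score),
        all_vs_all(b, a, gg[2], gg[1], min_score = min_score)
      )
    })
  }
  partition <- venn_partition(prot, pairs)
  counts <- venn_counts(partition)
  out <- ensure_dir(need(config, "out_dir"))
  readr::write_tsv(bind_rows(pairs), file.path(out, "bbh_pairs.tsv"))
  readr::write_tsv(partition, file.path(out, "venn_membership.tsv"))
  readr::write_tsv(counts, file.path(out, "venn_counts.tsv"))
  invisible(list(pairs = pairs, partition = partition, counts = counts))
}

#' Run NJ tree construction with bootstrap
#'
#' Config fields: `alignment` (aligned FASTA), `out_dir`, optional `kind`
#' (`"protein"` default), `n_replicates` (default 100), `seed` (default 1),
#' `correction` (`"none"` or `"poisson"`), `pairwise_deletion` (default
#' true). Writes `tree.nwk` (supports as internal node labels) and
#' `supports.tsv` (with the shown/hidden flag at the >50 display rule).
#'
#' @param config YAML path or named list.
#' @return The `nj_boot` object, invisibly.
#' @export
run_tree <- function(config) {
  config <- load_config(config)
  aln <- read_fasta(need(config, "alignment"), config$kind %||% "protein")
  if (nrow(aln) < 3) abort("tree construction needs at least 3 taxa")
  boot <- nj_bootstrap(
    aln,
    n_replicates = config$n_replicates %||% 100,
    seed = config$seed %||% 1,
    pairwise_deletion = config$pairwise_deletion %||% TRUE,
    correction = config$correction %||% "none"
  )
  out <- ensure_dir(need(config, "out_dir"))
  write_newick(boot$tree, file.path(out, "tree.nwk"))
  readr::write_tsv(boot$support, file.path(out, "supports.tsv"))
  invisible(boot)
}

#' Simulate a community and write its files
#'
#' Config fields: `genomes` (list of entries with `genome_id`, `length_bp`,
#' `gc_percent`, `abundance`), `out_dir`, optional `total_reads`, `seed`, and
#' protein-set fields `n_core`, `n_accessory`, `mutation_rate`. Writes
#' `contigs.fasta`, `coverage.tsv`, `markers.tsv`, `truth.tsv` and one
#' `proteins_<genome>.faa` per genome.
#'
#' @param config YAML path or named list.
#' @return The community list, invisibly.
#' @export
run_simulate <- function(config) {
  config <- load_config(config)
  gl <- need(config, "genomes")
  genomes <- purrr::map_dfr(gl, ~ tibble(
    genome_id = .x$genome_id, length_bp = .x$length_bp,
    gc_percent = .x$gc_percent, abundance = .x$abundance
  ))
  seed <- config$seed %||% 1
  comm <- simulate_community(
    genomes,
    total_reads = config$total_reads %||% 2e5,
    min_contig_length = config$min_contig_length %||% 1000,
    seed = seed
  )
  out <- ensure_dir(need(config, "out_dir"))
  write_fasta(comm$contigs, file.path(out, "contigs.fasta"))
  write_coverage(comm$coverage, file.path(out, "coverage.tsv"))
  readr::write_tsv(comm$markers, file.path(out, "markers.tsv"))
  readr::write_tsv(comm$truth, file.path(out, "truth.tsv"))
  prot <- simulate_protein_sets(
    genomes$genome_id,
    n_core = config$n_core %||% 20,
    n_accessory = config$n_accessory %||% 5,
    mutation_rate = config$mutation_rate %||% 0.05,
    seed = seed + 1
  )
  for (g in names(prot$proteins)) {
    write_fasta(prot$proteins[[g]], file.path(out, sprintf("proteins_%s.faa", g)))
  }
  invisible(c(comm, list(proteins = prot$proteins, protein_truth = prot$truth)))
}
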