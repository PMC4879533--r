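# small deterministic stats table builder for selection tests
toy_stats <- function() {
  tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c4"),
    length_bp = c(2000, 3000, 1500, 800),
    gc_percent = c(63.1, 48.9, 66.0, 62.0),
    mapped_reads = c(100, 500, 20, 5),
    rpkm = c(9.9, 17.4, 5.0, 1.2),
    tetra = replicate(4, tetra_profile("ACGTACGTAC"), simplify = FALSE)
  )
}

test_that("select_contigs applies closed bounds and preserves order", {
  st <- toy_stats()
  bin <- select_contigs(st, selection_region(60, 66, 5, Inf), "b")
  expect_equal(bin$contig_ids, c("c1", "c3")) # c2 wrong GC, c4 low RPKM

  all_bin <- select_contigs(st, selection_region(0, 100), "all")
  expect_equal(all_bin$contig_ids, st$contig_id)

  # boundary contig at gc_max is included (closed interval)
  edge <- select_contigs(st, selection_region(48.9, 48.9, 0, Inf), "edge")
  expect_equal(edge$contig_ids, "c2")

  expect_error(select_contigs(st, selection_region(90, 95), "none"),
               "selects no contigs")
  expect_error(selection_region(66, 60), "gc_min")
})

test_that("nested regions select nested bins (monotonicity)", {
  genomes <- tibble::tibble(genome_id = "g1", length_bp = 3e5,
                            gc_percent = 50, abundance = 1)
  comm <- simulate_community(genomes, seed = 5)
  st <- contig_stats(comm$contigs, comm$coverage)
  inner <- select_contigs(st, selection_region(49, 51, 0, Inf), "in")
  outer <- select_contigs(st, selection_region(45, 55, 0, Inf), "out")
  expect_true(all(inner$contig_ids %in% outer$contig_ids))
})

test_that("tetra refinement removes alien contigs and is idempotent", {
  # 9 contigs from one genome + 1 from a compositionally distant genome
  ga <- simulate_genome("a", 2e5, 42, seed = 21)
  gb <- simulate_genome("b", 3e4, 65, seed = 22)
  frag <- function(g, n) {
    l <- nchar(g) %/% n
    vapply(seq_len(n), function(i) substr(g, (i - 1) * l + 1, i * l), "")
  }
  seqs <- c(frag(ga, 9), substr(gb, 1, 2e4))
  contigs <- tibble::tibble(id = sprintf("c%02d", 1:10), description = "",
                            sequence = seqs)
  cov <- tibble::tibble(contig_id = contigs$id, mapped_reads = rep(10, 10))
  st <- contig_stats(contigs, cov)

  bin <- mag_bin("test", contigs$id)
  refined <- refine_by_tetra(bin, st, min_correlation = 0.9)
  expect_equal(setdiff(bin$contig_ids, refined$contig_ids), "c10")
  expect_equal(refined$refinement_log$reason, "tetra")

  # idempotence: a second pass changes nothing
  again <- refine_by_tetra(refined, st, min_correlation = 0.9)
  expect_equal(again$contig_ids, refined$contig_ids)

  # a pure bin is a no-op
  pure <- refine_by_tetra(mag_bin("test", contigs$id[1:9]), st)
  expect_equal(pure$contig_ids, contigs$id[1:9])

  # single-contig bin unchanged
  single <- refine_by_tetra(mag_bin("test", "c01"), st)
  expect_equal(single$contig_ids, "c01")
})

test_that("dedup_markers enforces at most one contig per marker", {
  ga <- simulate_genome("a", 1.2e5, 50, seed = 31)
  gb <- simulate_genome("b", 2e4, 68, seed = 32)
  frag <- function(g, n) {
    l <- nchar(g) %/% n
    vapply(seq_len(n), function(i) substr(g, (i - 1) * l + 1, i * l), "")
  }
  contigs <- tibble::tibble(id = sprintf("c%02d", 1:7), description = "",
                            sequence = c(frag(ga, 6), substr(gb, 1, 2e4)))
  cov <- tibble::tibble(contig_id = contigs$id, mapped_reads = rep(10, 7))
  st <- contig_stats(contigs, cov)
  bin <- mag_bin("test", contigs$id)

  # distinct markers: unchanged
  mk0 <- tibble::tibble(contig_id = c("c01", "c02"),
                        marker_id = c("USCG_001", "USCG_002"))
  attr(mk0, "marker_universe") <- default_marker_universe()
  expect_equal(dedup_markers(bin, mk0, st)$contig_ids, bin$contig_ids)

  # duplicated marker on the alien contig c07: c07 correlates worse -> removed
  mk1 <- tibble::tibble(contig_id = c("c01", "c07"),
                        marker_id = c("USCG_001", "USCG_001"))
  attr(mk1, "marker_universe") <- default_marker_universe()
  dd <- dedup_markers(bin, mk1, st)
  expect_false("c07" %in% dd$contig_ids)
  expect_true("c01" %in% dd$contig_ids)
  expect_equal(dd$refinement_log$reason, "marker-dup")

  # two copies within ONE contig: contig retained, warning raised
  mk2 <- tibble::tibble(contig_id = c("c01", "c01"),
                        marker_id = c("USCG_001", "USCG_001"))
  attr(mk2, "marker_universe") <- default_marker_universe()
  expect_warning(dd2 <- dedup_markers(bin, mk2, st), "within contig")
  expect_true("c01" %in% dd2$contig_ids)

  # end condition holds regardless of how tangled the duplication is
  set.seed(9)
  mk3 <- tibble::tibble(
    contig_id = sample(contigs$id, 30, replace = TRUE),
    marker_id = sample(default_marker_universe(10), 30, replace = TRUE)
  ) |> dplyr::distinct()
  attr(mk3, "marker_universe") <- default_marker_universe()
  dd3 <- dedup_markers(bin, mk3, st)
  per_marker <- mk3 |>
    dplyr::filter(contig_id %in% dd3$contig_ids) |>
    dplyr::distinct(contig_id, marker_id) |>
    dplyr::count(marker_id)
  expect_true(all(per_marker$n <= 1))
})

test_that("bin tidiers expose membership and summary", {
  b <- mag_bin("binZ", c("c1", "c2"))
  td <- tidy(b)
  expect_equal(td$bin_id, c("binZ", "binZ"))
  expect_equal(td$contig_id, c("c1", "c2"))
  expect_equal(glance(b)$n_contigs, 2)
  expect_equal(bin_membership(list(b))$contig_id, c("c1", "c2"))
})
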