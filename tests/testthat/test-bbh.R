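test_that("align_score is a symmetric local alignment score", {
  expect_equal(align_score("A", "A"), 4) # BLOSUM62 diagonal for Ala
  s <- "MKVLAWWTEYR"
  diag_sum <- sum(vapply(strsplit(s, "")[[1]],
                         function(a) align_score(a, a), numeric(1)))
  expect_equal(align_score(s, s), diag_sum)
  set.seed(11)
  for (i in 1:5) {
    a <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30, TRUE), collapse = "")
    b <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 25, TRUE), collapse = "")
    expect_equal(align_score(a, b), align_score(b, a))
  }
  expect_error(align_score("MK", "MK", matrix_name = "NOTAMATRIX"),
               "unknown substitution matrix")
  expect_error(align_score("", "MK"), "non-empty")
})

test_that("all_vs_all scores every pair and applies the threshold", {
  a <- tibble::tibble(id = "x1", sequence = "MKVLAWWTEYRMKVLAWWTEYR")
  b <- tibble::tibble(id = "y1", sequence = "MKVLAWWTEYRMKVLAWWTEYR")
  one <- all_vs_all(a, b, "A", "B", min_score = 10)
  expect_equal(nrow(one), 1)
  expect_equal(one$query_id, "x1")

  none <- all_vs_all(a, tibble::tibble(id = "y2", sequence = "GGGG"),
                     "A", "B", min_score = 1e6)
  expect_equal(nrow(none), 0)

  # equals a brute-force double loop over align_score
  set.seed(4)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pa <- tibble::tibble(id = sprintf("p%d", 1:6),
                       sequence = replicate(6, paste(sample(aa, 40, TRUE), collapse = "")))
  pb <- tibble::tibble(id = sprintf("q%d", 1:5),
                       sequence = replicate(5, paste(sample(aa, 40, TRUE), collapse = "")))
  hits <- all_vs_all(pa, pb, "A", "B", min_score = -Inf)
  for (k in sample(nrow(hits), 8)) {
    expect_equal(hits$score[k],
                 align_score(pa$sequence[pa$id == hits$query_id[k]],
                             pb$sequence[pb$id == hits$subject_id[k]]))
  }
})

test_that("dedup_paralogs collapses near-identical proteins by single linkage", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(12)
  base <- paste(sample(aa, 120, TRUE), collapse = "")
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), k)
    for (i in pos) v[i] <- sample(setdiff(aa, v[i]), 1)
    paste(v, collapse = "")
  }
  distinct <- tibble::tibble(
    id = c("u1", "u2"),
    sequence = c(base, paste(sample(aa, 120, TRUE), collapse = ""))
  )
  expect_equal(dedup_paralogs(distinct), distinct)

  twins <- tibble::tibble(id = c("t1", "t2"), sequence = c(base, base))
  expect_equal(dedup_paralogs(twins)$id, "t1") # tie on length -> smallest id

  # chain a~b, b~c with a,c more diverged: single linkage keeps one survivor
  a <- base
  b <- mut(base, 8)   # ~93% identical to both neighbours
  cc <- mut(b, 8)
  chain <- tibble::tibble(id = c("a", "b", "c"), sequence = c(a, b, cc))
  surv <- dedup_paralogs(chain, min_identity = 90)
  expect_equal(nrow(surv), 1)
})

test_that("bbh pairing handles mutual, asymmetric and empty cases", {
  M <- matrix(c(10, 1, 1, 8), 2) # mutual bests on the diagonal
  p <- bbh_pairs(mat_to_hits(M, "ab"), mat_to_hits(M, "ba"))
  expect_equal(paste(p$id_a, p$id_b), c("a01 b01", "a02 b02"))

  # x's best is y but y's best is z != x -> no pair for x
  M2 <- rbind(c(5, 0), c(9, 0)) # a1 -> b1, but b1 -> a2
  p2 <- bbh_pairs(mat_to_hits(M2, "ab"), mat_to_hits(M2, "ba"))
  expect_equal(paste(p2$id_a, p2$id_b), "a02 b01")

  empty <- mat_to_hits(M)[0, ]
  expect_equal(nrow(bbh_pairs(empty, mat_to_hits(M, "ba"))), 0)
})

test_that("bbh pairing is an involution under genome-role swap", {
  set.seed(33)
  for (i in 1:20) {
    M <- matrix(sample(1:50, 30, TRUE), 5, 6)
    fwd <- bbh_pairs(mat_to_hits(M, "ab"), mat_to_hits(M, "ba"))
    swapped <- bbh_pairs(mat_to_hits(t(M), "ab"), mat_to_hits(t(M), "ba"))
    # swapping roles transposes the pair set (modulo the a/b id prefixes)
    expect_equal(sort(paste(sub("b", "", fwd$id_b), sub("a", "", fwd$id_a))),
                 sort(paste(sub("a", "", swapped$id_a), sub("b", "", swapped$id_b))))
  }
})

test_that("evalue breaks score ties before subject id", {
  ab <- tibble::tibble(query_genome = "A", query_id = "a01",
                       subject_genome = "B", subject_id = c("b01", "b02"),
                       score = c(7, 7), evalue = c(1e-3, 1e-9))
  ba <- tibble::tibble(query_genome = "B", query_id = c("b01", "b02"),
                       subject_genome = "A", subject_id = "a01",
                       score = c(7, 7), evalue = c(1e-3, 1e-9))
  p <- bbh_pairs(ab, ba)
  expect_equal(p$id_b, "b02") # lower E-value wins despite larger id
})

test_that("venn partition assigns per-gene regions that tile each genome", {
  mk <- function(ids) tibble::tibble(id = ids, sequence = strrep("M", 10))
  prot <- list(X = mk(c("x1", "x2")), Y = mk("y1"), Z = mk("z1"))

  # no cross hits: three exclusive regions
  none <- tibble::tibble(genome_a = character(0), id_a = character(0),
                         genome_b = character(0), id_b = character(0))
  vp0 <- venn_partition(prot, list(none, none, none))
  expect_equal(sort(unique(vp0$region)), c("X", "Y", "Z"))
  expect_equal(nrow(vp0), 4)

  # x1 paired into both Y and Z lands in the triple region
  pxy <- tibble::tibble(genome_a = "X", id_a = "x1", genome_b = "Y", id_b = "y1")
  pxz <- tibble::tibble(genome_a = "X", id_a = "x1", genome_b = "Z", id_b = "z1")
  vp <- venn_partition(prot, list(pxy, pxz, none))
  expect_equal(vp$region[vp$protein_id == "x1"], "X&Y&Z")
  expect_equal(vp$region[vp$protein_id == "x2"], "X")
  # regions partition each genome's gene set exactly
  expect_equal(nrow(vp), sum(vapply(prot, nrow, integer(1))))
  cnt <- venn_counts(vp)
  expect_equal(sum(cnt$n_genes), nrow(vp))
})

test_that("import mode reads 12-column hit tables at the 1e-5 threshold", {
  lines <- c(
    "q1\ts1\t98.5\t100\t2\t0\t1\t100\t1\t100\t1e-30\t200",
    "q1\ts2\t40.0\t80\t40\t3\t1\t80\t1\t80\t0.01\t35",
    "q2\ts2\t90.0\t90\t9\t1\t1\t90\t1\t90\t1e-6\t150"
  )
  path <- write_tmp(lines, ".tsv")
  hits <- read_blast_tab(path, "A", "B")
  expect_equal(nrow(hits), 2) # the 0.01 E-value row is dropped
  expect_equal(hits$score, c(200, 150))
  expect_equal(hits$query_genome, c("A", "A"))
})
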