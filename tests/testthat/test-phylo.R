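test_that("p_distance counts differing sites with pairwise deletion", {
  expect_equal(p_distance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  # "A-CD" vs "AB-D": only sites 1 and 4 comparable, both equal
  expect_equal(p_distance(c(a = "A-CD", b = "AB-D"))["a", "b"], 0)
  # complete deletion removes gapped columns for all pairs
  d <- p_distance(c(a = "A-CD", b = "ABCD", c = "TBCD"), pairwise_deletion = FALSE)
  expect_equal(d["a", "b"], 0)      # compares CD only
  expect_equal(d["b", "c"], 1 / 3)  # compares BCD
  expect_error(p_distance(c(a = "--", b = "AA")), "no comparable sites")
  # Poisson correction
  dp <- p_distance(c(a = "AAAA", b = "AATT"), correction = "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.5))
})

test_that("nj limb lengths match the three-taxon closed form", {
  dm <- matrix(c(0, 7, 8, 7, 0, 9, 8, 9, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (7 + 8 - 9) / 2)
  expect_equal(lens[["B"]], (7 + 9 - 8) / 2)
  expect_equal(lens[["C"]], (8 + 9 - 7) / 2)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("nj recovers random additive matrices exactly", {
  for (seed in 1:25) {
    n <- 4 + (seed %% 7)
    fix <- random_additive(n, seed)
    tr <- nj_tree(fix$D)
    expect_equal(length(tr$tip.label), n)
    expect_equal(nrow(tr$edge), 2 * n - 3) # unrooted binary edge count
    coph <- ape::cophenetic.phylo(tr)[rownames(fix$D), colnames(fix$D)]
    expect_lt(max(abs(coph - fix$D)), 1e-9)
    expect_equal(ape::dist.topo(tr, fix$tree), 0, ignore_attr = TRUE)
  }
})

test_that("nj agrees with the independent ape implementation", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    D <- as.matrix(stats::dist(matrix(runif(n * 3), n)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
    ours <- nj_tree(D)
    theirs <- ape::nj(D)
    expect_equal(ape::dist.topo(ours, theirs), 0, ignore_attr = TRUE)
    ord <- rownames(D)
    expect_equal(ape::cophenetic.phylo(ours)[ord, ord],
                 ape::cophenetic.phylo(theirs)[ord, ord], tolerance = 1e-8)
  }
})

test_that("four-taxon nj picks the quartet satisfying the four-point condition", {
  for (seed in 101:120) {
    fix <- random_additive(4, seed)
    D <- fix$D
    lb <- rownames(D)
    # brute force over the 3 unrooted quartet topologies: the true split
    # minimizes the sum of within-pair distances
    sums <- c(
      "12|34" = D[1, 2] + D[3, 4],
      "13|24" = D[1, 3] + D[2, 4],
      "14|23" = D[1, 4] + D[2, 3]
    )
    best <- names(which.min(sums))
    tr <- nj_tree(D)
    bip <- magbinr:::tree_bipartitions(tr)
    expect_length(bip, 1)
    pair <- switch(best,
      "12|34" = sort(c(lb[1], lb[2])),
      "13|24" = sort(c(lb[1], lb[3])),
      "14|23" = sort(c(lb[1], lb[4]))
    )
    anchor <- sort(lb)[1]
    side <- if (anchor %in% pair) sort(setdiff(lb, pair)) else pair
    expect_equal(bip, paste(side, collapse = "|"))
  }
})

test_that("taxon order does not change the nj tree", {
  fix <- random_additive(7, 5)
  D <- fix$D
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  tr1 <- nj_tree(D)
  tr2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
  ord <- rownames(D)
  expect_equal(ape::cophenetic.phylo(tr1)[ord, ord],
               ape::cophenetic.phylo(tr2)[ord, ord], tolerance = 1e-9)
})

test_that("negative nj branch lengths are clamped to zero with a warning", {
  D <- matrix(c(0, 1, 1, 4,
                1, 0, 1, 4,
                1, 1, 0, 1,
                4, 4, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- nj_tree(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports behave at the degenerate extremes", {
  # every column supports the same split -> support 100
  aln <- c(A = paste0(strrep("A", 28), "GC"), B = paste0(strrep("A", 28), "CG"),
           C = paste0(strrep("T", 28), "GG"), D = paste0(strrep("T", 28), "CC"))
  nb <- nj_bootstrap(aln, n_replicates = 50, seed = 8)
  expect_equal(nb$support$percent[nb$support$bipartition == "C|D"], 100)

  # a single replicate can only give 0 or 100
  nb1 <- nj_bootstrap(aln, n_replicates = 1, seed = 3)
  expect_true(all(nb1$support$percent %in% c(0, 100)))

  # fixed seed -> identical supports; different seed may differ
  nb2 <- nj_bootstrap(aln, n_replicates = 50, seed = 8)
  expect_identical(nb$support, nb2$support)

  # the >50 display rule is a flag, not a filter
  expect_named(nb$support, c("bipartition", "count", "percent", "shown"))
  expect_equal(nb$support$shown, nb$support$percent > 50)
  expect_equal(glance(nb)$n_replicates, 50)
  expect_equal(nrow(tidy(nb)), length(aln) - 3)
})
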