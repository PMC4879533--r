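# Neighbor-joining phylogeny with bootstrap over pre-aligned sequences.
# Distances are uncorrected p-distances (optional Poisson correction for
# amino acids); NJ follows Saitou-Nei with the Studier-Keppler Q-criterion,
# deterministic tie-breaking and MEGA-style clamping of negative branch
# lengths to zero.

aln_matrix <- function(aln) {
  if (is.data.frame(aln)) {
    seqs <- setNames(aln$sequence, aln$id)
  } else {
    seqs <- aln
  }
  if (length(unique(nchar(seqs))) != 1) abort("aligned sequences must share one length")
  if (length(seqs) < 2) abort("alignment needs at least 2 sequences")
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Pairwise p-distances from an alignment
#'
#' `d[i,j]` = differing sites / compared sites. Sites holding a gap (`-`),
#' `X`, `?` or (for nucleotides) `N` in either sequence of a pair are skipped
#' under pairwise deletion (the default); under complete deletion such sites
#' are removed for all pairs. An optional Poisson correction
#' `-ln(1 - p)` for amino-acid saturation can be applied.
#'
#' @param aln Aligned sequences: a tibble (`id`, `sequence`) from
#'   [read_fasta()] or a named character vector; all the same length.
#' @param pairwise_deletion Logical (default `TRUE`).
#' @param correction `"none"` (p-distance, default) or `"poisson"`.
#' @return A labeled symmetric distance matrix.
#' @export
p_distance <- function(aln, pairwise_deletion = TRUE,
                       correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- aln_matrix(aln)
  labels <- rownames(m)
  missing_chars <- c("-", "X", "?", "N", ".")
  valid <- !matrix(m %in% missing_chars, nrow = nrow(m))
  if (!pairwise_deletion) {
    keep <- apply(valid, 2, all)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) {
        abort(sprintf("no comparable sites between %s and %s", labels[i], labels[j]))
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (correction == "poisson") {
        if (p >= 1) abort(sprintf("saturated pair %s / %s (p = 1)", labels[i], labels[j]))
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step join the pair `(i, j)`
#' minimizing `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` with `r(i) = sum_k
#' d(i,k)`; limb lengths by the usual formulas, negative lengths clamped to 0
#' with a warning. A tie in Q joins the lexicographically smallest label
#' pair. Exact on additive (tree-metric) distances.
#'
#' @param dm Symmetric distance matrix with row/column labels (n >= 3), or a
#'   `dist` object.
#' @return An unrooted binary `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  if (any(abs(dm - t(dm)) > 1e-12)) abort("distance matrix must be symmetric")

  labels <- rownames(dm)
  ntip <- n
  # node ids: tips 1..n in input label order; internals n+1, n+2, ...
  node_of <- seq_len(n)
  node_lab <- labels            # current display label per active row
  next_internal <- ntip + 1L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  D <- dm
  clamped <- FALSE

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    if (len < -1e-12) clamped <<- TRUE
    lens <<- c(lens, max(len, 0))
  }

  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pair <- sort(c(node_lab[cand[k, 1]], node_lab[cand[k, 2]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    u <- next_internal
    next_internal <- next_internal + 1L
    add_edge(u, node_of[i], li)
    add_edge(u, node_of[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, du), c(du, 0))
    keep <- setdiff(seq_len(m + 1), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    node_of <- c(node_of, u)[keep]
    node_lab <- c(node_lab, paste0("#", u))[keep]
  }

  # final three-way join
  root <- next_internal
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  add_edge(root, node_of[1], l1)
  add_edge(root, node_of[2], l2)
  add_edge(root, node_of[3], l3)
  if (clamped) warn("negative branch length(s) clamped to 0")

  # renumber internals into ape convention: root = ntip+1, then preorder
  internals <- sort(unique(edges[edges[, 1] > ntip, 1]))
  remap <- integer(max(internals))
  remap[root] <- ntip + 1L
  rest <- setdiff(internals, root)
  # preorder walk from root so ape plotting/traversal conventions hold
  ord <- integer(0)
  stack <- root
  kids_raw <- split(seq_len(nrow(edges)), edges[, 1])
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ord <- c(ord, nd)
    ch <- edges[kids_raw[[as.character(nd)]], 2]
    stack <- c(stack, rev(ch[ch > ntip]))
  }
  remap[ord] <- ntip + seq_along(ord)
  e2 <- edges
  e2[e2 > ntip] <- remap[e2[e2 > ntip]]
  o <- order(e2[, 1], e2[, 2])
  tree <- structure(
    list(edge = e2[o, , drop = FALSE], edge.length = lens[o],
         tip.label = labels, Nnode = ntip - 2L),
    class = "phylo", order = "cladewise"
  )
  tree
}

# non-trivial bipartitions of an unrooted tree, canonicalized on the side
# not containing the alphabetically first taxon; returns a character vector
# of keys, one per internal edge
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[[1]]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tipset <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipset))
  }
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  vapply(internal_children, function(nd) {
    s <- sort(tipset(nd))
    if (anchor %in% s) s <- sort(setdiff(tree$tip.label, s))
    paste(s, collapse = "|")
  }, character(1))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times (seeded), rebuilds distances
#' and tree per replicate, and counts how often each internal bipartition of
#' the original tree recurs. Support = `round(100 * count / n_replicates)`.
#' Following the usual display rule, supports of 50 or less are still
#' computed and reported but flagged as hidden.
#'
#' @param aln Aligned sequences (tibble or named character vector).
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the column resampling.
#' @param pairwise_deletion,correction Passed to [p_distance()].
#' @return Object of class `nj_boot`: list with `tree` (a `phylo` with
#'   `node.label` supports; root label empty) and `support` (tibble
#'   `bipartition, count, percent, shown`).
#' @export
nj_bootstrap <- function(aln, n_replicates = 100, seed = 1,
                         pairwise_deletion = TRUE,
                         correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  m <- aln_matrix(aln)
  dist_of <- function(mm) {
    seqs <- setNames(apply(mm, 1, paste, collapse = ""), rownames(mm))
    p_distance(seqs, pairwise_deletion, correction)
  }
  tree <- nj_tree(dist_of(m))
  bips <- tree_bipartitions(tree)
  counts <- setNames(integer(length(bips)), bips)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- nj_tree(dist_of(m[, cols, drop = FALSE]))
    rb <- tree_bipartitions(rep_tree)
    hit <- names(counts) %in% rb
    counts[hit] <- counts[hit] + 1L
  }
  percent <- round(100 * counts / n_replicates)
  ntip <- length(tree$tip.label)
  # map bipartition of each internal (non-root) node to its support label
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  node_label <- character(tree$Nnode)
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  for (k in seq_along(internal_children)) {
    nd <- internal_children[[k]]
    node_label[nd - ntip] <- as.character(percent[bips[[k]]])
  }
  tree$node.label <- node_label
  support <- tibble(
    bipartition = bips,
    count = as.integer(counts),
    percent = as.numeric(percent),
    shown = percent > 50
  )
  structure(list(tree = tree, support = support,
                 n_replicates = n_replicates, seed = seed),
            class = "nj_boot")
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.nj_boot <- function(x, ...) {
  cat(sprintf("<nj_boot> %d tips, %d replicates, %d/%d bipartitions above 50%%\n",
              length(x$tree$tip.label), x$n_replicates,
              sum(x$support$shown), nrow(x$support)))
  invisible(x)
}

#' Tidy bootstrap supports into a tibble
#' @param x An `nj_boot` object.
#' @param ... Unused.
#' @return The support tibble `(bipartition, count, percent, shown)`.
#' @export
tidy.nj_boot <- function(x, ...) x$support

#' One-row summary of a bootstrapped NJ tree
#' @param x An `nj_boot` object.
#' @param ... Unused.
#' @return Tibble with tip count, replicate count and median support.
#' @export
glance.nj_boot <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label),
         n_replicates = x$n_replicates,
         median_support = stats::median(x$support$percent),
         n_shown = sum(x$support$shown))
}
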