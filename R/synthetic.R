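# Seeded synthetic communities with the statistical structure the binning
# analysis assumes: genome-specific G+C and order-k Markov (hence
# tetranucleotide) signatures, abundance-proportional Poisson read counts,
# planted single-copy markers, and planted-ortholog protein sets.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# run code under a local RNG stream without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# order-k Markov conditional distributions with per-context G+C jitter in
# logit space; jitter gives each genome its own tetranucleotide signature
markov_model <- function(target_gc, markov_order, jitter_sd = 0.8) {
  nctx <- 4L^markov_order
  g <- target_gc / 100
  jit <- rnorm(nctx, 0, jitter_sd)
  gsplit <- runif(nctx, 0.35, 0.65)   # share of GC mass on G, per context
  asplit <- runif(nctx, 0.35, 0.65)   # share of AT mass on A, per context
  list(nctx = nctx, order = markov_order, g = g, jit = jit,
       gsplit = gsplit, asplit = asplit)
}

markov_cumprobs <- function(model, delta = 0) {
  pgc <- stats::plogis(stats::qlogis(model$g) + model$jit + delta)
  pA <- (1 - pgc) * model$asplit
  pC <- pgc * (1 - model$gsplit)
  pG <- pgc * model$gsplit
  # order A, C, G, T; cumulative cut points
  list(c1 = pA, c2 = pA + pC, c3 = pA + pC + pG)
}

markov_generate <- function(model, cum, length) {
  k <- model$order
  mod_hi <- 4L^(k - 1L)
  v <- integer(length)
  u <- runif(length)
  # seed the first k bases from the marginal GC
  pgc0 <- model$g
  v[1:k] <- (u[1:k] > (1 - pgc0) / 2) + (u[1:k] > (1 - pgc0)) + (u[1:k] > 1 - pgc0 / 2)
  ctx <- 0L
  for (i in 1:k) ctx <- ctx * 4L + v[i]
  c1 <- cum$c1; c2 <- cum$c2; c3 <- cum$c3
  for (i in (k + 1L):length) {
    r <- u[i]
    ci <- ctx + 1L
    b <- (r > c1[ci]) + (r > c2[ci]) + (r > c3[ci])
    v[i] <- b
    ctx <- (ctx %% mod_hi) * 4L + b
  }
  paste(BASES[v + 1L], collapse = "")
}

#' Generate a genome sequence from a seeded order-k Markov model
#'
#' Samples a nucleotide sequence from a randomly initialized Markov chain of
#' the given order whose per-context conditional G+C is jittered around the
#' target (so each seed yields a genome-specific tetranucleotide signature)
#' and whose realized G+C is calibrated to the target within about one
#' percentage point. Identical arguments give identical sequences.
#'
#' @param genome_id Label (unused in the sequence, kept for bookkeeping).
#' @param length Sequence length in bp (>= 1000 recommended).
#' @param target_gc Target G+C in percent, strictly between 0 and 100.
#' @param markov_order Markov order (default 3, i.e. tetranucleotide-level
#'   structure).
#' @param seed Integer seed.
#' @param jitter_sd Logit-scale spread of per-context G+C (default 0.8);
#'   larger values give stronger compositional signatures.
#' @return A nucleotide string.
#' @export
simulate_genome <- function(genome_id, length, target_gc, markov_order = 3,
                            seed = 1, jitter_sd = 0.8) {
  if (target_gc <= 0 || target_gc >= 100) {
    abort("target_gc must be strictly between 0 and 100")
  }
  if (length < 4 * markov_order) abort("genome length too short")
  with_local_seed(seed, {
    model <- markov_model(target_gc, markov_order, jitter_sd)
    delta <- 0
    lcal <- min(length, 40000L)
    for (it in 1:4) {
      s <- markov_generate(model, markov_cumprobs(model, delta), lcal)
      realized <- gc_percent(s)
      if (abs(realized - target_gc) <= 0.5) break
      delta <- delta + stats::qlogis(target_gc / 100) - stats::qlogis(realized / 100)
    }
    s <- markov_generate(model, markov_cumprobs(model, delta), length)
    if (abs(gc_percent(s) - target_gc) > 0.9) {
      delta <- delta + stats::qlogis(target_gc / 100) - stats::qlogis(gc_percent(s) / 100)
      s <- markov_generate(model, markov_cumprobs(model, delta), length)
    }
    s
  })
}

# truncated lognormal contig lengths partitioning total_len
fragment_lengths <- function(total_len, meanlog, sdlog, min_len) {
  lens <- integer(0)
  remaining <- total_len
  while (remaining > 0) {
    l <- 0
    while (l < max(min_len, 4)) l <- round(rlnorm(1, meanlog, sdlog))
    l <- min(l, remaining)
    lens <- c(lens, l)
    remaining <- remaining - l
  }
  # a trailing stub shorter than min_len is merged into the previous contig
  n <- length(lens)
  if (n > 1 && lens[n] < min_len) {
    lens[n - 1] <- lens[n - 1] + lens[n]
    lens <- lens[-n]
  }
  lens
}

#' Simulate a multi-genome community for binning
#'
#' Generates one Markov genome per row of `genomes`, fragments each into
#' contigs with truncated-lognormal lengths, assigns each contig a Poisson
#' read count with expectation `total_reads * abundance * contig_length /
#' genome_length`, and plants each requested single-copy marker on exactly
#' one contig of its genome. All randomness derives from `seed`; identical
#' inputs give byte-identical outputs.
#'
#' @param genomes Tibble with columns `genome_id`, `length_bp`,
#'   `gc_percent`, `abundance` (weights are normalized to sum to 1).
#' @param total_reads Community-wide read count (default 2e5).
#' @param contig_meanlog,contig_sdlog Lognormal parameters of contig length
#'   (defaults `log(20000)` and 0.5, i.e. a ~22 kb mean contig, matching the
#'   tens-of-kb contigs typical of well-assembled dominant community
#'   members).
#' @param min_contig_length Minimum contig length in bp (default 10000).
#' @param markov_order Markov order of the genome models (default 3).
#' @param marker_universe Marker ids planted once per genome (default the
#'   full 105-marker universe, as every complete bacterial genome carries
#'   every universal single-copy gene).
#' @param jitter_sd Compositional-signature strength (see
#'   [simulate_genome()]).
#' @param seed Integer seed.
#' @return List with `contigs` (sequence tibble), `coverage` (tibble with
#'   `total_mapped_reads` attribute), `markers` (tibble with
#'   `marker_universe` attribute), `truth` (tibble `contig_id, genome_id`)
#'   and `marker_truth` (tibble `genome_id, marker_id, contig_id`).
#' @export
simulate_community <- function(genomes, total_reads = 2e5,
                               contig_meanlog = log(20000), contig_sdlog = 0.5,
                               min_contig_length = 10000, markov_order = 3,
                               marker_universe = default_marker_universe(),
                               jitter_sd = 0.8, seed = 1) {
  stopifnot(all(c("genome_id", "length_bp", "gc_percent", "abundance") %in% names(genomes)))
  if (any(genomes$abundance <= 0)) abort("abundance weights must be positive")
  w <- genomes$abundance / sum(genomes$abundance)
  with_local_seed(seed, {
    gseeds <- sample.int(.Machine$integer.max, nrow(genomes) + 1)
    contigs <- list(); cover <- list(); truth <- list(); marker_truth <- list()
    for (i in seq_len(nrow(genomes))) {
      g <- genomes$genome_id[[i]]
      seq_g <- simulate_genome(g, genomes$length_bp[[i]], genomes$gc_percent[[i]],
                               markov_order, seed = gseeds[[i]], jitter_sd = jitter_sd)
      lens <- fragment_lengths(nchar(seq_g), contig_meanlog, contig_sdlog,
                               min_contig_length)
      stops <- cumsum(lens)
      starts <- c(1, head(stops, -1) + 1)
      ids <- sprintf("%s_c%04d", g, seq_along(lens))
      seqs <- substring(seq_g, starts, stops)
      expected <- total_reads * w[[i]] * lens / nchar(seq_g)
      reads <- rpois(length(lens), expected)
      planted <- sample(seq_along(lens), length(marker_universe),
                        replace = TRUE, prob = lens)
      contigs[[i]] <- tibble(id = ids, description = paste0("genome=", g),
                             sequence = seqs)
      cover[[i]] <- tibble(contig_id = ids, mapped_reads = as.numeric(reads))
      truth[[i]] <- tibble(contig_id = ids, genome_id = g)
      marker_truth[[i]] <- tibble(genome_id = g, marker_id = marker_universe,
                                  contig_id = ids[planted])
    }
    contigs <- bind_rows(contigs)
    attr(contigs, "kind") <- "nucleotide"
    coverage <- bind_rows(cover)
    attr(coverage, "total_mapped_reads") <- sum(coverage$mapped_reads)
    marker_truth <- bind_rows(marker_truth)
    markers <- tibble(contig_id = marker_truth$contig_id,
                      marker_id = marker_truth$marker_id)
    attr(markers, "marker_universe") <- marker_universe
    list(contigs = contigs, coverage = coverage, markers = markers,
         truth = bind_rows(truth), marker_truth = marker_truth)
  })
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

#' Simulate protein sets with planted orthologs
#'
#' Builds `n_core` ortholog families shared by every genome (each genome's
#' copy carries independent per-site substitutions at `mutation_rate`) plus
#' `n_accessory` genome-specific genes, for validating BBH pairing and the
#' Venn partition against a known design.
#'
#' @param genome_ids Character vector of genome names (default three).
#' @param n_core Number of shared ortholog families (default 20).
#' @param n_accessory Accessory genes per genome (default 5).
#' @param mutation_rate Per-site substitution probability in ortholog copies,
#'   in `[0, 0.5]` (default 0.05).
#' @param len_range Protein length range in residues (default 150-400).
#' @param seed Integer seed.
#' @return List with `proteins` (named list of tibbles `id, sequence`) and
#'   `truth` (tibble `genome_id, protein_id, family, type`).
#' @export
simulate_protein_sets <- function(genome_ids = c("G1", "G2", "G3"),
                                  n_core = 20, n_accessory = 5,
                                  mutation_rate = 0.05,
                                  len_range = c(150, 400), seed = 1) {
  if (mutation_rate < 0 || mutation_rate > 0.5) {
    abort("mutation_rate must lie in [0, 0.5]")
  }
  with_local_seed(seed, {
    core_seqs <- replicate(n_core, random_protein(sample(len_range[1]:len_range[2], 1)))
    proteins <- list(); truth <- list()
    for (g in genome_ids) {
      ids <- character(0); seqs <- character(0)
      fam <- character(0); type <- character(0)
      for (f in seq_len(n_core)) {
        ids <- c(ids, sprintf("core%03d", f))
        seqs <- c(seqs, mutate_protein(core_seqs[[f]], mutation_rate))
        fam <- c(fam, sprintf("fam%03d", f)); type <- c(type, "core")
      }
      for (a in seq_len(n_accessory)) {
        ids <- c(ids, sprintf("acc%03d", a))
        seqs <- c(seqs, random_protein(sample(len_range[1]:len_range[2], 1)))
        fam <- c(fam, sprintf("acc_%s_%03d", g, a)); type <- c(type, "accessory")
      }
      tb <- tibble(id = ids, description = "", sequence = seqs)
      attr(tb, "kind") <- "protein"
      proteins[[g]] <- tb
      truth[[g]] <- tibble(genome_id = g, protein_id = ids, family = fam, type = type)
    }
    list(proteins = proteins, truth = bind_rows(truth))
  })
}
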