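# Independent pure-R oracles and fixture builders used across tests.

# Brute-force affine-gap Smith-Waterman (full O(mn) matrices, no seeding,
# no heuristics) — deliberately a separate code path from the package's
# C++ aligner. Gap of length g costs go + g * ge; N never matches.
sw_oracle <- function(q, s, match = 1, mismatch = -2, go = 5, ge = 2) {
  qq <- strsplit(q, "")[[1]]
  ss <- strsplit(s, "")[[1]]
  m <- length(qq)
  n <- length(ss)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - (go + ge), E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - (go + ge), F[i - 1, j] - ge)
      sc <- if (qq[i - 1] == ss[j - 1] &&
                  qq[i - 1] %in% c("A", "C", "G", "T")) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Best score over both query orientations, as local_align reports.
sw_oracle_2strand <- function(q, s, ...) {
  max(sw_oracle(q, s, ...), sw_oracle(srnatile::revcomp(q), s, ...))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal in-memory genome: one or more replicons with explicit genes.
toy_genome <- function(lengths, genes = NULL, topology = "circular",
                       kind = NULL, seed = 99) {
  withr::with_seed(seed, {
    ids <- names(lengths)
    if (is.null(ids)) ids <- sprintf("rep%d", seq_along(lengths))
    if (is.null(kind)) {
      kind <- c("chromosome", rep("plasmid", length(lengths) - 1))
    }
    reps <- data.frame(id = ids, length = unname(lengths),
                       topology = topology, kind = kind,
                       stringsAsFactors = FALSE)
    seqs <- stats::setNames(
      vapply(unname(lengths), random_dna, character(1)), ids)
    genome_annotation(reps, genes, seqs)
  })
}

toy_genes <- function(replicon, starts, ends) {
  data.frame(id = sprintf("g%02d", seq_along(starts)), replicon = replicon,
             start = starts, end = ends, strand = "+", type = "gene",
             stringsAsFactors = FALSE)
}

# Small simulated study shared by several module tests (cheap: ~250 kb).
# Overrides in ... replace the small-study defaults.
small_config <- function(seed = 11, ...) {
  defaults <- list(
    seed = seed,
    replicons = data.frame(id = c("chr", "pA"), length = c(2e5, 5e4),
                           topology = "circular",
                           kind = c("chromosome", "plasmid"),
                           stringsAsFactors = FALSE),
    n_candidates = 40, n_expressed = 10, n_decoys = 20)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
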