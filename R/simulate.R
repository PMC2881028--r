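#' Configuration for the synthetic tiling-array study
#'
#' Fixes every parameter of the simulated study: a multi-replicon genome
#' with genes and intergenic regions, a set of candidate ncRNA intervals
#' planted inside IGRs (a subset of which is expressed condition-
#' specifically), mutated "literature prediction" copies of those
#' intervals plus random decoys, and a 60-mer / 13-bp tiling array with
#' log-scale intensities carrying per-array offsets, per-probe affinities,
#' a smooth intensity-dependent bias and Gaussian noise. All randomness
#' is driven by `seed`; the same seed reproduces every output byte for
#' byte.
#'
#' @param seed integer seed.
#' @param replicons data.frame with `id`, `length`, `topology`, `kind`
#'   (default: 2 Mb circular chromosome + 0.5 Mb circular plasmid).
#' @param gene_shape,gene_scale Gamma parameters for gene lengths in bp
#'   (default mean 900 bp); `gene_min` floors them.
#' @param gap_mean mean intergenic gap in bp (exponential).
#' @param n_candidates number of candidate ncRNA intervals planted in IGRs.
#' @param n_expressed how many of them are expressed (the true ncRNAs).
#' @param ncrna_len_range candidate length range in bp (default 60-250).
#' @param conditions condition names (default the five-condition design:
#'   two exponential-phase points, stationary phase, and nodule samples at
#'   two and three weeks).
#' @param groups named list mapping expression-group names to the condition
#'   indices in which that group is switched on.
#' @param effect_size expression increment in log2 units (default 2).
#' @param copies_range how many mutated prediction copies each candidate
#'   gets (default 1-3).
#' @param mutation_rate substitutions per site for prediction copies.
#' @param trim_max maximum random end trim in bp per prediction copy.
#' @param n_decoys random decoy predictions matching nothing.
#' @param n_studies number of pseudo-studies predictions are attributed to.
#' @param probe_length,spacing tiling design (default 60-mer / 13 bp).
#' @param baseline_mean background log2 intensity.
#' @param affinity_sd per-probe affinity sd (log2).
#' @param offset_sd per-array offset sd (log2).
#' @param bias_coef per-condition quadratic intensity-bias coefficients.
#' @param noise_sd Gaussian probe noise sd (log2).
#' @param min_overlap_frac probe-in-region rule shared with
#'   [assign_probes()].
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 1,
    replicons = data.frame(
      id = c("chr", "pA"),
      length = c(2e6, 5e5),
      topology = "circular",
      kind = c("chromosome", "plasmid"),
      stringsAsFactors = FALSE),
    gene_shape = 9, gene_scale = 100, gene_min = 150,
    gap_mean = 200,
    n_candidates = 500, n_expressed = 50,
    ncrna_len_range = c(60, 250),
    conditions = c("early_exp", "late_exp", "stationary",
                   "nodule_2w", "nodule_3w"),
    groups = list(exponential = c(1, 2), stationary = 3, symbiosis = c(4, 5)),
    effect_size = 2,
    copies_range = c(1, 3), mutation_rate = 0.05, trim_max = 10,
    n_decoys = 200, n_studies = 6,
    probe_length = 60, spacing = 13,
    baseline_mean = 7, affinity_sd = 0.5, offset_sd = 0.25,
    bias_coef = c(0.02, -0.015, 0.025, 0, -0.01),
    noise_sd = 0.3,
    min_overlap_frac = 0.5) {
  stopifnot(length(seed) == 1, is.finite(seed),
            mutation_rate >= 0, mutation_rate <= 0.5,
            n_expressed <= n_candidates,
            ncrna_len_range[1] >= 1,
            ncrna_len_range[2] >= ncrna_len_range[1],
            length(bias_coef) == length(conditions),
            all(unlist(groups) %in% seq_along(conditions)))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "simulation_config"
  cfg
}

# Deterministic local RNG scope: runs expr with a seed derived from the
# config seed and a stage offset, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate an annotated genome with planted candidate ncRNAs
#'
#' Generates random replicon sequences, packs non-overlapping genes along
#' each replicon (Gamma lengths, exponential gaps), extracts the IGRs and
#' plants `n_candidates` ncRNA intervals wholly inside distinct IGRs of
#' sufficient length. The first `n_expressed` (after placement
#' randomization) are assigned an expression group.
#'
#' @param config a [simulation_config()].
#' @return List with `annotation` (a [genome_annotation]) and `truth` (an
#'   object of class `ground_truth`: `intervals` data.frame with `id`,
#'   `replicon`, `start`, `end`, `length`, `expressed`, `group`;
#'   `expression` logical truth x conditions matrix; `effects` numeric
#'   matrix of log2 increments).
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    reps <- config$replicons
    sequences <- stats::setNames(
      vapply(reps$length, .random_dna, character(1)), reps$id)
    genes <- list()
    for (r in seq_len(nrow(reps))) {
      rid <- reps$id[r]
      L <- reps$length[r]
      pos <- 1L
      starts <- integer(); ends <- integer()
      repeat {
        gap <- stats::rexp(1, 1 / config$gap_mean)
        glen <- max(config$gene_min,
                    round(stats::rgamma(1, shape = config$gene_shape,
                                        scale = config$gene_scale)))
        s <- pos + as.integer(round(gap))
        e <- s + as.integer(glen) - 1L
        if (e > L - 1L) break
        starts <- c(starts, s); ends <- c(ends, e)
        pos <- e + 1L
      }
      if (!length(starts)) {
        stop("replicon '", rid, "' too short to place any gene")
      }
      genes[[rid]] <- data.frame(
        id = sprintf("G_%s_%05d", rid, seq_along(starts)),
        replicon = rid, start = starts, end = ends,
        strand = sample(c("+", "-"), length(starts), replace = TRUE),
        type = "gene", stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    rownames(genes) <- NULL
    annotation <- genome_annotation(reps, genes, sequences)

    igrs <- extract_igrs(annotation, min_len = config$ncrna_len_range[1])
    igrs <- igrs[igrs$start <= igrs$end, , drop = FALSE]  # unwrapped hosts
    lens <- round(stats::runif(config$n_candidates,
                               config$ncrna_len_range[1],
                               config$ncrna_len_range[2]))
    # greedy placement, longest first, each in its own IGR
    ord <- order(-lens)
    avail <- igrs[sample.int(nrow(igrs)), , drop = FALSE]
    used <- logical(nrow(avail))
    place <- data.frame(replicon = character(config$n_candidates),
                        start = integer(config$n_candidates),
                        end = integer(config$n_candidates),
                        stringsAsFactors = FALSE)
    for (i in ord) {
      fit <- which(!used & avail$length >= lens[i])
      if (!length(fit)) {
        stop("cannot place all candidate ncRNAs: not enough IGRs of ",
             "length >= ", lens[i])
      }
      j <- fit[1]
      used[j] <- TRUE
      slack <- avail$length[j] - lens[i]
      off <- if (slack > 0) sample.int(slack + 1L, 1) - 1L else 0L
      place$replicon[i] <- avail$replicon[j]
      place$start[i] <- avail$start[j] + off
      place$end[i] <- place$start[i] + lens[i] - 1L
    }
    ordg <- order(match(place$replicon, reps$id), place$start)
    place <- place[ordg, , drop = FALSE]
    n <- config$n_candidates
    expressed <- rep(FALSE, n)
    expressed[sample.int(n, config$n_expressed)] <- TRUE
    group <- rep("none", n)
    group[expressed] <- sample(names(config$groups), config$n_expressed,
                               replace = TRUE)
    intervals <- data.frame(
      id = sprintf("T_%04d", seq_len(n)),
      replicon = place$replicon, start = place$start, end = place$end,
      length = place$end - place$start + 1L,
      expressed = expressed, group = group, stringsAsFactors = FALSE)
    expr <- matrix(FALSE, n, length(config$conditions),
                   dimnames = list(intervals$id, config$conditions))
    for (g in names(config$groups)) {
      expr[group == g, config$groups[[g]]] <- TRUE
    }
    effects <- expr * config$effect_size
    truth <- structure(list(intervals = intervals, expression = expr,
                            effects = effects),
                       class = "ground_truth")
    list(annotation = annotation, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d candidate intervals, %d expressed\n",
              nrow(x$intervals), sum(x$intervals$expressed)))
  invisible(x)
}

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate literature-style ncRNA predictions
#'
#' Each planted candidate interval yields 1-3 mutated copies
#' (substitutions at `mutation_rate`, random end trims up to `trim_max`
#' bp, random orientation) attributed to random pseudo-studies, plus
#' `n_decoys` random sequences that match nothing in the genome.
#'
#' @param truth `ground_truth` from [simulate_genome()].
#' @param annotation the matching [genome_annotation].
#' @param config the [simulation_config()].
#' @return data.frame `id`, `source_study`, `sequence`, `truth_id`
#'   (`NA` for decoys).
#' @export
simulate_predictions <- function(truth, annotation,
                                 config = simulation_config()) {
  with_seed(config$seed + 1L, {
    studies <- sprintf("study%02d", seq_len(config$n_studies))
    iv <- truth$intervals
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(iv))) {
      ncopies <- sample(seq(config$copies_range[1], config$copies_range[2]),
                        1)
      full <- igr_sequence(iv[i, ], annotation)
      for (cp in seq_len(ncopies)) {
        t1 <- sample.int(config$trim_max + 1L, 1) - 1L
        t2 <- sample.int(config$trim_max + 1L, 1) - 1L
        if (t1 + t2 >= nchar(full) - 30L) { t1 <- 0L; t2 <- 0L }
        s <- substr(full, 1L + t1, nchar(full) - t2)
        s <- .mutate_seq(s, config$mutation_rate)
        if (stats::runif(1) < 0.5) s <- revcomp(s)
        k <- k + 1L
        rows[[k]] <- data.frame(
          id = sprintf("pred_%05d", k),
          source_study = sample(studies, 1),
          sequence = s, truth_id = iv$id[i], stringsAsFactors = FALSE)
      }
    }
    if (config$n_decoys > 0) {
      dlen <- round(stats::runif(config$n_decoys,
                                 config$ncrna_len_range[1],
                                 config$ncrna_len_range[2]))
      for (d in seq_len(config$n_decoys)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          id = sprintf("pred_%05d", k),
          source_study = sample(studies, 1),
          sequence = .random_dna(dlen[d]), truth_id = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate raw tiling-array intensities
#'
#' Probe-level model on the log2 scale:
#' `log2 I[p,c] = baseline + affinity[p] + signal[p,c] + offset[c] +
#' bias_c(a) + noise`, where `a = baseline + affinity + signal` is the
#' underlying abundance, `bias_c(a) = coef[c] * (a - baseline)^2` is a
#' smooth intensity-dependent distortion for the loess stage to remove,
#' and `signal[p,c]` is the planted log2 increment of any expressed truth
#' interval covering the probe (majority overlap) in condition c. Raw
#' intensities are `2^log2`.
#'
#' @param design a [design_tiling()] result for the simulated genome.
#' @param truth `ground_truth` from [simulate_genome()].
#' @param config the [simulation_config()].
#' @param annotation the matching [genome_annotation].
#' @return List with `raw` (probes x conditions matrix, raw scale),
#'   `truth_expr` (the truth expression matrix) and `params` (offsets,
#'   bias coefficients).
#' @export
simulate_intensities <- function(design, truth, annotation,
                                 config = simulation_config()) {
  with_seed(config$seed + 2L, {
    pr <- design$probes
    np <- nrow(pr)
    nc <- length(config$conditions)
    affinity <- stats::rnorm(np, 0, config$affinity_sd)
    offsets <- stats::rnorm(nc, 0, config$offset_sd)
    signal <- matrix(0, np, nc)
    plen <- design$probe_length
    need <- config$min_overlap_frac * plen
    iv <- truth$intervals
    for (i in which(iv$expressed)) {
      sel <- which(pr$replicon == iv$replicon[i] &
                     pr$start >= iv$start[i] - plen + ceiling(need) &
                     pr$start <= iv$end[i] - ceiling(need) + 1L)
      if (length(sel)) {
        signal[sel, ] <- signal[sel, ] +
          rep(truth$effects[iv$id[i], ], each = length(sel))
      }
    }
    a <- config$baseline_mean + affinity + signal
    log2v <- a +
      rep(offsets, each = np) +
      sweep((a - config$baseline_mean)^2, 2, config$bias_coef, `*`) +
      matrix(stats::rnorm(np * nc, 0, config$noise_sd), np, nc)
    raw <- 2^log2v
    dimnames(raw) <- list(pr$id, config$conditions)
    attr(raw, "scale") <- "raw"
    list(raw = raw, truth_expr = truth$expression,
         params = list(offsets = offsets, bias_coef = config$bias_coef))
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper: genome + truth, predictions, tiling design and raw
#' intensities, all under the configured seed.
#'
#' @param config a [simulation_config()].
#' @return List with `annotation`, `truth`, `predictions`, `design`,
#'   `intensities` and the `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  gen <- simulate_genome(config)
  predictions <- simulate_predictions(gen$truth, gen$annotation, config)
  design <- design_tiling(gen$annotation,
                          probe_length = config$probe_length,
                          spacing = config$spacing)
  intensities <- simulate_intensities(design, gen$truth, gen$annotation,
                                      config)
  list(annotation = gen$annotation, truth = gen$truth,
       predictions = predictions, design = design,
       intensities = intensities, config = config)
}

#' Simulate a diverged relative genome for the conservation scan
#'
#' Builds a synthetic target genome: random background of `length` bp in
#' which a `conserved_fraction` of the expressed truth intervals is
#' embedded after point mutation at `divergence` substitutions per site.
#' Returns the genome sequence and the ids of the intervals embedded, so
#' conservation calls can be checked against ground truth.
#'
#' @param truth `ground_truth` from [simulate_genome()].
#' @param annotation the matching [genome_annotation].
#' @param config the [simulation_config()].
#' @param length target genome length in bp.
#' @param conserved_fraction fraction of expressed intervals embedded.
#' @param divergence substitutions per site applied to embedded copies.
#' @param seed_offset offset added to the config seed (vary per genome).
#' @return List with `sequence` (single replicon) and `embedded`
#'   (character vector of truth ids).
#' @export
simulate_target_genome <- function(truth, annotation,
                                   config = simulation_config(),
                                   length = 2e5, conserved_fraction = 0.5,
                                   divergence = 0.1, seed_offset = 10L) {
  with_seed(config$seed + seed_offset, {
    expressed <- truth$intervals[truth$intervals$expressed, , drop = FALSE]
    n_emb <- round(conserved_fraction * nrow(expressed))
    emb <- expressed[sample.int(nrow(expressed), n_emb), , drop = FALSE]
    bg <- .random_dna(length)
    if (nrow(emb)) {
      # slots 300 bp apart so embeddings never overwrite each other
      slots <- seq(1L, length - 300L, by = 300L)
      if (nrow(emb) > base::length(slots)) {
        stop("target genome too short for the requested embeddings")
      }
      pos <- sort(sample(slots, nrow(emb)))
      for (i in seq_len(nrow(emb))) {
        s <- .mutate_seq(igr_sequence(emb[i, ], annotation), divergence)
        substr(bg, pos[i], pos[i] + nchar(s) - 1L) <- s
      }
    }
    list(sequence = stats::setNames(bg, "target"), embedded = emb$id)
  })
}
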