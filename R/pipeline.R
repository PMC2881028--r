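#' Run the full discovery pipeline on a simulated study
#'
#' Executes the stages in order — IGR extraction, prediction matching,
#' normalization, region summarization, expression detection, differential
#' calling, profile clustering, genomic density / hotspot scan and the
#' conservation scan — writing one TSV per stage plus a JSON run manifest
#' (parameters, input checksums, package version) into `outdir`. Outputs
#' are byte-stable under a fixed configuration.
#'
#' @param config a [simulation_config()] describing the study.
#' @param outdir output directory (created if needed).
#' @param scheme a [scoring_scheme()].
#' @param e_threshold E-value threshold for prediction matching.
#' @param span loess span.
#' @param percentile noise-cutoff percentile.
#' @param estimator noise scale estimator.
#' @param k number of expression-profile groups.
#' @param n_target_genomes simulated relative genomes for the conservation
#'   stage (0 skips the stage).
#' @param conservation_tiers strong/weak E-value thresholds.
#' @param min_igr_length minimum IGR length in bp.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with every stage result (`annotation`,
#'   `truth`, `igrs`, `candidates`, `normalized`, `summaries`,
#'   `detection`, `clusters`, `density`, `hotspots`, `conservation`) and
#'   `outdir`.
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         scheme = scoring_scheme(), e_threshold = 1e-5,
                         span = 0.25, percentile = 0.999,
                         estimator = "left-half", k = 3,
                         n_target_genomes = 2,
                         conservation_tiers = c(strong = 1e-5, weak = 1e-3),
                         min_igr_length = 60, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_all <- proc.time()[3]

  say("simulate: generating study (seed %d)", config$seed)
  sim <- simulate_dataset(config)
  write_genome(sim$annotation, file.path(outdir, "genome.fasta"),
               file.path(outdir, "genome.gff3"))
  write_predictions(sim$predictions[, c("id", "source_study", "sequence")],
                    file.path(outdir, "predictions.fasta"))
  write_intensities(sim$intensities$raw, file.path(outdir, "raw.tsv"))

  write_probes(sim$design, file.path(outdir, "probes.tsv"))

  say("igr: extracting intergenic regions (min %d bp)", min_igr_length)
  igrs <- extract_igrs(sim$annotation, min_len = min_igr_length)
  write_igrs(igrs, sim$annotation, tsv = file.path(outdir, "igrs.tsv"),
             bed = file.path(outdir, "igrs.bed"))

  say("match: %d predictions vs %d IGRs", nrow(sim$predictions), nrow(igrs))
  candidates <- match_predictions(sim$predictions, igrs, sim$annotation,
                                  scheme, e_threshold = e_threshold)
  write_regions(candidates, tsv = file.path(outdir, "regions.tsv"),
                bed = file.path(outdir, "regions.bed"))

  say("normalize: loess vs artificial reference (span %.2f)", span)
  logm <- log2_transform(sim$intensities$raw)
  normalized <- loess_normalize(logm, span = span)
  write_intensities(normalized, file.path(outdir, "normalized.tsv"))

  say("summarize: median polish over %d candidate regions",
      nrow(candidates$regions))
  assignment <- assign_probes(sim$design, candidates$regions,
                              sim$annotation,
                              min_overlap_frac = config$min_overlap_frac)
  summaries <- summarize_regions(normalized, assignment)
  utils::write.table(
    data.frame(region_id = rownames(summaries$summaries),
               summaries$summaries, check.names = FALSE),
    file.path(outdir, "summaries.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  say("detect/diff: noise threshold at %.3f%% (%s)", 100 * percentile,
      estimator)
  detection <- detect_regions(summaries$summaries, estimator = estimator,
                              percentile = percentile)
  write_detection(detection, file.path(outdir, "detection.tsv"))
  diff_tab <- detection[detection$differential,
                        c("region_id", "sd"), drop = FALSE]
  utils::write.table(diff_tab, file.path(outdir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  clusters <- NULL
  diff_ids <- detection$region_id[detection$differential]
  if (length(diff_ids) >= k) {
    say("cluster: %d differential regions into %d groups",
        length(diff_ids), k)
    clusters <- cluster_profiles(
      summaries$summaries[diff_ids, , drop = FALSE], k = k)
    write_clusters(clusters, file.path(outdir, "clusters.tsv"))
  } else {
    say("cluster: skipped (%d differential regions < k = %d)",
        length(diff_ids), k)
  }

  say("density: per-replicon counts and hotspot scan")
  expressed_regions <- candidates$regions[
    candidates$regions$id %in% detection$region_id[detection$expressed], ,
    drop = FALSE]
  density <- replicon_density(expressed_regions, sim$annotation)
  utils::write.table(density, file.path(outdir, "density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  main_rep <- sim$annotation$replicons$id[
    which.max(sim$annotation$replicons$length)]
  main_len <- max(sim$annotation$replicons$length)
  hotspots <- hotspot_scan(expressed_regions, main_rep, sim$annotation,
                           window = min(3e5, main_len),
                           step = min(5e4, max(1, main_len %/% 20)))
  utils::write.table(hotspots, file.path(outdir, "hotspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  conservation <- NULL
  if (n_target_genomes > 0 && nrow(expressed_regions)) {
    say("conserve: scanning %d simulated relative genome(s)",
        n_target_genomes)
    targets <- lapply(seq_len(n_target_genomes), function(i) {
      simulate_target_genome(sim$truth, sim$annotation, config,
                             seed_offset = 10L + i)$sequence
    })
    names(targets) <- sprintf("relative%02d", seq_len(n_target_genomes))
    seqs <- region_sequences(expressed_regions, sim$annotation)
    scan <- conservation_scan(seqs, targets, scheme)
    conservation <- conservation_matrix(scan,
                                        strong = conservation_tiers[["strong"]],
                                        weak = conservation_tiers[["weak"]])
    write_conservation(conservation, file.path(outdir, "conservation.tsv"))
  }

  manifest <- list(
    package = "srnatile",
    version = as.character(utils::packageVersion("srnatile")),
    parameters = list(
      seed = config$seed, min_igr_length = min_igr_length,
      e_threshold = e_threshold, span = span, percentile = percentile,
      estimator = estimator, k = k,
      conservation_tiers = as.list(conservation_tiers),
      probe_length = config$probe_length, spacing = config$spacing,
      conditions = config$conditions),
    inputs = as.list(tools::md5sum(file.path(outdir,
      c("genome.fasta", "genome.gff3", "predictions.fasta", "raw.tsv")))),
    elapsed_sec = round(proc.time()[3] - t_all, 2))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done in %.1f s -> %s", proc.time()[3] - t_all, outdir)

  invisible(list(annotation = sim$annotation, truth = sim$truth,
                 predictions = sim$predictions, design = sim$design,
                 igrs = igrs, candidates = candidates,
                 normalized = normalized, summaries = summaries,
                 detection = detection, clusters = clusters,
                 density = density, hotspots = hotspots,
                 conservation = conservation, outdir = outdir))
}

#' Run a single pipeline stage from prior outputs
#'
#' Re-executes one stage standalone against the files a previous
#' [run_pipeline()] (or earlier stages) left in `dir`. A missing
#' prerequisite file produces an error naming the stage that must be run
#' first.
#'
#' @param stage one of `"igr"`, `"match"`, `"normalize"`, `"summarize"`,
#'   `"detect"`, `"cluster"`, `"density"`.
#' @param dir the pipeline output directory.
#' @param scheme a [scoring_scheme()].
#' @param e_threshold,span,percentile,estimator,k,min_igr_length stage
#'   parameters as in [run_pipeline()].
#' @return Invisibly, the stage's main result object.
#' @export
pipeline_stage <- function(stage = c("igr", "match", "normalize",
                                     "summarize", "detect", "cluster",
                                     "density"),
                           dir, scheme = scoring_scheme(),
                           e_threshold = 1e-5, span = 0.25,
                           percentile = 0.999, estimator = "left-half",
                           k = 3, min_igr_length = 60) {
  stage <- match.arg(stage)
  need <- function(file, producer) {
    p <- file.path(dir, file)
    if (!file.exists(p)) {
      stop(sprintf("missing '%s'; run the '%s' stage first", file,
                   producer), call. = FALSE)
    }
    p
  }
  load_ann <- function() {
    load_genome(need("genome.fasta", "simulate"),
                need("genome.gff3", "simulate"))
  }
  read_tsv <- function(p) {
    utils::read.table(p, sep = "\t", header = TRUE, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  res <- switch(stage,
    igr = {
      ann <- load_ann()
      igrs <- extract_igrs(ann, min_len = min_igr_length)
      write_igrs(igrs, ann, tsv = file.path(dir, "igrs.tsv"),
                 bed = file.path(dir, "igrs.bed"))
      igrs
    },
    match = {
      ann <- load_ann()
      igrs <- read_tsv(need("igrs.tsv", "igr"))
      preds <- read_predictions(need("predictions.fasta", "simulate"))
      cr <- match_predictions(preds, igrs, ann, scheme,
                              e_threshold = e_threshold)
      write_regions(cr, tsv = file.path(dir, "regions.tsv"),
                    bed = file.path(dir, "regions.bed"))
      cr
    },
    normalize = {
      raw <- read_intensities(need("raw.tsv", "simulate"))
      nm <- loess_normalize(log2_transform(raw), span = span)
      write_intensities(nm, file.path(dir, "normalized.tsv"))
      nm
    },
    summarize = {
      ann <- load_ann()
      nm <- read_intensities(need("normalized.tsv", "normalize"),
                             scale = "log2")
      regions <- read_tsv(need("regions.tsv", "match"))
      design <- read_probes(need("probes.tsv", "simulate"))
      su <- summarize_regions(nm, assign_probes(design, regions, ann))
      utils::write.table(
        data.frame(region_id = rownames(su$summaries), su$summaries,
                   check.names = FALSE),
        file.path(dir, "summaries.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      su
    },
    detect = {
      su <- read_tsv(need("summaries.tsv", "summarize"))
      m <- as.matrix(su[, -1, drop = FALSE])
      rownames(m) <- su[[1]]
      det <- detect_regions(m, estimator = estimator,
                            percentile = percentile)
      write_detection(det, file.path(dir, "detection.tsv"))
      utils::write.table(det[det$differential, c("region_id", "sd")],
                         file.path(dir, "differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      det
    },
    cluster = {
      su <- read_tsv(need("summaries.tsv", "summarize"))
      det <- read_tsv(need("detection.tsv", "detect"))
      m <- as.matrix(su[, -1, drop = FALSE])
      rownames(m) <- su[[1]]
      ids <- det$region_id[det$differential == "TRUE" |
                             det$differential == TRUE]
      cl <- cluster_profiles(m[ids, , drop = FALSE], k = k)
      write_clusters(cl, file.path(dir, "clusters.tsv"))
      cl
    },
    density = {
      ann <- load_ann()
      regions <- read_tsv(need("regions.tsv", "match"))
      det <- read_tsv(need("detection.tsv", "detect"))
      expressed <- regions[regions$id %in%
                             det$region_id[det$expressed == "TRUE" |
                                             det$expressed == TRUE], ,
                           drop = FALSE]
      dens <- replicon_density(expressed, ann)
      utils::write.table(dens, file.path(dir, "density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dens
    })
  invisible(res)
}

#' Map candidate regions to planted ground truth
#'
#' Matches each candidate region to the truth interval it overlaps (same
#' replicon, >= 1 bp) and reports per-truth detection outcomes. Used for
#' parameter-recovery evaluation of synthetic runs.
#'
#' @param regions candidate region table (`id`, `replicon`, `start`,
#'   `end`).
#' @param truth a `ground_truth` object.
#' @return data.frame: one row per truth interval with `truth_id`,
#'   `region_id` (NA when undetected by matching), `expressed`, `group`.
#' @export
match_truth <- function(regions, truth) {
  iv <- truth$intervals
  region_id <- rep(NA_character_, nrow(iv))
  for (rid in unique(iv$replicon)) {
    ti <- which(iv$replicon == rid)
    ri <- which(regions$replicon == rid)
    if (!length(ri)) next
    ir_t <- IRanges::IRanges(iv$start[ti], iv$end[ti])
    ir_r <- IRanges::IRanges(regions$start[ri], regions$end[ri])
    ov <- IRanges::findOverlaps(ir_t, ir_r, select = "first")
    region_id[ti] <- regions$id[ri][ov]
  }
  data.frame(truth_id = iv$id, region_id = region_id,
             expressed = iv$expressed, group = iv$group,
             stringsAsFactors = FALSE)
}
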