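#' Read / write prediction FASTA
#'
#' Prediction headers are pipe-delimited: `id|source_study`. The source
#' study records which published prediction set a sequence came from, so
#' downstream candidate regions can count distinct supporting studies.
#'
#' @param path FASTA path.
#' @return data.frame with `id`, `source_study`, `sequence`.
#' @export
read_predictions <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, character(1), 1),
             source_study = vapply(parts, function(p) {
               if (length(p) >= 2) p[2] else NA_character_
             }, character(1)),
             sequence = unname(as.character(seqs)),
             stringsAsFactors = FALSE)
}

#' @rdname read_predictions
#' @param predictions data.frame with `id`, `source_study`, `sequence`.
#' @export
write_predictions <- function(predictions, path) {
  sset <- Biostrings::DNAStringSet(predictions$sequence)
  names(sset) <- paste(predictions$id, predictions$source_study, sep = "|")
  Biostrings::writeXStringSet(sset, path, width = 80)
  invisible(path)
}

# Project a hit interval inside an IGR onto genomic coordinates, splitting
# at the origin when the IGR wraps. Returns a data.frame of arcs.
.project_to_genome <- function(igr_start, s_start, s_end, L) {
  g1 <- (igr_start + s_start - 2L) %% L + 1L
  g2 <- (igr_start + s_end - 2L) %% L + 1L
  if (g1 <= g2) {
    data.frame(start = g1, end = g2)
  } else {
    data.frame(start = c(g1, 1L), end = c(L, g2))
  }
}

#' Match ncRNA predictions to intergenic regions
#'
#' Aligns every prediction (both orientations) against every IGR sequence,
#' keeps hits with E-value at or below the threshold, projects them onto
#' genomic coordinates, and transitively merges hits whose genomic
#' intervals overlap by at least 1 bp on the same replicon (strand
#' ignored) into non-redundant candidate ncRNA regions.
#'
#' @param predictions data.frame with `id`, `source_study`, `sequence`.
#' @param igrs IGR table from [extract_igrs()].
#' @param annotation the [genome_annotation] with sequences.
#' @param scheme a [scoring_scheme].
#' @param e_threshold maximum E-value for a supporting hit (default 1e-5).
#' @param word_size seed word length for the search.
#' @return An object of class `candidate_regions`: list with `regions`
#'   (data.frame `id`, `replicon`, `start`, `end`, `length`,
#'   `n_predictions`, `n_studies`, `best_evalue`) and `hits` (the
#'   supporting hit table with genomic coordinates and region ids).
#' @export
match_predictions <- function(predictions, igrs, annotation,
                              scheme = scoring_scheme(),
                              e_threshold = 1e-5, word_size = 11) {
  empty <- structure(
    list(regions = data.frame(id = character(), replicon = character(),
                              start = integer(), end = integer(),
                              length = integer(), n_predictions = integer(),
                              n_studies = integer(), best_evalue = numeric(),
                              stringsAsFactors = FALSE),
         hits = data.frame()),
    class = "candidate_regions")
  if (!nrow(predictions) || !nrow(igrs)) return(empty)
  igr_seqs <- region_sequences(igrs, annotation)
  queries <- stats::setNames(predictions$sequence, predictions$id)
  min_score <- floor(log(scheme$K * max(nchar(queries)) *
                           max(nchar(igr_seqs)) / e_threshold) /
                       scheme$lambda * 0.8)
  hits <- align_to_set(queries, igr_seqs, scheme, word_size = word_size,
                       min_score = max(10, min_score))
  hits <- hits[hits$evalue <= e_threshold, , drop = FALSE]
  if (!nrow(hits)) return(empty)

  ig <- igrs[match(hits$subject_id, igrs$id), ]
  L <- annotation$replicons$length[match(ig$replicon,
                                         annotation$replicons$id)]
  arcs <- lapply(seq_len(nrow(hits)), function(i) {
    a <- .project_to_genome(ig$start[i], hits$s_start[i], hits$s_end[i],
                            L[i])
    a$hit <- i
    a$replicon <- ig$replicon[i]
    a
  })
  arcs <- do.call(rbind, arcs)

  # transitive merge of overlapping genomic intervals, per replicon
  arcs$region_key <- NA_character_
  regions <- list()
  for (rid in unique(arcs$replicon)) {
    sel <- which(arcs$replicon == rid)
    ir <- IRanges::IRanges(arcs$start[sel], arcs$end[sel])
    red <- IRanges::reduce(ir)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    key <- sprintf("%s:%09d", rid, IRanges::start(red)[grp])
    arcs$region_key[sel] <- key
    regions[[rid]] <- data.frame(key = sprintf("%s:%09d", rid,
                                               IRanges::start(red)),
                                 replicon = rid,
                                 start = IRanges::start(red),
                                 end = IRanges::end(red),
                                 stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, regions)
  regions <- regions[order(match(regions$replicon, annotation$replicons$id),
                           regions$start), , drop = FALSE]
  regions$id <- sprintf("ReC_%04d", seq_len(nrow(regions)))
  regions$length <- regions$end - regions$start + 1L

  # a hit split at the origin belongs to every region its arcs touch;
  # attribute hit-level metadata through the arc->region map
  hit_region <- tapply(arcs$region_key, arcs$hit, function(k) unique(k))
  hit_rows <- rep(seq_len(nrow(hits)),
                  lengths(hit_region)[as.character(seq_len(nrow(hits)))])
  hits_exp <- hits[hit_rows, , drop = FALSE]
  hits_exp$region_id <- regions$id[match(unlist(hit_region),
                                         regions$key)]
  study <- predictions$source_study[match(hits_exp$query_id,
                                          predictions$id)]
  agg <- function(f, what) {
    v <- tapply(what, hits_exp$region_id, f)
    v[regions$id]
  }
  regions$n_predictions <- as.integer(agg(function(x) length(unique(x)),
                                          hits_exp$query_id))
  regions$n_studies <- as.integer(
    tapply(study, hits_exp$region_id,
           function(x) length(unique(x[!is.na(x)])))[regions$id])
  regions$best_evalue <- as.numeric(agg(min, hits_exp$evalue))
  rownames(regions) <- NULL
  structure(list(regions = regions[, c("id", "replicon", "start", "end",
                                       "length", "n_predictions",
                                       "n_studies", "best_evalue")],
                 hits = hits_exp),
            class = "candidate_regions")
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat(sprintf(
    "candidate_regions: %d non-redundant regions from %d supporting hits\n",
    nrow(x$regions), nrow(x$hits)))
  invisible(x)
}

#' Write candidate regions as TSV and/or BED
#'
#' @param cr a [match_predictions()] result.
#' @param tsv,bed output paths (`NULL` to skip).
#' @return Invisibly, the region table.
#' @export
write_regions <- function(cr, tsv = NULL, bed = NULL) {
  r <- cr$regions
  if (!is.null(tsv)) {
    utils::write.table(r, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    utils::write.table(
      data.frame(r$replicon, r$start - 1L, r$end, r$id),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(r)
}

#' Scan target genomes for conservation of candidate regions
#'
#' For each candidate-region sequence and each target genome, records the
#' best (smallest) E-value over both strands, with the E-value computed
#' against the total genome length. Regions with no alignment at all get
#' `Inf`.
#'
#' @param region_seqs named character vector of region sequences.
#' @param targets named list of target genomes; each element is either a
#'   FASTA path or a character vector of replicon sequences.
#' @param scheme a [scoring_scheme].
#' @param word_size seed word length.
#' @param min_score smallest alignment score considered.
#' @return data.frame in long form: `region_id`, `genome`, `best_evalue`.
#' @export
conservation_scan <- function(region_seqs, targets,
                              scheme = scoring_scheme(),
                              word_size = 11, min_score = 12) {
  if (!length(targets)) {
    return(data.frame(region_id = character(), genome = character(),
                      best_evalue = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(names(targets))) {
    names(targets) <- sprintf("genome%02d", seq_along(targets))
  }
  out <- lapply(names(targets), function(g) {
    tg <- targets[[g]]
    if (is.character(tg) && length(tg) == 1 &&
        !grepl("^[ACGTNacgtn]+$", tg)) {
      # looks like a file path, not a sequence
      if (!file.exists(tg)) stop("unreadable target genome file: ", tg)
      tg <- as.character(Biostrings::readDNAStringSet(tg))
    }
    if (!is.character(tg) || !length(tg)) {
      stop("unreadable target genome: ", g)
    }
    n_total <- sum(nchar(tg))
    hits <- align_to_set(region_seqs, tg, scheme, word_size = word_size,
                         min_score = min_score, n_evalue = n_total)
    best <- rep(Inf, length(region_seqs))
    names(best) <- names(region_seqs)
    if (nrow(hits)) {
      bb <- tapply(hits$evalue, hits$query_id, min)
      best[names(bb)] <- bb
    }
    data.frame(region_id = names(best), genome = g, best_evalue = best,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
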