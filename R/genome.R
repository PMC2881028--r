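#' Construct a genome annotation object
#'
#' Container for a (possibly multi-replicon) bacterial genome: replicon
#' table, gene table and optional nucleotide sequences. Coordinates are
#' 1-based inclusive throughout.
#'
#' @param replicons data.frame with columns `id`, `length`, `topology`
#'   (`"circular"` or `"linear"`) and `kind` (`"chromosome"` or `"plasmid"`).
#' @param genes data.frame with columns `id`, `replicon`, `start`, `end`,
#'   `strand` (and optionally `type`). May have zero rows.
#' @param sequences named character vector of replicon sequences
#'   (alphabet A, C, G, T, N), or `NULL` if sequences are not needed yet.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(replicons, genes = NULL, sequences = NULL) {
  stopifnot(is.data.frame(replicons),
            all(c("id", "length") %in% names(replicons)))
  replicons$id <- as.character(replicons$id)
  replicons$length <- as.integer(replicons$length)
  if (any(replicons$length < 1)) stop("replicon lengths must be >= 1")
  if (anyDuplicated(replicons$id)) stop("duplicated replicon ids")
  if (is.null(replicons$topology)) replicons$topology <- "circular"
  if (is.null(replicons$kind)) replicons$kind <- "chromosome"
  stopifnot(all(replicons$topology %in% c("circular", "linear")),
            all(replicons$kind %in% c("chromosome", "plasmid")))

  if (is.null(genes)) {
    genes <- data.frame(id = character(), replicon = character(),
                        start = integer(), end = integer(),
                        strand = character(), type = character(),
                        stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    for (col in c("id", "replicon", "strand")) {
      genes[[col]] <- as.character(genes[[col]])
    }
    if (is.null(genes$type)) genes$type <- "gene"
    bad <- !genes$replicon %in% replicons$id
    if (any(bad)) {
      stop("gene(s) reference unknown replicon: ",
           paste(unique(genes$replicon[bad]), collapse = ", "))
    }
    rlen <- replicons$length[match(genes$replicon, replicons$id)]
    if (any(genes$start < 1 | genes$end < genes$start | genes$end > rlen)) {
      off <- which(genes$start < 1 | genes$end < genes$start |
                     genes$end > rlen)[1]
      stop(sprintf("gene '%s' has coordinates outside replicon '%s' (1..%d)",
                   genes$id[off], genes$replicon[off], rlen[off]))
    }
  }
  if (!is.null(sequences)) {
    sequences <- vapply(sequences, as.character, character(1))
    miss <- setdiff(replicons$id, names(sequences))
    if (length(miss)) stop("missing sequence for replicon(s): ",
                           paste(miss, collapse = ", "))
    nch <- nchar(sequences[replicons$id])
    if (any(nch != replicons$length)) {
      stop("sequence length disagrees with stated replicon length for: ",
           paste(replicons$id[nch != replicons$length], collapse = ", "))
    }
    if (any(grepl("[^ACGTN]", sequences))) {
      stop("replicon sequences may contain only A, C, G, T, N")
    }
  }
  structure(list(replicons = replicons, genes = genes,
                 sequences = sequences),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d replicon(s), %.3f Mb, %d gene(s)%s\n",
              nrow(x$replicons), sum(x$replicons$length) / 1e6,
              nrow(x$genes),
              if (is.null(x$sequences)) " (no sequences)" else ""))
  invisible(x)
}

#' Load an annotated genome from FASTA and GFF3
#'
#' Reads replicon sequences from a FASTA file and gene features from a GFF3
#' file. Replicon kind is inferred from the FASTA description (records whose
#' header mentions "plasmid" become plasmids) unless `kind` is supplied.
#'
#' @param fasta_path path to a FASTA file of replicon sequences.
#' @param annotation_path path to a GFF3 file, or `NULL` for a genome with
#'   no gene features.
#' @param feature_types GFF3 feature types that bound intergenic regions
#'   (default `"gene"`; e.g. `c("gene","rRNA","tRNA")` to let structural
#'   RNA genes bound IGRs too).
#' @param topology default replicon topology, recycled across replicons.
#' @param kind optional character vector (named by replicon id) overriding
#'   the inferred chromosome/plasmid kind.
#' @return A [genome_annotation] object with sequences attached.
#' @export
load_genome <- function(fasta_path, annotation_path = NULL,
                        feature_types = "gene",
                        topology = "circular", kind = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(seqs)) stop("no sequence records in ", fasta_path)
  full_names <- names(seqs)
  ids <- sub("\\s.*$", "", full_names)
  sequences <- as.character(seqs)
  names(sequences) <- ids
  inferred <- ifelse(grepl("plasmid", full_names, ignore.case = TRUE),
                     "plasmid", "chromosome")
  if (!is.null(kind)) {
    inferred[match(names(kind), ids)] <- unname(kind)
  }
  replicons <- data.frame(id = ids, length = nchar(sequences),
                          topology = rep_len(topology, length(ids)),
                          kind = inferred, stringsAsFactors = FALSE)

  genes <- NULL
  if (!is.null(annotation_path)) {
    if (!file.exists(annotation_path)) {
      stop("annotation file not found: ", annotation_path)
    }
    gff <- tryCatch(
      rtracklayer::import(annotation_path, format = "gff3"),
      error = function(e) stop("malformed GFF3 in ", annotation_path, ": ",
                               conditionMessage(e)))
    if (length(gff)) {
      keep <- as.character(gff$type) %in% feature_types
      gff <- gff[keep]
    }
    if (length(gff)) {
      gid <- if (!is.null(gff$ID)) as.character(gff$ID) else NA_character_
      gid[is.na(gid)] <- sprintf("feature_%d", which(is.na(gid)))
      genes <- data.frame(
        id = gid,
        replicon = as.character(GenomicRanges::seqnames(gff)),
        start = GenomicRanges::start(gff),
        end = GenomicRanges::end(gff),
        strand = ifelse(as.character(GenomicRanges::strand(gff)) == "-",
                        "-", "+"),
        type = as.character(gff$type),
        stringsAsFactors = FALSE)
    }
  }
  genome_annotation(replicons, genes, sequences)
}

#' Extract intergenic regions (IGRs)
#'
#' IGRs are the maximal gaps between the strand-ignored union of gene
#' intervals on each replicon, filtered to a minimum length. On circular
#' replicons the gap spanning the origin is kept as a single wrapped region,
#' stored with `start > end`; a circular replicon without genes yields one
#' IGR covering the whole replicon.
#'
#' @param annotation a [genome_annotation].
#' @param min_len minimum IGR length in bp (default 60).
#' @return data.frame with columns `id`, `replicon`, `start`, `end`,
#'   `length`, ordered by replicon then start.
#' @export
extract_igrs <- function(annotation, min_len = 60) {
  stopifnot(inherits(annotation, "genome_annotation"), min_len >= 1)
  out <- list()
  for (r in seq_len(nrow(annotation$replicons))) {
    rid <- annotation$replicons$id[r]
    L <- annotation$replicons$length[r]
    circular <- annotation$replicons$topology[r] == "circular"
    g <- annotation$genes[annotation$genes$replicon == rid, , drop = FALSE]
    if (!nrow(g)) {
      gaps <- data.frame(start = 1L, end = L)
      if (!circular && L < 1) gaps <- gaps[0, ]
    } else {
      ir <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
      st <- IRanges::start(ir); en <- IRanges::end(ir)
      k <- length(st)
      gaps <- data.frame(start = integer(), end = integer())
      if (k > 1) {
        gaps <- data.frame(start = en[-k] + 1L, end = st[-1] - 1L)
        gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]
      }
      if (circular) {
        # terminal gap wraps the origin unless genes touch both ends
        ws <- en[k] + 1L
        we <- st[1] - 1L
        if (ws > L) ws <- ws - L
        if (we < 1) we <- we + L
        wrap_len <- (we - ws) %% L + 1L
        covered <- sum(en - st + 1L)
        if (covered < L) {
          gaps <- rbind(gaps, data.frame(start = ws, end = we))
        }
      } else {
        if (st[1] > 1) gaps <- rbind(data.frame(start = 1L, end = st[1] - 1L),
                                     gaps)
        if (en[k] < L) gaps <- rbind(gaps,
                                     data.frame(start = en[k] + 1L, end = L))
      }
    }
    if (!nrow(gaps)) next
    len <- ifelse(gaps$end >= gaps$start,
                  gaps$end - gaps$start + 1L,
                  (gaps$end - gaps$start) %% L + 1L)
    gaps$length <- as.integer(len)
    gaps <- gaps[gaps$length >= min_len, , drop = FALSE]
    if (!nrow(gaps)) next
    gaps <- gaps[order(gaps$start), , drop = FALSE]
    gaps$replicon <- rid
    out[[rid]] <- gaps
  }
  if (!length(out)) {
    return(data.frame(id = character(), replicon = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  igrs <- do.call(rbind, out)
  rownames(igrs) <- NULL
  igrs$id <- sprintf("IGR_%s_%05d", igrs$replicon,
                     stats::ave(seq_len(nrow(igrs)), igrs$replicon,
                                FUN = seq_along))
  igrs[, c("id", "replicon", "start", "end", "length")]
}

#' Fetch the forward-strand sequence of an intergenic region
#'
#' Wrapped regions (circular replicons, `start > end`) concatenate the arc
#' up to the replicon end with the arc from position 1.
#'
#' @param region one-row data.frame (or list) with `replicon`, `start`,
#'   `end` as produced by [extract_igrs()].
#' @param annotation a [genome_annotation] carrying sequences.
#' @return Nucleotide string.
#' @export
igr_sequence <- function(region, annotation) {
  if (is.null(annotation$sequences)) {
    stop("annotation carries no sequences; reload the genome with FASTA")
  }
  rid <- as.character(region$replicon)
  s <- annotation$sequences[[rid]]
  if (is.null(s)) stop("unknown replicon: ", rid)
  a <- as.integer(region$start)
  b <- as.integer(region$end)
  if (a <= b) {
    substr(s, a, b)
  } else {
    paste0(substr(s, a, nchar(s)), substr(s, 1, b))
  }
}

#' Fetch sequences for a table of regions
#'
#' @param regions data.frame with `replicon`, `start`, `end` and `id`.
#' @param annotation a [genome_annotation] carrying sequences.
#' @return Named character vector of sequences (names = region ids).
#' @export
region_sequences <- function(regions, annotation) {
  out <- vapply(seq_len(nrow(regions)), function(i) {
    igr_sequence(regions[i, ], annotation)
  }, character(1))
  names(out) <- regions$id
  out
}

#' Write intergenic regions to TSV and/or BED
#'
#' The TSV uses 1-based inclusive coordinates; the BED is 0-based
#' half-open. Wrapped regions are written with their stored `start > end`
#' in the TSV and are split at the origin in the BED.
#'
#' @param igrs data.frame from [extract_igrs()].
#' @param annotation the source [genome_annotation] (needed to split
#'   wrapped regions for BED output).
#' @param tsv,bed output paths (`NULL` to skip either).
#' @return Invisibly, the IGR table.
#' @export
write_igrs <- function(igrs, annotation, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(igrs, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed)) {
    L <- annotation$replicons$length[match(igrs$replicon,
                                           annotation$replicons$id)]
    rows <- lapply(seq_len(nrow(igrs)), function(i) {
      if (igrs$start[i] <= igrs$end[i]) {
        data.frame(chrom = igrs$replicon[i], start0 = igrs$start[i] - 1L,
                   end = igrs$end[i], name = igrs$id[i])
      } else {
        data.frame(chrom = igrs$replicon[i],
                   start0 = c(igrs$start[i] - 1L, 0L),
                   end = c(L[i], igrs$end[i]),
                   name = paste0(igrs$id[i], c("_a", "_b")))
      }
    })
    bed_df <- do.call(rbind, rows)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(igrs)
}

#' Write a genome to FASTA and GFF3
#'
#' @param annotation a [genome_annotation] with sequences.
#' @param fasta_path,gff_path output paths (`NULL` to skip either).
#' @return Invisibly, `annotation`.
#' @export
write_genome <- function(annotation, fasta_path = NULL, gff_path = NULL) {
  if (!is.null(fasta_path)) {
    if (is.null(annotation$sequences)) stop("no sequences to write")
    hdr <- ifelse(annotation$replicons$kind == "plasmid",
                  paste(annotation$replicons$id, "plasmid"),
                  annotation$replicons$id)
    sset <- Biostrings::DNAStringSet(
      annotation$sequences[annotation$replicons$id])
    names(sset) <- hdr
    Biostrings::writeXStringSet(sset, fasta_path, width = 80)
  }
  if (!is.null(gff_path)) {
    g <- annotation$genes
    con <- file(gff_path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(g)) {
      writeLines(sprintf("%s\tsrnatile\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                         g$replicon, g$type, g$start, g$end, g$strand, g$id),
                 con)
    }
  }
  invisible(annotation)
}
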