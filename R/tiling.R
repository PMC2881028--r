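#' Design a regular tiling probe layout
#'
#' Places fixed-length probes at a constant start-to-start spacing along
#' each replicon. With a 60-mer probe every 13 bp, consecutive probes
#' overlap by 47 bp. On linear replicons the last probe is the last one
#' that fits entirely; on circular replicons probe starts run to the end
#' of the replicon and the final probes wrap across the origin.
#'
#' @param annotation a [genome_annotation].
#' @param probe_length probe length in bp (default 60).
#' @param spacing start-to-start spacing in bp (default 13).
#' @param strands strands to tile (default forward only).
#' @return An object of class `tiling_design`: list with `probes`
#'   (data.frame `id`, `replicon`, `start`, `length`, `strand`),
#'   `probe_length` and `spacing`.
#' @export
design_tiling <- function(annotation, probe_length = 60, spacing = 13,
                          strands = "+") {
  stopifnot(inherits(annotation, "genome_annotation"),
            spacing >= 1, probe_length >= 1,
            all(strands %in% c("+", "-")))
  probes <- list()
  for (r in seq_len(nrow(annotation$replicons))) {
    rid <- annotation$replicons$id[r]
    L <- annotation$replicons$length[r]
    circular <- annotation$replicons$topology[r] == "circular"
    if (probe_length > L) {
      stop(sprintf("probe length %d exceeds replicon '%s' length %d",
                   probe_length, rid, L))
    }
    max_start <- if (circular) L else L - probe_length + 1L
    starts <- seq.int(1L, max_start, by = spacing)
    for (strand in strands) {
      probes[[paste(rid, strand)]] <- data.frame(
        id = sprintf("P_%s_%s_%07d", rid,
                     ifelse(strand == "+", "f", "r"), starts),
        replicon = rid, start = as.integer(starts),
        length = as.integer(probe_length), strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, probes)
  rownames(probes) <- NULL
  structure(list(probes = probes, probe_length = as.integer(probe_length),
                 spacing = as.integer(spacing)),
            class = "tiling_design")
}

#' @export
print.tiling_design <- function(x, ...) {
  cat(sprintf(
    "tiling_design: %d probes, %d-mers every %d bp (overlap %d bp)\n",
    nrow(x$probes), x$probe_length, x$spacing,
    max(x$probe_length - x$spacing, 0L)))
  invisible(x)
}

# Decompose a (possibly origin-wrapped) interval into linear arcs.
interval_arcs <- function(start, end, L) {
  if (start <= end) {
    cbind(start = start, end = end)
  } else {
    rbind(cbind(start = start, end = L), cbind(start = 1L, end = end))
  }
}

# Total overlap in bp between two possibly wrapped intervals on a circle
# of length L.
arc_overlap <- function(s1, e1, s2, e2, L) {
  a1 <- interval_arcs(s1, e1, L)
  a2 <- interval_arcs(s2, e2, L)
  ov <- 0L
  for (i in seq_len(nrow(a1))) {
    for (j in seq_len(nrow(a2))) {
      ov <- ov + max(0L, min(a1[i, "end"], a2[j, "end"]) -
                       max(a1[i, "start"], a2[j, "start"]) + 1L)
    }
  }
  ov
}

#' Assign probes to a genomic region
#'
#' A probe is assigned to a region when its overlap with the region is at
#' least `min_overlap_frac` of the probe length (majority overlap by
#' default, which keeps flanking-gene signal out of region summaries).
#'
#' @param design a [design_tiling()] result.
#' @param region one-row data.frame (or list) with `replicon`, `start`,
#'   `end`.
#' @param annotation the [genome_annotation] (for replicon lengths, needed
#'   to resolve wrapped probes/regions).
#' @param min_overlap_frac minimum overlap as a fraction of probe length.
#' @return The assigned rows of `design$probes`, ordered by start.
#' @export
probes_for_region <- function(design, region, annotation,
                              min_overlap_frac = 0.5) {
  rid <- as.character(region$replicon)
  L <- annotation$replicons$length[match(rid, annotation$replicons$id)]
  pr <- design$probes[design$probes$replicon == rid, , drop = FALSE]
  if (!nrow(pr)) return(pr)
  need <- min_overlap_frac * design$probe_length
  rs <- as.integer(region$start); re <- as.integer(region$end)
  plen <- design$probe_length
  if (rs <= re && all(pr$start + plen - 1L <= L)) {
    # fast vectorized path: nothing wraps
    pe <- pr$start + plen - 1L
    ov <- pmin(pe, re) - pmax(pr$start, rs) + 1L
    keep <- ov >= need
  } else {
    pend <- (pr$start + plen - 2L) %% L + 1L
    keep <- vapply(seq_len(nrow(pr)), function(i) {
      arc_overlap(pr$start[i], pend[i], rs, re, L) >= need
    }, logical(1))
  }
  out <- pr[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Assign probes to many regions at once
#'
#' Vectorized convenience around the single-region assignment rule:
#' returns, for each region, the ids of probes whose overlap with the
#' region is at least `min_overlap_frac` of the probe length.
#'
#' @inheritParams probes_for_region
#' @param regions data.frame of regions (`id`, `replicon`, `start`, `end`).
#' @return Named list (by region id) of probe id character vectors.
#' @export
assign_probes <- function(design, regions, annotation,
                          min_overlap_frac = 0.5) {
  plen <- design$probe_length
  need <- min_overlap_frac * plen
  out <- vector("list", nrow(regions))
  names(out) <- regions$id
  for (rid in unique(regions$replicon)) {
    L <- annotation$replicons$length[match(rid, annotation$replicons$id)]
    pr <- design$probes[design$probes$replicon == rid, , drop = FALSE]
    ord <- order(pr$start)
    pr <- pr[ord, , drop = FALSE]
    idx <- which(regions$replicon == rid)
    wraps <- pr$start + plen - 1L > L
    for (i in idx) {
      rs <- regions$start[i]; re <- regions$end[i]
      if (rs <= re) {
        # probe starts that can reach the overlap threshold
        lo <- rs - plen + ceiling(need)
        hi <- re - ceiling(need) + 1L
        sel <- which(pr$start >= lo & pr$start <= hi)
        if (length(sel)) {
          pe <- pr$start[sel] + plen - 1L
          ov <- pmin(pe, re) - pmax(pr$start[sel], rs) + 1L
          ov[pe > L] <- NA  # wrapped probes: exact arc check below
          keep <- !is.na(ov) & ov >= need
          slow <- sel[is.na(ov)]
        } else {
          keep <- logical(0); slow <- integer(0)
        }
        ids <- pr$id[sel[keep]]
      } else {
        ids <- character(0)
        slow <- seq_len(nrow(pr))
        sel <- integer(0)
      }
      if (length(slow)) {
        pend <- (pr$start[slow] + plen - 2L) %% L + 1L
        extra <- vapply(seq_along(slow), function(k) {
          arc_overlap(pr$start[slow[k]], pend[k], rs, re, L) >= need
        }, logical(1))
        ids <- c(ids, pr$id[slow[extra]])
      }
      out[[regions$id[i]]] <- ids
    }
  }
  out
}

#' Write / read a probe layout TSV
#'
#' Columns: `probe_id`, `replicon`, `start`, `length`, `strand`. The
#' reader accepts externally produced layouts in the same dialect.
#'
#' @param design a `tiling_design`.
#' @param path TSV path.
#' @return `write_probes` returns the path invisibly; `read_probes`
#'   returns a `tiling_design` (spacing inferred as the modal start
#'   difference).
#' @export
write_probes <- function(design, path) {
  df <- design$probes
  names(df)[names(df) == "id"] <- "probe_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "probe_id"] <- "id"
  plen <- as.integer(stats::median(df$length))
  d <- diff(sort(df$start[df$replicon == df$replicon[1] &
                            df$strand == df$strand[1]]))
  spacing <- if (length(d)) {
    as.integer(names(sort(table(d), decreasing = TRUE))[1])
  } else plen
  structure(list(probes = df, probe_length = plen, spacing = spacing),
            class = "tiling_design")
}
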