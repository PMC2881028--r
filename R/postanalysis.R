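#' Hierarchically cluster expression profiles
#'
#' Each region's per-condition profile is standardized (mean 0, sd 1
#' across conditions), clustered agglomeratively and cut into `k` groups.
#' Groups are relabelled deterministically by decreasing size (ties broken
#' by first occurrence). Rows with zero standard deviation cannot be
#' standardized and are excluded with a warning.
#'
#' @param summaries regions x conditions matrix (typically the
#'   differential regions).
#' @param k number of groups (default 3: the exponential / stationary /
#'   symbiosis pattern).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"complete"`, R's hclust default).
#' @param metric distance metric for [stats::dist()].
#' @return An object of class `profile_clusters`: list with `labels`
#'   (named integer vector), `standardized` (z-scored matrix), `tree`
#'   (the `hclust` object), `k` and `excluded`.
#' @export
cluster_profiles <- function(summaries, k = 3, linkage = "complete",
                             metric = "euclidean") {
  sds <- apply(summaries, 1, stats::sd)
  bad <- sds == 0 | is.na(sds)
  if (any(bad)) {
    warning(sum(bad), " region(s) with zero profile sd excluded from ",
            "clustering: ", paste(rownames(summaries)[bad], collapse = ", "))
    summaries <- summaries[!bad, , drop = FALSE]
  }
  if (nrow(summaries) < k) {
    stop("fewer regions (", nrow(summaries), ") than requested groups (",
         k, ")")
  }
  z <- t(scale(t(summaries)))
  tree <- stats::hclust(stats::dist(z, method = metric), method = linkage)
  raw <- stats::cutree(tree, k = k)
  # deterministic labels: 1 = largest group
  size <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(size), as.integer(first))
  relabel <- stats::setNames(seq_len(k), names(size)[ord])
  labels <- unname(relabel[as.character(raw)])
  names(labels) <- rownames(z)
  structure(list(labels = labels, standardized = z, tree = tree, k = k,
                 excluded = names(bad)[bad]),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("profile_clusters: %d regions in %d groups (%s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Write cluster assignments (and optionally the dendrogram)
#'
#' @param clusters a [cluster_profiles()] result.
#' @param tsv TSV path for standardized values + group column.
#' @param newick optional Newick path for the dendrogram (requires the
#'   `ape` package).
#' @return Invisibly, the exported data.frame.
#' @export
write_clusters <- function(clusters, tsv, newick = NULL) {
  df <- data.frame(region_id = names(clusters$labels),
                   clusters$standardized,
                   group = clusters$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(newick)) {
    if (!requireNamespace("ape", quietly = TRUE)) {
      stop("the 'ape' package is required for Newick export")
    }
    ape::write.tree(ape::as.phylo(clusters$tree), file = newick)
  }
  invisible(df)
}

#' Per-replicon density of candidate regions
#'
#' Counts regions per replicon and reports regions per megabase, plus
#' chromosome/plasmid aggregates.
#'
#' @param regions data.frame with a `replicon` column.
#' @param annotation a [genome_annotation].
#' @return An object of class `density_report`: data.frame `replicon`,
#'   `kind`, `length_mb`, `count`, `density_per_mb`, with aggregate
#'   chromosome/plasmid counts, densities and fractions in the
#'   `"aggregates"` attribute.
#' @export
replicon_density <- function(regions, annotation) {
  rep_tab <- annotation$replicons
  count <- vapply(rep_tab$id, function(r) sum(regions$replicon == r),
                  numeric(1))
  df <- data.frame(replicon = rep_tab$id, kind = rep_tab$kind,
                   length_mb = rep_tab$length / 1e6,
                   count = as.integer(count),
                   density_per_mb = count / (rep_tab$length / 1e6),
                   stringsAsFactors = FALSE)
  agg <- lapply(c(chromosome = "chromosome", plasmid = "plasmid"),
                function(kind) {
    sel <- df$kind == kind
    n <- sum(df$count[sel])
    len <- sum(df$length_mb[sel])
    list(count = n,
         density_per_mb = if (len > 0) n / len else NA_real_,
         fraction = if (nrow(regions)) n / nrow(regions) else NA_real_)
  })
  rownames(df) <- NULL
  structure(df, aggregates = agg, class = c("density_report", "data.frame"))
}

#' Sliding-window hotspot scan
#'
#' Slides a window along a replicon, counts region midpoints per window,
#' and flags windows whose count exceeds the `1 - alpha` quantile of the
#' Poisson distribution implied by uniform placement at the replicon-wide
#' rate. Formalizes the visual identification of ncRNA-dense genomic
#' stretches.
#'
#' @param regions data.frame with `replicon`, `start`, `end`.
#' @param replicon replicon id to scan.
#' @param annotation a [genome_annotation] (for the replicon length).
#' @param window window width in bp (default 300 kb).
#' @param step step between window starts in bp (default 50 kb).
#' @param alpha flagging level (default 0.01).
#' @return data.frame `replicon`, `start`, `end`, `count`, `expected`,
#'   `flagged`.
#' @export
hotspot_scan <- function(regions, replicon, annotation, window = 3e5,
                         step = 5e4, alpha = 0.01) {
  L <- annotation$replicons$length[match(replicon, annotation$replicons$id)]
  if (is.na(L)) stop("unknown replicon: ", replicon)
  if (window > L) stop("window exceeds replicon length")
  r <- regions[regions$replicon == replicon, , drop = FALSE]
  mid <- ifelse(r$start <= r$end,
                (r$start + r$end) / 2,
                ((r$start - 1 + ((r$end - r$start) %% L) / 2) %% L) + 1)
  starts <- seq(1, max(1, L - window + 1), by = step)
  count <- vapply(starts, function(s) {
    sum(mid >= s & mid <= s + window - 1)
  }, numeric(1))
  rate <- nrow(r) / L
  expected <- rate * window
  cutoff <- stats::qpois(1 - alpha, expected)
  data.frame(replicon = replicon, start = starts,
             end = pmin(starts + window - 1, L),
             count = as.integer(count), expected = expected,
             flagged = count > cutoff)
}

#' Build the region-by-genome conservation matrix
#'
#' Categorizes each (region, genome) best E-value into `strong`
#' (E <= `strong`), `weak` (E <= `weak`) or `none`, and reports the
#' percentage of conserved regions (category != `none`) per genome.
#'
#' @param scan long-form data.frame from [conservation_scan()]
#'   (`region_id`, `genome`, `best_evalue`).
#' @param strong,weak inclusive E-value tier thresholds (defaults 1e-5 and
#'   1e-3).
#' @return An object of class `conservation_matrix`: list with
#'   `categories` (regions x genomes character matrix), `best_evalue`
#'   (numeric matrix) and `pct_conserved` (named vector, percent).
#' @export
conservation_matrix <- function(scan, strong = 1e-5, weak = 1e-3) {
  stopifnot(strong <= weak)
  regions <- unique(scan$region_id)
  genomes <- unique(scan$genome)
  ev <- matrix(Inf, length(regions), length(genomes),
               dimnames = list(regions, genomes))
  ev[cbind(match(scan$region_id, regions),
           match(scan$genome, genomes))] <- scan$best_evalue
  cat_m <- matrix("none", length(regions), length(genomes),
                  dimnames = dimnames(ev))
  cat_m[ev <= weak] <- "weak"
  cat_m[ev <= strong] <- "strong"
  pct <- 100 * colMeans(cat_m != "none")
  structure(list(categories = cat_m, best_evalue = ev, pct_conserved = pct),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat(sprintf("conservation_matrix: %d regions x %d genomes\n",
              nrow(x$categories), ncol(x$categories)))
  print(round(x$pct_conserved, 1))
  invisible(x)
}

#' Write the conservation matrix TSV
#'
#' @param cm a [conservation_matrix()] result.
#' @param path TSV output path.
#' @return Invisibly, the path.
#' @export
write_conservation <- function(cm, path) {
  df <- data.frame(region_id = rownames(cm$categories), cm$categories,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
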