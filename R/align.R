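#' Nucleotide scoring scheme with Karlin-Altschul statistics
#'
#' Bundles the local-alignment scoring parameters with the statistical
#' constants needed for E-values: `lambda` is computed as the unique
#' positive root of \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for the
#' background base frequencies, and `K` is a configurable constant
#' (default 0.46, the classic value for +1/-2 nucleotide scoring).
#' Gap costs follow the BLAST convention: a gap of length g costs
#' `gap_open + g * gap_extend`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open,gap_extend gap opening / per-base extension costs
#'   (positive numbers).
#' @param K Karlin-Altschul K.
#' @param background background base frequencies (A, C, G, T); must make
#'   the expected pairwise score negative.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = 5,
                           gap_extend = 2, K = 0.46,
                           background = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0, K > 0,
            length(background) == 4, all(background >= 0))
  background <- background / sum(background)
  scheme <- structure(list(match = match, mismatch = mismatch,
                           gap_open = gap_open, gap_extend = gap_extend,
                           K = K, background = background, lambda = NA_real_),
                      class = "scoring_scheme")
  scheme$lambda <- karlin_lambda(scheme, background)
  scheme
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(paste0("scoring_scheme: match %+g mismatch %+g ",
                     "gap %g+%gk | lambda %.4f K %.3f\n"),
              x$match, x$mismatch, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

#' Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for
#' \eqn{\lambda > 0}, where \eqn{s_{ij}} is `match` on the diagonal and
#' `mismatch` off it. The statistics are undefined unless the expected
#' pairwise score is negative.
#'
#' @param scheme a [scoring_scheme] (or list with `match` / `mismatch`).
#' @param background base frequencies (A, C, G, T).
#' @return lambda, in nats per score unit.
#' @export
karlin_lambda <- function(scheme, background = rep(0.25, 4)) {
  p <- background / sum(background)
  p_match <- sum(p^2)
  exp_score <- p_match * scheme$match + (1 - p_match) * scheme$mismatch
  if (exp_score >= 0) {
    stop("expected pairwise score is non-negative; ",
         "Karlin-Altschul statistics are undefined")
  }
  f <- function(l) {
    p_match * exp(l * scheme$match) +
      (1 - p_match) * exp(l * scheme$mismatch) - 1
  }
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
}

#' Alignment E-value
#'
#' \eqn{E = K m n e^{-\lambda S}}: the expected number of chance local
#' alignments scoring at least S between a length-m query and a length-n
#' subject. Raw (unadjusted) lengths are used; no edge-effect correction.
#'
#' @param score alignment score S.
#' @param m query length in bp.
#' @param n subject length in bp.
#' @param scheme a [scoring_scheme].
#' @return E-value(s); vectorized over `score`.
#' @export
evalue <- function(score, m, n, scheme) {
  scheme$K * as.numeric(m) * as.numeric(n) * exp(-scheme$lambda * score)
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences (A, C, G, T, N).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgtn", "TGCATGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.validate_seq <- function(x, what) {
  if (!nzchar(x)) stop(what, " sequence is empty")
  if (grepl("[^ACGTNacgtn]", x)) stop(what, " contains non-ACGTN characters")
  toupper(x)
}

#' Local alignment of two nucleotide sequences
#'
#' Smith-Waterman-scored local alignment with affine gaps, searching both
#' query orientations (hits on the reverse complement are reported with
#' `strand == "-"` and query coordinates mapped back to the forward
#' query). Small problems (`m * n <= exact_limit` cells) are solved by the
#' full local dynamic program, so reported top scores are exact optimum
#' Smith-Waterman scores; larger problems use 11-mer seed-and-extend, in
#' which each extension is an exact windowed dynamic program (reported
#' scores are true local-alignment scores of the reported intervals, but
#' a hit with no seed word can be missed, as in any seeded search).
#'
#' @param query,subject nucleotide strings (A, C, G, T, N; N never
#'   matches).
#' @param scheme a [scoring_scheme].
#' @param min_score smallest score to report (default 5).
#' @param max_hits maximum hits per orientation in the exact path.
#' @param word_size seed word length for the seeded path.
#' @param exact_limit cell-count limit below which the exact dynamic
#'   program is used.
#' @return data.frame of hits: `score`, `evalue`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `strand`, sorted by decreasing score. Subject
#'   coordinates are always on the forward subject strand.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        min_score = 5, max_hits = 10, word_size = 11,
                        exact_limit = 4e6) {
  query <- .validate_seq(query, "query")
  subject <- .validate_seq(subject, "subject")
  m <- nchar(query)
  n <- nchar(subject)
  one <- function(q, strand) {
    if (as.double(m) * n <= exact_limit) {
      h <- .sw_align_cpp(q, subject, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend,
                         min_score, max_hits)
    } else {
      h <- .seed_extend_cpp(q, subject, scheme$match, scheme$mismatch,
                            scheme$gap_open, scheme$gap_extend,
                            as.integer(word_size), min_score, 30L)
      h <- h[, c("score", "q_start", "q_end", "s_start", "s_end")]
    }
    if (!nrow(h)) return(cbind(h, strand = character(0)))
    if (strand == "-") {
      qs <- m - h$q_end + 1L
      qe <- m - h$q_start + 1L
      h$q_start <- qs
      h$q_end <- qe
    }
    h$strand <- strand
    h
  }
  hits <- rbind(one(query, "+"), one(revcomp(query), "-"))
  hits$evalue <- evalue(hits$score, m, n, scheme)
  hits <- hits[order(-hits$score), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("score", "evalue", "q_start", "q_end", "s_start", "s_end",
           "strand")]
}

#' Search a set of queries against a set of subjects
#'
#' Seed-and-extend search (shared k-mer index over all subjects, both
#' query orientations, exact windowed dynamic-program extensions). This is
#' the genome-scale workhorse behind prediction-to-IGR matching and the
#' conservation scan.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param scheme a [scoring_scheme].
#' @param word_size seed word length (default 11).
#' @param min_score smallest alignment score to report.
#' @param n_evalue subject length to use in E-values: `"subject"` (each
#'   hit's own subject, the default) or a single number (e.g. total genome
#'   length for a conservation scan).
#' @return data.frame: `query_id`, `subject_id`, `score`, `evalue`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `strand`.
#' @export
align_to_set <- function(queries, subjects, scheme = scoring_scheme(),
                         word_size = 11, min_score = 12,
                         n_evalue = "subject") {
  stopifnot(length(queries) > 0)
  if (is.null(names(queries))) names(queries) <- sprintf("Q%04d",
                                                         seq_along(queries))
  if (is.null(names(subjects))) names(subjects) <- sprintf("S%04d",
                                                           seq_along(subjects))
  queries <- toupper(queries)
  subjects <- toupper(subjects)
  qlen <- nchar(queries)
  run <- function(qs, strand) {
    h <- .seed_extend_cpp(unname(qs), unname(subjects),
                          scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          as.integer(word_size), min_score, 30L)
    if (!nrow(h)) {
      return(data.frame(query_id = character(), subject_id = character(),
                        score = numeric(), q_start = integer(),
                        q_end = integer(), s_start = integer(),
                        s_end = integer(), strand = character(),
                        stringsAsFactors = FALSE))
    }
    m <- qlen[h$query]
    out <- data.frame(query_id = names(queries)[h$query],
                      subject_id = names(subjects)[h$subject],
                      score = h$score,
                      q_start = h$q_start, q_end = h$q_end,
                      s_start = h$s_start, s_end = h$s_end,
                      strand = strand, stringsAsFactors = FALSE)
    if (strand == "-") {
      qs_ <- m - out$q_end + 1L
      out$q_end <- m - out$q_start + 1L
      out$q_start <- qs_
    }
    out
  }
  hits <- rbind(run(queries, "+"), run(revcomp(queries), "-"))
  m <- qlen[hits$query_id]
  n <- if (identical(n_evalue, "subject")) {
    nchar(subjects)[hits$subject_id]
  } else {
    as.numeric(n_evalue)
  }
  hits$evalue <- evalue(hits$score, m, n, scheme)
  hits <- hits[order(hits$query_id, hits$evalue), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "subject_id", "score", "evalue", "q_start", "q_end",
           "s_start", "s_end", "strand")]
}
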