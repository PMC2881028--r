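#' Read / write a probe intensity matrix
#'
#' TSV dialect: a `probe_id` column followed by one numeric column per
#' condition. The matrix is stored as a plain numeric matrix with probe
#' ids as rownames and a `"scale"` attribute (`"raw"` or `"log2"`).
#'
#' @param path TSV path.
#' @param scale scale of the stored values.
#' @return Numeric matrix (probes x conditions).
#' @export
read_intensities <- function(path, scale = "raw") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyNA(m)) stop("intensity matrix contains missing values: ", path)
  attr(m, "scale") <- scale
  m
}

#' @rdname read_intensities
#' @param mat intensity matrix.
#' @export
write_intensities <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a raw intensity matrix
#'
#' @param mat raw intensity matrix (positive values).
#' @return The matrix on log2 scale (attribute `scale = "log2"`).
#' @export
log2_transform <- function(mat) {
  if (identical(attr(mat, "scale"), "log2")) return(mat)
  if (any(mat <= 0)) stop("raw intensities must be positive")
  out <- log2(mat)
  attr(out, "scale") <- "log2"
  out
}

#' Build the artificial reference array
#'
#' The per-probe median of log2 intensities across all arrays: the common
#' baseline each array is normalized against.
#'
#' @param mat log2 intensity matrix (probes x conditions).
#' @return Named numeric vector of per-probe medians.
#' @export
build_reference <- function(mat) {
  stopifnot(ncol(mat) >= 1)
  ref <- apply(mat, 1, stats::median)
  names(ref) <- rownames(mat)
  ref
}

#' Loess normalization against the artificial reference
#'
#' For each array j the log-ratio `M = x_j - ref` is regressed on the
#' anchor `A = ref` (the reference value itself, not the usual
#' `(x_j + ref)/2`, so the reference is never altered by the rescaling)
#' with a degree-1 local fit using tricube weights over the `span`
#' fraction of nearest probes; the fitted smooth bias is subtracted from
#' the array.
#'
#' @param mat log2 intensity matrix.
#' @param reference per-probe reference (default: [build_reference()] of
#'   `mat`).
#' @param span fraction of probes in each local fit window (default 0.25).
#' @param robust_iterations robustness (bisquare) re-weighting iterations
#'   (default 0).
#' @return Normalized log2 matrix, same shape as `mat`. The fitted bias
#'   curves are attached as attribute `"fits"` (list of `x`/`y` pairs per
#'   array) for MA-plot diagnostics.
#' @export
loess_normalize <- function(mat, reference = NULL, span = 0.25,
                            robust_iterations = 0) {
  stopifnot(span > 0, span <= 1)
  if (is.null(reference)) reference <- build_reference(mat)
  if (!is.null(rownames(mat)) && !is.null(names(reference))) {
    if (!identical(rownames(mat), names(reference))) {
      reference <- reference[rownames(mat)]
      if (anyNA(reference)) stop("reference and matrix probe ids differ")
    }
  }
  n <- nrow(mat)
  if (floor(span * n) < 3) {
    stop(sprintf("span %.3f gives local windows of fewer than 3 probes",
                 span))
  }
  out <- mat
  fits <- vector("list", ncol(mat))
  names(fits) <- colnames(mat)
  for (j in seq_len(ncol(mat))) {
    M <- mat[, j] - reference
    fit <- stats::lowess(reference, M, f = span,
                         iter = as.integer(robust_iterations))
    mhat <- stats::approx(fit$x, fit$y, xout = reference, rule = 2,
                          ties = mean)$y
    out[, j] <- mat[, j] - mhat
    fits[[j]] <- fit
  }
  attr(out, "scale") <- "log2"
  attr(out, "fits") <- fits
  out
}

#' Export MA-plot diagnostics
#'
#' Writes, for one or all arrays, the per-probe anchor `A` (reference
#' value), observed log-ratio `M` and the fitted bias curve value, as a
#' TSV for plotting.
#'
#' @param mat log2 matrix before normalization.
#' @param normalized result of [loess_normalize()] on `mat` (carries the
#'   fitted curves).
#' @param reference the reference used (default recomputed from `mat`).
#' @param path TSV output path.
#' @return Invisibly, the exported data.frame.
#' @export
export_ma_data <- function(mat, normalized, reference = NULL, path) {
  if (is.null(reference)) reference <- build_reference(mat)
  rows <- lapply(colnames(mat), function(cn) {
    data.frame(array = cn, probe_id = rownames(mat), A = reference,
               M = mat[, cn] - reference,
               fitted = mat[, cn] - normalized[, cn],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Tukey median polish
#'
#' Robust additive decomposition `x[i,j] = overall + row[i] + col[j] +
#' residual[i,j]` by alternating row and column median sweeps (rows
#' first). Iteration stops when the largest absolute sweep adjustment
#' falls below `tol` or after `max_iter` full sweeps.
#'
#' @param x numeric matrix.
#' @param tol convergence tolerance on the sweep adjustments.
#' @param max_iter maximum number of full row+column sweeps.
#' @return List with `overall`, `row`, `col`, `residuals`, `iterations`,
#'   `converged`.
#' @export
median_polish <- function(x, tol = 1e-4, max_iter = 10) {
  x <- as.matrix(x)
  z <- x
  r <- numeric(nrow(x))
  cc <- numeric(ncol(x))
  t0 <- 0
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    rdelta <- apply(z, 1, stats::median)
    z <- z - rdelta
    r <- r + rdelta
    d <- stats::median(cc)
    cc <- cc - d
    t0 <- t0 + d
    cdelta <- apply(z, 2, stats::median)
    z <- sweep(z, 2, cdelta)
    cc <- cc + cdelta
    d2 <- stats::median(r)
    r <- r - d2
    t0 <- t0 + d2
    adj <- max(abs(c(rdelta, cdelta, d, d2)))
    if (adj < tol) {
      converged <- TRUE
      break
    }
  }
  list(overall = t0, row = stats::setNames(r, rownames(x)),
       col = stats::setNames(cc, colnames(x)),
       residuals = z, iterations = it, converged = converged)
}

#' Summarize regions by median polish
#'
#' Combines the normalized intensities of the probes assigned to each
#' region into one value per condition: the median-polish overall effect
#' plus the condition (column) effect. Single-probe regions return that
#' probe's values; regions with no assigned probe are flagged and excluded
#' from the summary matrix.
#'
#' @param mat normalized log2 intensity matrix (probes x conditions).
#' @param assignment named list (by region id) of probe id vectors, as
#'   from [assign_probes()].
#' @param tol,max_iter median-polish convergence controls.
#' @return An object of class `region_summaries`: list with `summaries`
#'   (regions x conditions matrix, excluded regions dropped), `n_probes`
#'   (named vector over all regions) and `excluded` (ids of zero-probe
#'   regions).
#' @export
summarize_regions <- function(mat, assignment, tol = 1e-4, max_iter = 10) {
  ids <- names(assignment)
  n_probes <- stats::setNames(lengths(assignment), ids)
  keep <- n_probes > 0
  summ <- matrix(NA_real_, sum(keep), ncol(mat),
                 dimnames = list(ids[keep], colnames(mat)))
  for (rid in ids[keep]) {
    probes <- assignment[[rid]]
    sub <- mat[probes, , drop = FALSE]
    if (nrow(sub) == 1) {
      summ[rid, ] <- sub[1, ]
    } else {
      mp <- median_polish(sub, tol = tol, max_iter = max_iter)
      summ[rid, ] <- mp$overall + mp$col
    }
  }
  structure(list(summaries = summ, n_probes = n_probes,
                 excluded = ids[!keep]),
            class = "region_summaries")
}

#' @export
print.region_summaries <- function(x, ...) {
  cat(sprintf(
    "region_summaries: %d regions x %d conditions (%d excluded, 0 probes)\n",
    nrow(x$summaries), ncol(x$summaries), length(x$excluded)))
  invisible(x)
}
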