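#' Fit a robust noise model to log2 expression summaries
#'
#' Models the unexpressed bulk of a per-condition summary distribution as
#' Gaussian noise, estimated robustly so an expressed upper tail cannot
#' inflate it, and sets the expression cutoff at the inverse normal
#' cumulative distribution function at `percentile`:
#' `threshold = location + qnorm(percentile) * scale`.
#'
#' Estimators for the scale:
#' \describe{
#'   \item{`"left-half"` (default)}{`median - Q(0.1587)`, the one-sided
#'     normal sigma estimate using only the lower tail (for a Gaussian,
#'     the 15.87th percentile lies one sigma below the median). Immune to
#'     an expressed upper tail.}
#'   \item{`"mad"`}{`1.4826 * median(|x - median|)`.}
#' }
#'
#' @param values numeric vector of log2 summaries (>= 20 values).
#' @param estimator `"left-half"` or `"mad"`.
#' @param percentile cutoff percentile (default 0.999).
#' @return An object of class `noise_model`: list with `location`,
#'   `scale`, `estimator`, `percentile`, `threshold`, `n`.
#' @export
fit_noise <- function(values, estimator = c("left-half", "mad"),
                      percentile = 0.999) {
  estimator <- match.arg(estimator)
  values <- values[!is.na(values)]
  if (length(values) < 20) {
    stop("need at least 20 values to fit the noise model, got ",
         length(values))
  }
  stopifnot(percentile > 0, percentile < 1)
  location <- stats::median(values)
  scale <- switch(estimator,
    "left-half" = location - stats::quantile(values, stats::pnorm(-1),
                                             names = FALSE, type = 7),
    "mad" = stats::mad(values))
  if (scale <= 0) {
    stop("noise scale is zero (values are degenerate); cannot set a cutoff")
  }
  structure(list(location = location, scale = scale, estimator = estimator,
                 percentile = percentile,
                 threshold = location + stats::qnorm(percentile) * scale,
                 n = length(values)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "noise_model (%s): location %.4f scale %.4f -> threshold %.4f (%.2f%%)\n",
    x$estimator, x$location, x$scale, x$threshold, 100 * x$percentile))
  invisible(x)
}

#' Call expressed regions against per-condition noise thresholds
#'
#' A region is expressed in a condition when its summary exceeds that
#' condition's noise threshold, and expressed overall when it is expressed
#' in at least one condition.
#'
#' @param summaries regions x conditions matrix of log2 summaries.
#' @param models list of [fit_noise()] models, one per condition (in
#'   column order), each fitted on the corresponding summary column.
#' @return List with `expressed_in` (logical matrix), `expressed` (logical
#'   vector) and `thresholds` (numeric vector).
#' @export
call_expressed <- function(summaries, models) {
  stopifnot(length(models) == ncol(summaries))
  thr <- vapply(models, function(m) m$threshold, numeric(1))
  names(thr) <- colnames(summaries)
  flags <- sweep(summaries, 2, thr, `>`)
  list(expressed_in = flags,
       expressed = apply(flags, 1, any),
       thresholds = thr)
}

#' Call differentially expressed regions from profile standard deviations
#'
#' Computes each region's sample standard deviation (n-1 denominator)
#' across conditions and applies the same robust noise-threshold procedure
#' to the distribution of those standard deviations. The noise model is
#' fitted on the standard deviations of all supplied regions (the bulk of
#' which behave like noise); the differential flag is granted only to
#' regions in `universe` (typically the expressed ones).
#'
#' @param summaries regions x conditions matrix (>= 2 conditions).
#' @param universe logical vector or region id vector restricting which
#'   regions may be flagged; `NULL` means all.
#' @param estimator,percentile passed to [fit_noise()].
#' @return List with `sd` (named vector), `threshold`, `differential`
#'   (logical vector) and `model` (the fitted [fit_noise()] model).
#' @export
call_differential <- function(summaries, universe = NULL,
                              estimator = c("left-half", "mad"),
                              percentile = 0.999) {
  stopifnot(ncol(summaries) >= 2)
  sds <- apply(summaries, 1, stats::sd)
  model <- fit_noise(sds, estimator = estimator, percentile = percentile)
  diff <- sds > model$threshold
  if (!is.null(universe)) {
    if (is.character(universe)) {
      universe <- rownames(summaries) %in% universe
    }
    diff <- diff & universe
  }
  list(sd = sds, threshold = model$threshold, differential = diff,
       model = model)
}

#' Detect expressed and differential regions in one step
#'
#' Fits one noise model per condition on the region summaries of that
#' condition, calls expression, then calls differential expression on the
#' profile standard deviations (flags restricted to expressed regions by
#' default).
#'
#' @param summaries regions x conditions matrix of normalized log2
#'   summaries.
#' @param estimator,percentile noise-model controls (see [fit_noise()]).
#' @param differential_universe `"expressed"` (default) or `"all"`.
#' @return An object of class `region_expression`: data.frame with the
#'   per-condition summaries, per-condition `expressed_in.*` flags,
#'   `expressed`, `sd` and `differential`; per-condition thresholds and
#'   the sd threshold are attached as attributes `"thresholds"` and
#'   `"sd_threshold"`.
#' @export
detect_regions <- function(summaries, estimator = c("left-half", "mad"),
                           percentile = 0.999,
                           differential_universe = c("expressed", "all")) {
  estimator <- match.arg(estimator)
  differential_universe <- match.arg(differential_universe)
  models <- lapply(seq_len(ncol(summaries)), function(j) {
    fit_noise(summaries[, j], estimator = estimator,
              percentile = percentile)
  })
  expr <- call_expressed(summaries, models)
  universe <- if (differential_universe == "expressed") {
    expr$expressed
  } else NULL
  diff <- call_differential(summaries, universe = universe,
                            estimator = estimator, percentile = percentile)
  out <- data.frame(region_id = rownames(summaries), summaries,
                    expr$expressed_in, expressed = expr$expressed,
                    sd = diff$sd, differential = diff$differential,
                    check.names = TRUE, stringsAsFactors = FALSE)
  names(out)[seq_len(ncol(summaries)) + 1] <- colnames(summaries)
  names(out)[seq_len(ncol(summaries)) + 1 + ncol(summaries)] <-
    paste0("expressed_", colnames(summaries))
  rownames(out) <- NULL
  attr(out, "thresholds") <- expr$thresholds
  attr(out, "sd_threshold") <- diff$threshold
  attr(out, "estimator") <- estimator
  attr(out, "percentile") <- percentile
  class(out) <- c("region_expression", "data.frame")
  out
}

#' @export
print.region_expression <- function(x, ...) {
  cat(sprintf(
    "region_expression: %d regions, %d expressed, %d differential\n",
    nrow(x), sum(x$expressed), sum(x$differential)))
  invisible(x)
}

#' Write the detection report
#'
#' TSV with one row per region; the per-condition and sd thresholds are
#' recorded in `#`-prefixed header metadata lines.
#'
#' @param detection a [detect_regions()] result.
#' @param path TSV output path.
#' @return Invisibly, the path.
#' @export
write_detection <- function(detection, path) {
  con <- file(path, "w")
  on.exit(close(con))
  thr <- attr(detection, "thresholds")
  writeLines(c(
    sprintf("# estimator=%s percentile=%g", attr(detection, "estimator"),
            attr(detection, "percentile")),
    sprintf("# threshold %s=%.6f", names(thr), thr),
    sprintf("# sd_threshold=%.6f", attr(detection, "sd_threshold"))), con)
  utils::write.table(detection, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
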