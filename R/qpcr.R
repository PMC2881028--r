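#' Efficiency-corrected relative expression (Pfaffl ratio)
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, where each efficiency E
#' is the fold amplification per cycle (2 = perfect doubling) and each
#' delta-Ct is `Ct(calibrator) - Ct(sample)` (Pfaffl's original sign
#' convention: a sample with fewer cycles than the calibrator has a
#' positive delta-Ct and a ratio above 1).
#'
#' @param e_target,e_ref amplification efficiencies (> 0; sane assays lie
#'   in 1-2.2).
#' @param dct_target,dct_ref delta-Ct values in cycles (calibrator minus
#'   sample).
#' @return Relative expression ratio(s); vectorized.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (any(e_target <= 0) || any(e_ref <= 0)) {
    stop("amplification efficiencies must be positive")
  }
  e_target^dct_target / e_ref^dct_ref
}

#' Amplification efficiency from a standard-curve slope
#'
#' For a dilution-series standard curve of Ct against log10 template
#' amount, `efficiency = 10^(-1/slope)`; a perfect assay has slope
#' -3.3219 and efficiency 2.
#'
#' @param slope standard-curve slope in Ct per log10 dilution (must be
#'   negative).
#' @return Efficiency in fold per cycle; vectorized.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) {
    stop("standard-curve slope must be negative (Ct decreases with ",
         "template amount)")
  }
  10^(-1 / slope)
}

#' Compute Pfaffl ratios for a qPCR measurement table
#'
#' @param measurements data.frame with columns `target`, `e_target`,
#'   `dct_target`, `e_ref`, `dct_ref` (one row per target x condition).
#' @param path optional TSV output path.
#' @return The input with a `ratio` column appended.
#' @export
pfaffl_table <- function(measurements, path = NULL) {
  measurements$ratio <- pfaffl_ratio(measurements$e_target,
                                     measurements$dct_target,
                                     measurements$e_ref,
                                     measurements$dct_ref)
  if (!is.null(path)) {
    utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  measurements
}
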