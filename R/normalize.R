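#' TMM normalization and counts per million
#'
#' Trimmed-mean-of-M-values scaling factors (trimming 30% on log-ratios and
#' 5% on average log-abundance by default, reference chosen by the
#' 75th-percentile rule) rescaled to geometric mean 1, and CPM on the
#' effective library sizes: CPM_ij = counts_ij / (libsize_j x factor_j) x 1e6.
#' Computed with edgeR, the implementation this normalization originates
#' from.
#'
#' @param x A [count_table] (>= 2 samples).
#' @param trim_M Fraction trimmed from each tail of the M-values.
#' @param trim_A Fraction trimmed by average log-abundance.
#' @return List of class `normalized_table`: `cpm` (taxa x samples matrix),
#'   `tmm_factors`, `lib_sizes` (both named by sample), `kingdom`.
#' @export
tmm_normalize <- function(x, trim_M = 0.3, trim_A = 0.05) {
  stopifnot(inherits(x, "count_table"), ncol(x$counts) >= 2)
  dge <- edgeR::DGEList(counts = x$counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM",
                                logratioTrim = trim_M, sumTrim = trim_A)
  cpm <- edgeR::cpm(dge, normalized.lib.sizes = TRUE, log = FALSE)
  structure(list(cpm = cpm,
                 tmm_factors = stats::setNames(dge$samples$norm.factors,
                                               colnames(x$counts)),
                 lib_sizes = stats::setNames(dge$samples$lib.size,
                                             colnames(x$counts)),
                 kingdom = x$kingdom),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("normalized_table: %d taxa x %d samples (%s), TMM factors in [%.3f, %.3f]\n",
              nrow(x$cpm), ncol(x$cpm), x$kingdom,
              min(x$tmm_factors), max(x$tmm_factors)))
  invisible(x)
}
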