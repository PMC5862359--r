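#' Per-sample library sizes
#'
#' Column sums of a count matrix. Errors if any sample has total zero,
#' naming it.
#'
#' @param counts gene x sample matrix.
#' @return Positive numeric vector of totals, one per sample.
#' @export
library_sizes <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    bad <- colnames(counts)[tot <= 0]
    if (is.null(bad)) bad <- which(tot <= 0)
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  tot
}

#' Normalization factors
#'
#' Computes per-sample size factors by one of two methods.
#' \code{"libsize"} uses the library size; \code{"median_ratio"} uses the
#' median-of-ratios method of bulk RNA-seq: for each sample, the factor is
#' the median over all-positive genes of the ratio of the sample's count to
#' the gene's geometric mean across samples. Factors are rescaled to
#' geometric mean one, so effective library sizes (factor times the mean
#' library size on the log scale) remain interpretable as sequencing depths.
#'
#' @param counts gene x sample matrix.
#' @param method \code{"libsize"} or \code{"median_ratio"}.
#' @return An object of class \code{"norm_factors"}: list with
#'   \code{size_factor} (geometric mean 1), \code{effective_libsize} and
#'   \code{method}.
#' @export
normalization_factors <- function(counts, method = c("libsize", "median_ratio")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  lib <- library_sizes(counts)
  sf <- switch(method,
    libsize = lib,
    median_ratio = median_ratio_size_factors(counts)
  )
  sf <- sf / exp(mean(log(sf)))
  structure(list(size_factor = sf,
                 effective_libsize = sf * exp(mean(log(lib))),
                 method = method),
            class = "norm_factors")
}

#' Median-of-ratios size factors
#'
#' Raw median-of-ratios factors: per sample, the median over genes with
#' all-positive counts of count / (geometric mean of the gene across
#' samples). Errors if no gene is positive in every sample (filter first).
#'
#' @param counts gene x sample matrix.
#' @return Positive numeric vector of per-sample factors (unrescaled).
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos)) {
    stop("no gene has positive counts in all samples; ",
         "filter low-abundance genes before median-of-ratios normalization")
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2L, stats::median)
}

#' Counts per million
#'
#' CPM on effective library sizes; with \code{log = TRUE}, returns
#' \code{log2((count + prior_count) / (lib + 2 * prior_count) * 1e6)}, the
#' standard prior-damped log-CPM that keeps zero counts finite.
#'
#' @param counts gene x sample matrix.
#' @param lib effective library sizes (positive; default column sums).
#' @param log return log2-CPM values.
#' @param prior_count prior count added before logging (default 0.5).
#' @return Real matrix with the dimensions of \code{counts}.
#' @export
cpm <- function(counts, lib = NULL, log = FALSE, prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(lib)) lib <- colSums(counts)
  if (inherits(lib, "norm_factors")) lib <- lib$effective_libsize
  if (length(lib) != ncol(counts)) {
    stop("'lib' must have one entry per sample")
  }
  if (any(!is.finite(lib)) || any(lib <= 0)) {
    stop("effective library sizes must be positive and finite")
  }
  if (log) {
    t((log2(t(counts) + prior_count) - log2(lib + 2 * prior_count)) + log2(1e6))
  } else {
    t(t(counts) / lib) * 1e6
  }
}
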