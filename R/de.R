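#' Differential expression between two groups
#'
#' The central fitting function. Takes a gene x sample count matrix (cells,
#' or per-plate sums from [sum_by_plate()]) and a two-level group factor,
#' normalizes, and tests every gene for a difference in mean expression
#' between the groups with one of three engines:
#' \describe{
#'   \item{\code{"ql"}}{NB GLM with Cox-Reid adjusted-profile-likelihood
#'     dispersion estimation and a quasi-likelihood F-test with
#'     empirical-Bayes shrinkage of the quasi-dispersions.}
#'   \item{\code{"lrt"}}{NB GLM likelihood-ratio test at the per-gene
#'     Cox-Reid dispersion estimates, without shrinkage. Warns on designs
#'     with few residual degrees of freedom (e.g. per-plate sums), where
#'     per-gene dispersion estimation is unstable.}
#'   \item{\code{"voom"}}{precision-weighted moderated linear model on
#'     log2-CPMs with empirical-Bayes variance moderation and a moderated
#'     t-test.}
#' }
#'
#' @param counts gene x sample count matrix, or a \code{"summed_counts"}
#'   object (whose plate groups are then used when \code{group} is
#'   missing).
#' @param group factor with exactly two levels, one entry per sample. The
#'   reported log2 fold change is second level over first.
#' @param engine \code{"ql"}, \code{"lrt"} or \code{"voom"}.
#' @param normalization \code{"libsize"} (per-cell analyses) or
#'   \code{"median_ratio"} (recommended for per-plate sums).
#' @param dispersion_trend \code{"auto"} (LOWESS smoothing of the CR-APL
#'   dispersions on abundance when at least 100 genes are available to pool
#'   across, raw per-gene estimates otherwise), \code{"none"}, or
#'   \code{"lowess"}. Pooling is essential at low residual degrees of
#'   freedom (e.g. per-plate sums), where per-gene dispersion maxima are
#'   far too noisy to anchor the quasi-likelihood denominator. Ignored by
#'   the voom engine.
#' @param ... further engine arguments (e.g. \code{span}, \code{prior_count}
#'   for voom).
#' @return Object of class \code{"de_fit"}: list with \code{table}
#'   (data.frame: \code{gene}, \code{log2fc}, \code{stat}, \code{pvalue},
#'   \code{fdr}), \code{engine}, \code{n_samples}, \code{residual_df},
#'   \code{group_levels}, and engine extras (\code{d0}, \code{dispersion}).
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 60, mean_log_mu = log(20),
#'                                  seed = 1))
#' s <- sum_by_plate(d$counts, d$design)
#' fit <- de_test(s, engine = "voom", normalization = "median_ratio")
#' summary(fit)
#' @export
de_test <- function(counts, group = NULL,
                    engine = c("ql", "lrt", "voom"),
                    normalization = c("libsize", "median_ratio"),
                    dispersion_trend = c("auto", "none", "lowess"),
                    ...) {
  engine <- match.arg(engine)
  normalization <- match.arg(normalization)
  dispersion_trend <- match.arg(dispersion_trend)
  if (inherits(counts, "summed_counts")) {
    if (is.null(group)) group <- counts$plate_group
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("'group' must have exactly two levels")
  if (length(group) != ncol(counts)) {
    stop("'group' must have one entry per sample")
  }
  nf <- normalization_factors(counts, normalization)
  n <- ncol(counts)
  df <- residual_df(n, 2L)
  extras <- list()

  if (engine == "voom") {
    tab <- .de_voom(counts, group, nf, ...)
  } else {
    offsets <- log(nf$effective_libsize)
    phi_raw <- cr_apl_dispersion(counts, group, offsets)
    use_trend <- switch(dispersion_trend,
                        auto = nrow(counts) >= 100L, lowess = TRUE,
                        none = FALSE)
    phi <- if (use_trend) {
      ab <- rowMeans(cpm(counts, nf, log = TRUE))
      .dispersion_trend(phi_raw, ab)
    } else {
      phi_raw
    }
    if (engine == "lrt") {
      if (df < 10L) {
        warning("only ", df, " residual degrees of freedom: per-gene NB ",
                "dispersion estimates are unstable without empirical-Bayes ",
                "shrinkage; prefer engine = 'ql' or 'voom' for summed counts")
      }
      tab <- nb_lrt(counts, group, offsets, phi)
    } else {
      tab <- nb_ql_ftest(counts, group, offsets, phi)
      extras$d0 <- attr(tab, "d0")
      extras$quasi_dispersion <- attr(tab, "quasi_dispersion")
    }
    extras$dispersion <- phi
    tab <- data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
                      tab, row.names = NULL)
  }
  structure(c(list(table = tab, engine = engine,
                   normalization = normalization,
                   n_samples = n, residual_df = df,
                   group_levels = levels(group)),
              extras),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("DE fit (engine '%s'): %d genes, %d samples (%s vs %s), %d residual d.f.\n",
              x$engine, nrow(x$table), x$n_samples,
              x$group_levels[2L], x$group_levels[1L], x$residual_df))
  cat(sprintf("  genes at FDR < 0.05: %d\n", sum(x$table$fdr < 0.05)))
  invisible(x)
}

#' Summarize a DE fit
#'
#' @param object a \code{"de_fit"}.
#' @param n number of top genes to display (by p-value).
#' @param fdr FDR threshold for the rejection count.
#' @param ... unused.
#' @export
summary.de_fit <- function(object, n = 10, fdr = 0.05, ...) {
  print(object)
  o <- order(object$table$pvalue)
  top <- utils::head(object$table[o, ], n)
  print(top, digits = 4, row.names = FALSE)
  invisible(top)
}

#' @export
coef.de_fit <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$gene)
}

#' Diagnostic plots for a DE fit
#'
#' Histogram of p-values (left) and log2 fold change against the test
#' statistic significance (right).
#'
#' @param x a \code{"de_fit"}.
#' @param ... passed to \code{hist}.
#' @export
plot.de_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$table$pvalue, breaks = 20, main = paste0(x$engine, ": p-values"),
                 xlab = "p-value", col = "grey", ...)
  graphics::plot(x$table$log2fc, -log10(x$table$pvalue),
                 pch = 16, cex = 0.4, xlab = "log2 fold change",
                 ylab = "-log10 p", main = "volcano")
  invisible(x)
}
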