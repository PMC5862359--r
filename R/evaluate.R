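#' Observed type I error rate
#'
#' Proportion of genes with a p-value strictly below the nominal level. On
#' an all-null simulation this is the observed type I error rate; a method
#' is liberal when it exceeds the nominal level.
#'
#' @param pvalues p-values in \code{[0, 1]}.
#' @param alpha nominal level.
#' @return A proportion in \code{[0, 1]}.
#' @export
observed_error_rate <- function(pvalues, alpha = 0.01) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  mean(pvalues < alpha)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps \code{stats::p.adjust(method = "BH")}).
#'
#' @param pvalues p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Observed false discovery rate
#'
#' Among genes rejected at an adjusted-p threshold, the fraction whose true
#' state is non-DE; defined as 0 when nothing is rejected.
#'
#' @param adjusted BH-adjusted p-values.
#' @param true_de logical ground truth, aligned with \code{adjusted}.
#' @param threshold rejection threshold on the adjusted scale (default
#'   0.05).
#' @return A proportion in \code{[0, 1]}.
#' @export
observed_fdr <- function(adjusted, true_de, threshold = 0.05) {
  if (length(adjusted) != length(true_de)) {
    stop("'adjusted' and 'true_de' must have the same length")
  }
  rej <- adjusted < threshold
  if (!any(rej)) return(0)
  mean(!true_de[rej])
}

#' ROC points from per-gene p-values
#'
#' Sweeps the rejection threshold over the sorted unique p-values (ties
#' grouped, one point per unique value), returning false and true positive
#' rates, anchored at (0, 0) and (1, 1).
#'
#' @param pvalues per-gene p-values.
#' @param true_de logical ground truth (both classes must be present).
#' @return \code{data.frame} with columns \code{fpr} and \code{tpr},
#'   non-decreasing in both.
#' @export
roc_points <- function(pvalues, true_de) {
  if (length(pvalues) != length(true_de)) {
    stop("'pvalues' and 'true_de' must have the same length")
  }
  true_de <- as.logical(true_de)
  if (!any(true_de) || all(true_de)) {
    stop("both DE and non-DE genes are required for a ROC curve")
  }
  o <- order(pvalues)
  p <- pvalues[o]; d <- true_de[o]
  last <- !duplicated(p, fromLast = TRUE)  # group tied p-values
  tpr <- cumsum(d)[last] / sum(d)
  fpr <- cumsum(!d)[last] / sum(!d)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Area under a ROC curve
#'
#' Trapezoidal area under the points returned by [roc_points()].
#'
#' @param roc a \code{data.frame} with \code{fpr}, \code{tpr}.
#' @return Scalar in \code{[0, 1]}.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# TPR at a given FPR, by linear interpolation of the ROC curve
.tpr_at_fpr <- function(roc, fpr) {
  stats::approx(roc$fpr, roc$tpr, xout = fpr, ties = max, rule = 2)$y
}

#' Run the simulation benchmark
#'
#' For each scenario and iteration: simulate a dataset, filter
#' low-abundance genes on the single-cell matrix (the same kept-gene set is
#' used for both modes so they test identical genes), then for each
#' requested mode analyse either the single-cell matrix with cells as
#' replicates (library-size normalization) or the per-plate count sums with
#' plates as replicates (median-of-ratios normalization), with every
#' requested engine. Error rates are aggregated across iterations as
#' geometric means with standard errors of the log rates; zero rates are
#' replaced by \code{0.5 / n_genes} before logging. When the configuration
#' spikes DE genes, the observed FDR at BH 5\%, the ROC AUC and the TPR at
#' FPR 0.01 are reported instead of error rates.
#'
#' Per-iteration seeds are derived deterministically from the root seed as
#' \code{seed + 104729 * scenario_index + 7919 * iteration}, so any grid
#' cell can be reproduced in isolation.
#'
#' @param scenarios character vector of [scenario()] names.
#' @param engines subset of \code{c("ql", "lrt", "voom")}.
#' @param modes subset of \code{c("single_cell", "summed")}.
#' @param n_iterations simulation iterations per scenario (default 10).
#' @param alpha nominal per-gene level for error rates (default 0.01).
#' @param seed root seed.
#' @param n_genes genes per simulated dataset.
#' @param de_fraction,de_log2fc DE spike-in (0 for a null benchmark).
#' @param config_args further arguments passed to [scenario()].
#' @return Object of class \code{"benchmark_summary"}: a data.frame with
#'   columns \code{scenario}, \code{engine}, \code{mode}, \code{metric},
#'   \code{value}, \code{se_log}, \code{n_iter}; per-iteration values in
#'   \code{attr(, "detail")}.
#' @export
run_benchmark <- function(scenarios = "default",
                          engines = c("ql", "voom"),
                          modes = c("single_cell", "summed"),
                          n_iterations = 10, alpha = 0.01, seed = 1,
                          n_genes = 5000, de_fraction = 0, de_log2fc = 1,
                          config_args = list()) {
  engines <- match.arg(engines, c("ql", "lrt", "voom"), several.ok = TRUE)
  modes <- match.arg(modes, c("single_cell", "summed"), several.ok = TRUE)
  detail <- list()
  for (s_idx in seq_along(scenarios)) {
    sc <- scenarios[s_idx]
    for (it in seq_len(n_iterations)) {
      iseed <- (as.integer(seed) + 104729L * s_idx + 7919L * it) %%
        .Machine$integer.max
      cfg <- do.call(scenario, c(list(name = sc, n_genes = n_genes,
                                      de_fraction = de_fraction,
                                      de_log2fc = de_log2fc, seed = iseed),
                                 config_args))
      dat <- simulate_dataset(cfg)
      flt <- filter_low_abundance(dat$counts)
      truth <- dat$true_de[flt$keep]
      summed <- if ("summed" %in% modes) {
        sum_by_plate(flt$counts, dat$design)
      }
      for (mode in modes) {
        for (eng in engines) {
          fit <- if (mode == "single_cell") {
            de_test(flt$counts, dat$design$cell_group, engine = eng,
                    normalization = "libsize")
          } else {
            suppressWarnings(
              de_test(summed, engine = eng, normalization = "median_ratio"))
          }
          p <- fit$table$pvalue
          rows <- if (de_fraction > 0) {
            roc <- roc_points(p, truth)
            data.frame(metric = c("fdr", "auc", "tpr_at_fpr_0.01"),
                       value = c(observed_fdr(fit$table$fdr, truth),
                                 roc_auc(roc), .tpr_at_fpr(roc, 0.01)))
          } else {
            data.frame(metric = "error_rate",
                       value = observed_error_rate(p, alpha))
          }
          detail[[length(detail) + 1L]] <- data.frame(
            scenario = sc, engine = eng, mode = mode, iteration = it,
            seed = iseed, n_tested = length(p), rows)
        }
      }
    }
  }
  detail <- do.call(rbind, detail)
  agg <- do.call(rbind, lapply(
    split(detail, detail[c("metric", "mode", "engine", "scenario")],
          drop = TRUE),
    function(d) {
      if (d$metric[1L] == "error_rate") {
        lr <- log(pmax(d$value, 0.5 / d$n_tested))  # continuity-correct zeros
        data.frame(scenario = d$scenario[1L], engine = d$engine[1L],
                   mode = d$mode[1L], metric = d$metric[1L],
                   value = exp(mean(lr)),
                   se_log = stats::sd(lr) / sqrt(nrow(d)),
                   n_iter = nrow(d))
      } else {
        data.frame(scenario = d$scenario[1L], engine = d$engine[1L],
                   mode = d$mode[1L], metric = d$metric[1L],
                   value = mean(d$value),
                   se_log = stats::sd(d$value) / sqrt(nrow(d)),
                   n_iter = nrow(d))
      }
    }))
  rownames(agg) <- NULL
  structure(agg, detail = detail, alpha = alpha,
            class = c("benchmark_summary", "data.frame"))
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("Benchmark summary (", attr(x, "alpha"), " nominal level; ",
      "error rates are geometric means across iterations)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot a benchmark summary
#'
#' Bar chart of observed error rates on a log scale, one bar per
#' engine/mode/scenario cell, with the nominal level as a dashed line.
#'
#' @param x a \code{"benchmark_summary"}.
#' @param ... passed to \code{barplot}.
#' @export
plot.benchmark_summary <- function(x, ...) {
  er <- x[x$metric == "error_rate", ]
  if (nrow(er) == 0L) stop("no error-rate rows to plot")
  lab <- paste(er$engine, er$mode, er$scenario, sep = "\n")
  bp <- graphics::barplot(er$value, names.arg = lab, log = "y",
                          ylab = "observed type I error rate",
                          cex.names = 0.7, ...)
  graphics::abline(h = attr(x, "alpha"), lty = 2)
  graphics::segments(bp, exp(log(er$value) - er$se_log),
                     bp, exp(log(er$value) + er$se_log))
  invisible(x)
}
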