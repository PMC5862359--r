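# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# weighted least squares by direct normal equations
bf_wls <- function(y, X, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)[, 1]
}

# Benjamini-Hochberg step-up, written out longhand
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# ROC by explicit confusion-matrix counting at every unique threshold
bf_roc <- function(p, truth) {
  th <- sort(unique(p))
  pts <- t(vapply(th, function(t) {
    called <- p <= t
    c(fpr = sum(called & !truth) / sum(!truth),
      tpr = sum(called & truth) / sum(truth))
  }, c(fpr = 0, tpr = 0)))
  rbind(c(fpr = 0, tpr = 0), pts, c(fpr = 1, tpr = 1))
}

bf_fdr <- function(adjusted, truth, threshold) {
  rej <- which(adjusted < threshold)
  if (length(rej) == 0) return(0)
  sum(!truth[rej]) / length(rej)
}

# median-of-ratios size factors with explicit loops
bf_median_ratio <- function(counts) {
  ok <- apply(counts, 1, function(r) all(r > 0))
  ref <- apply(counts[ok, , drop = FALSE], 1,
               function(r) exp(mean(log(r))))
  sapply(seq_len(ncol(counts)), function(j) {
    median(counts[ok, j] / ref)
  })
}

# full NB log-likelihood for one gene at given coefficients
bf_nb_loglik <- function(y, X, offsets, beta, phi) {
  mu <- exp(drop(X %*% beta) + offsets)
  if (phi == 0) {
    sum(dpois(y, mu, log = TRUE))
  } else {
    sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

# a small deterministic NB dataset for engine tests
make_test_counts <- function(n_genes = 80, n_samples = 6, mu = 50,
                             phi = 0.2, seed = 99) {
  set.seed(seed)
  matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / phi),
         n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}
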