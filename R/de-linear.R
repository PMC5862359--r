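#' Precision weights from the log-CPM mean-variance trend
#'
#' Models counts on the log2-CPM scale with observation-level precision
#' weights. Per gene, an ordinary least-squares fit of the log-CPMs on the
#' design gives residual standard deviations; a robust LOWESS of the square
#' root of these against average log2 count yields the mean-variance trend;
#' each observation's fitted log-count is mapped through the trend and the
#' weight is the predicted standard deviation to the power minus four
#' (inverse predicted variance of the log-CPM). Extrapolation beyond the
#' trend's support is clamped to the boundary values.
#'
#' @param counts gene x sample count matrix.
#' @param lib effective library sizes (or a \code{"norm_factors"} object);
#'   default column sums.
#' @param design design matrix (full column rank, fewer columns than
#'   samples).
#' @param span LOWESS span (default 0.5, 3 robustness iterations).
#' @param prior_count prior count for the log-CPMs (default 0.5).
#' @return List with \code{logcpm}, \code{weights} (both gene x sample),
#'   and \code{trend} (a function mapping average log2 count to predicted
#'   sqrt-sd).
#' @export
voom_transform <- function(counts, lib = NULL, design, span = 0.5,
                           prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(lib)) lib <- colSums(counts)
  if (inherits(lib, "norm_factors")) lib <- lib$effective_libsize
  n <- ncol(counts)
  p <- qr(design)$rank
  if (p != ncol(design)) stop("design matrix is not of full column rank")
  residual_df(n, p)  # errors on a saturated design

  y <- cpm(counts, lib, log = TRUE, prior_count = prior_count)
  fit <- .ols_matrix(y, design)
  # average log2 count per gene (log-CPM shifted back to the count scale)
  sx <- rowMeans(y) + mean(log2(lib + 2 * prior_count)) - log2(1e6)
  sy <- sqrt(fit$sigma)   # sqrt of residual sd, the classic variance scale
  ok <- is.finite(sx) & is.finite(sy)
  lo <- stats::lowess(sx[ok], sy[ok], f = span, iter = 3L)
  trend <- function(x) {
    x <- pmin(pmax(x, min(lo$x)), max(lo$x))
    stats::approx(lo$x, lo$y, xout = x, ties = mean)$y
  }
  fitted_logcount <- fit$fitted +
    matrix(log2(lib + 2 * prior_count) - log2(1e6), nrow(y), n, byrow = TRUE)
  w <- matrix(trend(fitted_logcount), nrow(y), n)
  w <- 1 / pmax(w, 1e-6)^4
  dimnames(w) <- dimnames(y)
  list(logcpm = y, weights = w, trend = trend)
}

# per-gene OLS for a common design: coefficients, fitted values, residual sd
.ols_matrix <- function(y, design) {
  qrX <- qr(design)
  beta <- t(qr.coef(qrX, t(y)))
  fitted <- beta %*% t(design)
  df <- ncol(y) - qrX$rank
  rss <- rowSums((y - fitted)^2)
  list(coefficients = beta, fitted = fitted,
       sigma = sqrt(rss / df), df = df)
}

#' Weighted least squares for one gene
#'
#' Minimizes \eqn{\sum_j w_j (y_j - x_j'\beta)^2}; the residual variance is
#' the weighted residual sum of squares over the residual degrees of
#' freedom.
#'
#' @param y response vector.
#' @param X design matrix (full rank).
#' @param w positive weights.
#' @return List with \code{beta}, \code{s2}, \code{residual_df} and
#'   \code{cov_unscaled} (the unscaled coefficient covariance
#'   \eqn{(X'WX)^{-1}}).
#' @export
fit_weighted_lm <- function(y, X, w = rep(1, length(y))) {
  X <- as.matrix(X)
  if (any(w <= 0) || any(!is.finite(w))) stop("weights must be positive and finite")
  if (qr(X)$rank != ncol(X)) stop("design matrix is rank deficient")
  sw <- sqrt(w)
  fit <- lm.fit(X * sw, y * sw)
  df <- residual_df(length(y), ncol(X))
  s2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)
  cov_unscaled <- chol2inv(R[, order(fit$qr$pivot), drop = FALSE])
  list(beta = fit$coefficients, s2 = s2, residual_df = df,
       cov_unscaled = cov_unscaled)
}

#' Empirical-Bayes variance moderation
#'
#' Fits a scaled inverse-chi-squared prior to gene-wise residual variances
#' by matching the first two moments of \code{log(s2)} to a log-F
#' distribution: the excess spread of the log variances beyond the sampling
#' trigamma term determines the prior degrees of freedom \code{d0}
#' (trigamma inversion), and the prior variance \code{s0_2} follows from
#' the mean. Posterior variances are the usual shrinkage combination
#' \code{(d0 * s0_2 + df * s2) / (d0 + df)}; if the observed spread does
#' not exceed the sampling spread, \code{d0} is infinite and all posterior
#' variances equal \code{s0_2}.
#'
#' @param s2 gene-wise residual variances (at least two positive).
#' @param residual_df residual degrees of freedom of each \code{s2}.
#' @return List with \code{d0} (prior d.f., possibly \code{Inf}),
#'   \code{s0_2} (prior variance) and \code{s2_post}.
#' @export
squeeze_variances <- function(s2, residual_df) {
  pos <- which(is.finite(s2) & s2 > 0)
  if (length(pos) < 2L) stop("need at least two positive variances")
  df <- residual_df
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    # no excess spread beyond sampling noise: infinite prior d.f., prior at
    # the mean of the observed variances (unbiased for the common variance
    # under the sampling model)
    d0 <- Inf
    s0_2 <- mean(s2[pos])
    s2_post <- rep(s0_2, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

# Newton solve of trigamma(x) = y for x > 0
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Moderated t-test for one coefficient
#'
#' t statistic = coefficient estimate over its standard error computed with
#' the posterior (moderated) variance; two-sided p from a t distribution
#' with \code{d0 + residual_df} degrees of freedom (normal when \code{d0}
#' is infinite). BH-adjusted p-values are included.
#'
#' @param fit list with per-gene \code{coefficients} (gene x coefficient
#'   matrix), \code{cov_unscaled} (list or single matrix of unscaled
#'   covariances), \code{residual_df}, and squeeze output \code{d0},
#'   \code{s2_post}.
#' @param coef index of the tested coefficient (default last).
#' @return \code{data.frame} with \code{log2fc} (the coefficient, on the
#'   log2 scale of the fitted response), \code{stat}, \code{pvalue},
#'   \code{fdr}.
#' @export
moderated_t_test <- function(fit, coef = ncol(fit$coefficients)) {
  beta <- fit$coefficients[, coef]
  v <- if (is.list(fit$cov_unscaled)) {
    vapply(fit$cov_unscaled, function(m) m[coef, coef], numeric(1))
  } else {
    fit$cov_unscaled[coef, coef]
  }
  se <- sqrt(fit$s2_post * v)
  tstat <- beta / se
  df_total <- fit$d0 + fit$residual_df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(log2fc = beta, stat = tstat, pvalue = p, fdr = bh_adjust(p))
}

# Full moderated linear-model engine on a one-way layout, vectorized across
# genes: weighted group means, weighted RSS, EB squeeze, moderated t.
.de_voom <- function(counts, group, lib, span = 0.5, prior_count = 0.5) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("engine expects exactly two groups")
  design <- stats::model.matrix(~group)
  vw <- voom_transform(counts, lib, design, span = span,
                       prior_count = prior_count)
  y <- vw$logcpm
  w <- vw$weights
  g2 <- group == levels(group)[2L]
  # weighted one-way WLS in closed form, per gene
  sw1 <- rowSums(w[, !g2, drop = FALSE]); sw2 <- rowSums(w[, g2, drop = FALSE])
  m1 <- rowSums((w * y)[, !g2, drop = FALSE]) / sw1
  m2 <- rowSums((w * y)[, g2, drop = FALSE]) / sw2
  fitted <- matrix(m1, nrow(y), ncol(y))
  fitted[, g2] <- m2
  df <- residual_df(ncol(y), 2L)
  s2 <- rowSums(w * (y - fitted)^2) / df
  sq <- squeeze_variances(s2, df)
  se <- sqrt(sq$s2_post * (1 / sw1 + 1 / sw2))
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df = sq$d0 + df)
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             log2fc = m2 - m1, stat = tstat, pvalue = p,
             fdr = bh_adjust(p), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
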