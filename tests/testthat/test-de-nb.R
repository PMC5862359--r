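test_that("NB IRLS matches closed forms and a grid-search maximizer", {
  set.seed(20)
  y <- rnbinom(30, mu = 25, size = 5)
  o <- rep(log(2), 30)
  # intercept only with equal offsets: beta = log(mean) - offset, any phi
  for (phi in c(0, 0.2, 1)) {
    f <- nb_glm_irls(y, matrix(1, 30, 1), offsets = o, phi = phi)
    expect_equal(unname(f$beta[1]), log(mean(y)) - log(2), tolerance = 1e-6)
    expect_true(f$converged)
  }
  # two-group layout: fitted means are offset-weighted group averages
  g <- rep(0:1, 15)
  X <- cbind(1, g)
  off <- log(runif(30, 0.5, 2))
  f2 <- nb_glm_irls(y, X, offsets = off, phi = 0)
  for (lev in 0:1) {
    idx <- g == lev
    expect_equal(mean(f2$mu[idx] / exp(off[idx]) / (sum(y[idx]) / sum(exp(off[idx])))),
                 1, tolerance = 1e-6)
  }
  # random instance against a brute-force grid maximizer of the likelihood
  phi <- 0.4
  f3 <- nb_glm_irls(y, X, offsets = off, phi = phi)
  grid <- as.matrix(expand.grid(b0 = seq(f3$beta[1] - 0.3, f3$beta[1] + 0.3,
                                         length.out = 121),
                                b1 = seq(f3$beta[2] - 0.3, f3$beta[2] + 0.3,
                                         length.out = 121)))
  ll <- apply(grid, 1, function(b) bf_nb_loglik(y, X, off, b, phi))
  expect_equal(unname(f3$beta), unname(grid[which.max(ll), ]),
               tolerance = 1e-2)
  # and the IRLS solution is at least as good as the best grid point
  expect_gte(bf_nb_loglik(y, X, off, f3$beta, phi) + 1e-8, max(ll))
  expect_error(nb_glm_irls(y, cbind(X, g), phi = 0.1), "rank deficient")
  # all-zero response: clamped fit, flagged converged
  f0 <- nb_glm_irls(rep(0L, 10), matrix(1, 10, 1), phi = 0.1)
  expect_true(f0$converged)
  expect_lte(unname(f0$beta[1]), -30 + 1e-8)
})

test_that("NB deviance has the Poisson limit and saturated zero", {
  y <- c(3, 0, 7, 2)
  mu <- c(2.5, 0.5, 8, 2)
  # hand-computed Poisson deviance
  hand <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  expect_equal(nb_deviance(y, mu, 0), hand, tolerance = 1e-12)
  # phi -> 0 converges to the Poisson value
  expect_equal(nb_deviance(y, mu, 1e-8), hand, tolerance = 1e-5)
  # saturated fit has zero deviance
  expect_equal(nb_deviance(y, pmax(y, 1e-8), 0.3), 0, tolerance = 1e-6)
})

test_that("IRLS deviance decreases across iterations with step-halving", {
  set.seed(33)
  y <- rnbinom(40, mu = 15, size = 2)
  X <- cbind(1, rnorm(40), runif(40))
  devs <- sapply(1:8, function(k) {
    nb_glm_irls(y, X, phi = 0.5, maxit = k, tol = 0)$deviance
  })
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("Cox-Reid APL dispersion estimation recovers the truth", {
  set.seed(44)
  y <- matrix(rnbinom(500 * 300, mu = 20, size = 1 / 0.3), 500)
  grp <- factor(rep(c("a", "b"), each = 150))
  phi <- cr_apl_dispersion(y, grp)
  expect_lt(abs(mean(phi) - 0.3) / 0.3, 0.1)
  # underdispersed data hits the lower bound
  yb <- matrix(rbinom(50 * 200, size = 1, prob = 0.5), 50)
  phib <- cr_apl_dispersion(yb, factor(rep(c("a", "b"), each = 100)))
  # at the search floor up to the refinement tolerance of the flat profile
  expect_true(all(phib < 1e-7))
  # invariance to a constant offset shift with correspondingly scaled means
  set.seed(45)
  y1 <- matrix(rnbinom(200 * 100, mu = 10, size = 1 / 0.2), 200)
  y2 <- matrix(rnbinom(200 * 100, mu = 30, size = 1 / 0.2), 200)
  g2 <- factor(rep(c("a", "b"), each = 50))
  p1 <- cr_apl_dispersion(y1, g2, offsets = rep(0, 100))
  p2 <- cr_apl_dispersion(y2, g2, offsets = rep(log(3), 100))
  expect_equal(mean(p1), mean(p2), tolerance = 0.05)
  expect_error(cr_apl_dispersion(matrix(1:2, 1), factor(c("a", "b"))),
               "saturated")
})

test_that("CR-APL agrees with the reference estimator on a fixture", {
  skip_if_not_installed("edgeR")
  counts <- make_test_counts(n_genes = 150, n_samples = 12, mu = 60,
                             phi = 0.25, seed = 61)
  grp <- factor(rep(c("a", "b"), each = 6))
  X <- stats::model.matrix(~grp)
  mine <- cr_apl_dispersion(counts, grp, offsets = log(colSums(counts)))
  ref <- edgeR::estimateDisp(edgeR::DGEList(counts, group = grp), X,
                             prior.df = 0)$tagwise.dispersion
  expect_gt(cor(log(mine + 1e-3), log(ref + 1e-3)), 0.95)
  expect_equal(median(mine), median(ref), tolerance = 0.1)
})

test_that("the likelihood-ratio test behaves as a nested-model deviance test", {
  set.seed(50)
  y <- matrix(rnbinom(100 * 20, mu = 30, size = 4), 100)
  grp <- factor(rep(c("a", "b"), each = 10))
  phi <- rep(0.25, 100)
  out <- nb_lrt(y, grp, phi = phi)
  expect_true(all(out$stat >= 0))
  expect_true(all(out$pvalue >= 0 & out$pvalue <= 1))
  # equal group means: the full model adds nothing, statistic 0 and p = 1
  ye <- matrix(c(4L, 7L, 9L, 4L, 7L, 9L), 1)
  oe <- nb_lrt(ye, factor(rep(c("a", "b"), each = 3)), phi = 0.2)
  expect_equal(oe$stat, 0, tolerance = 1e-10)
  expect_equal(oe$pvalue, 1)
  # Poisson limit single gene vs hand-computed deviance difference
  y1 <- c(5L, 8L, 3L, 12L, 15L, 9L)
  g1 <- factor(rep(c("a", "b"), each = 3))
  o1 <- nb_lrt(matrix(y1, 1), g1, phi = 0)
  mu_full <- ifelse(g1 == "a", mean(y1[1:3]), mean(y1[4:6]))
  dev_full <- 2 * sum(y1 * log(y1 / mu_full) - (y1 - mu_full))
  dev_null <- 2 * sum(y1 * log(y1 / mean(y1)) - (y1 - mean(y1)))
  expect_equal(o1$stat, dev_null - dev_full, tolerance = 1e-8)
  expect_equal(o1$pvalue, pchisq(dev_null - dev_full, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("QL F-test squeezing and monotonicity contracts hold", {
  set.seed(52)
  y <- matrix(rnbinom(200 * 10, mu = 40, size = 4), 200)
  grp <- factor(rep(c("a", "b"), each = 5))
  out <- nb_ql_ftest(y, grp, phi = rep(0.25, 200))
  expect_true(all(out$pvalue >= 0 & out$pvalue <= 1))
  expect_gt(attr(out, "d0"), 0)
  # p decreases monotonically in the deviance statistic at fixed dispersion
  d0 <- attr(out, "d0")
  p_of <- function(stat) pf(stat / 1, 1, 8 + d0, lower.tail = FALSE)
  expect_true(all(diff(p_of(c(0.1, 1, 5, 20))) < 0))
  # equal quasi-dispersions squeeze to themselves
  sq <- squeeze_variances(rep(1.7, 50), 8)
  expect_equal(sq$s2_post, rep(1.7, 50))
})

test_that("LRT and QL rank genes identically with unit quasi-dispersion", {
  set.seed(53)
  y <- matrix(rnbinom(60 * 12, mu = 35, size = 3), 60)
  grp <- factor(rep(c("a", "b"), each = 6))
  phi <- rep(0.3, 60)
  lrt <- nb_lrt(y, grp, phi = phi)
  ql <- nb_ql_ftest(y, grp, phi = phi)
  # the F numerator is the same deviance difference, so with any common
  # denominator the ranking coincides in the d0 -> Inf limit
  expect_equal(cor(rank(lrt$stat), rank(ql$stat * attr(ql, "quasi_dispersion"))),
               1)
})

test_that("count sums approach the Poisson variance limit", {
  # variance/mean of a sum of m iid NB(mu, phi) is 1 + phi*mu relative to
  # Poisson at any m; summing over cells with independent means shrinks the
  # *relative* overdispersion of the per-plate mean
  set.seed(54)
  m_cells <- c(1, 10, 80)
  rel <- sapply(m_cells, function(m) {
    sums <- replicate(4000, sum(rnbinom(m, mu = 5, size = 1 / 0.4)))
    var(sums) / mean(sums)
  })
  # var/mean of the sum is constant = 1 + phi*mu in theory; check the
  # per-plate CPM-scale variance instead shrinks like 1/m
  expect_equal(rel, rep(1 + 0.4 * 5, 3), tolerance = 0.15)
  cv2 <- sapply(m_cells, function(m) {
    sums <- replicate(4000, sum(rnbinom(m, mu = 5, size = 1 / 0.4)))
    var(sums) / mean(sums)^2
  })
  expect_true(all(diff(cv2) < 0))
})

test_that("de_test warns when the LRT is applied to summed counts", {
  d <- simulate_dataset(sim_config(n_genes = 150, mean_log_mu = log(30),
                                   seed = 70))
  s <- sum_by_plate(d$counts, d$design)
  expect_warning(de_test(s, engine = "lrt", normalization = "median_ratio"),
                 "residual degrees of freedom")
  # no warning with hundreds of cells as replicates
  expect_silent(de_test(d$counts, d$design$cell_group, engine = "lrt"))
})
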