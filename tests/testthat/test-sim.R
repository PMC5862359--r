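test_that("plate effects and cell factors are unit-mean log-normals", {
  set.seed(1)
  # degenerate distributions at sigma = 0
  expect_equal(sample_plate_effects(5, 3, 0), matrix(1, 5, 3))
  expect_equal(sample_cell_factors(7, 0), rep(1, 7))
  expect_error(sample_plate_effects(5, 3, -0.1), "non-negative")
  expect_error(sample_cell_factors(5, -1), "non-negative")

  # law of large numbers: mean within 4 MC standard errors of 1 across sigmas
  for (sigma in c(0.2, 0.5, 1)) {
    delta <- sample_plate_effects(1e5, 1, sigma)
    mc_se <- sd(delta) / sqrt(length(delta))
    expect_lt(abs(mean(delta) - 1), 4 * mc_se)
    expect_true(all(delta > 0))
  }
  # log-scale variance matches the parameterization
  delta <- sample_plate_effects(2e5, 1, 0.5)
  expect_equal(var(log(delta[, 1])), 0.25, tolerance = 0.02)
  # independence of theta from delta
  theta <- sample_cell_factors(2e5, 0.3)
  expect_lt(abs(cor(theta, delta[, 1])), 4 / sqrt(2e5))
  mc_se <- sd(theta) / sqrt(length(theta))
  expect_lt(abs(mean(theta) - 1), 4 * mc_se)
})

test_that("spiked DE genes get exact balanced fold changes", {
  cfg0 <- sim_config(n_genes = 1000, de_fraction = 0, seed = 1)
  s0 <- spike_de(cfg0)
  expect_false(any(s0$true_de))
  expect_true(all(s0$multipliers == 1))

  set.seed(5)
  cfg <- sim_config(n_genes = 1000, de_fraction = 0.1, de_log2fc = 2)
  s <- spike_de(cfg)
  expect_identical(sum(s$true_de), 100L)
  expect_true(all(s$true_de == (s$true_log2fc != 0)))
  ratio <- s$multipliers[s$true_de, 1] / s$multipliers[s$true_de, 2]
  expect_true(all(ratio %in% c(2^2, 2^-2)))
  expect_equal(2^s$true_log2fc[s$true_de], ratio)
  expect_error(spike_de(sim_config(n_genes = 10, n_groups = 1,
                                   de_fraction = 0.5)),
               "two groups")
})

test_that("simulated counts follow the conditional NB law", {
  # all factors at 1 and phi -> 0: per-gene mean over cells approaches mu
  cfg <- sim_config(n_genes = 200, sigma_plate = 0, sigma_theta = 0,
                    nb_dispersion = 0, cells_per_plate_range = c(80, 80),
                    seed = 42)
  d <- simulate_dataset(cfg)
  n <- ncol(d$counts)
  mc_se <- sqrt(d$mu / n)  # Poisson MC error of the mean
  expect_gt(mean(abs(rowMeans(d$counts) - d$mu) < 4 * mc_se), 0.98)

  # moment check of the NB variance mu + phi * mu^2 at fixed dispersion
  cfg2 <- sim_config(n_genes = 2000, sigma_plate = 0, sigma_theta = 0,
                     nb_dispersion = 0.3, mean_log_mu = log(50),
                     sd_log_mu = 0, cells_per_plate_range = c(100, 100),
                     seed = 43)
  d2 <- simulate_dataset(cfg2)
  v <- apply(d2$counts, 1, var)
  expect_equal(mean(v), 50 + 0.3 * 50^2, tolerance = 0.05)
})

test_that("dataset structure matches the design and is reproducible", {
  cfg <- sim_config(n_genes = 100, seed = 7)
  d <- simulate_dataset(cfg)
  # 6 plates of 50-100 cells each
  expect_true(ncol(d$counts) >= 300 && ncol(d$counts) <= 600)
  expect_identical(length(d$design$plate_group), 6L)
  expect_true(all(d$counts >= 0))
  expect_true(all(d$counts == floor(d$counts)))
  expect_true(all(d$plate_effects > 0))
  expect_true(all(d$cell_factors > 0))
  # each cell's group equals its plate's group
  expect_identical(unname(d$design$plate_group[d$design$cell_plate]),
                   d$design$cell_group)
  # bit-identical on replay
  d2 <- simulate_dataset(cfg)
  expect_identical(d, d2)
  # simulate() method draws distinct iterations deterministically
  reps <- simulate(cfg, nsim = 2, seed = 7)
  expect_identical(reps[[1]], d)
  expect_false(identical(reps[[1]]$counts, reps[[2]]$counts))
})

test_that("plate effects induce within-plate residual correlation", {
  avg_within_plate_cor <- function(d, n_use = 60) {
    y <- log1p(d$counts[seq_len(n_use), ])
    grp <- d$design$cell_group
    # residuals after removing group means
    for (g in unique(grp)) {
      y[, grp == g] <- y[, grp == g] - rowMeans(y[, grp == g])
    }
    cors <- c()
    for (pl in names(d$design$plate_group)) {
      cells <- which(d$design$cell_plate == pl)
      cm <- cor(y[, cells])  # cell-cell correlation of residuals over genes
      cors <- c(cors, cm[upper.tri(cm)])
    }
    mean(cors, na.rm = TRUE)
  }
  with_pe <- simulate_dataset(sim_config(n_genes = 60, seed = 21,
                                         mean_log_mu = log(20)))
  without_pe <- simulate_dataset(scenario("no_plate_effect", n_genes = 60,
                                          seed = 21,
                                          mean_log_mu = log(20)))
  expect_gt(avg_within_plate_cor(with_pe), 0.05)
  expect_lt(abs(avg_within_plate_cor(without_pe)), 0.05)
})

test_that("scenario presets modify the default configuration as named", {
  def <- scenario("default")
  expect_identical(scenario("no_plate_effect")$sigma_plate, 0)
  expect_identical(scenario("half_plate_effect")$sigma_plate,
                   def$sigma_plate / 2)
  expect_identical(scenario("variable_libsizes")$sigma_theta,
                   2 * def$sigma_theta)
  expect_gt(scenario("more_plates")$plates_per_group, def$plates_per_group)
  wider <- scenario("variable_cell_numbers")$cells_per_plate_range
  expect_lt(wider[1], def$cells_per_plate_range[1])
  expect_gt(wider[2], def$cells_per_plate_range[2])
  expect_identical(scenario("zinb")$zero_inflation, 0.2)
  expect_error(scenario("bogus"), "valid names")
})

test_that("zero inflation adds the configured excess of zeros", {
  base <- sim_config(n_genes = 500, mean_log_mu = log(100), sd_log_mu = 0,
                     sigma_plate = 0, sigma_theta = 0, nb_dispersion = 0.1,
                     cells_per_plate_range = c(50, 50), seed = 3)
  zi <- base; zi$zero_inflation <- 0.2
  d0 <- simulate_dataset(base)
  d1 <- simulate_dataset(zi)
  # at mu = 100 almost all zeros come from dropout
  expect_equal(mean(d1$counts == 0), 0.2, tolerance = 0.01)
  expect_lt(mean(d0$counts == 0), 0.01)
})
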