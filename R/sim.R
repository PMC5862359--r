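#' Sample gene- and plate-specific multiplicative effects
#'
#' Draws the plate effects \eqn{\delta_{ik}}: independent log-normal variates
#' with parameters \eqn{(-\sigma^2/2, \sigma^2)}, so that
#' \eqn{E[\delta] = 1} exactly for every \eqn{\sigma \ge 0}. With
#' \code{sigma_plate = 0} the distribution degenerates at its unit mean and a
#' matrix of ones is returned.
#'
#' @param n_genes,n_plates dimensions of the returned matrix.
#' @param sigma_plate standard deviation of \eqn{\log\delta} (non-negative).
#' @return A \code{n_genes} x \code{n_plates} matrix of positive reals.
#' @export
sample_plate_effects <- function(n_genes, n_plates, sigma_plate) {
  if (length(sigma_plate) != 1L || is.na(sigma_plate) || sigma_plate < 0) {
    stop("'sigma_plate' must be a single non-negative number")
  }
  if (sigma_plate == 0) {
    return(matrix(1, n_genes, n_plates))
  }
  matrix(stats::rlnorm(n_genes * n_plates,
                       meanlog = -sigma_plate^2 / 2, sdlog = sigma_plate),
         n_genes, n_plates)
}

#' Sample cell-specific scaling factors
#'
#' Draws the per-cell factors \eqn{\theta_j} (capture efficiency / library
#' size bias): independent log-normal with parameters
#' \eqn{(-\sigma^2/2, \sigma^2)}, mean exactly one. Independent of the plate
#' effects.
#'
#' @param n_cells number of cells.
#' @param sigma_theta standard deviation of \eqn{\log\theta} (non-negative).
#' @return A positive vector of length \code{n_cells}.
#' @export
sample_cell_factors <- function(n_cells, sigma_theta) {
  if (length(sigma_theta) != 1L || is.na(sigma_theta) || sigma_theta < 0) {
    stop("'sigma_theta' must be a single non-negative number")
  }
  if (sigma_theta == 0) {
    return(rep(1, n_cells))
  }
  stats::rlnorm(n_cells, meanlog = -sigma_theta^2 / 2, sdlog = sigma_theta)
}

#' Spike differential expression into the group means
#'
#' Chooses a uniformly random subset of \code{floor(de_fraction * n_genes)}
#' genes, assigns each an up- or down-regulation direction with probability
#' one half, and returns the multiplier \code{2^(+-de_log2fc)} applied to the
#' first group's mean (the second group keeps multiplier 1), together with
#' the ground-truth labels.
#'
#' @param config a [sim_config()] object with \code{de_fraction > 0} only if
#'   it has at least two groups.
#' @return A list with \code{true_de} (logical), \code{true_log2fc}
#'   (signed log2 fold change of group 1 over group 2; 0 for non-DE genes)
#'   and \code{multipliers}, a \code{n_genes} x \code{n_groups} matrix.
#' @export
spike_de <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  mult <- matrix(1, n, config$n_groups)
  true_log2fc <- numeric(n)
  n_de <- floor(config$de_fraction * n)
  if (n_de > 0) {
    if (config$n_groups < 2L) {
      stop("DE spike-in requires at least two groups")
    }
    idx <- sample.int(n, n_de)
    up <- stats::runif(n_de) < 0.5
    l2fc <- ifelse(up, config$de_log2fc, -config$de_log2fc)
    true_log2fc[idx] <- l2fc
    mult[idx, 1L] <- 2^l2fc
  }
  list(true_de = true_log2fc != 0, true_log2fc = true_log2fc,
       multipliers = mult)
}

#' Simulate a plate-confounded scRNA-seq dataset
#'
#' Draws one dataset under the hierarchical model: base means
#' \eqn{\mu_i \sim} log-normal, gene-wise NB dispersions \eqn{\phi_i}, DE
#' spike-in multipliers, plate effects \eqn{\delta_{ik}} and cell factors
#' \eqn{\theta_j}, then counts
#' \eqn{Y_{ij} \sim NB(\delta_{ik(j)}\theta_j\mu_{ig(j)}, \phi_i)}
#' independently across genes and cells given \eqn{\delta, \theta}; optional
#' dropout replaces each count by zero with the configured probability. The
#' random stream is consumed in the documented order (design, means,
#' dispersions, spike-in, plate effects, cell factors, counts, dropout) so a
#' given seed reproduces the dataset bit for bit.
#'
#' @param config a [sim_config()] object. If \code{config$seed} is set,
#'   \code{set.seed} is called first.
#' @return An object of class \code{"sim_data"}: a list with \code{counts}
#'   (gene x cell integer matrix), \code{design} (a [plate_design()]),
#'   \code{mu} (base means), \code{phi} (gene dispersions),
#'   \code{plate_effects}, \code{cell_factors}, \code{true_de},
#'   \code{true_log2fc}, and the \code{config}.
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 50, seed = 7))
#' dim(d$counts)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$n_genes
  n_plates <- config$n_groups * config$plates_per_group

  # experimental design: plates nested in groups, cells nested in plates
  lo <- config$cells_per_plate_range[1L]
  hi <- config$cells_per_plate_range[2L]
  cells_per_plate <- if (lo == hi) rep(lo, n_plates) else
    lo + sample.int(hi - lo + 1L, n_plates, replace = TRUE) - 1L
  plate_ids <- paste0("plate", seq_len(n_plates))
  group_of_plate <- paste0("group", rep(seq_len(config$n_groups),
                                        each = config$plates_per_group))
  cell_plate <- rep(plate_ids, cells_per_plate)
  cell_group <- rep(group_of_plate, cells_per_plate)
  design <- plate_design(cell_plate, cell_group)
  n_cells <- length(cell_plate)

  mu <- stats::rlnorm(G, config$mean_log_mu, config$sd_log_mu)
  phi <- if (is.numeric(config$nb_dispersion)) {
    rep(config$nb_dispersion, G)
  } else {
    stats::rlnorm(G, config$nb_dispersion$meanlog, config$nb_dispersion$sdlog)
  }
  spike <- spike_de(config)
  delta <- sample_plate_effects(G, n_plates, config$sigma_plate)
  theta <- sample_cell_factors(n_cells, config$sigma_theta)

  plate_idx <- match(cell_plate, plate_ids)
  group_idx <- match(cell_group, unique(group_of_plate))
  # conditional mean: delta[i, k(j)] * theta[j] * mu[i] * multiplier[i, g(j)]
  M <- delta[, plate_idx, drop = FALSE] *
    (mu * spike$multipliers)[, group_idx, drop = FALSE]
  M <- sweep(M, 2L, theta, "*")

  pois <- phi == 0
  y <- numeric(G * n_cells)
  size <- rep(1 / phi, n_cells)  # recycles gene-wise down each column
  mv <- as.vector(M)
  if (any(!pois)) {
    nb_mask <- rep(!pois, n_cells)
    y[nb_mask] <- stats::rnbinom(sum(nb_mask), mu = mv[nb_mask],
                                 size = size[nb_mask])
  }
  if (any(pois)) {
    p_mask <- rep(pois, n_cells)
    y[p_mask] <- stats::rpois(sum(p_mask), mv[p_mask])
  }
  counts <- matrix(as.integer(y), G, n_cells)
  if (config$zero_inflation > 0) {
    drop <- stats::runif(G * n_cells) < config$zero_inflation
    counts[drop] <- 0L
  }
  dimnames(counts) <- list(paste0("gene", seq_len(G)),
                           paste0("cell", seq_len(n_cells)))
  colnames(delta) <- plate_ids

  structure(list(counts = counts, design = design, mu = mu, phi = phi,
                 plate_effects = delta, cell_factors = theta,
                 true_de = spike$true_de, true_log2fc = spike$true_log2fc,
                 config = config),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d genes x %d cells (%d plates, %d groups)\n",
              nrow(x$counts), ncol(x$counts),
              length(x$design$plate_group),
              length(unique(x$design$cell_group))))
  cat(sprintf("  DE genes: %d; sigma_plate=%.3g, sigma_theta=%.3g\n",
              sum(x$true_de), x$config$sigma_plate, x$config$sigma_theta))
  invisible(x)
}

#' Simulate one or more datasets from a configuration
#'
#' \code{simulate} method for \code{"sim_config"}: draws \code{nsim}
#' independent datasets, re-seeding each from \code{seed + iteration - 1}.
#'
#' @param object a [sim_config()] object.
#' @param nsim number of datasets.
#' @param seed root seed; defaults to the config's own seed.
#' @param ... unused.
#' @return A list of \code{"sim_data"} objects (a single object if
#'   \code{nsim = 1}).
#' @export
simulate.sim_config <- function(object, nsim = 1, seed = NULL, ...) {
  root <- if (!is.null(seed)) as.integer(seed) else object$seed
  if (is.null(root)) stop("a seed is required (config$seed or 'seed')")
  out <- lapply(seq_len(nsim), function(i) {
    object$seed <- root + i - 1L
    simulate_dataset(object)
  })
  if (nsim == 1L) out[[1L]] else out
}
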