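#' Simulation configuration for plate-confounded scRNA-seq counts
#'
#' Builds the parameter set for the hierarchical count simulator. Counts are
#' conditionally negative-binomial with mean \eqn{\delta_{ik}\theta_j\mu_{ig}}
#' for gene \eqn{i}, cell \eqn{j} on plate \eqn{k} of group \eqn{g}. The
#' plate effect \eqn{\delta} is gene- and plate-specific, log-normal with
#' mean exactly one; the cell factor \eqn{\theta} is cell-specific (library
#' size / capture efficiency), also log-normal with unit mean. Each plate
#' holds cells from exactly one group, so the plate effect is confounded
#' with the group comparison.
#'
#' @param n_genes number of genes.
#' @param n_groups number of biological groups (DE spike-in requires 2).
#' @param plates_per_group number of plates in each group.
#' @param cells_per_plate_range inclusive integer interval \code{c(lo, hi)};
#'   the number of cells on each plate is drawn uniformly from it.
#' @param mean_log_mu,sd_log_mu location and scale (natural-log scale) of the
#'   log-normal distribution of base expected counts \eqn{\mu_i}.
#' @param nb_dispersion per-gene NB dispersion \eqn{\phi}: either a single
#'   non-negative number (constant across genes) or a list
#'   \code{list(meanlog=, sdlog=)} from which gene-wise dispersions are drawn
#'   log-normally. \eqn{\phi = 0} gives Poisson counts.
#' @param sigma_plate standard deviation of \eqn{\log\delta}; 0 disables the
#'   plate effect.
#' @param sigma_theta standard deviation of \eqn{\log\theta}.
#' @param zero_inflation dropout probability in \code{[0, 1)}: each count is
#'   independently replaced by zero with this probability (zero-inflated NB).
#' @param de_fraction proportion of genes spiked as differentially expressed
#'   between the first two groups (0 for an all-null simulation).
#' @param de_log2fc magnitude of the spiked log2 fold change.
#' @param seed integer random seed consumed by [simulate_dataset()].
#'
#' @return An object of class \code{"sim_config"} (a named list).
#' @seealso [scenario()] for the named scenario presets,
#'   [simulate_dataset()] to draw a dataset.
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' cfg
#' @export
sim_config <- function(n_genes = 10000,
                       n_groups = 2,
                       plates_per_group = 3,
                       cells_per_plate_range = c(50L, 100L),
                       mean_log_mu = log(5),
                       sd_log_mu = 1.5,
                       nb_dispersion = list(meanlog = log(0.3), sdlog = 0.5),
                       sigma_plate = 0.5,
                       sigma_theta = 0.3,
                       zero_inflation = 0,
                       de_fraction = 0,
                       de_log2fc = 1,
                       seed = NULL) {
  stopifnot(
    length(n_genes) == 1L, n_genes >= 1, n_genes == floor(n_genes),
    length(n_groups) == 1L, n_groups >= 1,
    length(plates_per_group) == 1L, plates_per_group >= 1,
    length(cells_per_plate_range) == 2L,
    is.finite(mean_log_mu), sd_log_mu >= 0
  )
  cells_per_plate_range <- as.integer(cells_per_plate_range)
  if (cells_per_plate_range[1L] < 1L ||
      cells_per_plate_range[1L] > cells_per_plate_range[2L]) {
    stop("'cells_per_plate_range' must satisfy 1 <= lo <= hi")
  }
  if (sigma_plate < 0) stop("'sigma_plate' must be non-negative")
  if (sigma_theta < 0) stop("'sigma_theta' must be non-negative")
  if (zero_inflation < 0 || zero_inflation >= 1) {
    stop("'zero_inflation' must be in [0, 1)")
  }
  if (de_fraction < 0 || de_fraction > 1) {
    stop("'de_fraction' must be in [0, 1]")
  }
  if (is.numeric(nb_dispersion)) {
    if (length(nb_dispersion) != 1L || nb_dispersion < 0) {
      stop("constant 'nb_dispersion' must be a single non-negative number")
    }
  } else if (is.list(nb_dispersion)) {
    if (!all(c("meanlog", "sdlog") %in% names(nb_dispersion))) {
      stop("list 'nb_dispersion' needs elements 'meanlog' and 'sdlog'")
    }
  } else {
    stop("'nb_dispersion' must be a number or a list(meanlog=, sdlog=)")
  }
  out <- list(
    n_genes = as.integer(n_genes),
    n_groups = as.integer(n_groups),
    plates_per_group = as.integer(plates_per_group),
    cells_per_plate_range = cells_per_plate_range,
    mean_log_mu = mean_log_mu,
    sd_log_mu = sd_log_mu,
    nb_dispersion = nb_dispersion,
    sigma_plate = sigma_plate,
    sigma_theta = sigma_theta,
    zero_inflation = zero_inflation,
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(out) <- "sim_config"
  out
}

#' Named simulation scenarios
#'
#' Returns the default configuration with one named modification applied,
#' covering the robustness scenarios of the benchmark: no or halved plate
#' effect, more variable cell factors (library sizes), more variable numbers
#' of cells per plate, more plates per group, and zero-inflated NB counts.
#'
#' @param name one of \code{"default"}, \code{"no_plate_effect"},
#'   \code{"half_plate_effect"}, \code{"variable_libsizes"},
#'   \code{"variable_cell_numbers"}, \code{"more_plates"}, \code{"zinb"}.
#' @param ... further arguments passed to [sim_config()] (e.g. \code{n_genes},
#'   \code{seed}, \code{de_fraction}), applied on top of the scenario preset.
#' @return A \code{"sim_config"} object.
#' @examples
#' scenario("half_plate_effect")$sigma_plate
#' @export
scenario <- function(name = "default", ...) {
  choices <- c("default", "no_plate_effect", "half_plate_effect",
               "variable_libsizes", "variable_cell_numbers",
               "more_plates", "zinb")
  if (length(name) != 1L || !name %in% choices) {
    stop("unknown scenario; valid names are: ",
         paste(choices, collapse = ", "))
  }
  mods <- switch(name,
    default = list(),
    no_plate_effect = list(sigma_plate = 0),
    half_plate_effect = list(sigma_plate = formals(sim_config)$sigma_plate / 2),
    variable_libsizes = list(sigma_theta = 2 * formals(sim_config)$sigma_theta),
    variable_cell_numbers = list(cells_per_plate_range = c(20L, 130L)),
    more_plates = list(plates_per_group = 6L),
    zinb = list(zero_inflation = 0.2)
  )
  args <- utils::modifyList(mods, list(...))
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  disp <- if (is.numeric(x$nb_dispersion)) {
    sprintf("constant %.3g", x$nb_dispersion)
  } else {
    sprintf("log-normal(meanlog=%.3g, sdlog=%.3g)",
            x$nb_dispersion$meanlog, x$nb_dispersion$sdlog)
  }
  cat("Simulation configuration\n")
  cat(sprintf("  %d genes; %d group(s) x %d plate(s); %d-%d cells/plate\n",
              x$n_genes, x$n_groups, x$plates_per_group,
              x$cells_per_plate_range[1L], x$cells_per_plate_range[2L]))
  cat(sprintf("  base mean: log-normal(meanlog=%.3g, sdlog=%.3g); dispersion: %s\n",
              x$mean_log_mu, x$sd_log_mu, disp))
  cat(sprintf("  sigma_plate=%.3g, sigma_theta=%.3g, dropout=%.3g\n",
              x$sigma_plate, x$sigma_theta, x$zero_inflation))
  cat(sprintf("  DE spike-in: fraction=%.3g, |log2FC|=%.3g\n",
              x$de_fraction, x$de_log2fc))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
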