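#' Per-cell plate/group design
#'
#' Validates and stores the plate and group label of every cell. The design
#' must be plate-confounded: every cell on one plate belongs to the same
#' group (each plate holds one population of one group), which is the
#' structure that makes plate effects indistinguishable from group effects
#' at the cell level.
#'
#' @param cell_plate per-cell plate identifier.
#' @param cell_group per-cell group identifier.
#' @return An object of class \code{"plate_design"}: list with
#'   \code{cell_plate}, \code{cell_group} (character) and the derived
#'   \code{plate_group} (one group label per distinct plate, named by plate,
#'   in first-appearance order).
#' @export
plate_design <- function(cell_plate, cell_group) {
  if (length(cell_plate) != length(cell_group)) {
    stop("'cell_plate' and 'cell_group' must have the same length")
  }
  if (length(cell_plate) == 0L) stop("empty design")
  cell_plate <- as.character(cell_plate)
  cell_group <- as.character(cell_group)
  plates <- unique(cell_plate)
  plate_group <- vapply(plates, function(p) {
    g <- unique(cell_group[cell_plate == p])
    if (length(g) != 1L) {
      stop("plate '", p, "' spans more than one group; each plate must ",
           "contain cells from a single group")
    }
    g
  }, character(1))
  structure(list(cell_plate = cell_plate, cell_group = cell_group,
                 plate_group = plate_group),
            class = "plate_design")
}

#' @export
print.plate_design <- function(x, ...) {
  cat(sprintf("Plate design: %d cells on %d plates in %d groups\n",
              length(x$cell_plate), length(x$plate_group),
              length(unique(x$cell_group))))
  print(table(plate = x$cell_plate)[unique(x$cell_plate)])
  invisible(x)
}

#' Sum counts across all cells on each plate
#'
#' Collapses a gene x cell count matrix to a gene x plate matrix of count
#' sums (pseudobulk). The sums are then analysed with the plates as
#' replicate samples: the plate effect is sampled independently per plate,
#' so the plate-level observations are independent and the residual degrees
#' of freedom are counted honestly.
#'
#' @param counts gene x cell matrix of counts.
#' @param design a [plate_design()] covering every column of \code{counts}.
#' @return An object of class \code{"summed_counts"}: list with
#'   \code{counts} (gene x plate matrix, columns in first-appearance plate
#'   order) and \code{plate_group}.
#' @examples
#' y <- matrix(1:4, 1)
#' d <- plate_design(c("A", "A", "B", "B"), c("g1", "g1", "g2", "g2"))
#' sum_by_plate(y, d)$counts
#' @export
sum_by_plate <- function(counts, design) {
  stopifnot(inherits(design, "plate_design"))
  counts <- as.matrix(counts)
  if (ncol(counts) != length(design$cell_plate)) {
    stop("design describes ", length(design$cell_plate),
         " cells but 'counts' has ", ncol(counts), " columns")
  }
  plates <- names(design$plate_group)
  f <- factor(design$cell_plate, levels = plates)
  summed <- t(rowsum(t(counts), f))
  colnames(summed) <- plates
  structure(list(counts = summed, plate_group = design$plate_group),
            class = "summed_counts")
}

#' @export
print.summed_counts <- function(x, ...) {
  cat(sprintf("Summed counts: %d genes x %d plates\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$plate_group)
  invisible(x)
}

#' Residual degrees of freedom of a linear layout
#'
#' Number of samples minus number of fitted coefficients. With 300 cells
#' and a two-group one-way layout this is 298 when cells are (incorrectly)
#' treated as independent replicates; after per-plate summation of the same
#' design (6 plates) it is 4 — the honest amount of replication.
#'
#' @param n_samples number of independent samples.
#' @param n_coefficients number of model coefficients (>= 1).
#' @return Integer residual degrees of freedom (> 0, else an error).
#' @examples
#' residual_df(300, 2)  # 298
#' residual_df(6, 2)    # 4
#' @export
residual_df <- function(n_samples, n_coefficients) {
  stopifnot(length(n_samples) == 1L, length(n_coefficients) == 1L,
            n_coefficients >= 1)
  if (n_samples <= n_coefficients) {
    stop("no residual degrees of freedom: ", n_samples, " samples with ",
         n_coefficients, " coefficients (the model is saturated; ",
         "variances cannot be estimated without replication)")
  }
  as.integer(n_samples) - as.integer(n_coefficients)
}

#' Filter low-abundance genes
#'
#' Removes genes whose average count across samples is below
#' \code{min_mean}; a mean exactly equal to \code{min_mean} is kept. The
#' filter is defined on the matrix actually being averaged (cells for
#' single-cell analyses), and the kept-gene index can be reused so that
#' single-cell and summed analyses test an identical gene set.
#'
#' @param counts gene x sample matrix.
#' @param min_mean minimum average count (default 1).
#' @return List with \code{counts} (filtered matrix) and \code{keep}
#'   (integer indices of retained rows in the input).
#' @export
filter_low_abundance <- function(counts, min_mean = 1) {
  stopifnot(min_mean >= 0)
  counts <- as.matrix(counts)
  keep <- which(rowMeans(counts) >= min_mean)
  list(counts = counts[keep, , drop = FALSE], keep = keep)
}
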