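#' Read a gene x sample count matrix
#'
#' TSV: tab-separated, header row, gene identifiers in the first column.
#' MTX: MatrixMarket coordinate file with sidecar identifier files
#' \code{genes.tsv} and \code{cells.tsv} (one id per line, no header) in
#' the same directory. Counts must be non-negative integers; violations are
#' reported with the offending gene and sample.
#'
#' @param path file path (\code{.tsv} or \code{.mtx}).
#' @param format \code{"tsv"} or \code{"mtx"}; inferred from the extension
#'   by default.
#' @return Integer matrix with unique row (gene) and column (sample)
#'   names.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(path))
    gf <- file.path(dirname(path), "genes.tsv")
    cf <- file.path(dirname(path), "cells.tsv")
    genes <- readLines(gf)
    cells <- readLines(cf)
    if (length(genes) != nrow(m)) {
      stop("genes.tsv has ", length(genes), " ids but the matrix has ",
           nrow(m), " rows")
    }
    if (length(cells) != ncol(m)) {
      stop("cells.tsv has ", length(cells), " ids but the matrix has ",
           ncol(m), " columns")
    }
    dimnames(m) <- list(genes, cells)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("gene and sample identifiers must be unique")
  }
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-integer or negative count for gene '",
         rownames(m)[bad[1L, 1L]], "', sample '",
         colnames(m)[bad[1L, 2L]], "'")
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' @param counts gene x sample matrix.
#' @param path output path; MatrixMarket (with sidecar id files) when it
#'   ends in \code{.mtx}, TSV otherwise.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- as.matrix(counts)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(counts), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(counts), file.path(dirname(path), "cells.tsv"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cell design table
#'
#' TSV with header columns \code{cell}, \code{plate}, \code{group}. The
#' plate-to-group map must be consistent (a plate spanning two groups is an
#' error, since the model assumes each plate holds one group).
#'
#' @param path file path.
#' @return A [plate_design()] with cell names in \code{names(cell_plate)}.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell", "plate", "group")
  if (nrow(tab) == 0L || !all(need %in% names(tab))) {
    stop("design table needs non-empty columns: ",
         paste(need, collapse = ", "))
  }
  d <- plate_design(tab$plate, tab$group)
  names(d$cell_plate) <- tab$cell
  d
}

#' Write a design table
#'
#' @param design a [plate_design()].
#' @param path output TSV path.
#' @param cells cell identifiers (default from the design, else generated).
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path, cells = NULL) {
  if (is.null(cells)) {
    cells <- names(design$cell_plate) %||%
      paste0("cell", seq_along(design$cell_plate))
  }
  utils::write.table(
    data.frame(cell = cells, plate = design$cell_plate,
               group = design$cell_group),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a small deterministic fixture on disk
#'
#' Writes a scenario-derived dataset (at most 500 genes, fixed seed) as
#' \code{counts.tsv}, \code{design.tsv} and a ground-truth table
#' \code{truth.tsv} (columns \code{gene}, \code{true_de},
#' \code{true_log2fc}) into \code{dir}. Re-running with the same arguments
#' reproduces the files byte for byte.
#'
#' @param name a [scenario()] name, or \code{"spiked"} for the default
#'   scenario with 10\% DE genes.
#' @param dir output directory (created if needed).
#' @param n_genes number of genes (<= 500).
#' @param seed fixed seed (default 42).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture <- function(name = "default", dir = tempfile("fixture"),
                         n_genes = 200, seed = 42) {
  stopifnot(n_genes <= 500)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- if (identical(name, "spiked")) {
    scenario("default", n_genes = n_genes, seed = seed, de_fraction = 0.1)
  } else {
    scenario(name, n_genes = n_genes, seed = seed)
  }
  dat <- simulate_dataset(cfg)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(dat$counts, paths[["counts"]])
  write_design(dat$design, paths[["design"]], cells = colnames(dat$counts))
  utils::write.table(
    data.frame(gene = rownames(dat$counts), true_de = dat$true_de,
               true_log2fc = dat$true_log2fc),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
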