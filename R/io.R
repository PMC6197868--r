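# Reading/writing count matrices and the cell/gene quality filters.

#' Read a UMI count matrix
#'
#' Accepts either a directory holding a MatrixMarket triplet file
#' (`matrix.mtx`) with `genes.tsv`/`barcodes.tsv` sidecars (the layout
#' written by [write_pineal_dataset()]), a path to an `.mtx` file with
#' sidecars next to it, or a dense delimited table (CSV/TSV) with gene
#' rows, cell columns, a header row of cell identifiers and a first
#' column of gene identifiers.
#'
#' @param path Directory or file path.
#' @return A sparse integer `dgCMatrix`, genes x cells, with unique
#'   dimnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path)
    return(read_counts_mtx(mtx))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path)) read_counts_mtx(path) else read_counts_dense(path)
}

read_counts_mtx <- function(mtx) {
  dir <- dirname(mtx)
  m <- Matrix::readMM(mtx)
  genes <- readLines(file.path(dir, "genes.tsv"))
  genes <- sub("\t.*$", "", genes)
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecars (", length(genes), " genes, ",
         length(cells), " barcodes)")
  dimnames(m) <- list(genes, cells)
  validate_counts(methods::as(m, "CsparseMatrix"))
}

read_counts_dense <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  m <- Matrix::Matrix(as.matrix(df), sparse = TRUE)
  validate_counts(methods::as(m, "CsparseMatrix"))
}

validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene and cell identifiers")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(rownames(m)[duplicated(rownames(m))]), 3),
               collapse = ", "))
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
  x <- m@x
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integers")
  m
}

qc_report <- function(per_cell, removed_cells, removed_genes, thresholds) {
  structure(list(per_cell = per_cell, removed_cells = removed_cells,
                 removed_genes = removed_genes, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> removed ", nrow(x$removed_cells), " cells, ",
      length(x$removed_genes), " genes (",
      paste(names(x$thresholds), unlist(x$thresholds), sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Per-cell QC summary
#'
#' @param m Count matrix (genes x cells).
#' @return Tibble with `cell_id`, `n_genes` (genes with count > 0) and
#'   `total_umi`.
#' @export
qc_cell_stats <- function(m) {
  tibble::tibble(cell_id = colnames(m),
                 n_genes = Matrix::colSums(m > 0),
                 total_umi = Matrix::colSums(m))
}

#' Remove cells expressing too few genes
#'
#' A gene is detected in a cell when its count is > 0; cells detecting
#' fewer than `min_genes` genes are removed (strict: exactly `min_genes`
#' is retained).
#'
#' @param m Count matrix.
#' @param min_genes Minimum detected genes (default 800).
#' @return List with the filtered `counts` and a `report` (`qc_report`).
#' @export
filter_cells_min_genes <- function(m, min_genes = 800) {
  st <- qc_cell_stats(m)
  keep <- st$n_genes >= min_genes
  rep <- qc_report(st,
                   tibble::tibble(cell_id = st$cell_id[!keep], reason = "low_genes"),
                   character(), list(min_genes = min_genes))
  list(counts = m[, keep, drop = FALSE], report = rep)
}

#' Remove cells with outlier UMI totals
#'
#' Cells whose total UMI count strictly exceeds `max_umi` are removed,
#' excluding likely multi-cell droplets.  The cutoff is sample-specific
#' and has no default: pass `Inf` to disable.
#'
#' @param m Count matrix.
#' @param max_umi Per-sample UMI ceiling (strict >).
#' @return List with filtered `counts` and a `report`.
#' @export
filter_umi_outliers <- function(m, max_umi) {
  stopifnot(max_umi > 0)
  st <- qc_cell_stats(m)
  keep <- st$total_umi <= max_umi
  rep <- qc_report(st,
                   tibble::tibble(cell_id = st$cell_id[!keep], reason = "umi_outlier"),
                   character(), list(max_umi = max_umi))
  list(counts = m[, keep, drop = FALSE], report = rep)
}

#' Remove genes detected in too few cells
#'
#' Genes detected (count > 0) in fewer than `min_cells` cells are
#' excluded; exactly `min_cells` is retained.
#'
#' @param m Count matrix.
#' @param min_cells Minimum number of cells (default 3).
#' @return List with filtered `counts` and a `report`.
#' @export
filter_genes_min_cells <- function(m, min_cells = 3) {
  det <- Matrix::rowSums(m > 0)
  keep <- det >= min_cells
  rep <- qc_report(qc_cell_stats(m), tibble::tibble(cell_id = character(),
                                                    reason = character()),
                   rownames(m)[!keep], list(min_cells = min_cells))
  list(counts = m[keep, , drop = FALSE], report = rep)
}

#' Apply the standard QC sequence
#'
#' Cell filters first (minimum detected genes, then the per-sample UMI
#' ceiling), gene filter last — detection counts therefore refer to the
#' QC-passing cells.
#'
#' @param m Count matrix.
#' @param min_genes Minimum detected genes per cell.
#' @param max_umi Per-sample UMI ceiling (required; `Inf` disables).
#' @param min_cells Minimum cells per gene.
#' @return List with filtered `counts` and a combined `report`.
#' @export
qc_filter <- function(m, min_genes = 800, max_umi, min_cells = 3) {
  if (missing(max_umi))
    stop("max_umi is sample-specific and must be supplied (use Inf to disable)")
  s1 <- filter_cells_min_genes(m, min_genes)
  s2 <- filter_umi_outliers(s1$counts, max_umi)
  s3 <- filter_genes_min_cells(s2$counts, min_cells)
  rep <- qc_report(s1$report$per_cell,
                   dplyr::bind_rows(s1$report$removed_cells, s2$report$removed_cells),
                   s3$report$removed_genes,
                   list(min_genes = min_genes, max_umi = max_umi,
                        min_cells = min_cells))
  list(counts = s3$counts, report = rep)
}

#' Pool replicate samples into one matrix
#'
#' Columns are concatenated over the shared gene universe; cell
#' identifiers are prefixed with the replicate label to stay unique.
#'
#' @param samples List of count matrices.
#' @param labels Character vector of replicate labels, one per sample.
#' @param join `"intersect"` (default) restricts to genes present in all
#'   samples; `"strict"` errors unless gene universes are identical.
#' @return Pooled sparse count matrix.
#' @export
pool_replicates <- function(samples, labels, join = c("intersect", "strict")) {
  join <- match.arg(join)
  stopifnot(length(samples) == length(labels), length(samples) >= 1)
  genes <- Reduce(intersect, lapply(samples, rownames))
  if (join == "strict" &&
      !all(vapply(samples, function(s) identical(sort(rownames(s)), sort(genes)),
                  logical(1))))
    stop("gene universes differ between replicates")
  if (length(genes) == 0) stop("replicates share no genes")
  pooled <- do.call(cbind, purrr::map2(samples, labels, function(s, l) {
    s <- s[genes, , drop = FALSE]
    colnames(s) <- paste0(l, "_", colnames(s))
    s
  }))
  if (anyDuplicated(colnames(pooled))) stop("cell identifiers collide after prefixing")
  pooled
}
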