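# Normalization, log transform, variable-gene selection, scaling.

new_norm_matrix <- function(values, scheme, totals) {
  structure(list(values = values, scheme = scheme, totals = totals),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("<norm_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells, scheme = ", x$scheme, "\n", sep = "")
  invisible(x)
}

#' Normalize counts to a fixed total per cell
#'
#' Each cell's counts are scaled so the column sums to `scale_total`
#' (default 10,000 molecules per cell).
#'
#' @param m Count matrix (genes x cells).
#' @param scale_total Target column total.
#' @return A `norm_matrix` with scheme `"per_total"`.
#' @export
normalize_per_cell <- function(m, scale_total = 10000) {
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(colnames(m)[totals == 0], 3), collapse = ", "))
  v <- m %*% Matrix::Diagonal(x = scale_total / totals)
  dimnames(v) <- dimnames(m)
  new_norm_matrix(methods::as(v, "CsparseMatrix"), "per_total", totals)
}

#' Natural-log transform normalized values
#'
#' Applies `ln(x + 1)` elementwise; zeros stay zero, preserving sparsity.
#' Refuses to run twice (the scheme tag tracks state).
#'
#' @param nm A `norm_matrix` with scheme `"per_total"`.
#' @return A `norm_matrix` with scheme `"lognorm"`.
#' @export
log_transform <- function(nm) {
  stopifnot(inherits(nm, "norm_matrix"))
  if (nm$scheme != "per_total")
    stop("log_transform expects per-total normalized values, got scheme '",
         nm$scheme, "'")
  v <- nm$values
  v@x <- log1p(v@x)
  new_norm_matrix(v, "lognorm", nm$totals)
}

# Row means and variances of a sparse matrix without densifying.
row_mean_var <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowSums(m) / n
  ex2 <- Matrix::rowSums(m^2) / n
  list(mean = mu, var = (ex2 - mu^2) * n / max(1, n - 1))
}

#' Select highly variable genes by binned dispersion
#'
#' Per gene the mean statistic is `ln(mean(exp(value) - 1) + 1)` (the log
#' of the mean un-logged normalized count) and the dispersion statistic
#' is `ln(variance / mean)` of the un-logged normalized counts.  Genes
#' are binned into `n_bins` equal-width bins of the mean statistic (ties
#' at edges fall to the lower bin) and the dispersion is z-scored within
#' each bin.  A gene is selected when
#' `x_low < mean-stat < x_high` and `z > y` (all strict).
#'
#' @param nm A log-transformed `norm_matrix`.
#' @param x_low,x_high,y Cutoffs (defaults 0.0125, 3, 0.3).
#' @param n_bins Number of mean bins (default 20).
#' @return A tibble (`hvg_selection`): `gene`, `mean_stat`, `dispersion`,
#'   `z`, `selected`, with cutoffs stored as attributes.
#' @export
select_hvg <- function(nm, x_low = 0.0125, x_high = 3, y = 0.3, n_bins = 20) {
  stopifnot(inherits(nm, "norm_matrix"))
  if (nm$scheme != "lognorm") stop("select_hvg expects log-transformed values")
  un <- nm$values
  un@x <- expm1(un@x)
  mv <- row_mean_var(un)
  mean_stat <- log1p(mv$mean)
  dispersion <- ifelse(mv$mean > 0, log(mv$var / mv$mean), NA_real_)
  dispersion[is.nan(dispersion) | is.infinite(dispersion)] <- NA_real_

  rng <- range(mean_stat)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(mean_stat, edges, left.open = TRUE, all.inside = TRUE)
  z <- rep(NA_real_, length(mean_stat))
  for (b in unique(bin)) {
    i <- which(bin == b & !is.na(dispersion))
    if (length(i) == 0) next
    s <- stats::sd(dispersion[i])
    z[i] <- if (length(i) < 2 || is.na(s) || s == 0) 0
            else (dispersion[i] - mean(dispersion[i])) / s
  }
  out <- tibble::tibble(
    gene = rownames(nm$values), mean_stat = unname(mean_stat),
    dispersion = unname(dispersion), z = unname(z),
    selected = !is.na(z) & mean_stat > x_low & mean_stat < x_high & z > y
  )
  attr(out, "cutoffs") <- list(x_low = x_low, x_high = x_high, y = y,
                               n_bins = n_bins)
  class(out) <- c("hvg_selection", class(out))
  out
}

#' Genes selected by an HVG table
#' @param hvg An `hvg_selection` tibble.
#' @return Character vector of selected gene identifiers.
#' @export
hvg_genes <- function(hvg) hvg$gene[hvg$selected]

#' Center and scale genes for PCA
#'
#' Restricts to `genes`, then standardizes each gene row to zero mean and
#' unit variance across cells; zero-variance genes become all-zero rows.
#' Scaled values are clipped at `±clip` to bound outlier influence.
#'
#' @param nm A log-transformed `norm_matrix`.
#' @param genes Genes to keep (typically [hvg_genes()]).
#' @param clip Absolute clipping bound (default 10; `Inf` disables).
#' @return Dense numeric matrix, genes x cells.
#' @export
scale_genes <- function(nm, genes, clip = 10) {
  stopifnot(inherits(nm, "norm_matrix"))
  missing <- setdiff(genes, rownames(nm$values))
  if (length(missing)) stop("genes not in matrix: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  x <- as.matrix(nm$values[genes, , drop = FALSE])
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  x <- (x - mu) / ifelse(sd > 0, sd, 1)
  x[sd == 0, ] <- 0
  if (is.finite(clip)) x <- pmin(pmax(x, -clip), clip)
  x
}
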