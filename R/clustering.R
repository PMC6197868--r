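# PCA, SNN graph, Louvain communities, cluster consolidation, doublet
# exclusion, the cluster dendrogram and proportion tables.

#' Principal component analysis of scaled expression
#'
#' Exact PCA via an eigendecomposition of the smaller Gram matrix (the
#' matrices are desk-scale).  Deterministic up to component sign, which
#' is fixed by making each component's largest-magnitude gene loading
#' positive.
#'
#' @param scaled Dense genes x cells matrix from [scale_genes()].
#' @param k Number of components (2 <= k <= min(dim)).
#' @return A `pca_model`: `loadings` (genes x k, orthonormal), `scores`
#'   (cells x k), `var_explained`, `k`.
#' @export
run_pca <- function(scaled, k) {
  x <- t(scaled)                       # cells x genes, columns centered
  n <- nrow(x); g <- ncol(x)
  if (k < 2 || k > min(n, g)) stop("k must lie in [2, ", min(n, g), "]")
  if (g <= n) {
    e <- eigen(crossprod(x), symmetric = TRUE)
    load <- e$vectors[, seq_len(k), drop = FALSE]
    scores <- x %*% load
    ev <- e$values
  } else {
    e <- eigen(tcrossprod(x), symmetric = TRUE)
    ev <- e$values
    pos <- pmax(ev[seq_len(k)], .Machine$double.eps)
    scores <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos), k)
    load <- crossprod(x, e$vectors[, seq_len(k), drop = FALSE]) %*%
      diag(1 / sqrt(pos), k)
  }
  flip <- vapply(seq_len(k), function(j) {
    l <- load[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  rownames(load) <- rownames(scaled)
  rownames(scores) <- colnames(scaled)
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(k))
  tot <- sum(pmax(ev, 0))
  structure(list(loadings = load, scores = scores,
                 var_explained = pmax(ev[seq_len(k)], 0) / tot, k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", nrow(x$scores), " cells x ", x$k, " PCs (",
      round(100 * sum(x$var_explained), 1), "% variance)\n", sep = "")
  invisible(x)
}

# k-nearest-neighbor indices (self included) in PC space, by exact
# chunked Euclidean distances; ties broken by cell index.
knn_indices <- function(scores, knn_k) {
  n <- nrow(scores)
  stopifnot(knn_k >= 1, knn_k <= n)
  sq <- rowSums(scores^2)
  idx <- matrix(0L, n, knn_k)
  step <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = step)) {
    rows <- start:min(n, start + step - 1L)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(scores[rows, , drop = FALSE],
                                                    scores)
    for (i in seq_along(rows))
      idx[rows[i], ] <- order(d2[i, ])[seq_len(knn_k)]
  }
  idx
}

#' Shared-nearest-neighbor graph
#'
#' Nodes are cells; the weight of edge (i, j) is the Jaccard overlap of
#' the two cells' `knn_k`-nearest-neighbor sets (Euclidean in PC space,
#' each set including the cell itself).  Edges with weight below `prune`
#' are dropped, as are self-loops.
#'
#' @param pca A `pca_model` (or a cells x k score matrix).
#' @param knn_k Neighborhood size (default 30).
#' @param prune Minimum retained Jaccard weight (default 1/15).
#' @return An `snn_graph`: sparse symmetric `adjacency` plus parameters.
#' @export
build_snn <- function(pca, knn_k = 30, prune = 1 / 15) {
  scores <- if (inherits(pca, "pca_model")) pca$scores else pca
  n <- nrow(scores)
  if (knn_k >= n) stop("knn_k must be smaller than the number of cells")
  nn <- knn_indices(scores, knn_k)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), knn_k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  snn <- shared
  snn@x <- snn@x / (2 * knn_k - snn@x)     # |A n B| / |A u B|
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  snn <- Matrix::drop0(snn)
  dimnames(snn) <- list(rownames(scores), rownames(scores))
  structure(list(adjacency = snn, knn_k = knn_k, prune = prune),
            class = "snn_graph")
}

#' Modularity community detection on an SNN graph
#'
#' Louvain modularity maximization at the given resolution.
#' Deterministic for a fixed seed and node order; labels are
#' canonicalized to 1, 2, ... by decreasing community size (ties by
#' first member).
#'
#' @param snn An `snn_graph`.
#' @param resolution Modularity resolution (default 0.8).
#' @param seed Integer seed.
#' @return Integer vector of community labels named by cell.
#' @export
find_communities <- function(snn, resolution = 0.8, seed = 0L) {
  g <- igraph::graph_from_adjacency_matrix(snn$adjacency, mode = "undirected",
                                           weighted = TRUE)
  memb <- withr::with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  canonicalize_labels(as.integer(memb), names = rownames(snn$adjacency))
}

canonicalize_labels <- function(labels, names = NULL) {
  ord <- order(-tabulate(labels), match(seq_len(max(labels)), labels))
  out <- match(labels, ord)
  names(out) <- names
  out
}

#' Consolidate raw communities into final clusters
#'
#' Modularity clustering routinely over-partitions one biological
#' population.  Two raw communities are merged when no gene passes the
#' composite DE decision rule between them (all four criteria of
#' [de_criteria()]); merging is transitive (connected components of the
#' merge graph).  An explicit `manual` list of label groups overrides
#' the data-driven rule for the named communities.
#'
#' @param nm Per-total normalized matrix.
#' @param labels Named integer vector from [find_communities()].
#' @param criteria A [de_criteria()].
#' @param manual Optional list of integer vectors; each vector's raw
#'   communities are forced into one final cluster.
#' @return A `cluster_model`: `cells` tibble (`cell_id`, `raw_cluster`,
#'   `cluster`, `excluded`), the raw-to-final `map`, and parameters.
#' @export
consolidate <- function(nm, labels, criteria = de_criteria(), manual = NULL) {
  raw <- sort(unique(labels))
  k <- length(raw)
  merge_to <- seq_len(k)
  if (k > 1) {
    pairs <- utils::combn(k, 2)
    adj <- matrix(FALSE, k, k)
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]; j <- pairs[2, q]
      a <- names(labels)[labels == raw[i]]
      b <- names(labels)[labels == raw[j]]
      adj[i, j] <- adj[j, i] <- !any_de_between(nm, a, b, criteria)
    }
    if (!is.null(manual))
      for (grp in manual) {
        ii <- match(grp, raw)
        adj[ii, ii] <- TRUE
      }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    merge_to <- as.integer(igraph::components(g)$membership)
  }
  final <- merge_to[match(labels, raw)]
  final <- canonicalize_labels(final, names = names(labels))
  structure(list(
    cells = tibble::tibble(cell_id = names(labels),
                           raw_cluster = unname(labels),
                           cluster = unname(final),
                           excluded = FALSE),
    map = tibble::tibble(raw_cluster = raw,
                         cluster = unname(final[match(raw, labels)])),
    criteria = criteria
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  keep <- !x$cells$excluded
  cat("<cluster_model> ", sum(keep), " cells in ",
      length(unique(x$cells$cluster[keep])), " final clusters (",
      length(unique(x$cells$raw_cluster)), " raw); ",
      sum(!keep), " excluded\n", sep = "")
  invisible(x)
}

#' Flag putative doublets by cross-cluster marker expression
#'
#' A droplet containing two cells co-expresses markers that are
#' exclusive to separate clusters.  For every final cluster, each cell's
#' normalized counts are summed over that cluster's marker genes; a cell
#' is flagged when its marker sum exceeds the cluster-specific
#' moderate-to-high `level` for two or more distinct clusters.  By
#' default `level` is the `level_quantile` (95th percentile) of the
#' marker-sum distribution among cells outside the marker's own cluster.
#'
#' @param nm Per-total normalized matrix.
#' @param model A `cluster_model`.
#' @param markers Named list: final cluster -> exclusive marker genes
#'   (see [cluster_markers()]).
#' @param level Optional named numeric vector of explicit thresholds per
#'   cluster; `Inf` disables flagging.
#' @param level_quantile Quantile of the non-member marker-sum
#'   distribution entering the default level.
#' @param member_fraction The default level is additionally floored at
#'   this fraction of the member median marker sum (default 0.25), so
#'   that only moderate-to-high expression relative to genuine members
#'   counts — ambient contamination and stray counts sit far below it,
#'   while a doublet carries about half a member's signal.
#' @return The `cluster_model` with flagged cells marked `excluded` and
#'   an `excluded` tibble attached.
#' @export
exclude_doublets <- function(nm, model, markers, level = NULL,
                             level_quantile = 0.95, member_fraction = 0.25) {
  cells <- model$cells$cell_id
  cl <- as.character(model$cells$cluster)
  sums <- vapply(names(markers), function(c) {
    genes <- intersect(markers[[c]], rownames(nm$values))
    if (length(genes) == 0) return(rep(0, length(cells)))
    Matrix::colSums(nm$values[genes, cells, drop = FALSE])
  }, numeric(length(cells)))
  lev <- vapply(names(markers), function(c) {
    if (!is.null(level) && c %in% names(level)) return(level[[c]])
    max(stats::quantile(sums[cl != c, c], level_quantile, names = FALSE),
        member_fraction * stats::median(sums[cl == c, c]))
  }, numeric(1))
  hits <- sweep(sums, 2, lev, ">")
  flagged <- rowSums(hits) >= 2
  model$cells$excluded <- model$cells$excluded | flagged
  model$excluded <- tibble::tibble(cell_id = cells[flagged], reason = "doublet")
  model$doublet_levels <- lev
  model
}

#' Dendrogram over final cluster mean profiles
#'
#' Average-linkage hierarchical clustering of the Euclidean distances
#' between cluster mean log-normalized profiles over the highly variable
#' genes.  Deterministic; leaves of equal-height joins fall back to
#' label order.
#'
#' @param nm Log-normalized matrix.
#' @param model A `cluster_model` (excluded cells are ignored).
#' @param hvg An `hvg_selection` (or a character vector of genes).
#' @return List with the `hclust` tree, the corresponding `ape::phylo`,
#'   and the profile matrix.
#' @export
cluster_tree <- function(nm, model, hvg) {
  stopifnot(nm$scheme == "lognorm")
  genes <- if (is.character(hvg)) hvg else hvg_genes(hvg)
  cells <- model$cells[!model$cells$excluded, ]
  cl <- sort(unique(cells$cluster))
  if (length(cl) < 2) stop("need at least 2 final clusters")
  prof <- vapply(cl, function(c)
    Matrix::rowMeans(nm$values[genes, cells$cell_id[cells$cluster == c],
                               drop = FALSE]),
    numeric(length(genes)))
  colnames(prof) <- as.character(cl)
  hc <- stats::hclust(stats::dist(t(prof)), method = "average")
  list(hclust = hc, phylo = ape::as.phylo(hc), profiles = prof)
}

#' Cell-type proportion table
#'
#' Counts and percentages per annotated label, plus each subtype's share
#' within its family (pinealocytes, astrocytes, microglia, ...).
#'
#' @param annotation Tibble with `cell_id`, `label`, `family` (and
#'   optionally `subtype`) per retained cell.
#' @return Tibble: `label`, `family`, `n`, `pct` (of all cells),
#'   `pct_of_family`.
#' @export
cluster_proportions <- function(annotation) {
  annotation |>
    dplyr::count(.data$label, .data$family, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(pct_of_family = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$n))
}
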