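# Per-cluster marker discovery and reference-panel annotation.

#' Default pineal reference marker panel
#'
#' Established cell-type markers for the pineal gland: melatonin-pathway
#' and phototransduction-related genes for pinealocytes, glial markers
#' for astrocytes, immune markers for microglia, collagen/proteoglycan
#' genes for vascular and leptomeningeal cells (VLMC) and junction/
#' adhesion genes for endothelial cells.
#'
#' @return Named list: cell-type -> marker gene identifiers.
#' @export
default_reference_panel <- function() {
  list(pinealocyte = c("Tph1", "Asmt", "Sag"),
       astrocyte = c("Aldh1a1", "S100b", "Tnfrsf21"),
       microglia = c("Aif1", "Lyz2"),
       vlmc = c("Lum", "Dcn", "Col1a1", "Gjb2"),
       endothelial = c("Vwf", "Esam", "Cdh5", "Ecmn"))
}

#' One-vs-rest marker detection for final clusters
#'
#' For each tested cluster, every gene detected in at least
#' `min_detection` of cells in the cluster or in the rest is compared
#' between the two groups, either by the Wilcoxon rank-sum test
#' (`mode = "wilcox"`, ranked by p then by decreasing fold) or by ROC
#' analysis (`mode = "roc"`, ranked by classification power
#' `2|AUC - 0.5|`).
#'
#' @param nm Per-total normalized matrix.
#' @param model A `cluster_model` (excluded cells are ignored).
#' @param clusters Clusters to test (default all).
#' @param mode `"wilcox"` or `"roc"`.
#' @param min_detection Detection pre-filter (0 tests every gene).
#' @return Tibble: `cluster`, `gene`, `mean_in`, `mean_out`,
#'   `detection_in`, `detection_out`, `fold`, and `p`/`p_adj` or
#'   `auc`/`power`, ranked within cluster.
#' @export
find_markers <- function(nm, model, clusters = NULL,
                         mode = c("wilcox", "roc"), min_detection = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(nm, "norm_matrix"), nm$scheme == "per_total")
  cells <- model$cells[!model$cells$excluded, ]
  clusters <- clusters %||% sort(unique(cells$cluster))
  purrr::map_dfr(clusters, function(cl) {
    inc <- cells$cell_id[cells$cluster == cl]
    outc <- cells$cell_id[cells$cluster != cl]
    if (length(inc) < 3)
      warning("cluster ", cl, " has fewer than 3 cells", call. = FALSE)
    si <- group_stats(nm, inc); so <- group_stats(nm, outc)
    keep <- pmax(si$detection, so$detection) >= min_detection
    res <- tibble::tibble(
      cluster = cl, gene = si$gene[keep],
      mean_in = si$mean[keep], mean_out = so$mean[keep],
      detection_in = si$detection[keep], detection_out = so$detection[keep],
      fold = {
        r <- fold_change(si$mean[keep], so$mean[keep])
        pmax(r, 1 / r)
      }
    )
    vi <- as.matrix(nm$values[res$gene, inc, drop = FALSE])
    vo <- as.matrix(nm$values[res$gene, outc, drop = FALSE])
    if (mode == "wilcox") {
      res$p <- vapply(seq_len(nrow(res)), function(i)
        wilcoxon_rank_sum(vi[i, ], vo[i, ])$p.value, numeric(1))
      res$p_adj <- bh_adjust(res$p)
      res[order(res$p, -res$fold), ]
    } else {
      rp <- vapply(seq_len(nrow(res)), function(i) {
        r <- roc_power(vi[i, ], vo[i, ])
        c(r$auc, r$power)
      }, numeric(2))
      res$auc <- rp[1, ]; res$power <- rp[2, ]
      res[order(-res$power), ]
    }
  })
}

#' Exclusive marker lists per cluster
#'
#' Convenience wrapper over ROC-mode [find_markers()]: keeps up-markers
#' (`auc > 0.5`) whose detection fraction stays at or below
#' `max_detection_out` in *every* other final cluster individually —
#' genes shared by sibling clusters of one family are therefore not
#' treated as exclusive — and returns the top `n` per cluster, the
#' marker sets used for doublet exclusion.
#'
#' @param nm Per-total normalized matrix.
#' @param model A `cluster_model`.
#' @param n Markers per cluster (default 10).
#' @param max_detection_out Maximum per-cluster outside detection
#'   (default 0.5; ambient contamination keeps this permissive).
#' @param min_power Minimum classification power `2|AUC - 0.5|` for a
#'   gene to count as particularly specific (default 0.7); clusters
#'   without strongly specific genes contribute no marker set.
#' @return Named list: cluster -> marker genes.
#' @export
cluster_markers <- function(nm, model, n = 10, max_detection_out = 0.5,
                            min_power = 0.7) {
  mk <- find_markers(nm, model, mode = "roc")
  cells <- model$cells[!model$cells$excluded, ]
  cl <- sort(unique(cells$cluster))
  det <- vapply(cl, function(c) {
    ids <- cells$cell_id[cells$cluster == c]
    Matrix::rowSums(nm$values[, ids, drop = FALSE] > 0) / length(ids)
  }, numeric(nrow(nm$values)))
  dimnames(det) <- list(rownames(nm$values), as.character(cl))
  max_other <- vapply(seq_len(nrow(mk)), function(i) {
    other <- setdiff(cl, mk$cluster[i])
    if (length(other) == 0) 0 else max(det[mk$gene[i], as.character(other)])
  }, numeric(1))
  mk <- mk[mk$auc > 0.5 & mk$power >= min_power &
             max_other <= max_detection_out, ]
  split(mk$gene, as.character(mk$cluster)) |>
    lapply(utils::head, n)
}

#' Annotate final clusters against a reference panel
#'
#' Cluster mean log-normalized expression is z-scored per gene across
#' clusters; a cluster's score for a panel type is the mean z over the
#' type's panel genes, and the cluster is assigned the best-scoring type
#' unless the margin over the runner-up is below `margin`
#' ("unassigned").  Within a family holding several clusters, subtypes
#' are named by the subtype-defining gene when one is configured (e.g.
#' alpha-pinealocytes are the Asmt-high cluster(s), those above the
#' midpoint of the cluster-mean range, and every other cluster is beta;
#' a family without at least a 1.5-fold spread on the defining gene is
#' left unsplit), and otherwise by decreasing cluster size (alpha,
#' beta, gamma, ...).
#'
#' @param nm Log-normalized matrix.
#' @param model A `cluster_model` (excluded cells are ignored).
#' @param panel Named list, type -> marker genes
#'   ([default_reference_panel()]).  Panel genes missing from the matrix
#'   warn and are skipped.
#' @param subtype_genes Named character vector, family -> gene whose
#'   high expression defines the alpha subtype.
#' @param margin Minimum score margin before a cluster is "unassigned".
#' @param sd_floor Variance floor (ln-expression units) of the per-gene
#'   across-cluster standard deviation used in the z-score, so that
#'   panel genes that are essentially absent everywhere cannot dominate
#'   the scores through sampling noise.
#' @return An `annotation` list: `clusters` tibble (`cluster`, `family`,
#'   `subtype`, `label`, `score`, `margin`, `n`) and `cells` tibble
#'   (`cell_id`, `cluster`, `family`, `subtype`, `label`).
#' @export
annotate_clusters <- function(nm, model, panel = default_reference_panel(),
                              subtype_genes = c(pinealocyte = "Asmt"),
                              margin = 0.1, sd_floor = 0.5) {
  stopifnot(nm$scheme == "lognorm", length(panel) >= 1)
  cells <- model$cells[!model$cells$excluded, ]
  cl <- sort(unique(cells$cluster))
  panel_genes <- unique(unlist(panel))
  missing <- setdiff(panel_genes, rownames(nm$values))
  if (length(missing))
    warning("panel genes absent from matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  genes <- union(setdiff(panel_genes, missing),
                 intersect(subtype_genes, rownames(nm$values)))
  prof <- vapply(cl, function(c)
    Matrix::rowMeans(nm$values[genes, cells$cell_id[cells$cluster == c],
                               drop = FALSE]),
    numeric(length(genes)))
  prof <- matrix(prof, nrow = length(genes),
                 dimnames = list(genes, as.character(cl)))
  # z-score of cluster means across clusters, with a variance floor (in
  # ln-expression units) so that panel genes expressed nowhere cannot win
  # a cluster on sampling noise alone
  zs <- t(apply(prof, 1, function(x) {
    s <- stats::sd(x)
    if (length(x) < 2 || is.na(s)) return(rep(0, length(x)))
    (x - mean(x)) / max(s, sd_floor)
  }))
  scores <- vapply(panel, function(g) {
    g <- setdiff(g, missing)
    if (length(g) == 0) return(rep(NA_real_, length(cl)))
    colMeans(zs[g, , drop = FALSE])
  }, numeric(length(cl)))
  scores <- matrix(scores, nrow = length(cl),
                   dimnames = list(as.character(cl), names(panel)))

  top_type <- character(length(cl)); top_score <- numeric(length(cl))
  top_margin <- numeric(length(cl))
  for (i in seq_along(cl)) {
    s <- scores[i, ]
    o <- order(-s)
    top_type[i] <- colnames(scores)[o[1]]
    top_score[i] <- s[o[1]]
    top_margin[i] <- if (length(s) > 1) s[o[1]] - s[o[2]] else Inf
  }
  ann <- tibble::tibble(
    cluster = cl,
    family = ifelse(top_margin < margin, "unassigned", top_type),
    score = top_score,
    margin = top_margin,
    n = as.integer(table(cells$cluster)[as.character(cl)])
  )

  ann$subtype <- NA_character_
  for (fam in unique(ann$family)) {
    idx <- which(ann$family == fam)
    if (fam == "unassigned" || length(idx) < 2) next
    sub <- rep(NA_character_, length(idx))
    greek <- c("alpha", "beta", "gamma", "delta", "epsilon")
    if (fam %in% names(subtype_genes) &&
        subtype_genes[[fam]] %in% rownames(prof)) {
      # binary subtype split on the defining gene: clusters above the
      # midpoint of the cluster-mean range are alpha, the rest beta
      # (several beta-side clusters share the beta label — an
      # over-partitioned majority population is one biological subtype).
      # Without a meaningful spread (< 1.5-fold on ln scale) the family
      # is left unsplit rather than inventing subtypes from noise.
      m <- prof[subtype_genes[[fam]], as.character(ann$cluster[idx])]
      if (max(m) - min(m) >= log(1.5)) {
        sub <- ifelse(m > (min(m) + max(m)) / 2, "alpha", "beta")
      }
    } else {
      sub[order(-ann$n[idx])] <- greek[seq_along(idx)]
    }
    ann$subtype[idx] <- sub
  }
  ann$label <- ifelse(is.na(ann$subtype), ann$family,
                      paste(ann$family, ann$subtype, sep = "_"))
  ann <- ann[, c("cluster", "family", "subtype", "label", "score", "margin", "n")]
  cell_ann <- dplyr::left_join(
    cells[, c("cell_id", "cluster")],
    ann[, c("cluster", "family", "subtype", "label")], by = "cluster")
  structure(list(clusters = ann, cells = cell_ann), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation> ", nrow(x$cells), " cells in ", nrow(x$clusters),
      " clusters\n", sep = "")
  print(x$clusters)
  invisible(x)
}
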