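# End-to-end orchestration: simulate/read -> QC -> normalize -> HVG ->
# PCA -> SNN -> communities -> consolidation -> doublet exclusion ->
# annotation -> condition DE -> pooled gene groups -> overlaps.
#
# Conditions (day/night, or vehicle/drug) are processed as separate
# samples through clustering and annotation — each condition gets its
# own variable genes, principal-component count and cluster set — and
# are joined for the cross-condition differential-expression stage.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline.  `max_umi` is sample-specific
#' and has no default; supply one per condition (or a single value, or
#' `Inf` to disable).
#'
#' @param min_genes Minimum detected genes per cell (default 800).
#' @param max_umi Named numeric (per condition) or single UMI ceiling.
#' @param min_cells Minimum cells per gene (default 3).
#' @param scale_total Per-cell normalization target (default 10,000).
#' @param hvg_cutoffs List with `x_low`, `x_high`, `y` for
#'   [select_hvg()].
#' @param n_pcs Named integer vector of principal components per
#'   condition (defaults `c(day = 13, night = 10)`; a condition missing
#'   from the vector falls back to the first entry).
#' @param knn_k,prune,resolution SNN/Louvain parameters.
#' @param criteria [de_criteria()] for consolidation and DE.
#' @param panel Reference panel for [annotate_clusters()].
#' @param subtype_genes Family -> subtype-defining gene.
#' @param contrast Conditions contrasted in DE, a-over-b.
#' @param doublet_quantile Quantile for [exclude_doublets()] levels.
#' @param marker_n Markers per cluster for doublet exclusion.
#' @param seed Integer seed for community detection.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_genes = 800, max_umi = Inf, min_cells = 3,
                            scale_total = 10000,
                            hvg_cutoffs = list(x_low = 0.0125, x_high = 3, y = 0.3),
                            n_pcs = c(day = 13, night = 10),
                            knn_k = 30, prune = 1 / 15, resolution = 0.8,
                            criteria = de_criteria(),
                            panel = default_reference_panel(),
                            subtype_genes = c(pinealocyte = "Asmt"),
                            contrast = c("night", "day"),
                            doublet_quantile = 0.95, marker_n = 10,
                            seed = 0L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# One condition through QC, normalization, HVG, PCA, SNN, Louvain,
# consolidation, doublet exclusion and annotation.
analyze_sample <- function(counts, cfg, condition) {
  max_umi <- if (!is.null(names(cfg$max_umi)) && condition %in% names(cfg$max_umi))
    cfg$max_umi[[condition]] else cfg$max_umi[[1]]
  qc <- qc_filter(counts, min_genes = cfg$min_genes, max_umi = max_umi,
                  min_cells = cfg$min_cells)
  nm <- normalize_per_cell(qc$counts, cfg$scale_total)
  lg <- log_transform(nm)
  hvg <- select_hvg(lg, x_low = cfg$hvg_cutoffs$x_low,
                    x_high = cfg$hvg_cutoffs$x_high, y = cfg$hvg_cutoffs$y)
  k <- if (condition %in% names(cfg$n_pcs)) cfg$n_pcs[[condition]] else cfg$n_pcs[[1]]
  scaled <- scale_genes(lg, hvg_genes(hvg))
  pca <- run_pca(scaled, k = k)
  snn <- build_snn(pca, knn_k = min(cfg$knn_k, nrow(pca$scores) - 1),
                   prune = cfg$prune)
  raw <- find_communities(snn, resolution = cfg$resolution, seed = cfg$seed)
  model <- consolidate(nm, raw, criteria = cfg$criteria)

  # Doublet exclusion works on family-level groupings: sibling clusters
  # of one family share their expression program, so exclusive markers
  # only exist at the family level.  Annotate, pool clusters by family,
  # find family markers, flag cross-family co-expression, re-annotate.
  ann0 <- annotate_clusters(lg, model, panel = cfg$panel,
                            subtype_genes = cfg$subtype_genes)
  fam_of <- stats::setNames(ann0$clusters$family, ann0$clusters$cluster)
  fam_model <- model
  fam_model$cells$cluster <- match(fam_of[as.character(model$cells$cluster)],
                                   unique(fam_of))
  markers <- cluster_markers(nm, fam_model, n = cfg$marker_n)
  fam_model <- exclude_doublets(nm, fam_model, markers,
                                level_quantile = cfg$doublet_quantile)
  names(markers) <- vapply(names(markers), function(i)
    unique(fam_of)[as.integer(i)], character(1))
  model$cells$excluded <- fam_model$cells$excluded
  model$excluded <- fam_model$excluded
  model$doublet_levels <- fam_model$doublet_levels
  ann <- annotate_clusters(lg, model, panel = cfg$panel,
                           subtype_genes = cfg$subtype_genes)
  list(condition = condition, qc = qc$report, norm = nm, lognorm = lg,
       hvg = hvg, pca = pca, model = model, markers = markers,
       annotation = ann)
}

#' Run the full pipeline
#'
#' @param counts Sparse genes x cells count matrix (or a `pineal_sim`,
#'   whose ground-truth metadata supplies the conditions).
#' @param cell_meta Tibble with `cell_id` and `condition` (ignored when
#'   `counts` is a `pineal_sim`).
#' @param config A [pipeline_config()].
#' @param gene_groups Optional named list of candidate gene lists for the
#'   pooled pinealocyte-subtype group comparisons (defaults to the
#'   simulation's planted programs when available): entries `asmt`,
#'   `oxphos`, `ribosomal`, `ggamma`.
#' @return A `pineal_run`: per-condition sample analyses, the combined
#'   cell annotation, proportion table, per-type DE tables, pooled
#'   group comparisons between pinealocyte subtypes, DE overlap tables
#'   and a `summary` list.
#' @export
run_pipeline <- function(counts, cell_meta = NULL, config = pipeline_config(),
                         gene_groups = NULL) {
  sim <- NULL
  if (inherits(counts, "pineal_sim")) {
    sim <- counts
    cell_meta <- sim$cells[, c("cell_id", "condition")]
    if (is.null(gene_groups) && length(sim$config$programs))
      gene_groups <- sim$config$programs[c("asmt", "oxphos", "ribosomal", "ggamma")]
    counts <- sim$counts
  }
  stopifnot(!is.null(cell_meta), all(c("cell_id", "condition") %in% names(cell_meta)))
  conds <- intersect(c(config$contrast, unique(cell_meta$condition)),
                     unique(cell_meta$condition))

  samples <- lapply(conds, function(v) {
    cells <- cell_meta$cell_id[cell_meta$condition == v]
    analyze_sample(counts[, intersect(colnames(counts), cells), drop = FALSE],
                   config, v)
  })
  names(samples) <- conds

  annotation <- purrr::map_dfr(samples, function(s)
    dplyr::mutate(s$annotation$cells, condition = s$condition))
  proportions <- cluster_proportions(annotation)

  # cross-condition DE on the jointly normalized QC-passing cells
  de <- NULL; overlaps <- NULL
  if (all(config$contrast %in% conds)) {
    cells_ab <- annotation$cell_id[annotation$condition %in% config$contrast]
    genes_ab <- Reduce(intersect, lapply(config$contrast, function(v)
      rownames(samples[[v]]$norm$values)))
    nm_all <- normalize_per_cell(counts[genes_ab, cells_ab, drop = FALSE],
                                 config$scale_total)
    # the contrast is per cell type: when the two conditions resolve
    # different subtype sets within a family (e.g. astrocyte subtypes
    # found by day only), that family is tested at the family level
    ann_de <- annotation
    for (fam in unique(ann_de$family)) {
      per_cond <- lapply(config$contrast, function(v)
        unique(ann_de$label[ann_de$family == fam & ann_de$condition == v]))
      if (!setequal(per_cond[[1]], per_cond[[2]]))
        ann_de$label[ann_de$family == fam] <- fam
    }
    excl <- ambient_exclusion(unique(ann_de$label))
    de <- de_test(nm_all, ann_de, contrast = config$contrast,
                  criteria = config$criteria, exclusions = excl)
    up_a <- split(de$gene[de$de & de$direction == paste0(config$contrast[1], "_up")],
                  de$cell_type[de$de & de$direction == paste0(config$contrast[1], "_up")])
    up_b <- split(de$gene[de$de & de$direction == paste0(config$contrast[2], "_up")],
                  de$cell_type[de$de & de$direction == paste0(config$contrast[2], "_up")])
    pin <- grep("pinealocyte", unique(de$cell_type), value = TRUE)
    if (length(pin) >= 2) {
      sets <- c(stats::setNames(up_a[pin], paste0(pin, ".", config$contrast[1], "_up")),
                stats::setNames(up_b[pin], paste0(pin, ".", config$contrast[2], "_up")))
      sets <- sets[!vapply(sets, is.null, logical(1))]
      if (length(sets) >= 2) overlaps <- de_overlap(sets)
    }
  }

  groups <- subtype_group_ratios(samples, annotation, gene_groups, config)

  summary <- list(
    n_cells_input = ncol(counts),
    n_cells_retained = nrow(annotation),
    proportions = proportions,
    de_counts = if (!is.null(de))
      dplyr::count(de[de$de, ], .data$cell_type, .data$direction),
    group_ratios = groups$ratios
  )
  structure(list(samples = samples, annotation = annotation,
                 proportions = proportions, de = de, overlaps = overlaps,
                 groups = groups, config = config, sim = sim,
                 summary = summary),
            class = "pineal_run")
}

# Pooled alpha/beta pinealocyte group comparisons, per condition, using
# the jointly QC'd per-condition normalized matrices.  OxPhos and
# ribosomal memberships are data-driven: candidates are filtered by the
# subtype DE contrast (p < 0.05, fold >= 2) and ranked by effect size
# (top 8 / top 20), as for the published pooled groups.
subtype_group_ratios <- function(samples, annotation, gene_groups, config) {
  if (is.null(gene_groups)) return(list(ratios = NULL, genes = NULL))
  ratios <- purrr::map_dfr(samples, function(s) {
    ann <- annotation[annotation$condition == s$condition, ]
    a <- ann$cell_id[ann$label == "pinealocyte_alpha"]
    b <- ann$cell_id[ann$label == "pinealocyte_beta"]
    if (length(a) < 3 || length(b) < 3) return(NULL)
    de_ab <- de_between(s$norm, a, b, config$criteria)
    attr(de_ab, "criteria") <- config$criteria
    sel <- list(
      asmt = gene_groups$asmt,
      oxphos = select_group_genes(de_ab, gene_groups$oxphos, top_n = 8),
      ribosomal = select_group_genes(de_ab, gene_groups$ribosomal, top_n = 20),
      ggamma = gene_groups$ggamma
    )
    purrr::imap_dfr(sel, function(genes, nm_grp) {
      if (length(genes) == 0) return(NULL)
      gc <- group_comparison(s$norm, a, b, genes,
                             pseudocount = config$criteria$pseudocount)
      dplyr::mutate(gc, group = nm_grp, condition = s$condition,
                    ratio_alpha_over_beta = .data$ratio, .before = 1)
    })
  })
  list(ratios = ratios)
}

#' @export
print.pineal_run <- function(x, ...) {
  cat("<pineal_run> ", x$summary$n_cells_retained, "/",
      x$summary$n_cells_input, " cells retained, ",
      length(x$samples), " condition(s)\n", sep = "")
  print(x$proportions)
  invisible(x)
}

#' Human-readable run report
#'
#' Renders the proportion table, per-type DE counts, the pinealocyte
#' subtype overlap table and the pooled group-ratio table as text.
#'
#' @param run A `pineal_run`.
#' @param file Optional path; when given the report is also written
#'   there.
#' @return The report lines, invisibly.
#' @export
report <- function(run, file = NULL) {
  stopifnot(inherits(run, "pineal_run"))
  fmt_tbl <- function(df) utils::capture.output(print(as.data.frame(df),
                                                      row.names = FALSE))
  lines <- c(
    "== Cell-type proportions ==",
    fmt_tbl(run$proportions),
    "",
    "== Differentially expressed genes by cell type ==",
    if (!is.null(run$de) && any(run$de$de))
      fmt_tbl(dplyr::count(run$de[run$de$de, ], .data$cell_type, .data$direction))
    else "  (no DE genes called)",
    "",
    "== Pinealocyte subtype DE overlap ==",
    if (!is.null(run$overlaps)) fmt_tbl(run$overlaps) else "  (not computed)",
    "",
    "== Pooled gene-group ratios (alpha over beta pinealocytes) ==",
    if (!is.null(run$groups$ratios) && nrow(run$groups$ratios))
      fmt_tbl(run$groups$ratios) else "  (not computed)"
  )
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Subcluster an annotated cell subset
#'
#' Re-runs variable-gene selection, PCA, SNN and community detection on
#' a subset of cells of one condition (e.g. all astrocytes) to resolve
#' subtypes within a family.
#'
#' @param counts Full count matrix.
#' @param cell_ids Cells to subcluster.
#' @param config A [pipeline_config()]; `n_pcs`'s first entry, `knn_k`
#'   (capped at a third of the subset) and `resolution` are used.
#' @param consolidate_clusters Apply the zero-DE-gene merge rule
#'   (default TRUE).
#' @return A `cluster_model` for the subset.
#' @export
subcluster_cells <- function(counts, cell_ids, config = pipeline_config(),
                             consolidate_clusters = TRUE) {
  sub <- counts[, intersect(colnames(counts), cell_ids), drop = FALSE]
  sub <- sub[Matrix::rowSums(sub > 0) >= config$min_cells, , drop = FALSE]
  nm <- normalize_per_cell(sub, config$scale_total)
  lg <- log_transform(nm)
  hvg <- select_hvg(lg, x_low = config$hvg_cutoffs$x_low,
                    x_high = config$hvg_cutoffs$x_high, y = config$hvg_cutoffs$y)
  genes <- hvg_genes(hvg)
  if (length(genes) < 10) genes <- hvg$gene[order(-hvg$z)][1:50]
  k <- min(config$n_pcs[[1]], length(genes) - 1, ncol(sub) - 1)
  pca <- run_pca(scale_genes(lg, genes), k = k)
  # rare subpopulations need neighborhoods smaller than themselves; the
  # usual sqrt(n) heuristic caps the subset kNN size
  knn_k <- max(5, min(config$knn_k, ceiling(sqrt(ncol(sub)))))
  snn <- build_snn(pca, knn_k = knn_k, prune = config$prune)
  raw <- find_communities(snn, resolution = config$resolution, seed = config$seed)
  if (consolidate_clusters) {
    consolidate(nm, raw, criteria = config$criteria)
  } else {
    structure(list(
      cells = tibble::tibble(cell_id = names(raw), raw_cluster = unname(raw),
                             cluster = unname(raw), excluded = FALSE),
      map = tibble::tibble(raw_cluster = sort(unique(raw)),
                           cluster = sort(unique(raw))),
      criteria = config$criteria
    ), class = "cluster_model")
  }
}
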