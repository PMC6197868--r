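# The condition-contrast procedure: per-cell-type testing with the
# pseudocounted fold change, Cohen's d, detection fractions and the
# four-part composite decision rule; gene-group pooled comparisons;
# ambient-gene exclusion; DE-set overlap counting.

#' Thresholds of the composite differential-expression rule
#'
#' A gene is called DE when all four criteria hold: (adjusted) Wilcoxon
#' p below `p_threshold`, detected in at least `min_detection` of cells
#' in either group, direction-free fold change at least `fc_threshold`,
#' and `|Cohen's d|` at least `d_threshold`.  Fold/effect thresholds are
#' inclusive; the p threshold is strict.
#'
#' @param p_threshold P-value threshold (default 0.01, applied to the
#'   FDR-adjusted p when `p_is_adjusted`).
#' @param min_detection Minimum detection fraction in either group.
#' @param fc_threshold Minimum direction-free fold change.
#' @param d_threshold Minimum `|d|`.
#' @param pseudocount Pseudocount of the fold-change ratio.
#' @param fdr_alpha Nominal FDR level recorded with the result.
#' @param p_is_adjusted Apply `p_threshold` to the BH-adjusted p (the
#'   default) rather than the raw p.
#' @return A `de_criteria` list.
#' @export
de_criteria <- function(p_threshold = 0.01, min_detection = 0.15,
                        fc_threshold = 2.0, d_threshold = 0.35,
                        pseudocount = 0.01, fdr_alpha = 0.05,
                        p_is_adjusted = TRUE) {
  stopifnot(p_threshold > 0, min_detection >= 0, fc_threshold > 0,
            d_threshold >= 0, pseudocount > 0)
  structure(list(p_threshold = p_threshold, min_detection = min_detection,
                 fc_threshold = fc_threshold, d_threshold = d_threshold,
                 pseudocount = pseudocount, fdr_alpha = fdr_alpha,
                 p_is_adjusted = p_is_adjusted), class = "de_criteria")
}

# Per-gene mean, sd (n-1), size and detection fraction for a cell subset
# of a per-total normalized matrix.
group_stats <- function(nm, cells) {
  v <- nm$values[, cells, drop = FALSE]
  n <- ncol(v)
  mu <- Matrix::rowSums(v) / n
  ex2 <- Matrix::rowSums(v^2) / n
  var <- if (n > 1) pmax(0, (ex2 - mu^2) * n / (n - 1)) else rep(0, nrow(v))
  tibble::tibble(gene = rownames(v), mean = unname(mu), sd = unname(sqrt(var)),
                 n = n, detection = unname(Matrix::rowSums(v > 0) / n))
}

# Wilcoxon p per gene for cells_a vs cells_b; exact enumeration when the
# pooled group is small and tie-free, normal approximation otherwise.
rank_sum_p <- function(nm, cells_a, cells_b, genes = NULL) {
  va <- as.matrix(nm$values[genes %||% TRUE, cells_a, drop = FALSE])
  vb <- as.matrix(nm$values[genes %||% TRUE, cells_b, drop = FALSE])
  vapply(seq_len(nrow(va)), function(i)
    wilcoxon_rank_sum(va[i, ], vb[i, ])$p.value, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full composite evaluation between two cell sets (also drives cluster
# consolidation).  P-values are only computed where they can change the
# call: fold/effect/detection are cheap vectorized filters, and a raw p
# bounds the BH-adjusted p from below.
de_between <- function(nm, cells_a, cells_b, criteria = de_criteria(),
                       exclude = character()) {
  stopifnot(inherits(nm, "norm_matrix"), nm$scheme == "per_total")
  keep <- setdiff(rownames(nm$values), exclude)
  sa <- group_stats(nm, cells_a); sb <- group_stats(nm, cells_b)
  ok <- match(keep, sa$gene)
  sa <- sa[ok, ]; sb <- sb[ok, ]
  ratio <- fold_change(sa$mean, sb$mean, criteria$pseudocount)
  fold <- pmax(ratio, 1 / ratio)
  d <- cohens_d(sa$mean, sa$sd, sa$n[1], sb$mean, sb$sd, sb$n[1])
  pass_det <- pmax(sa$detection, sb$detection) >= criteria$min_detection
  pass_fold <- fold >= criteria$fc_threshold
  pass_d <- abs(d) >= criteria$d_threshold
  cand <- pass_det & pass_fold & pass_d

  p <- rep(NA_real_, length(keep))
  if (any(cand)) {
    p[cand] <- rank_sum_p(nm, cells_a, cells_b, keep[cand])
    # raw p is a lower bound on adjusted p: candidates failing it can
    # never pass, so the remaining genes' p-values are only needed when
    # some candidate might survive adjustment
    if (any(p[cand] < criteria$p_threshold) || !criteria$p_is_adjusted) {
      if (criteria$p_is_adjusted) p[!cand] <- rank_sum_p(nm, cells_a, cells_b,
                                                         keep[!cand])
    } else cand[] <- FALSE
  }
  p_adj <- if (all(is.na(p))) p else bh_adjust(p)
  p_use <- if (criteria$p_is_adjusted) p_adj else p
  de <- cand & !is.na(p_use) & p_use < criteria$p_threshold
  tibble::tibble(gene = keep,
                 mean_a = sa$mean, mean_b = sb$mean,
                 sd_a = sa$sd, sd_b = sb$sd,
                 n_a = sa$n[1], n_b = sb$n[1],
                 detection_a = sa$detection, detection_b = sb$detection,
                 ratio = ratio, fold = fold, d = d,
                 p = p, p_adj = p_adj,
                 pass_detection = pass_det, pass_fold = pass_fold,
                 pass_d = pass_d,
                 pass_p = !is.na(p_use) & p_use < criteria$p_threshold,
                 de = de,
                 direction = ifelse(sa$mean >= sb$mean, "a_up", "b_up"))
}

# Decision-only variant: does ANY gene pass the composite rule between
# the two cell sets?  Exploits p_adj <= p * m (step-up with rank >= 1)
# and p_adj >= p to avoid the full p-vector in clear-cut cases.
any_de_between <- function(nm, cells_a, cells_b, criteria = de_criteria()) {
  m <- nrow(nm$values)
  sa <- group_stats(nm, cells_a); sb <- group_stats(nm, cells_b)
  ratio <- fold_change(sa$mean, sb$mean, criteria$pseudocount)
  fold <- pmax(ratio, 1 / ratio)
  d <- cohens_d(sa$mean, sa$sd, sa$n[1], sb$mean, sb$sd, sb$n[1])
  cand <- pmax(sa$detection, sb$detection) >= criteria$min_detection &
    fold >= criteria$fc_threshold & abs(d) >= criteria$d_threshold
  if (!any(cand)) return(FALSE)
  p_cand <- rank_sum_p(nm, cells_a, cells_b, sa$gene[cand])
  if (!criteria$p_is_adjusted) return(any(p_cand < criteria$p_threshold))
  if (all(p_cand >= criteria$p_threshold)) return(FALSE)
  if (any(p_cand * m < criteria$p_threshold)) return(TRUE)
  any(de_between(nm, cells_a, cells_b, criteria)$de)
}

#' Condition-contrast differential expression within cell types
#'
#' For each cell type, compares the two conditions with the Wilcoxon
#' rank-sum test over all genes (no pre-filter), adjusts p-values by
#' Benjamini-Hochberg within the cell type, and applies the composite
#' decision rule of [de_criteria()].  Ambient-contamination genes listed
#' in `exclusions` for a type are removed before adjustment.
#'
#' @param nm Per-total normalized matrix ([normalize_per_cell()]).
#' @param annotation Tibble with `cell_id`, `label` and `condition`
#'   columns (e.g. the `cells` table of [annotate_clusters()] joined
#'   with conditions).
#' @param cell_types Types to test (default: all labels with at least
#'   `min_cells` cells in both conditions).
#' @param contrast Length-2 character: condition levels (a, b); fold
#'   change and direction are a-over-b (night over day in the default
#'   day/night design).
#' @param criteria A [de_criteria()].
#' @param exclusions Named list: type -> genes to drop (see
#'   [ambient_exclusion()]).
#' @param min_cells Minimum cells per type and condition (default 3).
#' @return Tibble (class `pineal_de`) with per-gene group statistics,
#'   fold change, Cohen's d, raw/adjusted p, per-criterion flags, the DE
#'   call and its direction (`"a_up"` means higher in `contrast[1]`).
#' @export
de_test <- function(nm, annotation, cell_types = NULL,
                    contrast = c("night", "day"), criteria = de_criteria(),
                    exclusions = list(), min_cells = 3) {
  stopifnot(all(c("cell_id", "label", "condition") %in% names(annotation)))
  ann <- annotation[annotation$condition %in% contrast &
                      annotation$cell_id %in% colnames(nm$values), ]
  types <- cell_types %||% sort(unique(ann$label))
  out <- purrr::map(types, function(ty) {
    a <- ann$cell_id[ann$label == ty & ann$condition == contrast[1]]
    b <- ann$cell_id[ann$label == ty & ann$condition == contrast[2]]
    if (length(a) < min_cells || length(b) < min_cells) {
      warning("skipping '", ty, "': fewer than ", min_cells,
              " cells in one condition", call. = FALSE)
      return(NULL)
    }
    res <- de_between(nm, a, b, criteria, exclude = exclusions[[ty]] %||% character())
    dplyr::mutate(res, cell_type = ty, .before = 1)
  })
  res <- dplyr::bind_rows(out)
  res$direction <- ifelse(res$direction == "a_up",
                          paste0(contrast[1], "_up"), paste0(contrast[2], "_up"))
  attr(res, "contrast") <- contrast
  attr(res, "criteria") <- criteria
  class(res) <- c("pineal_de", class(res))
  res
}

#' Ambient-contamination gene exclusions per cell type
#'
#' Highly expressed pinealocyte transcripts (by default Aanat) leak into
#' all droplets as ambient mRNA and can make non-pinealocytes appear to
#' regulate them; they are excluded from the DE analysis of every
#' non-pinealocyte type, and never from pinealocytes.
#'
#' @param cell_types Character vector of cell-type labels.
#' @param genes Genes to exclude (default `"Aanat"`; empty disables).
#' @param pinealocyte_pattern Regular expression identifying pinealocyte
#'   labels (exempt from exclusion).
#' @return Named list: type -> character vector of excluded genes.
#' @export
ambient_exclusion <- function(cell_types, genes = "Aanat",
                              pinealocyte_pattern = "pinealocyte") {
  out <- lapply(cell_types, function(ty)
    if (grepl(pinealocyte_pattern, ty)) character() else genes)
  stats::setNames(out, cell_types)
}

#' Pooled gene-group comparison between two cell populations
#'
#' Sums normalized counts over the group's genes within each cell, then
#' compares the per-cell pooled values between the populations: reports
#' each population's mean, the pseudocounted ratio of means (a over b)
#' and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param nm Per-total normalized matrix.
#' @param cells_a,cells_b Cell identifier vectors.
#' @param genes Gene group (members absent from the matrix are dropped
#'   with a warning).
#' @param pseudocount Pseudocount for the ratio.
#' @return One-row tibble: `n_genes`, `mean_a`, `mean_b`, `ratio`, `p`.
#' @export
group_comparison <- function(nm, cells_a, cells_b, genes, pseudocount = 0.01) {
  stopifnot(inherits(nm, "norm_matrix"), nm$scheme == "per_total")
  present <- intersect(genes, rownames(nm$values))
  if (length(present) == 0) stop("no group genes present in the matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " group genes absent, scoring over ",
            length(present), call. = FALSE)
  pooled <- function(cells)
    Matrix::colSums(nm$values[present, cells, drop = FALSE])
  xa <- pooled(cells_a); xb <- pooled(cells_b)
  tibble::tibble(n_genes = length(present),
                 mean_a = mean(xa), mean_b = mean(xb),
                 ratio = fold_change(mean(xa), mean(xb), pseudocount),
                 p = wilcoxon_rank_sum(xa, xb)$p.value)
}

#' Select a data-driven gene group from a DE table
#'
#' Mirrors the construction of the pooled OxPhos/ribosomal groups:
#' among `candidates` (a functional annotation, e.g. all ribosomal
#' protein genes), keep genes passing `p < p_threshold` and direction-free
#' fold change >= `fc_threshold` in `de_tbl`, rank by `|d|` and take the
#' top `top_n`.
#'
#' @param de_tbl A [de_test()] / `de_between` style tibble.
#' @param candidates Candidate gene identifiers.
#' @param p_threshold,fc_threshold Selection thresholds (defaults 0.05
#'   and 2.0).
#' @param top_n Maximum number of genes (default all passing).
#' @return Character vector of selected genes.
#' @export
select_group_genes <- function(de_tbl, candidates, p_threshold = 0.05,
                               fc_threshold = 2.0, top_n = Inf) {
  x <- de_tbl[de_tbl$gene %in% candidates, ]
  p_use <- if (!is.null(attr(de_tbl, "criteria")) &&
               attr(de_tbl, "criteria")$p_is_adjusted) x$p_adj else x$p
  p_use[is.na(p_use)] <- 1
  x <- x[p_use < p_threshold & x$fold >= fc_threshold, ]
  x <- x[order(-abs(x$d)), ]
  utils::head(x$gene, top_n)
}

#' Overlap table of named DE gene sets
#'
#' All pairwise intersection and difference cardinalities plus the full
#' intersection; the percentage overlap is `|A n B| / |A|`, i.e. the
#' share of set A also present in set B.
#'
#' @param sets Named list of at least two character vectors.
#' @return Tibble with one row per ordered pair: `set_a`, `set_b`,
#'   `n_a`, `n_b`, `n_common`, `n_a_only`, `pct_a_in_b`.  The size of the
#'   intersection of all sets is stored in attribute `n_all`.
#' @export
de_overlap <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  pairs <- tidyr::expand_grid(set_a = names(sets), set_b = names(sets)) |>
    dplyr::filter(.data$set_a != .data$set_b)
  out <- purrr::pmap_dfr(pairs, function(set_a, set_b) {
    a <- sets[[set_a]]; b <- sets[[set_b]]
    common <- length(intersect(a, b))
    tibble::tibble(set_a = set_a, set_b = set_b,
                   n_a = length(a), n_b = length(b), n_common = common,
                   n_a_only = length(a) - common,
                   pct_a_in_b = if (length(a)) 100 * common / length(a) else NA_real_)
  })
  attr(out, "n_all") <- length(Reduce(intersect, sets))
  out
}
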