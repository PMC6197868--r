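# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression table
#'
#' @param x A `pineal_de` tibble from [de_test()].
#' @param ... Unused.
#' @return A plain tibble of the key columns, one row per gene and cell
#'   type.
#' @export
tidy.pineal_de <- function(x, ...) {
  tibble::as_tibble(x)[, c("cell_type", "gene", "mean_a", "mean_b",
                           "detection_a", "detection_b", "fold", "d",
                           "p", "p_adj", "de", "direction")]
}

#' One-row DE summary
#'
#' @param x A `pineal_de` tibble.
#' @param ... Unused.
#' @return Tibble with genes tested, DE calls and calls per direction.
#' @export
glance.pineal_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  tibble::tibble(
    n_tests = nrow(x),
    n_cell_types = length(unique(x$cell_type)),
    n_de = sum(x$de),
    n_up_a = sum(x$de & x$direction == paste0(ct[1], "_up")),
    n_up_b = sum(x$de & x$direction == paste0(ct[2], "_up"))
  )
}

#' Tidy a cluster model
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return Per-cell tibble of raw/final cluster and exclusion flag.
#' @export
tidy.cluster_model <- function(x, ...) tibble::as_tibble(x$cells)

#' One-row cluster-model summary
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @export
glance.cluster_model <- function(x, ...) {
  keep <- !x$cells$excluded
  tibble::tibble(n_cells = nrow(x$cells),
                 n_raw = length(unique(x$cells$raw_cluster)),
                 n_final = length(unique(x$cells$cluster[keep])),
                 n_excluded = sum(!keep))
}

#' One-row pipeline-run summary
#' @param x A `pineal_run`.
#' @param ... Unused.
#' @export
glance.pineal_run <- function(x, ...) {
  tibble::tibble(
    n_cells_input = x$summary$n_cells_input,
    n_cells_retained = x$summary$n_cells_retained,
    n_types = nrow(x$proportions),
    pct_pinealocyte = sum(x$proportions$pct[x$proportions$family == "pinealocyte"]),
    n_de = if (is.null(x$de)) NA_integer_ else sum(x$de$de)
  )
}

#' Mean-dispersion plot of variable-gene selection
#'
#' @param object An `hvg_selection`.
#' @param ... Unused.
#' @return A ggplot: binned dispersion z-score against the mean
#'   statistic, selected genes highlighted.
#' @export
autoplot.hvg_selection <- function(object, ...) {
  cut <- attr(object, "cutoffs")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_stat, y = .data$z,
                                       colour = .data$selected)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(cut$x_low, cut$x_high), linetype = 3) +
    ggplot2::geom_hline(yintercept = cut$y, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "ln(mean normalized counts + 1)",
                  y = "dispersion z-score (within mean bin)",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Fold-change / effect-size plot of a DE table
#'
#' @param object A `pineal_de` tibble.
#' @param ... Unused.
#' @return A ggplot of log2 direction-free fold change against `|d|`,
#'   DE calls highlighted, faceted by cell type.
#' @export
autoplot.pineal_de <- function(object, ...) {
  crit <- attr(object, "criteria")
  df <- tibble::as_tibble(object)
  df$d_abs <- pmin(abs(df$d), 5)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold), y = .data$d_abs,
                                   colour = .data$de)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = log2(crit$fc_threshold), linetype = 3) +
    ggplot2::geom_hline(yintercept = crit$d_threshold, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::labs(x = "log2 fold change (direction-free)", y = "|Cohen's d|",
                  colour = "DE") +
    ggplot2::theme_minimal()
}

#' Cell-type proportion bar chart
#'
#' @param run A `pineal_run` (or a [cluster_proportions()] tibble).
#' @return A ggplot of per-type percentages.
#' @export
plot_proportions <- function(run) {
  df <- if (inherits(run, "pineal_run")) run$proportions else run
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$n),
                                   y = .data$pct, fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of cells", fill = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cluster dendrogram plot
#'
#' @param tree Result of [cluster_tree()].
#' @param labels Optional named labels (cluster -> text).
#' @return Invisibly, the `phylo` object (plotted as a side effect).
#' @export
plot_cluster_tree <- function(tree, labels = NULL) {
  phy <- tree$phylo
  if (!is.null(labels))
    phy$tip.label <- ifelse(phy$tip.label %in% names(labels),
                            labels[phy$tip.label], phy$tip.label)
  ape::plot.phylo(phy)
  invisible(phy)
}
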