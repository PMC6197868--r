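# Synthetic pineal-gland scRNA-seq generator.
#
# Cells are drawn from nine transcriptomic types (two pinealocyte, three
# astrocyte and two microglia subtypes, VLMCs, endothelial cells) at the
# proportions reported for the dissociated rat gland.  Alpha-pinealocytes
# differ from beta-pinealocytes by four planted modules (Asmt up 3.4x,
# OxPhos up 2.3x, ribosomal down 8.2x, G-protein gamma-subunits down
# 5.4x).  Every cell receives a uniform low-level admixture of the pooled
# pinealocyte profile, emulating ambient mRNA from lysed pinealocytes.

PINEAL_FAMILY_MARKERS <- c("Tph1", "Sag", "Crx", "Rom1", "Pde6c")
ASTRO_FAMILY_MARKERS  <- c("Aldh1a1", "S100b", "Tnfrsf21", "Penk", "Apoe", "Esm1")
ASTRO_SUBTYPE_MARKERS <- list(
  astrocyte_alpha = c("Sparcl1", "Mdfic", "Efemp1", "Oat", "Gad2"),
  astrocyte_beta  = c("Slc22a8", "Shox2", "Lgals1", "Mlf1"),
  astrocyte_gamma = c("Nkain4", "Aqp4", "Slc1a3", "Bcan", "Gfap")
)
MICRO_FAMILY_MARKERS  <- c("Aif1", "Lyz2", "Cx3cr1", "Csf1r")
MICRO_SUBTYPE_MARKERS <- list(
  microglia_alpha = c("C1qa", "C1qb", "C1qc"),
  microglia_beta  = c("RT1-Da", "RT1-Db1", "RT1-Ba")
)
VLMC_MARKERS <- c("Lum", "Dcn", "Col1a1", "Gjb2", "Col1a2")
ENDO_MARKERS <- c("Vwf", "Esam", "Cdh5", "Ecmn", "Cldn5")
OXPHOS_GENES <- c("Ndufa1", "Ndufa4", "Ndufb2", "Cox4i1", "Cox6a1", "Cox7b",
                  "Atp5e", "Uqcrb")
RIBO_GENES   <- c("Rpl3", "Rpl4", "Rpl5", "Rpl6", "Rpl7", "Rpl8", "Rpl10",
                  "Rpl11", "Rpl12", "Rpl13", "Rps2", "Rps3", "Rps4x", "Rps5",
                  "Rps6", "Rps7", "Rps8", "Rps9", "Rps10", "Rps11")
GGAMMA_GENES <- c("Gngt1", "Gngt2", "Gng10", "Gng13")

#' Construct a validated simulation configuration
#'
#' Low-level constructor used by [default_pineal_config()] and by tests that
#' need bespoke populations.  `profiles` holds one relative expression
#' column per cell type; each column is renormalized to sum to one.
#'
#' @param cell_types Tibble with columns `name`, `family`, `subtype`,
#'   `proportion`.  Proportions must sum to 1 within 1e-9.
#' @param profiles Numeric matrix, genes x cell types, non-negative, with
#'   row names (gene identifiers) and column names matching
#'   `cell_types$name`.
#' @param condition_effects Tibble with columns `gene`, `target_type`,
#'   `fold` (positive multiplier applied in the night/drug condition).
#' @param n_cells Number of cells to draw.
#' @param ambient_fraction Fraction in `[0, 1)` of each cell's expected
#'   counts contributed by the pooled pinealocyte profile.
#' @param depth_log_mean,depth_log_sd Meanlog/sdlog of the lognormal
#'   per-cell library-size distribution.
#' @param doublet_rate Fraction of droplets containing two cells, in
#'   `[0, 0.05]`.
#' @param night_fraction Fraction of cells assigned to the night (or drug)
#'   condition.
#' @param dispersion Optional per-gene gamma overdispersion; `0` gives
#'   pure Poisson noise conditional on the rate.
#' @param programs Named list of gene-identifier vectors recording planted
#'   gene programs (kept as ground truth).
#' @param seed Integer seed; identical config plus seed reproduces the
#'   dataset exactly.
#' @return A `pineal_config` object.
#' @export
pineal_config <- function(cell_types, profiles, condition_effects = NULL,
                          n_cells = 5000, ambient_fraction = 0.02,
                          depth_log_mean = log(6000), depth_log_sd = 0.35,
                          doublet_rate = 0.015, night_fraction = 0.5,
                          dispersion = 0, programs = list(), seed = 1L) {
  cell_types <- tibble::as_tibble(cell_types)
  stopifnot(all(c("name", "family", "subtype", "proportion") %in% names(cell_types)))
  if (abs(sum(cell_types$proportion) - 1) > 1e-9)
    stop("cell type proportions must sum to 1 (got ",
         format(sum(cell_types$proportion), digits = 12), ")")
  if (any(cell_types$proportion < 0)) stop("proportions must be non-negative")
  if (anyDuplicated(cell_types$name)) stop("cell type names must be unique")
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) stop("profiles must carry gene row names")
  if (!identical(sort(colnames(profiles)), sort(cell_types$name)))
    stop("profile columns must match cell type names")
  profiles <- profiles[, cell_types$name, drop = FALSE]
  if (any(profiles < 0)) stop("profile entries must be >= 0")
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  if (!is.null(condition_effects)) {
    condition_effects <- tibble::as_tibble(condition_effects)
    stopifnot(all(c("gene", "target_type", "fold") %in% names(condition_effects)))
    if (any(condition_effects$fold <= 0)) stop("condition folds must be > 0")
    bad <- setdiff(condition_effects$gene, rownames(profiles))
    if (length(bad)) stop("unknown condition-effect genes: ", paste(bad, collapse = ", "))
  } else {
    condition_effects <- tibble::tibble(gene = character(), target_type = character(),
                                        fold = numeric())
  }
  stopifnot(n_cells >= 1, ambient_fraction >= 0, ambient_fraction < 1,
            depth_log_sd >= 0, doublet_rate >= 0, doublet_rate <= 0.05,
            night_fraction >= 0, night_fraction <= 1, dispersion >= 0)
  rare <- which.min(cell_types$proportion)
  if (n_cells * cell_types$proportion[rare] < 2)
    stop("n_cells = ", n_cells, " is too small to represent '",
         cell_types$name[rare], "' (proportion ",
         signif(cell_types$proportion[rare], 3), ") at >= 2 expected cells; need n_cells >= ",
         ceiling(2 / cell_types$proportion[rare]))
  structure(list(
    n_cells = as.integer(n_cells), n_genes = nrow(profiles),
    cell_types = cell_types, profiles = profiles,
    condition_effects = condition_effects,
    ambient_fraction = ambient_fraction,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    doublet_rate = doublet_rate, night_fraction = night_fraction,
    dispersion = dispersion, programs = programs, seed = as.integer(seed)
  ), class = "pineal_config")
}

#' @export
print.pineal_config <- function(x, ...) {
  cat("<pineal_config> ", x$n_cells, " cells, ", x$n_genes, " genes, ",
      nrow(x$cell_types), " cell types, seed ", x$seed, "\n", sep = "")
  print(x$cell_types)
  invisible(x)
}

#' Default nine-type pineal gland configuration
#'
#' Builds the study configuration: pinealocytes 90% of cells split 5/95
#' into alpha/beta subtypes, astrocytes 7% split 85/7/8, microglia 1%
#' split 64/36, VLMCs 2% and endothelial cells 0.1% (proportions
#' renormalized to sum to one).  Alpha-pinealocytes carry the four planted
#' subtype modules relative to beta-pinealocytes: Asmt x3.4, an
#' eight-gene OxPhos program x2.3, a twenty-gene ribosomal program
#' x(1/8.2) and the four G-protein gamma-subunit genes x(1/5.4).  Each
#' non-pinealocyte type has at least three exclusive marker genes at
#' enrichment >= 8.  A night condition-effect set touches mostly
#' pinealocytes (400 genes at folds 2-8 in both directions, plus Aanat
#' x8), with 80 genes in alpha-astrocytes and 10 in alpha-microglia.
#'
#' @param n_cells Number of cells (>= ~2100 so the rarest type, 0.1%
#'   endothelial cells, is expected at >= 2 cells).
#' @param seed Integer seed controlling both the configuration draws and,
#'   by default, the simulation.
#' @param n_genes Size of the gene universe (planted programs occupy ~80).
#' @inheritParams pineal_config
#' @return A `pineal_config`.
#' @export
default_pineal_config <- function(n_cells = 5000, seed = 1L, n_genes = 2000,
                                  ambient_fraction = 0.02,
                                  depth_log_mean = log(6000),
                                  depth_log_sd = 0.35,
                                  doublet_rate = 0.015,
                                  night_fraction = 0.5,
                                  dispersion = 0) {
  raw <- c(pinealocyte_alpha = 90 * 0.05, pinealocyte_beta = 90 * 0.95,
           astrocyte_alpha = 7 * 0.85, astrocyte_beta = 7 * 0.07,
           astrocyte_gamma = 7 * 0.08,
           microglia_alpha = 1 * 0.64, microglia_beta = 1 * 0.36,
           vlmc = 2, endothelial = 0.1)
  prop <- raw / sum(raw)
  cell_types <- tibble::tibble(
    name = names(prop),
    family = sub("_(alpha|beta|gamma)$", "", names(prop)),
    subtype = ifelse(grepl("_(alpha|beta|gamma)$", names(prop)),
                     sub("^.*_", "", names(prop)), NA_character_),
    proportion = unname(prop)
  )

  named_genes <- unique(c(
    PINEAL_FAMILY_MARKERS, "Asmt", "Aanat", GGAMMA_GENES,
    ASTRO_FAMILY_MARKERS, unlist(ASTRO_SUBTYPE_MARKERS, use.names = FALSE),
    MICRO_FAMILY_MARKERS, unlist(MICRO_SUBTYPE_MARKERS, use.names = FALSE),
    VLMC_MARKERS, ENDO_MARKERS, OXPHOS_GENES, RIBO_GENES
  ))
  n_generic <- n_genes - length(named_genes)
  if (n_generic < 200)
    stop("n_genes too small: need >= ", length(named_genes) + 200, " genes")
  genes <- c(named_genes, sprintf("G%04d", seq_len(n_generic)))

  withr::local_seed(seed)

  # Baseline relative expression shared by all types: cell-type markers
  # sit near-absent (~0.1 expected counts per cell) outside their type
  # and are strongly enriched within it, as for real marker genes; the
  # OxPhos/ribosomal programs are expressed everywhere; the generic
  # background gets lognormal masses.
  base <- numeric(n_genes); names(base) <- genes
  base[named_genes] <- 2e-5
  base[RIBO_GENES] <- 2e-3
  base[OXPHOS_GENES] <- 2e-3
  named_mass <- sum(base)
  w <- stats::rlnorm(n_generic, meanlog = 0, sdlog = 1.25)
  base[n_genes - n_generic + seq_len(n_generic)] <- w / sum(w) * (1 - named_mass)

  enrich <- function(profile, genes, mult) {
    profile[genes] <- profile[genes] * mult
    profile
  }
  fam_enr <- 250   # marker mass ~0.5% of the library in the own type
  sub_enr <- 60
  pineal_genes <- c(PINEAL_FAMILY_MARKERS, "Asmt", GGAMMA_GENES)
  beta_p <- enrich(base, pineal_genes, fam_enr)
  beta_p <- enrich(beta_p, "Aanat", 100)
  alpha_p <- enrich(beta_p, "Asmt", 3.4)
  alpha_p <- enrich(alpha_p, OXPHOS_GENES, 2.3)
  alpha_p <- enrich(alpha_p, RIBO_GENES, 1 / 8.2)
  alpha_p <- enrich(alpha_p, GGAMMA_GENES, 1 / 5.4)
  astro <- enrich(base, ASTRO_FAMILY_MARKERS, fam_enr)
  micro <- enrich(base, MICRO_FAMILY_MARKERS, fam_enr)
  prof <- cbind(
    pinealocyte_alpha = alpha_p, pinealocyte_beta = beta_p,
    astrocyte_alpha = enrich(astro, ASTRO_SUBTYPE_MARKERS$astrocyte_alpha, sub_enr),
    astrocyte_beta  = enrich(astro, ASTRO_SUBTYPE_MARKERS$astrocyte_beta, sub_enr),
    astrocyte_gamma = enrich(astro, ASTRO_SUBTYPE_MARKERS$astrocyte_gamma, sub_enr),
    microglia_alpha = enrich(micro, MICRO_SUBTYPE_MARKERS$microglia_alpha, sub_enr),
    microglia_beta  = enrich(micro, MICRO_SUBTYPE_MARKERS$microglia_beta, sub_enr),
    vlmc = enrich(base, VLMC_MARKERS, fam_enr),
    endothelial = enrich(base, ENDO_MARKERS, fam_enr)
  )
  rownames(prof) <- genes

  # Night condition effects: drawn from the low-mass half of the generic
  # background so the total transcript mass shift stays small.
  generic <- genes[(length(named_genes) + 1):n_genes]
  low_mass <- generic[base[generic] <= stats::median(base[generic])]
  de_pineal <- sample(low_mass, 400)
  rest <- setdiff(low_mass, de_pineal)
  de_astro <- sample(rest, 80)
  de_micro <- sample(setdiff(rest, de_astro), 10)
  fold_updown <- function(n, lo, hi) {
    up <- stats::runif(ceiling(n / 2), lo, hi)
    dn <- 1 / stats::runif(floor(n / 2), lo, hi)
    sample(c(up, dn))
  }
  eff <- dplyr::bind_rows(
    tidyr::expand_grid(gene = c(de_pineal, "Aanat"),
                       target_type = c("pinealocyte_alpha", "pinealocyte_beta")) |>
      dplyr::mutate(fold = rep(c(fold_updown(400, 2, 8), 8), each = 2L)),
    tibble::tibble(gene = de_astro, target_type = "astrocyte_alpha",
                   fold = fold_updown(80, 2, 6)),
    tibble::tibble(gene = de_micro, target_type = "microglia_alpha",
                   fold = fold_updown(10, 2, 4))
  )

  programs <- c(
    list(pinealocyte = pineal_genes, astrocyte = ASTRO_FAMILY_MARKERS,
         microglia = MICRO_FAMILY_MARKERS, vlmc = VLMC_MARKERS,
         endothelial = ENDO_MARKERS,
         asmt = "Asmt", oxphos = OXPHOS_GENES, ribosomal = RIBO_GENES,
         ggamma = GGAMMA_GENES),
    ASTRO_SUBTYPE_MARKERS, MICRO_SUBTYPE_MARKERS
  )

  pineal_config(cell_types, prof, condition_effects = eff, n_cells = n_cells,
                ambient_fraction = ambient_fraction,
                depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
                doublet_rate = doublet_rate, night_fraction = night_fraction,
                dispersion = dispersion, programs = programs, seed = seed)
}

# Per-condition expected expression profiles, each column renormalized to
# sum to one so a cell's expected total equals its drawn library size.
sim_rate_profiles <- function(config) {
  p <- config$profiles
  fold <- matrix(1, nrow(p), ncol(p), dimnames = dimnames(p))
  eff <- config$condition_effects
  if (nrow(eff)) {
    idx <- cbind(match(eff$gene, rownames(p)), match(eff$target_type, colnames(p)))
    keep <- !is.na(idx[, 2])
    fold[idx[keep, , drop = FALSE]] <- eff$fold[keep]
  }
  pin <- config$cell_types$family == "pinealocyte"
  if (!any(pin) && config$ambient_fraction > 0)
    stop("ambient contamination draws from the pooled pinealocyte profile; ",
         "no pinealocyte cell type is configured")
  pin_w <- config$cell_types$proportion[pin] / sum(config$cell_types$proportion[pin])
  mix <- function(pe) {
    q <- if (any(pin))
      drop(pe[, config$cell_types$name[pin], drop = FALSE] %*% pin_w)
    else 0
    out <- (1 - config$ambient_fraction) * pe + config$ambient_fraction * q
    sweep(out, 2, colSums(out), "/")
  }
  list(day = mix(p), night = mix(p * fold))
}

#' Simulate a UMI count matrix from a configuration
#'
#' Each singlet cell draws a lognormal library size `L`; its per-gene
#' Poisson rate is `L` times a mixture of the type- and
#' condition-specific expression profile (weight `1 - ambient_fraction`)
#' and the pooled pinealocyte profile (weight `ambient_fraction`),
#' renormalized to sum to one.  Doublets average the rate vectors of two
#' independently drawn singlets.  Column order is randomized.
#'
#' @param config A [pineal_config()].
#' @return A `pineal_sim` list: `counts` (sparse integer genes x cells
#'   matrix), `cells` (ground-truth tibble: type, family, condition,
#'   replicate, doublet status and parents, library size), `genes`
#'   (per-gene tibble) and the `config`.
#' @export
simulate_pineal <- function(config) {
  stopifnot(inherits(config, "pineal_config"))
  withr::local_seed(config$seed + 1L)
  n <- config$n_cells
  types <- config$cell_types$name
  fam <- stats::setNames(config$cell_types$family, types)

  type1 <- sample(types, n, replace = TRUE, prob = config$cell_types$proportion)
  cond <- sample(c("day", "night"), n, replace = TRUE,
                 prob = c(1 - config$night_fraction, config$night_fraction))
  is_dbl <- stats::runif(n) < config$doublet_rate
  type2 <- rep(NA_character_, n)
  type2[is_dbl] <- sample(types, sum(is_dbl), replace = TRUE,
                          prob = config$cell_types$proportion)
  depth1 <- stats::rlnorm(n, config$depth_log_mean, config$depth_log_sd)
  depth2 <- stats::rlnorm(n, config$depth_log_mean, config$depth_log_sd)

  prof <- sim_rate_profiles(config)
  g <- config$n_genes
  rate_for <- function(i) {
    r <- depth1[i] * prof[[cond[i]]][, type1[i]]
    if (is_dbl[i]) r <- 0.5 * r + 0.5 * depth2[i] * prof[[cond[i]]][, type2[i]]
    r
  }
  # draw in (type, condition, doublet) blocks, one sparse conversion each
  draw_block <- function(idx) {
    rates <- vapply(idx, rate_for, numeric(g))
    if (config$dispersion > 0) {
      sh <- 1 / config$dispersion
      rates <- rates * matrix(stats::rgamma(length(rates), shape = sh, rate = sh),
                              nrow = g)
    }
    Matrix::Matrix(matrix(stats::rpois(length(rates), rates), nrow = g), sparse = TRUE)
  }
  blocks <- split(seq_len(n), interaction(type1, cond, is_dbl, drop = TRUE))
  counts <- do.call(cbind, lapply(blocks, draw_block))
  counts <- counts[, order(unlist(blocks, use.names = FALSE)), drop = FALSE]

  perm <- sample(n)
  counts <- counts[, perm, drop = FALSE]
  cell_id <- sprintf("C%05d", seq_len(n))
  dimnames(counts) <- list(rownames(config$profiles), cell_id)
  lib <- ifelse(is_dbl, 0.5 * (depth1 + depth2), depth1)
  cells <- tibble::tibble(
    cell_id = cell_id,
    type = type1[perm], family = unname(fam[type1[perm]]),
    condition = cond[perm],
    replicate = sample(1:2, n, replace = TRUE),
    is_doublet = is_dbl[perm], type2 = type2[perm],
    library_size = lib[perm]
  )
  ref_col <- if ("pinealocyte_beta" %in% colnames(config$profiles))
    "pinealocyte_beta" else colnames(config$profiles)[1]
  genes <- tibble::tibble(
    gene = rownames(config$profiles),
    base_fraction = unname(config$profiles[, ref_col])
  )
  structure(list(counts = counts, cells = cells, genes = genes, config = config),
            class = "pineal_sim")
}

#' @export
print.pineal_sim <- function(x, ...) {
  cat("<pineal_sim> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells (",
      sum(x$cells$is_doublet), " doublets, ",
      sum(x$cells$condition == "night"), " night cells)\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits MatrixMarket counts plus TSV sidecars (genes, barcodes, cell
#' metadata with ground truth, condition effects) and a JSON manifest.
#' The dataset round-trips losslessly through [read_counts()].
#'
#' @param sim A `pineal_sim`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_pineal_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "pineal_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(matrix = "matrix.mtx", genes = "genes.tsv", barcodes = "barcodes.tsv",
             cell_metadata = "cell_metadata.tsv",
             condition_effects = "condition_effects.tsv",
             manifest = "manifest.json")
  Matrix::writeMM(sim$counts, file.path(dir, files["matrix"]))
  writeLines(rownames(sim$counts), file.path(dir, files["genes"]))
  writeLines(colnames(sim$counts), file.path(dir, files["barcodes"]))
  utils::write.table(sim$cells, file.path(dir, files["cell_metadata"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$config$condition_effects,
                     file.path(dir, files["condition_effects"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(files = as.list(files[setdiff(names(files), "manifest")]),
                   seed = sim$config$seed, n_cells = ncol(sim$counts),
                   n_genes = nrow(sim$counts))
  jsonlite::write_json(manifest, file.path(dir, files["manifest"]),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
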