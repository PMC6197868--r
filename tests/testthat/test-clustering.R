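test_that("exact PCA captures low-rank structure and fixes component signs", {
  set.seed(3)
  # rank-2 data: two latent directions across 40 cells
  u <- matrix(rnorm(30 * 2), 30)
  v <- matrix(rnorm(2 * 40), 2)
  x <- u %*% v
  x <- x - rowMeans(x)
  dimnames(x) <- list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:40))
  p <- run_pca(x, 2)
  expect_gt(sum(p$var_explained), 0.999)
  expect_equal(crossprod(p$loadings), diag(2), ignore_attr = TRUE,
               tolerance = 1e-6)
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_error(run_pca(x, 50), "k must lie")
})

test_that("full-rank scores reproduce pairwise distances; duplicates coincide", {
  set.seed(4)
  x <- matrix(rnorm(8 * 20), 8, dimnames = list(paste0("g", 1:8), paste0("c", 1:20)))
  x <- t(scale(t(x)))
  p <- run_pca(x, 8)
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(t(x))),
               tolerance = 1e-8, ignore_attr = TRUE)

  x2 <- cbind(x, dup = x[, 1])
  colnames(x2)[21] <- "c21"
  x2 <- x2 - rowMeans(x2)
  p2 <- run_pca(x2, 4)
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[21, ]), tolerance = 1e-9)
})

test_that("SNN weights are Jaccard overlaps of kNN sets", {
  # 6 points in 2D: two tight triplets far apart
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 10), c(10, 11), c(11, 10))
  rownames(pts) <- paste0("c", 1:6)
  g <- build_snn(pts, knn_k = 3, prune = 0)
  a <- as.matrix(g$adjacency)
  # within a triplet every pair shares all 3 neighbors -> weight 1
  expect_equal(unname(a[1, 2]), 1)
  expect_equal(unname(a[4, 5]), 1)
  # across triplets, neighbor sets are disjoint -> no edge
  expect_equal(unname(a[1, 4]), 0)
  expect_true(isSymmetric(a))
  expect_true(all(diag(a) == 0))

  # manual Jaccard on an asymmetric layout
  pts2 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(4, 0), c(5, 0))
  rownames(pts2) <- paste0("c", 1:6)
  g2 <- build_snn(pts2, knn_k = 2, prune = 0)
  # kNN sets (self + nearest): {1,2},{2,1},{3,2},{4,3},{5,4},{6,5}
  m <- as.matrix(g2$adjacency)
  expect_equal(unname(m[1, 2]), 1)       # identical sets {1,2} and {2,1}
  expect_equal(unname(m[2, 3]), 1 / 3)   # share {2}
  expect_equal(unname(m[4, 6]), 0)       # disjoint
})

test_that("community detection splits cliques and collapses at low resolution", {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  adj[5, 6] <- adj[6, 5] <- 0.05        # weak bridge
  rownames(adj) <- colnames(adj) <- paste0("c", 1:10)
  snn <- structure(list(adjacency = methods::as(Matrix::Matrix(adj, sparse = TRUE),
                                                "CsparseMatrix"),
                        knn_k = 5, prune = 0), class = "snn_graph")
  lab <- find_communities(snn, resolution = 1, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:5])), 1)
  lab0 <- find_communities(snn, resolution = 1e-4, seed = 1)
  expect_equal(length(unique(lab0)), 1)
  # determinism
  expect_identical(lab, find_communities(snn, resolution = 1, seed = 1))
})

test_that("consolidation merges artificial splits of one population only", {
  # one homogeneous population, forcibly over-clustered
  sim <- simulate_pineal(single_type_config(n_cells = 300, n_genes = 500,
                                            night_fraction = 0))
  nm <- normalize_per_cell(sim$counts)
  labels <- stats::setNames(rep(1:3, length.out = 300), colnames(sim$counts))
  model <- consolidate(nm, labels)
  expect_equal(length(unique(model$cells$cluster)), 1)

  # two genuinely distinct populations stay apart
  sim2 <- simulate_pineal(two_type_config(n_cells = 400))
  nm2 <- normalize_per_cell(sim2$counts)
  truth <- sim2$cells$type[match(colnames(sim2$counts), sim2$cells$cell_id)]
  labels2 <- stats::setNames(as.integer(factor(truth)), colnames(sim2$counts))
  model2 <- consolidate(nm2, labels2)
  expect_equal(length(unique(model2$cells$cluster)), 2)

  # manual override forces a merge
  model3 <- consolidate(nm2, labels2, manual = list(c(1, 2)))
  expect_equal(length(unique(model3$cells$cluster)), 1)
})

test_that("alpha and beta pinealocyte populations are never consolidated", {
  sim <- shared_default_sim()
  day <- sim$cells[sim$cells$condition == "day" & !sim$cells$is_doublet, ]
  ab <- day[day$family == "pinealocyte", ]
  nm <- normalize_per_cell(sim$counts[, ab$cell_id])
  labels <- stats::setNames(as.integer(factor(ab$type)), ab$cell_id)
  model <- consolidate(nm, labels)
  expect_equal(length(unique(model$cells$cluster)), 2)
})

test_that("doublet exclusion flags cross-population doublets sensitively", {
  cfg <- two_type_config(n_cells = 1500, doublet_rate = 0.05, seed = 5)
  sim <- simulate_pineal(cfg)
  truth <- sim$cells
  nm <- normalize_per_cell(sim$counts)
  lg <- log_transform(nm)
  labels <- stats::setNames(as.integer(factor(truth$type)), truth$cell_id)
  model <- consolidate(nm, labels, criteria = de_criteria())
  markers <- cluster_markers(nm, model)
  out <- exclude_doublets(nm, model, markers)
  flagged <- out$cells$cell_id[out$cells$excluded]
  cross <- truth$is_doublet & !is.na(truth$type2) & truth$type != truth$type2
  expect_gte(sum(truth$cell_id[cross] %in% flagged) / sum(cross), 0.7)
  # pure singlets are overwhelmingly retained
  singlet <- truth$cell_id[!truth$is_doublet]
  expect_lt(mean(singlet %in% flagged), 0.02)
  # an infinite level disables flagging
  lev <- stats::setNames(rep(Inf, length(markers)), names(markers))
  out2 <- exclude_doublets(nm, model, markers, level = lev)
  expect_false(any(out2$cells$excluded))
})

test_that("the cluster dendrogram matches direct distance computation", {
  # three clusters with hand-set mean profiles
  prof <- cbind(`1` = c(0, 0, 0), `2` = c(0.1, 0, 0), `3` = c(5, 5, 5))
  vals <- prof[, rep(1:3, each = 4)] # 4 identical cells per cluster
  rownames(vals) <- paste0("g", 1:3)
  colnames(vals) <- paste0("c", 1:12)
  nm <- structure(list(values = methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                            "CsparseMatrix"),
                       scheme = "lognorm", totals = rep(1, 12)),
                  class = "norm_matrix")
  model <- structure(list(cells = tibble::tibble(
    cell_id = colnames(vals), raw_cluster = rep(1:3, each = 4),
    cluster = rep(1:3, each = 4), excluded = FALSE)), class = "cluster_model")
  tr <- cluster_tree(nm, model, paste0("g", 1:3))
  hc <- tr$hclust
  # clusters 1 and 2 join first at their Euclidean distance, 3 joins last
  expect_equal(hc$height[1], 0.1)
  expect_equal(hc$height[2], mean(c(dist(t(prof))[c(2, 3)])))
  # identical clusters join at height zero
  model0 <- model
  vals0 <- vals; vals0[, 5:8] <- vals[, 1:4]   # clusters 1 and 2 identical
  nm0 <- nm; nm0$values <- methods::as(Matrix::Matrix(vals0, sparse = TRUE),
                                       "CsparseMatrix")
  tr0 <- cluster_tree(nm0, model0, paste0("g", 1:3))
  expect_equal(tr0$hclust$height[1], 0)
  expect_s3_class(tr$phylo, "phylo")
  expect_error(cluster_tree(nm, structure(list(cells = tibble::tibble(
    cell_id = colnames(vals), raw_cluster = 1, cluster = 1,
    excluded = FALSE)), class = "cluster_model"), paste0("g", 1:3)),
    "at least 2")
})

test_that("alpha and beta pinealocytes are mutual nearest dendrogram leaves", {
  run <- shared_default_run()
  s <- run$samples$day
  tr <- cluster_tree(s$lognorm, s$model, s$hvg)
  labs <- stats::setNames(s$annotation$clusters$label,
                          s$annotation$clusters$cluster)
  d <- as.matrix(dist(t(tr$profiles)))
  diag(d) <- Inf
  alpha <- names(labs)[labs == "pinealocyte_alpha"][1]
  nn_of_alpha <- colnames(d)[which.min(d[alpha, ])]
  expect_match(labs[[nn_of_alpha]], "^pinealocyte")
})

test_that("proportion tables reproduce printed within-family arithmetic", {
  ann <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(275 + 4822)),
    label = rep(c("pinealocyte_alpha", "pinealocyte_beta"), c(275, 4822)),
    family = "pinealocyte")
  pr <- cluster_proportions(ann)
  expect_equal(round(pr$pct_of_family[pr$label == "pinealocyte_alpha"]), 5)
  expect_equal(sum(pr$pct), 100)
  one <- cluster_proportions(tibble::tibble(cell_id = "c1", label = "x",
                                            family = "x"))
  expect_equal(one$pct, 100)
})
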