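test_that("pseudocounted fold change follows its closed form", {
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(0, 0), 1)
  expect_equal(fold_change(0.99, 0.49), 2)
  expect_error(fold_change(-1, 2), ">= 0")
  # reciprocal identity, exactly
  set.seed(1)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(fold_change(a, b) * fold_change(b, a), rep(1, 50))
})

test_that("Cohen's d uses the pooled deviation and handles degeneracy", {
  expect_equal(cohens_d(2, 1, 10, 2, 3, 12), 0)
  # a = {0, 2}, b = {1, 3}: means 1, 2; each variance 2; pooled sd sqrt(2)
  expect_equal(cohens_d(1, sqrt(2), 2, 2, sqrt(2), 2), -1 / sqrt(2))
  # location shift with equal sd: d = shift / sd exactly
  expect_equal(cohens_d(7, 2, 30, 4, 2, 30), 1.5)
  # antisymmetry
  expect_equal(cohens_d(1.3, 0.7, 9, 2.9, 1.1, 14),
               -cohens_d(2.9, 1.1, 14, 1.3, 0.7, 9))
  # zero pooled deviation
  expect_equal(cohens_d(1, 0, 5, 1, 0, 5), 0)
  expect_equal(cohens_d(2, 0, 5, 1, 0, 5), Inf)
  expect_error(cohens_d(1, 1, 1, 1, 1, 1), "at least 3")
})

test_that("BH adjustment equals the brute-force suffix-minimum definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      j <- which(o == i)  # rank of p[i]
      adj[i] <- min(1, min(p[o[j:m]] * m / (j:m)))
    }
    adj
  }
  base <- c(0.001, 0.011, 0.012, 0.4, 0.9)
  for (idx in all_perms(5)) {
    p <- base[idx]
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("the composite rule keeps its thresholds inclusive", {
  crit <- de_criteria()
  # a fold of exactly 2.0 (means 0.99 vs 0.49, pseudocount 0.01) passes
  expect_equal(fold_change(0.99, 0.49), 2)
  expect_true(fold_change(0.99, 0.49) >= crit$fc_threshold)
  # an effect size of exactly 0.35 (difference 0.35, pooled sd 1) passes
  expect_identical(cohens_d(0.35, 1, 50, 0, 1, 50), 0.35)
  expect_true(abs(cohens_d(0.35, 1, 50, 0, 1, 50)) >= crit$d_threshold)
  # detection of exactly 15% in one group passes
  expect_true(max(0.15, 0.02) >= crit$min_detection)

  # a gene at fold 1.9 fails the fold criterion even when all else passes
  vals <- rbind(fc19 = c(1.88, 0.94, 0, 0.98, 0.49, 0))
  colnames(vals) <- paste0("c", 1:6)
  res <- scpineal:::de_between(as_norm(vals), paste0("c", 1:3),
                               paste0("c", 4:6), crit)
  expect_equal(res$fold[1], 1.9)
  expect_false(res$pass_fold[1])
  expect_false(res$de[1])
})

test_that("planted condition effects are recovered and nulls stay silent", {
  # 40 well-expressed genes with night folds >= 4
  genes <- sprintf("G%04d", 1:40)
  eff <- tibble::tibble(gene = genes, target_type = "pinealocyte",
                        fold = rep(c(4, 6, 1 / 4, 1 / 6), 10))
  cfg <- single_type_config(n_cells = 450, n_genes = 900, seed = 3,
                            effects = eff)
  sim <- simulate_pineal(cfg)
  nm <- normalize_per_cell(sim$counts)
  ann <- tibble::tibble(cell_id = sim$cells$cell_id, label = "pinealocyte",
                        condition = sim$cells$condition)
  de <- de_test(nm, ann)
  det <- de$detection_b[match(genes, de$gene)]   # baseline (day) detection
  eligible <- genes[det >= 0.3]
  called <- de$gene[de$de]
  expect_gte(mean(eligible %in% called), 0.9)
  # directions match the planted folds
  up <- intersect(de$gene[de$de & de$direction == "night_up"], genes)
  expect_true(all(up %in% genes[eff$fold > 1]))

  # null: same generator without effects yields no calls
  cfg0 <- single_type_config(n_cells = 450, n_genes = 900, seed = 4)
  sim0 <- simulate_pineal(cfg0)
  nm0 <- normalize_per_cell(sim0$counts)
  ann0 <- tibble::tibble(cell_id = sim0$cells$cell_id, label = "pinealocyte",
                         condition = sim0$cells$condition)
  de0 <- de_test(nm0, ann0)
  expect_lte(sum(de0$de), 2)
})

test_that("ambient exclusions apply to non-pinealocyte types only", {
  ex <- ambient_exclusion(c("pinealocyte_alpha", "pinealocyte_beta",
                            "astrocyte_alpha", "microglia"))
  expect_equal(ex$pinealocyte_alpha, character())
  expect_equal(ex$astrocyte_alpha, "Aanat")
  expect_equal(ex$microglia, "Aanat")
  ex0 <- ambient_exclusion(c("astrocyte"), genes = character())
  expect_equal(ex0$astrocyte, character())
})

test_that("excluded ambient genes never appear in a type's DE table", {
  genes <- c("Aanat", sprintf("G%04d", 1:20))
  eff <- tibble::tibble(gene = "Aanat", target_type = "astrocyte", fold = 6)
  # an 'astrocyte' population in which Aanat rises at night (as ambient
  # contamination would make it appear to)
  base <- c(2e-3, rep(1, 20)); base <- base / sum(base)
  ct <- tibble::tibble(name = "astrocyte", family = "astrocyte",
                       subtype = NA_character_, proportion = 1)
  prof <- matrix(base, dimnames = list(genes, "astrocyte"))
  cfg <- pineal_config(ct, prof, eff, n_cells = 300, ambient_fraction = 0,
                       doublet_rate = 0, seed = 2)
  sim <- simulate_pineal(cfg)
  nm <- normalize_per_cell(sim$counts)
  ann <- tibble::tibble(cell_id = sim$cells$cell_id, label = "astrocyte",
                        condition = sim$cells$condition)
  de <- de_test(nm, ann, exclusions = ambient_exclusion("astrocyte"))
  expect_false("Aanat" %in% de$gene)
  de_pin <- de_test(nm, dplyr::mutate(ann, label = "pinealocyte"),
                    exclusions = ambient_exclusion("pinealocyte"))
  expect_true("Aanat" %in% de_pin$gene)
})

test_that("pooled group comparison reduces to per-gene analysis for singletons", {
  sim <- simulate_pineal(two_type_config(n_cells = 500))
  truth <- sim$cells
  nm <- normalize_per_cell(sim$counts)
  a <- truth$cell_id[truth$type == "pinealocyte"]
  b <- truth$cell_id[truth$type == "astrocyte"]
  g1 <- group_comparison(nm, a, b, "Tph1")
  expect_equal(g1$mean_a, mean(nm$values["Tph1", a]))
  expect_equal(g1$ratio, fold_change(mean(nm$values["Tph1", a]),
                                     mean(nm$values["Tph1", b])))
  # identical populations: ratio near 1, large p
  half <- split(a, rep(1:2, length.out = length(a)))
  g0 <- group_comparison(nm, half[[1]], half[[2]], c("Tph1", "Sag"))
  expect_lt(abs(log(g0$ratio)), log(1.2))
  expect_gt(g0$p, 0.05)
  expect_error(group_comparison(nm, a, b, "NotAGene"), "no group genes")
  expect_warning(group_comparison(nm, a, b, c("Tph1", "NotAGene")), "absent")
})

test_that("overlap tables count pairwise intersections and shares", {
  ov <- de_overlap(list(A = c("g1", "g2"), B = c("g2", "g3")))
  ab <- ov[ov$set_a == "A" & ov$set_b == "B", ]
  expect_equal(ab$n_common, 1)
  expect_equal(ab$pct_a_in_b, 50)
  expect_equal(attr(ov, "n_all"), 1)
  dis <- de_overlap(list(A = "g1", B = "g2"))
  expect_equal(dis$n_common, c(0, 0))
  sub <- de_overlap(list(A = c("g1", "g2"), B = c("g1", "g2", "g3")))
  expect_equal(sub$pct_a_in_b[sub$set_a == "A"], 100)
})
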