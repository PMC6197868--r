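test_that("configuration validation enforces proportions, rates and sizing", {
  expect_error(default_pineal_config(100), "too small")
  cfg <- default_pineal_config(5000, seed = 1)
  expect_s3_class(cfg, "pineal_config")
  expect_equal(sum(cfg$cell_types$proportion), 1, tolerance = 1e-12)
  expect_equal(colSums(cfg$profiles), rep(1, 9), ignore_attr = TRUE,
               tolerance = 1e-12)

  pin <- cfg$cell_types
  expect_equal(sum(pin$proportion[pin$family == "pinealocyte"]), 90 / 100.1,
               tolerance = 1e-9)
  # planted subtype multipliers, relative to the beta profile before
  # per-type renormalization
  ab <- cfg$profiles[, "pinealocyte_alpha"] / cfg$profiles[, "pinealocyte_beta"]
  scale <- ab[["Tph1"]]  # renormalization constant (Tph1 is unmodified)
  expect_equal(ab[["Asmt"]] / scale, 3.4, tolerance = 1e-9)
  expect_equal(unname(ab["Rpl3"] / scale), 1 / 8.2, tolerance = 1e-9)
  expect_equal(unname(ab["Gngt1"] / scale), 1 / 5.4, tolerance = 1e-9)
  expect_equal(unname(ab["Cox4i1"] / scale), 2.3, tolerance = 1e-9)

  bad <- cfg$cell_types
  bad$proportion[1] <- bad$proportion[1] + 1e-3
  expect_error(pineal_config(bad, cfg$profiles), "sum to 1")
  expect_error(two_type_config(doublet_rate = 0.2), "doublet_rate")
})

test_that("simulation is deterministic and conserves library size", {
  cfg <- two_type_config(n_cells = 300)
  s1 <- simulate_pineal(cfg)
  s2 <- simulate_pineal(cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cells, s2$cells)

  # expected totals equal the drawn library sizes up to Poisson error
  tot <- Matrix::colSums(s1$counts)
  rel <- sum(tot) / sum(s1$cells$library_size)
  expect_lt(abs(rel - 1), 0.02)
})

test_that("degenerate single-population case reproduces the baseline", {
  cfg <- single_type_config(n_cells = 400, n_genes = 300, night_fraction = 0)
  sim <- simulate_pineal(cfg)
  est <- Matrix::rowSums(sim$counts) / sum(sim$counts)
  base <- cfg$profiles[, 1]
  keep <- base > 1e-3
  expect_lt(max(abs(est[keep] - base[keep]) / base[keep]), 0.15)
  expect_false(any(sim$cells$is_doublet))
})

test_that("true alpha/beta Asmt ratio on ground-truth labels is near 3.4", {
  sim <- shared_default_sim()
  nm <- normalize_per_cell(sim$counts)
  a <- sim$cells$cell_id[sim$cells$type == "pinealocyte_alpha" & !sim$cells$is_doublet]
  b <- sim$cells$cell_id[sim$cells$type == "pinealocyte_beta" & !sim$cells$is_doublet]
  ratio <- mean(nm$values["Asmt", a]) / mean(nm$values["Asmt", b])
  expect_gt(ratio, 2.9)
  expect_lt(ratio, 3.9)
})

test_that("ambient contamination places pinealocyte markers uniformly in others", {
  cfg <- two_type_config(n_cells = 1200, ambient_fraction = 0.05)
  sim <- simulate_pineal(cfg)
  ast <- sim$cells$cell_id[sim$cells$type == "astrocyte"]
  counts <- sim$counts[, ast]
  lib <- sim$cells$library_size[match(ast, sim$cells$cell_id)]
  # expected counts of an exclusive pinealocyte marker in astrocytes:
  # ambient_fraction * pooled pinealocyte profile * library size
  q <- cfg$profiles[, "pinealocyte"]
  expected <- (0.95 * cfg$profiles["Tph1", "astrocyte"] + 0.05 * q["Tph1"]) * sum(lib)
  observed <- sum(counts["Tph1", ])
  expect_lt(abs(observed / expected - 1), 0.25)
  # and with no ambient fraction the marker is essentially absent
  sim0 <- simulate_pineal(two_type_config(n_cells = 1200, ambient_fraction = 0))
  ast0 <- sim0$cells$cell_id[sim0$cells$type == "astrocyte"]
  expect_lt(mean(sim0$counts["Tph1", ast0] > 0), 0.2)
  expect_lt(mean(sim0$counts["Tph1", ast0]),
            mean(sim$counts["Tph1", ast]))
})

test_that("raising a condition fold raises the night mean monotonically", {
  eff <- function(f) tibble::tibble(gene = "G0005", target_type = "pinealocyte",
                                    fold = f)
  means <- vapply(c(1, 2, 4), function(f) {
    sim <- simulate_pineal(single_type_config(n_cells = 600, n_genes = 300,
                                              effects = eff(f)))
    night <- sim$cells$cell_id[sim$cells$condition == "night"]
    mean(sim$counts["G0005", night])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("datasets round-trip losslessly through the MatrixMarket writer", {
  sim <- simulate_pineal(two_type_config(n_cells = 120))
  dir <- withr::local_tempdir()
  manifest <- write_pineal_dataset(sim, dir)
  expect_true(file.exists(file.path(dir, "matrix.mtx")))
  back <- read_counts(dir)
  expect_identical(as.matrix(back), as.matrix(sim$counts))
  expect_equal(manifest$n_cells, 120)

  # nnz of the triplet file matches the number of nonzero entries
  toy <- toy_counts(matrix(c(0, 1, 2, 3, 0, 1), nrow = 2, byrow = TRUE))
  sim_toy <- list(counts = toy,
                  cells = tibble::tibble(cell_id = colnames(toy)),
                  genes = tibble::tibble(gene = rownames(toy)),
                  config = list(seed = 1L, condition_effects = tibble::tibble(
                    gene = character(), target_type = character(),
                    fold = numeric())))
  class(sim_toy) <- "pineal_sim"
  d2 <- withr::local_tempdir()
  write_pineal_dataset(sim_toy, d2)
  lines <- readLines(file.path(d2, "matrix.mtx"), n = 5)
  dims_line <- lines[!startsWith(lines, "%")][1]
  dims <- scan(text = dims_line, quiet = TRUE)
  expect_equal(dims[3], sum(as.matrix(toy) != 0))
})
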