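# Fixtures are generated in code: small bespoke configurations exercise
# single stages; one shared default-configuration run backs the
# end-to-end recovery checks and is computed lazily, once per session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# tiny deterministic dense count matrix with dimnames
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  genes <- genes %||% rownames(mat) %||% sprintf("g%02d", seq_len(nrow(mat)))
  cells <- cells %||% colnames(mat) %||% sprintf("c%02d", seq_len(ncol(mat)))
  methods::as(Matrix::Matrix(mat, sparse = TRUE,
                             dimnames = list(genes, cells)), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a plain matrix as a per-total normalized object without rescaling
as_norm <- function(mat, scheme = "per_total") {
  m <- toy_counts(mat)
  structure(list(values = m, scheme = scheme, totals = Matrix::colSums(m)),
            class = "norm_matrix")
}

# two well-separated populations (pinealocyte-like and astrocyte-like)
# with exclusive markers; used for marker, doublet and clustering tests
two_type_config <- function(n_cells = 800, seed = 7, doublet_rate = 0,
                            night_fraction = 0, ambient_fraction = 0.02,
                            condition_effects = NULL) {
  n_genes <- 400
  genes <- c("Tph1", "Asmt", "Sag", "Aldh1a1", "S100b", "Tnfrsf21",
             sprintf("G%03d", seq_len(n_genes - 6)))
  base <- withr::with_seed(seed, {
    w <- stats::rlnorm(n_genes - 6, 0, 1)
    c(rep(2e-5, 6), w / sum(w) * (1 - 1.2e-4))
  })
  names(base) <- genes
  pin <- base; pin[c("Tph1", "Asmt", "Sag")] <- pin[c("Tph1", "Asmt", "Sag")] * 250
  ast <- base; ast[c("Aldh1a1", "S100b", "Tnfrsf21")] <-
    ast[c("Aldh1a1", "S100b", "Tnfrsf21")] * 250
  prof <- cbind(pinealocyte = pin, astrocyte = ast)
  ct <- tibble::tibble(name = c("pinealocyte", "astrocyte"),
                       family = name, subtype = NA_character_,
                       proportion = c(0.7, 0.3))
  pineal_config(ct, prof, condition_effects = condition_effects,
                n_cells = n_cells, ambient_fraction = ambient_fraction,
                doublet_rate = doublet_rate, night_fraction = night_fraction,
                seed = seed)
}

# a single homogeneous population; optionally with planted night effects
single_type_config <- function(n_cells = 500, n_genes = 1000, seed = 11,
                               night_fraction = 0.5, effects = NULL) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  base <- withr::with_seed(seed, {
    w <- stats::rlnorm(n_genes, 0, 1)
    w / sum(w)
  })
  names(base) <- genes
  ct <- tibble::tibble(name = "pinealocyte", family = "pinealocyte",
                       subtype = NA_character_, proportion = 1)
  pineal_config(ct, cbind(pinealocyte = base), condition_effects = effects,
                n_cells = n_cells, ambient_fraction = 0, doublet_rate = 0,
                night_fraction = night_fraction, seed = seed)
}

shared_default_sim <- function()
  memo("default_sim", simulate_pineal(default_pineal_config(5000, seed = 1)))

shared_default_run <- function()
  memo("default_run", run_pipeline(shared_default_sim(),
                                   config = pipeline_config(max_umi = 30000,
                                                            seed = 1)))

# all permutations of 1:n as a list of index vectors
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(all_perms(n - 1), function(p) c(i, (seq_len(n)[-i])[p]))))
}
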