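# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Tiny two-cell-type world used across module tests.
tiny_world <- function() {
  memo("tiny", {
    cfg <- sim_config(n_individuals = 60, n_genes = 40, n_cell_types = 2,
                      n_chromosomes = 5, snps_per_gene = 12,
                      n_cells_per_ind = 8, seed = 42)
    truth <- sim_truth(cfg)
    panel <- gen_genotypes(truth)
    list(cfg = cfg, truth = truth, panel = panel,
         backend = oracle_backend(truth, panel))
  })
}

tiny_counts <- function() {
  memo("tiny_counts", {
    w <- tiny_world()
    gen_pseudobulk_counts(w$truth, w$panel)
  })
}

# Hand-built pseudobulk matrix wrapper for unit tests.
make_pb <- function(counts, cell_type = "ctX") {
  structure(list(cell_type = cell_type, counts = counts,
                 n_cells = rep(1L, ncol(counts))),
            class = "pseudobulk_matrix")
}

# Independent rank-percentile oracle: counting definition of the average
# rank, no calls to rank().
oracle_percentile <- function(x) {
  n <- length(x)
  unname(vapply(x, function(xi) {
    r <- sum(x < xi) + (sum(x == xi) + 1) / 2
    (r - 1) / (n - 1)
  }, numeric(1)))
}
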