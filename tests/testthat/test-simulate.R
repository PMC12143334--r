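# Synthetic-data module: genotypes, epigenome oracle, counts, GWAS.

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(nonlinear_fraction = 1.5), "nonlinear_fraction")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_chromosomes = 2), "n_chromosomes")
  expect_equal(sim_config(profile = "full")$n_tracks, 5313L)
})

test_that("genotypes: LD, allele frequency and determinism", {
  # independence case: ld_decay = 0 gives |r| < 3/sqrt(n) for adjacent SNPs
  cfg0 <- sim_config(n_individuals = 400, n_genes = 4, n_cell_types = 1,
                     snps_per_gene = 10, ld_decay = 0,
                     n_chromosomes = 4, seed = 1)
  t0 <- sim_truth(cfg0)
  p0 <- gen_genotypes(t0)
  rs <- vapply(1:9, function(j) {
    cor(p0$dosages[, j], p0$dosages[, j + 1])
  }, numeric(1))
  expect_lt(max(abs(rs)), 3 / sqrt(400))

  # symmetric MAF = 0.5 gives mean dosage ~ 1
  cfg5 <- sim_config(n_individuals = 600, n_genes = 3, n_cell_types = 1,
                     snps_per_gene = 10, maf_range = c(0.5, 0.5),
                     n_chromosomes = 3, seed = 2)
  p5 <- gen_genotypes(sim_truth(cfg5))
  expect_lt(max(abs(colMeans(p5$dosages) - 1)), 3 * sqrt(0.5 / 600) * 2)

  # positive LD shows up as positive adjacent correlation
  cfgL <- sim_config(n_individuals = 400, n_genes = 4, n_cell_types = 1,
                     snps_per_gene = 10, ld_decay = 0.7,
                     n_chromosomes = 4, seed = 3)
  pL <- gen_genotypes(sim_truth(cfgL))
  rsL <- vapply(1:9, function(j) {
    cor(pL$dosages[, j], pL$dosages[, j + 1])
  }, numeric(1))
  expect_gt(mean(rsL), 0.3)

  expect_error(gen_genotypes(t0, n_individuals = 1), "n_individuals")
})

test_that("VCF output is byte-identical under a fixed seed and round-trips", {
  w <- tiny_world()
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(gen_genotypes(w$truth, seed = 99), f1)
  write_vcf(gen_genotypes(w$truth, seed = 99), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_vcf_dosages(f1)
  expect_identical(back$dosages, gen_genotypes(w$truth, seed = 99)$dosages)
})

test_that("VCF is readable by bcftools and dosages agree", {
  w <- tiny_world()
  f <- tempfile(fileext = ".vcf")
  write_vcf(w$panel, f)
  out <- system2("bcftools", c("query", "-f", "'[%GT,]\\n'", f),
                 stdout = TRUE)
  first <- strsplit(gsub("'|,$", "", out[1]), ",")[[1]]
  dos <- vapply(strsplit(first, "/"),
                function(g) sum(as.integer(g)), numeric(1))
  expect_equal(unname(dos), unname(w$panel$dosages[, 1]))
})

test_that("epigenome oracle: baseline, determinism and planted effects", {
  w <- tiny_world()
  truth <- w$truth
  g <- truth$genes$gene_id[1]
  m0 <- epigenome_oracle(truth, g, rep(0, truth$config$snps_per_gene))
  # zero-genetics case equals the baseline exactly
  gi <- 1
  baseline <- outer(truth$track_base[gi, ], celltwas:::oracle_bin_profile())
  expect_equal(m0, baseline)

  # determinism for identical inputs
  d <- w$panel$dosages[3, celltwas:::gene_variant_rows(truth, g)]
  expect_identical(epigenome_oracle(truth, g, d),
                   epigenome_oracle(truth, g, d))

  # matrix difference vs an independent brute-force loop over cell types
  d2 <- w$panel$dosages[7, celltwas:::gene_variant_rows(truth, g)]
  got <- epigenome_oracle(truth, g, d2) - m0
  want <- matrix(0, truth$config$n_tracks, 896)
  for (ct in seq_along(truth$cell_types)) {
    info <- truth$causal[[g]][[truth$cell_types[ct]]]
    gshift <- sum(info$effects * d2[info$snp_idx]) +
      info$interaction * d2[info$snp_idx[1]] * d2[info$snp_idx[2]]
    for (t in truth$track_groups[[ct]]) {
      for (b in 447:450) want[t, b] <- want[t, b] + gshift
    }
  }
  expect_equal(got, want, tolerance = 1e-12)

  # single-SNP linear term: dosage 0 vs 2 moves causal tracks by 2 * effect
  info <- truth$causal[[g]][["ct1"]]
  dd <- rep(0, truth$config$snps_per_gene)
  snp <- info$snp_idx[3]  # causal for ct1; may overlap other cell types
  dd[snp] <- 2
  diffm <- epigenome_oracle(truth, g, dd) - m0
  tr <- truth$track_groups[[1]][1]
  other_ct_shift <- 0
  for (ct in seq_along(truth$cell_types)) {
    inf2 <- truth$causal[[g]][[truth$cell_types[ct]]]
    if (tr %in% truth$track_groups[[ct]] && snp %in% inf2$snp_idx &&
          ct != 1) {
      other_ct_shift <- other_ct_shift +
        2 * inf2$effects[match(snp, inf2$snp_idx)]
    }
  }
  expect_equal(diffm[tr, 448],
               2 * info$effects[3] + other_ct_shift, tolerance = 1e-12)
  # confined to the central four bins
  expect_true(all(diffm[, -(447:450)] == 0))
})

test_that("pseudobulk counts: null world, Poisson limit, planted gene", {
  # all effects zero: across-individual variance of pseudobulk means is
  # pure sampling noise; compare to the NB prediction var = mu + disp*mu^2
  cfg <- sim_config(n_individuals = 40, n_genes = 30, n_cell_types = 1,
                    n_chromosomes = 3, effect_sd = 0,
                    interaction_sd = 0, nonlinear_fraction = 0,
                    n_cells_per_ind = 25, seed = 5)
  truth <- sim_truth(cfg)
  panel <- gen_genotypes(truth)
  sc <- gen_pseudobulk_counts(truth, panel)
  pb <- aggregate_pseudobulk(sc$counts, sc$metadata)[[1]]
  s <- celltwas:::true_expression_matrix(truth, panel, "ct1")
  mu <- truth$ct_scale[1] * exp(cfg$expr_scale * s)  # constant per gene
  ratio <- vapply(seq_len(nrow(pb$counts)), function(g) {
    m <- mu[g, 1]
    expected_var <- 25 * (m + cfg$nb_dispersion * m^2)  # var of cell sum
    var(pb$counts[g, ]) / expected_var
  }, numeric(1))
  expect_gt(mean(ratio), 0.7)
  expect_lt(mean(ratio), 1.4)

  # dispersion -> 0 limit: variance/mean ~ 1 per (gene, individual)
  cfg0 <- sim_config(n_individuals = 6, n_genes = 20, n_cell_types = 1,
                     n_chromosomes = 3, nb_dispersion = 0,
                     n_cells_per_ind = 200, seed = 6)
  tr0 <- sim_truth(cfg0)
  p0 <- gen_genotypes(tr0)
  sc0 <- gen_pseudobulk_counts(tr0, p0)
  md <- sc0$metadata
  cells1 <- md$cell_id[md$individual == p0$individuals[1]]
  sub <- as.matrix(sc0$counts[, cells1])
  vm <- apply(sub, 1, var) / pmax(rowMeans(sub), 1e-9)
  expect_lt(abs(median(vm) - 1), 0.25)

  # planted high-expression gene ranks top in pseudobulk mean
  tr_hi <- truth
  tr_hi$track_base[5, ] <- tr_hi$track_base[5, ] + 8
  sc_hi <- gen_pseudobulk_counts(tr_hi, panel)
  pb_hi <- aggregate_pseudobulk(sc_hi$counts, sc_hi$metadata)[[1]]
  expect_equal(unname(which.max(rowMeans(pb_hi$counts))), 5L)
})

test_that("GWAS: null calibration and sqrt(n) scaling", {
  w <- tiny_world()
  null_cg <- data.frame(gene_id = w$truth$genes$gene_id[1],
                        cell_type = "ct1", effect = 0)
  g0 <- gen_gwas_sumstats(w$truth, causal_genes = null_cg, gwas_n = 800,
                          seed = 21)
  z <- g0$beta / g0$se
  expect_lt(abs(mean(abs(z) > 1.96) - 0.05), 0.02)
  lambda_gc <- median(z^2) / qchisq(0.5, 1)
  expect_lt(abs(lambda_gc - 1), 0.15)
  expect_gt(ks.test(pnorm(z), "punif")$p.value, 0.01)

  # planted causal SNP: |z| grows ~ sqrt(n)
  gid <- w$truth$genes$gene_id[2]
  cg <- data.frame(gene_id = gid, cell_type = "ct1", effect = 1.5)
  top_z <- function(n, seed) {
    g <- gen_gwas_sumstats(w$truth, causal_genes = cg, gwas_n = n,
                           seed = seed)
    sub <- g[startsWith(g$variant_id, gid), ]
    max(abs(sub$beta / sub$se))
  }
  z1 <- top_z(1000, 31); z4 <- top_z(4000, 31)
  expect_gt(z4 / z1, 1.3)
  expect_lt(z4 / z1, 3.2)

  expect_error(gen_gwas_sumstats(w$truth, causal_genes = null_cg,
                                 gwas_n = 5), "gwas_n")
  expect_error(gen_gwas_sumstats(w$truth,
                                 causal_genes = data.frame()[0, ]),
               "causal_genes")
})

test_that("ground truth JSON round trip preserves generators", {
  w <- tiny_world()
  f <- tempfile(fileext = ".json")
  write_truth_json(w$truth, f)
  back <- read_truth_json(f)
  expect_identical(gen_genotypes(back, seed = 17)$dosages,
                   gen_genotypes(w$truth, seed = 17)$dosages)
  g <- w$truth$genes$gene_id[4]
  d <- w$panel$dosages[1:5, celltwas:::gene_variant_rows(w$truth, g)]
  expect_equal(true_genetic_expression(back, g, "ct2", d),
               true_genetic_expression(w$truth, g, "ct2", d))
})

test_that("true genetic expression matches the oracle's aggregated features", {
  w <- tiny_world()
  truth <- w$truth
  g <- truth$genes$gene_id[9]
  d <- w$panel$dosages[11, celltwas:::gene_variant_rows(truth, g)]
  f <- aggregate_bins(epigenome_oracle(truth, g, d))
  for (ct in seq_along(truth$cell_types)) {
    expect_equal(sum(truth$readout[[ct]] * f),
                 true_genetic_expression(truth, g, truth$cell_types[ct],
                                         d),
                 tolerance = 1e-10)
  }
})
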