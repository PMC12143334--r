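# Association module: harmonization, Z-score, scan.

# Minimal hand-built model over explicit variants.
mk_model <- function(variants, weights, gene_id = "gX",
                     cell_type = "ct1") {
  structure(list(gene_id = gene_id, cell_type = cell_type,
                 converged = TRUE, intercept = 0, weights = weights,
                 variants = variants, n_snps = length(weights),
                 cv_spearman = NA_real_, target = "insilico"),
            class = "linear_gene_model")
}

mk_gwas <- function(df) structure(df, class = c("gwas_sumstats",
                                                "data.frame"))

test_that("harmonize: identity, swap, ambiguous, hand enumeration", {
  v <- data.frame(variant_id = paste0("s", 1:6), chromosome = "1",
                  position = c(100, 200, 300, 400, 500, 600),
                  ref = c("A", "A", "A", "C", "G", "T"),
                  alt = c("C", "G", "T", "T", "A", "G"),
                  stringsAsFactors = FALSE)
  model <- mk_model(v, rep(1, 6))
  gwas <- mk_gwas(data.frame(
    variant_id = paste0("s", 1:6), chromosome = "1",
    position = v$position,
    #       match    swap     ambig    match    swap     mismatch
    effect_allele     = c("C", "A", "T", "T", "G", "A"),
    non_effect_allele = c("A", "G", "A", "C", "A", "C"),
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), se = rep(0.1, 6),
    stringsAsFactors = FALSE))
  h <- harmonize(gwas, model)
  # hand enumeration: s1 kept as-is, s2 flipped, s3 dropped (A/T), s4
  # kept, s5 flipped, s6 dropped (allele set mismatch)
  expect_equal(h$matched$variant_id, c("s1", "s2", "s4", "s5"))
  expect_equal(h$matched$beta, c(0.1, -0.2, 0.4, -0.5))
  expect_equal(h$matched$flipped, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(h$n_dropped_ambiguous, 1L)
  expect_equal(h$n_dropped_mismatch, 1L)
  expect_equal(h$n_snps_used, 4L)
  expect_equal(h$n_snps_in_model, 6L)

  # keeping ambiguous variants is configurable
  h2 <- harmonize(gwas, model, drop_ambiguous = FALSE)
  expect_equal(h2$n_snps_used, 5L)

  # unmatched model SNPs counted
  h3 <- harmonize(gwas[1:2, ], model)
  expect_equal(h3$n_unmatched, 4L)
})

test_that("single-SNP Z reduces to beta/se exactly; sign follows weight", {
  v1 <- data.frame(variant_id = "s1", chromosome = "1", position = 100,
                   ref = "A", alt = "C", stringsAsFactors = FALSE)
  G <- matrix(0.37, 1, 1, dimnames = list("s1", "s1"))
  gwas <- mk_gwas(data.frame(variant_id = "s1", chromosome = "1",
                             position = 100, effect_allele = "C",
                             non_effect_allele = "A", beta = 0.23,
                             se = 0.055, stringsAsFactors = FALSE))
  for (wgt in c(0.8, 2.5)) {
    a <- spredixcan_z(mk_model(v1, wgt), harmonize(gwas, mk_model(v1, wgt)),
                      G)
    expect_equal(a$zscore, 0.23 / 0.055, tolerance = 1e-14)
  }
  aneg <- spredixcan_z(mk_model(v1, -0.8),
                       harmonize(gwas, mk_model(v1, -0.8)), G)
  expect_equal(aneg$zscore, -0.23 / 0.055, tolerance = 1e-14)
  expect_equal(aneg$pvalue, 2 * pnorm(-abs(0.23 / 0.055)))
})

test_that("two-SNP worked example and invariances", {
  v2 <- data.frame(variant_id = c("s1", "s2"), chromosome = "1",
                   position = c(100, 200), ref = c("A", "A"),
                   alt = c("C", "G"), stringsAsFactors = FALSE)
  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("s1", "s2")))
  # per-SNP z-statistics (2, 2): beta = 2, se = 1
  gwas <- mk_gwas(data.frame(variant_id = c("s1", "s2"),
                             chromosome = "1", position = c(100, 200),
                             effect_allele = c("C", "G"),
                             non_effect_allele = c("A", "A"),
                             beta = c(2, 2), se = c(1, 1),
                             stringsAsFactors = FALSE))
  model <- mk_model(v2, c(1, 1))
  a <- spredixcan_z(model, harmonize(gwas, model), G)
  expect_equal(a$zscore, 4 / sqrt(3), tolerance = 1e-12)
  expect_equal(a$sigma_g, sqrt(3))

  # scale invariance: weights * c leave |Z| unchanged, sign follows c
  for (cc in c(3, -0.5)) {
    ms <- mk_model(v2, c(1, 1) * cc)
    as_ <- spredixcan_z(ms, harmonize(gwas, ms), G)
    expect_equal(abs(as_$zscore), abs(a$zscore), tolerance = 1e-12)
    expect_equal(sign(as_$zscore), sign(cc) * sign(a$zscore))
  }

  # allele-flip invariance to machine precision
  gwas_flip <- gwas
  gwas_flip$effect_allele <- c("A", "A")
  gwas_flip$non_effect_allele <- c("C", "G")
  gwas_flip$beta <- -gwas_flip$beta
  af <- spredixcan_z(model, harmonize(gwas_flip, model), G)
  expect_equal(af$zscore, a$zscore, tolerance = 1e-15)

  # p-value symmetry
  expect_equal(2 * pnorm(-abs(a$zscore)), 2 * pnorm(-abs(-a$zscore)))
})

test_that("degenerate cases flagged as undefined", {
  v1 <- data.frame(variant_id = "s1", chromosome = "1", position = 100,
                   ref = "A", alt = "C", stringsAsFactors = FALSE)
  gwas <- mk_gwas(data.frame(variant_id = "sZ", chromosome = "9",
                             position = 1, effect_allele = "C",
                             non_effect_allele = "A", beta = 1, se = 1,
                             stringsAsFactors = FALSE))
  model <- mk_model(v1, 1)
  a <- spredixcan_z(model, harmonize(gwas, model),
                    matrix(1, 1, 1, dimnames = list("s1", "s1")))
  expect_true(a$undefined)

  # zero dosage variance
  gwas2 <- mk_gwas(data.frame(variant_id = "s1", chromosome = "1",
                              position = 100, effect_allele = "C",
                              non_effect_allele = "A", beta = 1, se = 1,
                              stringsAsFactors = FALSE))
  a2 <- spredixcan_z(model, harmonize(gwas2, model),
                     matrix(0, 1, 1, dimnames = list("s1", "s1")))
  expect_true(a2$undefined)
})

test_that("null Z-scores are standard normal (simulation, 500 genes)", {
  set.seed(77)
  n_ref <- 300; n_gwas <- 600
  zs <- vapply(1:500, function(g) {
    maf <- runif(5, 0.1, 0.5)
    ref <- celltwas:::sim_dosage_block(n_ref, maf, 0.4)
    coh <- celltwas:::sim_dosage_block(n_gwas, maf, 0.4)
    y <- rnorm(n_gwas)
    xc <- scale(coh, center = TRUE, scale = FALSE)
    sxx <- colSums(xc^2)
    beta <- as.numeric(crossprod(xc, y - mean(y))) / sxx
    sig2 <- pmax(0, (sum((y - mean(y))^2) - beta^2 * sxx) / (n_gwas - 2))
    se <- sqrt(sig2 / sxx)
    w <- rnorm(5)
    G <- cov(ref)
    var_g <- as.numeric(t(w) %*% G %*% w)
    sum(w * sqrt(diag(G)) / sqrt(var_g) * beta / se)
  }, numeric(1))
  expect_gt(ks.test(zs, "pnorm")$p.value, 0.01)
})

test_that("run_association end-to-end mechanics and error reporting", {
  w <- tiny_world()
  lin <- make_linear_ctpred(w$truth$readout[[1]])
  lin$cell_type <- "ct1"
  ids <- w$truth$genes$gene_id[1:10]
  insilico <- build_insilico_reference(lin, w$backend, w$panel, ids)
  fits <- lapply(ids, function(g) {
    fit_elastic_net(w$truth$genes[w$truth$genes$gene_id == g, ],
                    insilico$expr[g, ], w$panel, enet_params(seed = 7),
                    "ct1")
  })
  conv <- Filter(function(m) isTRUE(m$converged), fits)
  covs <- compute_covariance(w$panel, conv)
  gw <- gen_gwas_sumstats(
    w$truth, causal_genes = data.frame(gene_id = ids[2],
                                       cell_type = "ct1", effect = 1),
    gwas_n = 3000, seed = 41)
  a <- run_association(conv, covs, mk_gwas(gw))
  expect_equal(nrow(a$results), length(conv))
  expect_equal(a$results$gene_id[which.min(a$results$pvalue)], ids[2])
  expect_true(all(a$results$pvalue > 0 & a$results$pvalue <= 1))
  expect_equal(a$results$pvalue,
               2 * pnorm(-abs(a$results$zscore)))

  # empty intersection of GWAS and model variants: zero rows, drop report
  far <- mk_gwas(data.frame(variant_id = "nope", chromosome = "99",
                            position = 1, effect_allele = "A",
                            non_effect_allele = "C", beta = 0, se = 1,
                            stringsAsFactors = FALSE))
  a0 <- run_association(conv[1], covs, far)
  expect_equal(nrow(a0$results), 0)
  expect_equal(nrow(a0$undefined), 1)
  expect_match(a0$undefined$reason[1], "no matched SNPs")
})

test_that("sumstats reader: round trip, column map, malformed lines", {
  w <- tiny_world()
  gw <- gen_gwas_sumstats(
    w$truth, causal_genes = data.frame(gene_id = w$truth$genes$gene_id[1],
                                       cell_type = "ct1", effect = 0),
    gwas_n = 200, seed = 51, path = tempfile(fileext = ".tsv"))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(gw, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_gwas(f)
  expect_equal(back$beta, gw$beta)

  # column mapping
  gw2 <- gw; names(gw2)[names(gw2) == "beta"] <- "BETA"
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(gw2, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_gwas(f2), "missing columns")
  back2 <- read_gwas(f2, column_map = c(beta = "BETA"))
  expect_equal(back2$beta, gw$beta)

  # malformed line reported with its number
  gw3 <- gw; gw3$se[3] <- -1
  f3 <- tempfile(fileext = ".tsv")
  utils::write.table(gw3, f3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_gwas(f3), "line 3")
})
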