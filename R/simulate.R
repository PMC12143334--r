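# Synthetic-data module: genotypes with LD, a deterministic epigenome
# oracle, negative-binomial pseudobulk counts, and GWAS summary statistics
# with planted causal genes. Every generator is a pure function of
# (ground truth, seed), so downstream modules can be tested against the
# closed-form genetic expression the truth object carries.

N_BINS <- 896L
BIN_WIDTH <- 128L
CENTRAL_BINS <- 447:450  # 1-based, the four bins flanking the window centre
FULL_N_TRACKS <- 5313L

#' Simulation configuration
#'
#' Describes one synthetic world: a genotyped cohort, a gene set laid out on
#' synthetic chromosomes, per-gene cis effects on epigenomic feature tracks,
#' cell-type readouts of those tracks, count noise, and a GWAS cohort.
#'
#' Defaults are the package's "stated world": 200 reference individuals
#' (desk-scale stand-in for a several-hundred-individual European reference
#' panel), 300 genes on 10 chromosomes with 20 cis SNPs each, 3 cell types,
#' moderate LD (adjacent-SNP latent correlation 0.3), 20% of genes with a
#' non-additive dosage interaction, negative-binomial dispersion 0.5 and 20
#' cells per individual and cell type (typical of a mid-frequency immune
#' cell type), and a 5,000-individual GWAS cohort.
#'
#' @param n_individuals reference-panel size (>= 2).
#' @param n_genes number of genes (>= 2).
#' @param n_cell_types number of cell types (>= 1).
#' @param snps_per_gene cis SNPs simulated per gene.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_decay adjacent-SNP correlation of the latent AR(1) Gaussian
#'   copula; correlation between SNPs i and j decays as `ld_decay^|i-j|`.
#'   0 gives independent SNPs.
#' @param n_tracks number of epigenomic feature tracks. The full profile
#'   uses 5,313 (the human-head track count of the upstream
#'   sequence-to-epigenome model); the small profile (default 53) keeps the
#'   same geometry at test scale.
#' @param n_causal_tracks tracks per cell-type group that carry genetic
#'   effects (and that the cell type's expression readout weights).
#' @param n_causal_snps causal cis SNPs per (gene, cell type).
#' @param nonlinear_fraction fraction of genes whose causal effect includes
#'   a dosage-product interaction term.
#' @param effect_sd standard deviation of per-SNP effects on causal tracks.
#' @param interaction_sd standard deviation of the interaction coefficient
#'   for nonlinear genes.
#' @param nb_dispersion negative-binomial dispersion of per-cell counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param n_cells_per_ind cells per (individual, cell type).
#' @param expr_scale slope of log count mean on true genetic expression.
#' @param count_log_mean intercept of the per-cell log count mean.
#' @param gwas_n GWAS cohort size (>= 10).
#' @param causal_genes `data.frame(gene_id, cell_type, effect)` of planted
#'   trait effects, or `NULL`.
#' @param n_chromosomes number of synthetic chromosomes (>= 3 so that
#'   train/validation/test chromosome splits exist).
#' @param profile `"small"` or `"full"`; `"full"` forces `n_tracks = 5313`.
#' @param seed integer master seed; all generators derive child seeds.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 200L,
                       n_genes = 300L,
                       n_cell_types = 3L,
                       snps_per_gene = 20L,
                       maf_range = c(0.05, 0.5),
                       ld_decay = 0.3,
                       n_tracks = 53L,
                       n_causal_tracks = 8L,
                       n_causal_snps = 3L,
                       nonlinear_fraction = 0.2,
                       effect_sd = 0.12,
                       interaction_sd = 0.08,
                       nb_dispersion = 0.5,
                       n_cells_per_ind = 20L,
                       expr_scale = 0.8,
                       count_log_mean = 0,
                       gwas_n = 5000L,
                       causal_genes = NULL,
                       n_chromosomes = 10L,
                       profile = c("small", "full"),
                       seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "full") n_tracks <- FULL_N_TRACKS
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_genes = as.integer(n_genes),
    n_cell_types = as.integer(n_cell_types),
    snps_per_gene = as.integer(snps_per_gene),
    maf_range = as.numeric(maf_range), ld_decay = as.numeric(ld_decay),
    n_tracks = as.integer(n_tracks),
    n_causal_tracks = as.integer(n_causal_tracks),
    n_causal_snps = as.integer(n_causal_snps),
    nonlinear_fraction = as.numeric(nonlinear_fraction),
    effect_sd = as.numeric(effect_sd),
    interaction_sd = as.numeric(interaction_sd),
    nb_dispersion = as.numeric(nb_dispersion),
    n_cells_per_ind = as.integer(n_cells_per_ind),
    expr_scale = as.numeric(expr_scale),
    count_log_mean = as.numeric(count_log_mean),
    gwas_n = as.integer(gwas_n), causal_genes = causal_genes,
    n_chromosomes = as.integer(n_chromosomes), profile = profile,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_individuals", "n_genes", "n_cell_types", "snps_per_gene",
              "n_tracks", "n_causal_tracks", "n_causal_snps",
              "n_cells_per_ind", "gwas_n", "n_chromosomes")) {
    assert_that(is_count(cfg[[f]]), sprintf("'%s' must be a count >= 1", f))
  }
  assert_that(cfg$n_genes >= 2, "'n_genes' must be >= 2")
  assert_that(length(cfg$maf_range) == 2 && all(cfg$maf_range > 0) &&
                all(cfg$maf_range <= 0.5) &&
                cfg$maf_range[1] <= cfg$maf_range[2],
              "'maf_range' must be an ordered pair within (0, 0.5]")
  assert_that(cfg$ld_decay >= 0 && cfg$ld_decay < 1,
              "'ld_decay' must be in [0, 1)")
  assert_that(cfg$nonlinear_fraction >= 0 && cfg$nonlinear_fraction <= 1,
              "'nonlinear_fraction' must be in [0, 1]")
  assert_that(cfg$nb_dispersion >= 0, "'nb_dispersion' must be >= 0")
  assert_that(cfg$n_cell_types * cfg$n_causal_tracks <= cfg$n_tracks,
              "need n_cell_types * n_causal_tracks <= n_tracks")
  assert_that(cfg$n_causal_snps <= cfg$snps_per_gene,
              "'n_causal_snps' must be <= snps_per_gene")
  assert_that(cfg$n_chromosomes >= 3,
              "'n_chromosomes' must be >= 3 (chromosome splits need 3 sets)")
  if (!is.null(cfg$causal_genes)) {
    assert_that(is.data.frame(cfg$causal_genes) &&
                  all(c("gene_id", "cell_type", "effect") %in%
                        names(cfg$causal_genes)),
                "'causal_genes' needs columns gene_id, cell_type, effect")
  }
  invisible(cfg)
}

# Non-palindromic ref/alt pairs only: strand-ambiguous variants are
# exercised through hand-built fixtures in the association tests instead.
ALLELE_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)

#' Build the ground truth for a synthetic world
#'
#' Lays out genes on chromosomes (TSS spaced 2.2 Mb apart so +/-1 Mb
#' cis-windows never overlap), draws per-SNP minor allele frequencies,
#' assigns each cell type a disjoint group of `n_causal_tracks` feature
#' tracks together with a non-negative readout weight vector (summing to 1)
#' over that group, and plants, per (gene, cell type), `n_causal_snps`
#' causal cis SNPs with Gaussian effects on the group's tracks plus, for
#' nonlinear genes, a dosage-product interaction between the first two
#' causal SNPs.
#'
#' The resulting object gives the true genetic expression of every
#' (gene, individual, cell type) in closed form
#' (see [true_genetic_expression()]), which downstream parameter-recovery
#' tests use as their oracle.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, 1L), {
    gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    chrom <- as.character(((seq_len(cfg$n_genes) - 1L) %%
                             cfg$n_chromosomes) + 1L)
    idx_on_chrom <- stats::ave(seq_len(cfg$n_genes), chrom,
                               FUN = seq_along)
    tss <- 2200000L * idx_on_chrom
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    nonlinear <- rep(FALSE, cfg$n_genes)
    n_nl <- round(cfg$nonlinear_fraction * cfg$n_genes)
    if (n_nl > 0) nonlinear[sample.int(cfg$n_genes, n_nl)] <- TRUE
    genes <- data.frame(gene_id = gene_id, chromosome = chrom, tss = tss,
                        strand = strand, nonlinear = nonlinear,
                        stringsAsFactors = FALSE)

    variants <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(gi) {
      pos <- round(seq(tss[gi] - 50000, tss[gi] + 50000,
                       length.out = cfg$snps_per_gene))
      alle <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS),
                                      cfg$snps_per_gene, replace = TRUE), ,
                           drop = FALSE]
      data.frame(
        variant_id = sprintf("%s_snp_%02d", gene_id[gi],
                             seq_len(cfg$snps_per_gene)),
        gene_id = gene_id[gi], chromosome = chrom[gi], position = pos,
        ref = alle[, 1], alt = alle[, 2],
        maf = stats::runif(cfg$snps_per_gene, cfg$maf_range[1],
                           cfg$maf_range[2]),
        stringsAsFactors = FALSE)
    }))

    track_base <- matrix(stats::rnorm(cfg$n_genes * cfg$n_tracks),
                         nrow = cfg$n_genes,
                         dimnames = list(gene_id, NULL))

    track_groups <- lapply(seq_len(cfg$n_cell_types), function(ct) {
      ((ct - 1L) * cfg$n_causal_tracks + 1L):(ct * cfg$n_causal_tracks)
    })
    readout <- lapply(seq_len(cfg$n_cell_types), function(ct) {
      w <- numeric(cfg$n_tracks)
      raw <- abs(stats::rnorm(cfg$n_causal_tracks))
      w[track_groups[[ct]]] <- raw / sum(raw)
      w
    })
    cell_types <- sprintf("ct%d", seq_len(cfg$n_cell_types))
    ct_scale <- exp(seq(-0.3, 0.3, length.out = cfg$n_cell_types))

    causal <- lapply(seq_len(cfg$n_genes), function(gi) {
      per_ct <- lapply(seq_len(cfg$n_cell_types), function(ct) {
        list(snp_idx = sort(sample.int(cfg$snps_per_gene,
                                       cfg$n_causal_snps)),
             effects = stats::rnorm(cfg$n_causal_snps, sd = cfg$effect_sd),
             interaction = if (nonlinear[gi])
               stats::rnorm(1, sd = cfg$interaction_sd) else 0)
      })
      names(per_ct) <- cell_types
      per_ct
    })
    names(causal) <- gene_id

    structure(list(config = cfg, genes = genes, variants = variants,
                   track_base = track_base, track_groups = track_groups,
                   readout = readout, cell_types = cell_types,
                   ct_scale = ct_scale, causal = causal),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d genes x %d cell types, %d SNPs/gene, %d tracks (%s)\n",
    x$config$n_genes, x$config$n_cell_types, x$config$snps_per_gene,
    x$config$n_tracks, x$config$profile))
  invisible(x)
}

# Indices (in the truth-wide variants table) of one gene's cis SNPs.
gene_variant_rows <- function(truth, gene_id) {
  which(truth$variants$gene_id == gene_id)
}

#' True genetic expression under the ground truth
#'
#' Closed-form genetic expression for one gene in one cell type:
#' `base + sum_l effect_l * dosage_l (+ interaction * d1 * d2)`, where
#' `base` is the cell type's readout of the gene's baseline feature tracks.
#' This is the oracle downstream recovery tests compare against.
#'
#' @param truth a [sim_truth()].
#' @param gene_id gene identifier.
#' @param cell_type cell-type label (e.g. `"ct1"`).
#' @param dosages numeric matrix (individuals x cis SNPs of the gene) or a
#'   single dosage vector.
#' @return numeric vector of genetic expression values, one per individual.
#' @export
true_genetic_expression <- function(truth, gene_id, cell_type, dosages) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1)
  ct <- match(cell_type, truth$cell_types)
  assert_that(!is.na(ct), sprintf("unknown cell type '%s'", cell_type))
  gi <- match(gene_id, truth$genes$gene_id)
  assert_that(!is.na(gi), sprintf("unknown gene '%s'", gene_id))
  info <- truth$causal[[gene_id]][[cell_type]]
  base <- sum(truth$readout[[ct]] * truth$track_base[gi, ])
  g <- as.numeric(dosages[, info$snp_idx, drop = FALSE] %*% info$effects)
  if (info$interaction != 0) {
    g <- g + info$interaction * dosages[, info$snp_idx[1]] *
      dosages[, info$snp_idx[2]]
  }
  base + g
}

# Genes x individuals matrix of true genetic expression for one cell type.
true_expression_matrix <- function(truth, panel, cell_type) {
  genes <- truth$genes$gene_id
  out <- matrix(NA_real_, length(genes), nrow(panel$dosages),
                dimnames = list(genes, rownames(panel$dosages)))
  for (g in genes) {
    rows <- gene_variant_rows(truth, g)
    out[g, ] <- true_genetic_expression(
      truth, g, cell_type, panel$dosages[, rows, drop = FALSE])
  }
  out
}

# One gene's dosage block: latent Gaussian AR(1) copula per haplotype,
# thresholded at qnorm(maf); dosage = sum of two haplotypes, in {0,1,2}.
sim_dosage_block <- function(n, maf, rho) {
  m <- length(maf)
  thr <- stats::qnorm(maf)
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(NA_real_, n, m)
    z[, 1] <- stats::rnorm(n)
    if (m > 1) {
      for (j in 2:m) {
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
      }
    }
    dos <- dos + (z < rep(thr, each = n))
  }
  storage.mode(dos) <- "integer"
  dos
}

#' Simulate a genotype panel
#'
#' Draws dosages for every variant in the ground truth. Within each gene's
#' cis block, haplotypes follow a first-order autoregressive Gaussian
#' copula with adjacent-SNP correlation `ld_decay`; blocks of different
#' genes are independent (gene cis-windows do not overlap by construction).
#' Each gene's block gets its own derived seed so the GWAS-cohort generator
#' can regenerate single blocks reproducibly.
#'
#' @param truth a [sim_truth()].
#' @param n_individuals cohort size (default: the config's panel size).
#' @param seed integer seed (default derived from the config seed).
#' @param id_prefix prefix for individual identifiers.
#' @return a `genotype_panel`: list with `dosages` (individuals x variants
#'   integer matrix, dimnames set), `variants` (metadata data.frame) and
#'   `individuals`.
#' @export
gen_genotypes <- function(truth, n_individuals = NULL, seed = NULL,
                          id_prefix = "ind") {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  n <- as.integer(n_individuals %||% cfg$n_individuals)
  assert_that(n >= 2, "n_individuals < 2: downstream variances undefined")
  seed <- seed %||% derive_seed(cfg$seed, 2L)
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n))
  blocks <- lapply(seq_len(cfg$n_genes), function(gi) {
    rows <- which(truth$variants$gene_id == truth$genes$gene_id[gi])
    with_seed(derive_seed(seed, gi),
              sim_dosage_block(n, truth$variants$maf[rows], cfg$ld_decay))
  })
  dosages <- do.call(cbind, blocks)
  dimnames(dosages) <- list(ids, truth$variants$variant_id)
  structure(list(dosages = dosages, variants = truth$variants,
                 individuals = ids),
            class = "genotype_panel")
}

#' Write a genotype panel as VCF 4.2
#'
#' Emits a minimal, deterministic VCF with GT fields (`0/0`, `0/1`, `1/1`);
#' dosage counts the ALT allele. Companion reader: [read_vcf_dosages()].
#'
#' @param panel a `genotype_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[panel$dosages + 1L], nrow = nrow(panel$dosages))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=celltwas-synthetic",
    sprintf("##contig=<ID=%s>", unique(v$chromosome)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individuals), collapse = "\t"))
  body <- paste(v$chromosome, v$position, v$variant_id, v$ref, v$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages back from a VCF written by [write_vcf()]
#'
#' Minimal GT parser for the subset of VCF 4.2 this package emits (one GT
#' field per sample, unphased diploid calls); not a general-purpose reader.
#'
#' @param path VCF file path.
#' @return a `genotype_panel`.
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  assert_that(length(hdr) == 1, "malformed VCF: no #CHROM header")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  fields <- strsplit(body, "\t")
  v <- data.frame(
    variant_id = vapply(fields, `[`, "", 3),
    chromosome = vapply(fields, `[`, "", 1),
    position = as.integer(vapply(fields, `[`, "", 2)),
    ref = vapply(fields, `[`, "", 4), alt = vapply(fields, `[`, "", 5),
    stringsAsFactors = FALSE)
  dos <- vapply(fields, function(f) {
    gts <- substr(f[-(1:9)], 1, 3)
    as.integer(substr(gts, 1, 1) == "1") + as.integer(substr(gts, 3, 3) == "1")
  }, integer(length(ids)))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = length(ids))
  dimnames(dos) <- list(ids, v$variant_id)
  structure(list(dosages = dos, variants = v, individuals = ids),
            class = "genotype_panel")
}

#' Deterministic epigenome oracle
#'
#' Stand-in for an external sequence-to-epigenome predictor. Returns the
#' full tracks x 896-bin feature matrix for one gene and one cis dosage
#' vector: a fixed per-gene baseline (track-level values spread across bins
#' by a smooth TSS-centred profile whose mean over the central four bins is
#' exactly 1) plus, per cell-type track group, the planted linear dosage
#' effects and (for nonlinear genes) the dosage-product interaction, all
#' confined to the central four bins. Identical inputs always give
#' identical output; no RNG is consumed.
#'
#' @param truth a [sim_truth()].
#' @param gene_id gene identifier.
#' @param dosages dosage vector over the gene's cis SNPs (in truth order).
#' @return numeric matrix `n_tracks x 896`.
#' @export
epigenome_oracle <- function(truth, gene_id, dosages) {
  stopifnot(inherits(truth, "sim_truth"))
  gi <- match(gene_id, truth$genes$gene_id)
  assert_that(!is.na(gi), sprintf("unknown gene '%s'", gene_id))
  assert_that(length(dosages) == truth$config$snps_per_gene,
              "dosage vector does not cover the gene's cis SNPs")
  m <- outer(truth$track_base[gi, ], oracle_bin_profile())
  for (ct in seq_along(truth$cell_types)) {
    info <- truth$causal[[gene_id]][[truth$cell_types[ct]]]
    g <- sum(info$effects * dosages[info$snp_idx])
    if (info$interaction != 0) {
      g <- g + info$interaction * dosages[info$snp_idx[1]] *
        dosages[info$snp_idx[2]]
    }
    m[truth$track_groups[[ct]], CENTRAL_BINS] <-
      m[truth$track_groups[[ct]], CENTRAL_BINS] + g
  }
  m
}

# Smooth TSS-centred bin profile, normalized so that its mean over the
# central four bins is exactly 1 (bin aggregation then reproduces the
# track-level baseline values exactly).
oracle_bin_profile <- function() {
  b <- seq_len(N_BINS)
  prof <- exp(-((b - (N_BINS + 1) / 2)^2) / (2 * 150^2))
  prof / mean(prof[CENTRAL_BINS])
}

# Aggregated (central-four-bin) feature vector straight from the closed
# form, without materializing the bins x tracks matrix. Used by the oracle
# backend's fast path; equality with aggregating epigenome_oracle() output
# is asserted in the tests.
oracle_feature_vector <- function(truth, gene_id, dosages) {
  gi <- match(gene_id, truth$genes$gene_id)
  f <- truth$track_base[gi, ]
  for (ct in seq_along(truth$cell_types)) {
    info <- truth$causal[[gene_id]][[truth$cell_types[ct]]]
    g <- sum(info$effects * dosages[info$snp_idx])
    if (info$interaction != 0) {
      g <- g + info$interaction * dosages[info$snp_idx[1]] *
        dosages[info$snp_idx[2]]
    }
    f[truth$track_groups[[ct]]] <- f[truth$track_groups[[ct]]] + g
  }
  f
}

#' Simulate single-cell counts and pseudobulk metadata
#'
#' For each (individual, cell type) draws `n_cells_per_ind` cells; each
#' cell's per-gene count is negative binomial with mean
#' `ct_scale * exp(count_log_mean + expr_scale * s)` where `s` is the true
#' genetic expression from the ground truth, and dispersion
#' `nb_dispersion` (0 = Poisson). Returns a sparse genes x cells matrix
#' plus a cell metadata table (cell_id, individual, cell_type).
#'
#' @param truth a [sim_truth()].
#' @param panel a `genotype_panel` for the expression cohort.
#' @param seed integer seed (default derived from the config seed).
#' @return list with `counts` (dgCMatrix, genes x cells) and `metadata`.
#' @export
gen_pseudobulk_counts <- function(truth, panel, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"),
            inherits(panel, "genotype_panel"))
  cfg <- truth$config
  seed <- seed %||% derive_seed(cfg$seed, 3L)
  n_ind <- length(panel$individuals)
  cells_per <- cfg$n_cells_per_ind
  with_seed(seed, {
    mats <- list(); metas <- list()
    for (ct in seq_along(truth$cell_types)) {
      ctl <- truth$cell_types[ct]
      s <- true_expression_matrix(truth, panel, ctl)
      mu <- truth$ct_scale[ct] *
        exp(cfg$count_log_mean + cfg$expr_scale * s)
      n_cells <- n_ind * cells_per
      counts <- matrix(0L, cfg$n_genes, n_cells)
      ind_of_cell <- rep(panel$individuals, each = cells_per)
      for (j in seq_len(n_cells)) {
        m <- mu[, ind_of_cell[j]]
        counts[, j] <- if (cfg$nb_dispersion == 0) {
          stats::rpois(cfg$n_genes, m)
        } else {
          stats::rnbinom(cfg$n_genes, mu = m, size = 1 / cfg$nb_dispersion)
        }
      }
      cell_ids <- sprintf("%s_%s_c%02d", ctl,
                          rep(panel$individuals, each = cells_per),
                          rep(seq_len(cells_per), n_ind))
      mats[[ct]] <- counts
      metas[[ct]] <- data.frame(cell_id = cell_ids,
                                individual = ind_of_cell,
                                cell_type = ctl, stringsAsFactors = FALSE)
    }
    counts <- methods::as(Matrix::Matrix(do.call(cbind, mats),
                                         sparse = TRUE), "CsparseMatrix")
    metadata <- do.call(rbind, metas)
    dimnames(counts) <- list(truth$genes$gene_id, metadata$cell_id)
    list(counts = counts, metadata = metadata)
  })
}

#' Simulate GWAS summary statistics with planted causal genes
#'
#' Simulates a fresh cohort of `gwas_n` individuals from the same variant
#' frequencies and LD structure as the reference panel (per-gene blocks are
#' regenerated from per-gene derived seeds). The phenotype is
#' `sum_k effect_k * s_k + N(0, 1)` over the planted causal
#' (gene, cell type) pairs, where `s_k` is the true genetic expression.
#' Marginal per-SNP ordinary least squares then yields `beta` and `se`.
#' Setting all effects to 0 gives a null GWAS.
#'
#' @param truth a [sim_truth()].
#' @param causal_genes `data.frame(gene_id, cell_type, effect)`; defaults
#'   to the config's `causal_genes`. Must be non-empty (use zero effects
#'   for a null scan).
#' @param gwas_n cohort size (default from config; must be >= 10).
#' @param seed integer seed (default derived from the config seed).
#' @param path optional TSV output path.
#' @return data.frame with columns variant_id, chromosome, position,
#'   effect_allele, non_effect_allele, beta, se (effect allele = ALT).
#' @export
gen_gwas_sumstats <- function(truth, causal_genes = NULL, gwas_n = NULL,
                              seed = NULL, path = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  causal_genes <- causal_genes %||% cfg$causal_genes
  assert_that(!is.null(causal_genes) && nrow(causal_genes) > 0,
              "'causal_genes' must be non-empty (use effect = 0 for null)")
  n <- as.integer(gwas_n %||% cfg$gwas_n)
  assert_that(n >= 10, "gwas_n < 10")
  seed <- seed %||% derive_seed(cfg$seed, 4L)

  block_of <- function(gi) {
    rows <- which(truth$variants$gene_id == truth$genes$gene_id[gi])
    with_seed(derive_seed(seed, gi),
              sim_dosage_block(n, truth$variants$maf[rows], cfg$ld_decay))
  }
  # Phenotype from the causal genes' regenerated blocks.
  y <- with_seed(derive_seed(seed, 0L), stats::rnorm(n))
  for (k in seq_len(nrow(causal_genes))) {
    gid <- causal_genes$gene_id[k]
    gi <- match(gid, truth$genes$gene_id)
    assert_that(!is.na(gi), sprintf("unknown causal gene '%s'", gid))
    s <- true_genetic_expression(truth, gid, causal_genes$cell_type[k],
                                 block_of(gi))
    y <- y + causal_genes$effect[k] * s
  }
  yc <- y - mean(y)
  syy <- sum(yc^2)
  out <- vector("list", cfg$n_genes)
  for (gi in seq_len(cfg$n_genes)) {
    d <- block_of(gi)
    xc <- scale(d, center = TRUE, scale = FALSE)
    sxx <- colSums(xc^2)
    ok <- sxx > 0
    beta <- rep(NA_real_, ncol(d)); se <- rep(NA_real_, ncol(d))
    beta[ok] <- as.numeric(crossprod(xc[, ok, drop = FALSE], yc)) / sxx[ok]
    sig2 <- pmax(0, (syy - beta[ok]^2 * sxx[ok]) / (n - 2))
    se[ok] <- sqrt(sig2 / sxx[ok])
    rows <- which(truth$variants$gene_id == truth$genes$gene_id[gi])
    out[[gi]] <- data.frame(
      variant_id = truth$variants$variant_id[rows],
      chromosome = truth$variants$chromosome[rows],
      position = truth$variants$position[rows],
      effect_allele = truth$variants$alt[rows],
      non_effect_allele = truth$variants$ref[rows],
      beta = beta, se = se, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$beta) & res$se > 0, ]
  rownames(res) <- NULL
  if (!is.null(path)) {
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

#' Serialize a ground-truth object to JSON
#'
#' @param truth a [sim_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- unclass(truth)
  obj$config <- unclass(obj$config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth object back from JSON
#'
#' @param path JSON path written by [write_truth_json()].
#' @return a `sim_truth` object.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$causal_genes <- if (is.null(cfg$causal_genes) ||
                            length(cfg$causal_genes) == 0) NULL
    else as.data.frame(cfg$causal_genes)
  cfg <- structure(cfg, class = "sim_config")
  tb <- as.matrix(obj$track_base)
  rownames(tb) <- obj$genes$gene_id
  colnames(tb) <- NULL
  causal <- lapply(obj$causal, function(per_ct) {
    lapply(per_ct, function(x) {
      list(snp_idx = as.integer(x$snp_idx),
           effects = as.numeric(x$effects),
           interaction = as.numeric(x$interaction))
    })
  })
  # jsonlite simplifies lists of equal-length vectors to matrices; undo
  rows_as_list <- function(x, cast) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) cast(x[i, ]))
    else lapply(x, cast)
  }
  structure(list(config = cfg, genes = as.data.frame(obj$genes),
                 variants = as.data.frame(obj$variants), track_base = tb,
                 track_groups = rows_as_list(obj$track_groups, as.integer),
                 readout = rows_as_list(obj$readout, as.numeric),
                 cell_types = as.character(obj$cell_types),
                 ct_scale = as.numeric(obj$ct_scale), causal = causal),
            class = "sim_truth")
}
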