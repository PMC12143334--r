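# Pipeline module: orchestrates the three-step framework on a synthetic
# world -- (1) train the expression predictor per cell type, (2) linearize
# it into cis-SNP weights over the reference panel, (3) run the
# summary-statistics association scan -- plus the cross-cell-type
# statistics, with seeds, artifact hashes and stage toggles recorded in a
# manifest.

#' Build a pipeline configuration
#'
#' Validated hierarchical configuration. Either construct in code or load
#' from a JSON file with [read_run_config()]. Every stated default of the
#' synthetic world and the model hyperparameters is surfaced here.
#'
#' @param outdir output directory for artifacts.
#' @param seed master seed; stage seeds derive from it.
#' @param profile `"small"` or `"full"` feature-track profile.
#' @param sim named list of [sim_config()] overrides.
#' @param hyperparams named list of [ctpred_hyperparams()] overrides.
#' @param enet named list of [enet_params()] overrides.
#' @param causal_genes data.frame(gene_id, cell_type, effect) planted in
#'   the GWAS (default: none planted, a null scan with effect 0 on the
#'   first gene).
#' @param gwas_path optional external sumstats TSV; when given the
#'   simulated GWAS stage is skipped.
#' @param stages character vector of stages to run, subset of
#'   `c("simulate", "pseudobulk", "train", "linearize", "assoc", "stats")`.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L,
                       profile = c("small", "full"),
                       sim = list(), hyperparams = list(), enet = list(),
                       causal_genes = NULL, gwas_path = NULL,
                       stages = c("simulate", "pseudobulk", "train",
                                  "linearize", "assoc", "stats")) {
  profile <- match.arg(profile)
  assert_that(!missing(outdir) && is.character(outdir) &&
                length(outdir) == 1,
              "config field 'outdir' is required")
  known <- c("simulate", "pseudobulk", "train", "linearize", "assoc",
             "stats")
  bad <- setdiff(stages, known)
  assert_that(length(bad) == 0,
              paste("unknown stages:", paste(bad, collapse = ", ")))
  if (!is.null(gwas_path)) {
    assert_that(file.exists(gwas_path),
                sprintf("config field 'gwas_path': file not found: %s",
                        gwas_path))
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 profile = profile, sim = sim, hyperparams = hyperparams,
                 enet = enet, causal_genes = causal_genes,
                 gwas_path = gwas_path, stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(!is.null(obj$outdir), "config field 'outdir' is missing")
  cg <- obj$causal_genes
  if (!is.null(cg)) cg <- as.data.frame(cg)
  run_config(outdir = obj$outdir, seed = obj$seed %||% 1L,
             profile = obj$profile %||% "small",
             sim = as.list(obj$sim %||% list()),
             hyperparams = as.list(obj$hyperparams %||% list()),
             enet = as.list(obj$enet %||% list()),
             causal_genes = cg, gwas_path = obj$gwas_path,
             stages = obj$stages %||% c("simulate", "pseudobulk", "train",
                                        "linearize", "assoc", "stats"))
}

#' Run the full pipeline on a synthetic world
#'
#' Executes the enabled stages in order: synthetic-data generation,
#' QC + pseudobulk aggregation + percentile targets, per-cell-type
#' predictor training, linearization (in-silico reference, elastic nets,
#' covariances, weight database), summary-statistics association per cell
#' type, and cross-cell-type statistics (ACAT combination, Bonferroni,
#' specificity classes). Artifacts are written under `config$outdir`; a
#' manifest JSON records seeds, versions and md5 hashes of every artifact.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @param resume reload the outputs of stages missing from
#'   `config$stages` from artifacts persisted in `config$outdir` by an
#'   earlier run, so any stage can run standalone with identical results.
#' @return invisible list with all in-memory stage outputs (`truth`,
#'   `panel`, `pseudobulk`, `percentiles`, `models`, `linear`,
#'   `associations`, `stats`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- character(0)
  keep <- function(p) { art <<- c(art, p); p }
  state <- list()

  sim_args <- utils::modifyList(
    list(profile = config$profile, seed = config$seed), config$sim)
  scfg <- do.call(sim_config, sim_args)
  truth <- sim_truth(scfg)
  state$truth <- truth

  if (resume) state <- resume_state(config, state, truth)

  if ("simulate" %in% config$stages) {
    say("stage simulate: %d genes, %d individuals, %d cell types",
        scfg$n_genes, scfg$n_individuals, scfg$n_cell_types)
    panel <- gen_genotypes(truth)
    write_vcf(panel, keep(file.path(config$outdir, "panel.vcf")))
    write_truth_json(truth, keep(file.path(config$outdir, "truth.json")))
    sc <- gen_pseudobulk_counts(truth, panel)
    write_cell_counts(sc$counts, sc$metadata,
                      file.path(config$outdir, "cells"))
    keep(file.path(config$outdir, "cells", "counts.mtx"))
    utils::write.table(
      truth$genes[, c("gene_id", "chromosome", "tss", "strand")],
      keep(file.path(config$outdir, "genes.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    state$panel <- panel
    state$cells <- sc
  }

  if ("pseudobulk" %in% config$stages) {
    say("stage pseudobulk")
    sc <- state$cells
    pbs <- aggregate_pseudobulk(sc$counts, sc$metadata)
    percs <- lapply(pbs, rank_percentile)
    state$pseudobulk <- pbs
    state$percentiles <- percs
    for (ctl in names(pbs)) {
      utils::write.table(
        pbs[[ctl]]$counts,
        keep(file.path(config$outdir, sprintf("pseudobulk_%s.tsv", ctl))),
        sep = "\t", quote = FALSE)
    }
  }

  backend <- if (!is.null(state$panel)) {
    oracle_backend(truth, state$panel)
  }
  state$backend <- backend

  if ("train" %in% config$stages) {
    hp <- do.call(ctpred_hyperparams,
                  utils::modifyList(list(seed = derive_seed(config$seed,
                                                            11L)),
                                    config$hyperparams))
    split <- split_by_chromosome(truth$genes,
                                 seed = derive_seed(config$seed, 12L))
    feats <- reference_feature_matrix(backend, truth$genes$gene_id)
    models <- list()
    for (ctl in truth$cell_types) {
      say("stage train: cell type %s", ctl)
      models[[ctl]] <- train_ctpred(feats, state$percentiles[[ctl]],
                                    split, hp, cell_type = ctl)
      write_ctpred(models[[ctl]],
                   keep(file.path(config$outdir,
                                  sprintf("ctpred_%s.json", ctl))))
    }
    state$models <- models
    state$features <- feats
  }

  if ("linearize" %in% config$stages) {
    ep <- do.call(enet_params,
                  utils::modifyList(list(seed = derive_seed(config$seed,
                                                            13L)),
                                    config$enet))
    linear <- list()
    for (ctl in truth$cell_types) {
      say("stage linearize: cell type %s", ctl)
      insilico <- build_insilico_reference(state$models[[ctl]], backend,
                                           state$panel,
                                           truth$genes$gene_id)
      fits <- lapply(seq_len(nrow(truth$genes)), function(gi) {
        fit_elastic_net(truth$genes[gi, ],
                        insilico$expr[truth$genes$gene_id[gi], ],
                        state$panel, ep, cell_type = ctl)
      })
      names(fits) <- truth$genes$gene_id
      conv <- Filter(function(m) isTRUE(m$converged), fits)
      covs <- compute_covariance(state$panel, conv)
      db <- keep(file.path(config$outdir, sprintf("weights_%s.db", ctl)))
      cv <- keep(file.path(config$outdir,
                           sprintf("covariance_%s.txt", ctl)))
      if (length(conv) > 0) export_weights(conv, covs, db, cv)
      linear[[ctl]] <- list(insilico = insilico, fits = fits,
                            covariances = covs, db = db, cov_file = cv)
    }
    state$linear <- linear
  }

  if ("assoc" %in% config$stages) {
    gwas <- if (!is.null(config$gwas_path)) {
      read_gwas(config$gwas_path)
    } else {
      cg <- config$causal_genes %||%
        data.frame(gene_id = truth$genes$gene_id[1],
                   cell_type = truth$cell_types[1], effect = 0)
      g <- gen_gwas_sumstats(truth, causal_genes = cg,
                             seed = derive_seed(config$seed, 14L),
                             path = keep(file.path(config$outdir,
                                                   "gwas.tsv")))
      structure(g, class = c("gwas_sumstats", "data.frame"))
    }
    assoc <- list()
    for (ctl in truth$cell_types) {
      say("stage assoc: cell type %s", ctl)
      conv <- Filter(function(m) isTRUE(m$converged),
                     state$linear[[ctl]]$fits)
      a <- run_association(conv, state$linear[[ctl]]$covariances, gwas)
      utils::write.table(
        a$results,
        keep(file.path(config$outdir, sprintf("assoc_%s.tsv", ctl))),
        sep = "\t", quote = FALSE, row.names = FALSE)
      assoc[[ctl]] <- a
    }
    state$associations <- assoc
  }

  if ("stats" %in% config$stages) {
    say("stage stats")
    all_res <- do.call(rbind, lapply(state$associations,
                                     function(a) a$results))
    thresholds <- vapply(state$associations, function(a) {
      bonferroni_threshold(max(1L, nrow(a$results)))
    }, numeric(1))
    spec <- if (length(state$associations) >= 2) {
      classify_specificity(all_res, thresholds)
    } else {
      NULL
    }
    acat_by_gene <- vapply(split(all_res$pvalue, all_res$gene_id),
                           acat_combine, numeric(1))
    stats_out <- list(
      thresholds = as.list(thresholds),
      n_significant = as.list(vapply(names(state$associations),
        function(ctl) {
          r <- state$associations[[ctl]]$results
          sum(r$pvalue < thresholds[[ctl]])
        }, numeric(1))),
      acat_combined = acat_by_gene,
      specificity = spec)
    jsonlite::write_json(
      stats_out, keep(file.path(config$outdir, "stats.json")),
      digits = NA, auto_unbox = TRUE, dataframe = "rows", null = "null")
    state$stats <- stats_out
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("celltwas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, profile = config$profile,
    stages = config$stages,
    artifacts = as.list(tools::md5sum(art[file.exists(art)])))
  jsonlite::write_json(manifest, file.path(config$outdir,
                                           "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  state$manifest <- manifest
  invisible(state)
}

# Reload persisted artifacts for the stages this run does not execute.
resume_state <- function(config, state, truth) {
  d <- config$outdir
  want <- config$stages
  if (!("simulate" %in% want)) {
    vcf <- file.path(d, "panel.vcf")
    if (file.exists(vcf)) state$panel <- read_vcf_dosages(vcf)
    cells <- file.path(d, "cells")
    if (file.exists(file.path(cells, "counts.mtx"))) {
      state$cells <- read_cell_counts(cells)
    }
  }
  if (!("pseudobulk" %in% want)) {
    pbs <- list()
    for (ctl in truth$cell_types) {
      f <- file.path(d, sprintf("pseudobulk_%s.tsv", ctl))
      if (!file.exists(f)) next
      m <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                       check.names = FALSE))
      pbs[[ctl]] <- structure(list(cell_type = ctl, counts = m,
                                   n_cells = rep(NA_integer_, ncol(m))),
                              class = "pseudobulk_matrix")
    }
    if (length(pbs)) {
      state$pseudobulk <- pbs
      state$percentiles <- lapply(pbs, rank_percentile)
    }
  }
  if (!("train" %in% want)) {
    models <- list()
    for (ctl in truth$cell_types) {
      f <- file.path(d, sprintf("ctpred_%s.json", ctl))
      if (file.exists(f)) models[[ctl]] <- read_ctpred(f)
    }
    if (length(models)) state$models <- models
  }
  if (!("linearize" %in% want)) {
    linear <- list()
    for (ctl in truth$cell_types) {
      db <- file.path(d, sprintf("weights_%s.db", ctl))
      cv <- file.path(d, sprintf("covariance_%s.txt", ctl))
      if (!file.exists(db)) next
      fits <- read_weights(db)
      for (i in seq_along(fits)) fits[[i]]$cell_type <- ctl
      linear[[ctl]] <- list(fits = fits,
                            covariances = read_covariance(cv),
                            db = db, cov_file = cv)
    }
    if (length(linear)) state$linear <- linear
  }
  if (!("assoc" %in% want)) {
    assoc <- list()
    for (ctl in truth$cell_types) {
      f <- file.path(d, sprintf("assoc_%s.tsv", ctl))
      if (!file.exists(f)) next
      assoc[[ctl]] <- list(results = utils::read.table(
        f, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
    }
    if (length(assoc)) state$associations <- assoc
  }
  state
}

#' Command-line entry point
#'
#' `celltwas_cli(c("pipeline", "--config", "cfg.json"))` runs the full
#' pipeline from a JSON configuration; `--seed` and `--outdir` override
#' the config. A single stage name (`simulate`, `pseudobulk`, `train`,
#' `linearize`, `assoc`, `stats`) instead of `pipeline` runs that stage
#' standalone, resuming from artifacts persisted in the output directory.
#' Exposed for `Rscript -e 'celltwas::celltwas_cli()'` use.
#'
#' @param args character vector (default: `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
celltwas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c("simulate", "pseudobulk", "train", "linearize", "assoc",
              "stats")
  usage <- paste("usage: celltwas <pipeline|", paste(stages,
                                                     collapse = "|"),
                 "> --config <file.json> [--seed <int>] [--outdir <dir>]")
  if (length(args) == 0 || !(args[1] %in% c("pipeline", stages))) {
    message(usage); return(invisible(1L))
  }
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  cfg_path <- get_opt("--config")
  assert_that(!is.null(cfg_path), "missing --config")
  cfg <- read_run_config(cfg_path)
  seed <- get_opt("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outdir <- get_opt("--outdir")
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (args[1] == "pipeline") {
    run_pipeline(cfg)
  } else {
    cfg$stages <- args[1]
    run_pipeline(cfg, resume = TRUE)
  }
  invisible(0L)
}
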