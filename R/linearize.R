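# Linearization module: build an in-silico expression reference from the
# nonlinear predictor, fit per-gene cis-SNP elastic nets against it
# (and against observed pseudobulk percentiles as the canonical baseline),
# validate with 10-fold cross-validated Spearman correlation, and export
# weights/covariances in PredictDB-compatible form.

#' Elastic-net fitting parameters
#'
#' @param alpha elastic-net mixing parameter (0.5, the PrediXcan default).
#' @param maf_min minimum minor allele frequency for a cis SNP to enter
#'   the design (default 0.01).
#' @param nfolds folds for the internal penalty-selection CV (default 10).
#' @param cis_window cis-window half-width around the TSS in bp
#'   (default 1e6, the PrediXcan standard).
#' @param lambda_rule `"1se"` (default) or `"min"`: which CV-selected
#'   penalty defines the fitted model. The one-standard-error rule is the
#'   conservative glmnet convention; with `"min"` and small noisy cohorts,
#'   ~40% of pure-noise genes "converge" on spuriously selected SNPs,
#'   which makes convergence counts meaningless.
#' @param seed fold-assignment seed.
#' @return object of class `enet_params`.
#' @export
enet_params <- function(alpha = 0.5, maf_min = 0.01, nfolds = 10L,
                        cis_window = 1e6,
                        lambda_rule = c("1se", "min"), seed = 1L) {
  assert_that(alpha >= 0 && alpha <= 1, "alpha must be in [0, 1]")
  lambda_rule <- match.arg(lambda_rule)
  structure(list(alpha = alpha, maf_min = maf_min,
                 nfolds = as.integer(nfolds), cis_window = cis_window,
                 lambda_rule = lambda_rule, seed = as.integer(seed)),
            class = "enet_params")
}

#' Build the in-silico expression reference panel
#'
#' Runs the trained predictor on personalized feature vectors for every
#' (gene, individual) of a genotype panel, producing a genes x individuals
#' matrix of predicted expression percentiles. Deterministic given the
#' model and genotypes. This matrix carries only the genetic component of
#' expression, which is what makes the downstream elastic nets converge
#' for most genes.
#'
#' @param model a `ctpred_model`.
#' @param backend an `epigenome_backend` able to personalize every
#'   (gene, individual).
#' @param panel a `genotype_panel`.
#' @param gene_ids genes to include (default: all genes the backend's
#'   truth knows, supplied explicitly).
#' @return object of class `insilico_reference`: list with `expr`
#'   (genes x individuals matrix), `cell_type`, `provenance`.
#' @export
build_insilico_reference <- function(model, backend, panel, gene_ids) {
  stopifnot(inherits(model, "ctpred_model"),
            inherits(backend, "epigenome_backend"),
            inherits(panel, "genotype_panel"))
  inds <- panel$individuals
  expr <- matrix(NA_real_, length(gene_ids), length(inds),
                 dimnames = list(gene_ids, inds))
  for (g in gene_ids) {
    feats <- t(vapply(inds, function(i) backend_features(backend, g, i),
                      numeric(backend$n_tracks)))
    expr[g, ] <- predict(model, feats)
  }
  structure(list(expr = expr, cell_type = model$cell_type,
                 provenance = list(backend = backend$name,
                                   best_epoch = model$best_epoch)),
            class = "insilico_reference")
}

# Cis design matrix for one gene: dosage columns within the cis window,
# MAF- and variance-filtered. Returns NULL if fewer than 2 usable SNPs.
cis_design <- function(gene, panel, params) {
  v <- panel$variants
  sel <- v$chromosome == gene$chromosome &
    v$position >= gene$tss - params$cis_window &
    v$position <= gene$tss + params$cis_window
  if (!any(sel)) return(NULL)
  X <- panel$dosages[, which(sel), drop = FALSE]
  freq <- colMeans(X) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= params$maf_min & apply(X, 2, stats::sd) > 0
  if (sum(keep) < 2) return(NULL)
  list(X = X[, keep, drop = FALSE], variants = v[which(sel)[keep], ,
                                                 drop = FALSE])
}

#' Fit a per-gene cis-SNP elastic net
#'
#' Mixing parameter `alpha` (default 0.5), penalty chosen by internal
#' 10-fold cross-validation (`lambda.min`). A model "converges" iff at
#' least one SNP weight is nonzero at the selected penalty; constant
#' expression or an empty cis design yield a non-converged record (not an
#' error). Weights are reported on the counted (ALT) allele; dosages enter
#' raw (unstandardized) with an intercept.
#'
#' @param gene one-row gene annotation (needs gene_id, chromosome, tss).
#' @param expr_row numeric vector of expression values, named by
#'   individual, aligned with `panel` rows.
#' @param panel a `genotype_panel`.
#' @param params an [enet_params()].
#' @param cell_type label stored on the model.
#' @param target `"insilico"` or `"observed"`.
#' @return object of class `linear_gene_model`; check `$converged`.
#' @export
fit_elastic_net <- function(gene, expr_row, panel,
                            params = enet_params(),
                            cell_type = "unknown", target = "insilico") {
  stopifnot(inherits(params, "enet_params"))
  not_converged <- function(reason) {
    structure(list(gene_id = gene$gene_id, cell_type = cell_type,
                   converged = FALSE, reason = reason, target = target),
              class = "linear_gene_model")
  }
  if (stats::sd(expr_row) == 0) return(not_converged("constant expression"))
  d <- cis_design(gene, panel, params)
  if (is.null(d)) return(not_converged("fewer than 2 usable cis SNPs"))
  n <- length(expr_row)
  gene_tag <- sum(utf8ToInt(as.character(gene$gene_id)))
  foldid <- with_seed(derive_seed(params$seed, gene_tag),
                      sample(rep_len(seq_len(params$nfolds), n)))
  cvfit <- glmnet::cv.glmnet(d$X, expr_row, alpha = params$alpha,
                             foldid = foldid, standardize = TRUE)
  s_lambda <- paste0("lambda.", params$lambda_rule)
  co <- as.numeric(stats::coef(cvfit, s = s_lambda))
  nz <- which(co[-1] != 0)
  if (length(nz) == 0) return(not_converged("all weights zero"))
  structure(list(gene_id = gene$gene_id, cell_type = cell_type,
                 converged = TRUE,
                 intercept = co[1],
                 weights = co[-1][nz],
                 variants = d$variants[nz, , drop = FALSE],
                 n_snps = length(nz),
                 lambda = cvfit[[s_lambda]],
                 cv_spearman = NA_real_, target = target),
            class = "linear_gene_model")
}

#' Predict expression from a linear gene model
#'
#' `intercept + sum_l weight_l * dosage_l` over the model's variants.
#'
#' @param object a converged `linear_gene_model`.
#' @param panel a `genotype_panel` containing the model's variants.
#' @param ... unused.
#' @return named numeric vector over the panel's individuals.
#' @export
predict.linear_gene_model <- function(object, panel, ...) {
  assert_that(isTRUE(object$converged), "model did not converge")
  miss <- setdiff(object$variants$variant_id, colnames(panel$dosages))
  assert_that(length(miss) == 0,
              paste("variants absent from panel:",
                    paste(utils::head(miss, 5), collapse = ", ")))
  X <- panel$dosages[, object$variants$variant_id, drop = FALSE]
  as.numeric(X %*% object$weights) + object$intercept
}

#' 10-fold cross-validated Spearman correlation of the linearization
#'
#' Splits individuals into `folds` folds; for each fold fits the elastic
#' net on the remainder (penalty re-selected by internal CV; the
#' prediction-optimal `lambda.min` is always used here since this measures
#' best-achievable fidelity, not model parsimony) and predicts
#' the held-out individuals. The Spearman correlation between the
#' assembled out-of-fold linear predictions and the original (nonlinear
#' predictor's) values measures how well a linear cis-SNP model can mimic
#' the predictor for that gene.
#'
#' @inheritParams fit_elastic_net
#' @param folds number of outer folds (default 10).
#' @param seed fold-assignment seed.
#' @return Spearman correlation (NA if a fold fails to converge and
#'   predictions are constant).
#' @export
cv_spearman <- function(gene, expr_row, panel, params = enet_params(),
                        folds = 10L, seed = 1L) {
  n <- length(expr_row)
  assert_that(folds <= n, "more folds than individuals")
  if (stats::sd(expr_row) == 0) return(NA_real_)
  d <- cis_design(gene, panel, params)
  if (is.null(d)) return(NA_real_)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  oof <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    tr <- fold_of != k
    Xtr <- d$X[tr, , drop = FALSE]
    keep <- apply(Xtr, 2, stats::sd) > 0
    if (sum(keep) < 2 || stats::sd(expr_row[tr]) == 0) {
      oof[!tr] <- mean(expr_row[tr]); next
    }
    cvfit <- glmnet::cv.glmnet(Xtr[, keep, drop = FALSE], expr_row[tr],
                               alpha = params$alpha,
                               nfolds = min(params$nfolds, sum(tr)),
                               standardize = TRUE)
    oof[!tr] <- as.numeric(stats::predict(
      cvfit, newx = d$X[!tr, keep, drop = FALSE], s = "lambda.min"))
  }
  safe_cor(oof, expr_row, method = "spearman")
}

#' Canonical observed-expression elastic net (pseudobulk baseline)
#'
#' Identical machinery to [fit_elastic_net()] but targeting observed
#' per-individual pseudobulk expression percentiles; the comparison
#' baseline for the in-silico-trained models.
#'
#' @inheritParams fit_elastic_net
#' @export
fit_pen <- function(gene, expr_row, panel, params = enet_params(),
                    cell_type = "unknown") {
  fit_elastic_net(gene, expr_row, panel, params, cell_type,
                  target = "observed")
}

#' Reference-panel dosage covariance for each gene model
#'
#' Sample covariance (denominator n-1) of the model variants' dosages over
#' the reference individuals; the Gamma matrix of the summary-statistics
#' association test. Symmetric positive-semidefinite by construction.
#'
#' @param panel a `genotype_panel`.
#' @param models list of converged `linear_gene_model`s.
#' @return named list of covariance matrices (one per gene).
#' @export
compute_covariance <- function(panel, models) {
  models <- Filter(function(m) isTRUE(m$converged), models)
  out <- lapply(models, function(m) {
    miss <- setdiff(m$variants$variant_id, colnames(panel$dosages))
    assert_that(length(miss) == 0,
                paste("variant absent from panel:",
                      paste(utils::head(miss, 3), collapse = ", ")))
    X <- panel$dosages[, m$variants$variant_id, drop = FALSE]
    stats::cov(X)
  })
  names(out) <- vapply(models, `[[`, "", "gene_id")
  out
}

#' Export weights and covariances (PredictDB-style)
#'
#' Writes an SQLite weight database with tables
#' `weights(gene, rsid, varID, ref_allele, eff_allele, weight)` and
#' `extra(gene, n_snps, cv_performance, intercept)` (the intercept lives
#' in `extra` to keep the `weights` schema PredictDB-compatible), plus a
#' whitespace-delimited covariance file `GENE RSID1 RSID2 VALUE` covering
#' the upper triangle including the diagonal.
#'
#' @param models list of `linear_gene_model`s (non-converged are skipped).
#' @param covariances output of [compute_covariance()].
#' @param db_path SQLite database path.
#' @param cov_path covariance text file path.
#' @return invisible list with counts of exported genes and rows.
#' @export
export_weights <- function(models, covariances, db_path, cov_path) {
  models <- Filter(function(m) isTRUE(m$converged), models)
  assert_that(length(models) > 0, "no converged models to export")
  wt <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene = m$gene_id, rsid = m$variants$variant_id,
               varID = paste(m$variants$chromosome, m$variants$position,
                             m$variants$ref, m$variants$alt, sep = "_"),
               ref_allele = m$variants$ref, eff_allele = m$variants$alt,
               weight = m$weights, stringsAsFactors = FALSE)
  }))
  dup <- duplicated(wt[, c("gene", "rsid")])
  assert_that(!any(dup),
              paste("duplicate (gene, rsid) pairs:",
                    paste(utils::head(wt$rsid[dup], 3), collapse = ", ")))
  extra <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene = m$gene_id, n_snps = m$n_snps,
               cv_performance = m$cv_spearman, intercept = m$intercept,
               stringsAsFactors = FALSE)
  }))
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbWriteTable(con, "weights", wt, overwrite = TRUE)
  DBI::dbWriteTable(con, "extra", extra, overwrite = TRUE)
  cov_rows <- unlist(lapply(names(covariances), function(g) {
    G <- covariances[[g]]
    ids <- colnames(G)
    rows <- character(0)
    for (i in seq_along(ids)) {
      for (j in i:length(ids)) {
        rows <- c(rows, paste(g, ids[i], ids[j],
                              format(G[i, j], digits = 17)))
      }
    }
    rows
  }))
  writeLines(c("GENE RSID1 RSID2 VALUE", cov_rows), cov_path)
  invisible(list(n_genes = length(models), n_weights = nrow(wt),
                 n_cov_rows = length(cov_rows)))
}

#' Read a weight database back into linear gene models
#'
#' @param db_path SQLite path written by [export_weights()].
#' @return named list of `linear_gene_model`s.
#' @export
read_weights <- function(db_path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  wt <- DBI::dbReadTable(con, "weights")
  extra <- DBI::dbReadTable(con, "extra")
  out <- lapply(seq_len(nrow(extra)), function(i) {
    g <- extra$gene[i]
    rows <- wt[wt$gene == g, , drop = FALSE]
    parts <- strsplit(rows$varID, "_")
    structure(list(
      gene_id = g, cell_type = NA_character_, converged = TRUE,
      intercept = extra$intercept[i], weights = rows$weight,
      variants = data.frame(
        variant_id = rows$rsid,
        chromosome = vapply(parts, `[`, "", 1),
        position = as.integer(vapply(parts, `[`, "", 2)),
        ref = rows$ref_allele, alt = rows$eff_allele,
        stringsAsFactors = FALSE),
      n_snps = extra$n_snps[i], cv_spearman = extra$cv_performance[i],
      target = NA_character_), class = "linear_gene_model")
  })
  names(out) <- extra$gene
  out
}

#' Read a covariance file back into matrices
#'
#' @param cov_path path written by [export_weights()].
#' @return named list of symmetric covariance matrices.
#' @export
read_covariance <- function(cov_path) {
  tab <- utils::read.table(cov_path, header = TRUE,
                           stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(tab$GENE)) {
    sub <- tab[tab$GENE == g, , drop = FALSE]
    ids <- unique(c(sub$RSID1, sub$RSID2))
    G <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (k in seq_len(nrow(sub))) {
      G[sub$RSID1[k], sub$RSID2[k]] <- sub$VALUE[k]
      G[sub$RSID2[k], sub$RSID1[k]] <- sub$VALUE[k]
    }
    out[[g]] <- G
  }
  out
}
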