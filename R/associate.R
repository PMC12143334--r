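# Association module: harmonize GWAS summary statistics against gene
# models and compute the summary-statistics gene-trait Z-score
#   Z_g = sum_l w_{g,l} * (sigma_l / sigma_g) * (beta_l / se_l),
# with sigma_l = sqrt(Gamma_ll) and sigma_g = sqrt(w' Gamma w) taken from
# the reference-panel dosage covariance over the matched SNPs.

#' Read GWAS summary statistics from TSV
#'
#' Expected columns (renameable via `column_map`): variant_id, chromosome,
#' position, effect_allele, non_effect_allele, beta, se.
#'
#' @param path TSV path.
#' @param column_map named character vector mapping expected -> actual
#'   column names, e.g. `c(beta = "BETA")`.
#' @return validated data.frame of class `gwas_sumstats`.
#' @export
read_gwas <- function(path, column_map = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (k in names(column_map)) {
      names(tab)[names(tab) == column_map[[k]]] <- k
    }
  }
  need <- c("variant_id", "chromosome", "position", "effect_allele",
            "non_effect_allele", "beta", "se")
  assert_that(all(need %in% names(tab)),
              paste("sumstats missing columns:",
                    paste(setdiff(need, names(tab)), collapse = ", ")))
  bad <- which(!is.finite(tab$beta) | !is.finite(tab$se) | tab$se <= 0 |
                 tab$effect_allele == tab$non_effect_allele)
  if (length(bad) > 0) {
    stop(sprintf("malformed sumstats at line %d (of the data rows): %s",
                 bad[1], "non-finite beta/se, se <= 0, or equal alleles"),
         call. = FALSE)
  }
  structure(tab, class = c("gwas_sumstats", "data.frame"))
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize GWAS records against a gene model's variants
#'
#' Variants are matched by (chromosome, position); when that yields
#' nothing for a SNP, by variant id. Matched records where the GWAS effect
#' allele equals the model's counted allele keep their beta; records with
#' swapped alleles get beta negated; strand-ambiguous palindromic pairs
#' (A/T, C/G) are dropped by default; allele sets that match neither way
#' are dropped. Unmatched model SNPs are counted, not imputed.
#'
#' @param gwas a `gwas_sumstats` data.frame.
#' @param model a converged `linear_gene_model`.
#' @param drop_ambiguous drop palindromic variants (default TRUE).
#' @return list with `matched` (data.frame: variant_id, weight, beta, se,
#'   flipped), `n_snps_in_model`, `n_snps_used`, `n_dropped_ambiguous`,
#'   `n_dropped_mismatch`, `n_unmatched`.
#' @export
harmonize <- function(gwas, model, drop_ambiguous = TRUE) {
  assert_that(isTRUE(model$converged), "model did not converge")
  mv <- model$variants
  key_g <- paste(gwas$chromosome, gwas$position)
  rows <- list(); amb <- 0L; mism <- 0L; unm <- 0L
  for (i in seq_len(nrow(mv))) {
    j <- which(key_g == paste(mv$chromosome[i], mv$position[i]))
    if (length(j) == 0) j <- which(gwas$variant_id == mv$variant_id[i])
    if (length(j) == 0) { unm <- unm + 1L; next }
    j <- j[1]
    ea <- gwas$effect_allele[j]; oa <- gwas$non_effect_allele[j]
    if (drop_ambiguous && is_ambiguous_pair(ea, oa)) {
      amb <- amb + 1L; next
    }
    if (ea == mv$alt[i] && oa == mv$ref[i]) {
      flipped <- FALSE; beta <- gwas$beta[j]
    } else if (ea == mv$ref[i] && oa == mv$alt[i]) {
      flipped <- TRUE; beta <- -gwas$beta[j]
    } else {
      mism <- mism + 1L; next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = mv$variant_id[i], weight = model$weights[i],
      beta = beta, se = gwas$se[j], flipped = flipped,
      stringsAsFactors = FALSE)
  }
  matched <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), weight = numeric(0),
               beta = numeric(0), se = numeric(0), flipped = logical(0))
  list(matched = matched, n_snps_in_model = nrow(mv),
       n_snps_used = nrow(matched), n_dropped_ambiguous = amb,
       n_dropped_mismatch = mism, n_unmatched = unm)
}

#' Summary-statistics gene-trait Z-score
#'
#' Computes `Z_g = sum_l w_l * (sigma_l / sigma_g) * (beta_l / se_l)` over
#' the harmonized SNPs, with `sigma_l = sqrt(Gamma_ll)` and
#' `sigma_g = sqrt(w' Gamma w)` recomputed on the matched subset of the
#' reference covariance (missing SNPs are dropped, not imputed). The
#' two-tailed p-value is the standard-normal tail probability of `|Z_g|`;
#' `log10_pvalue` is computed on the log scale and remains finite far
#' below the double-precision underflow point.
#'
#' @param model a converged `linear_gene_model`.
#' @param harmonized output of [harmonize()].
#' @param cov_mat reference covariance matrix over (at least) the model's
#'   variants.
#' @return object of class `association_result`: list with gene_id,
#'   cell_type, zscore, pvalue, log10_pvalue, sigma_g, n_snps_used,
#'   n_snps_in_model, undefined flag.
#' @export
spredixcan_z <- function(model, harmonized, cov_mat) {
  m <- harmonized$matched
  base <- list(gene_id = model$gene_id, cell_type = model$cell_type,
               zscore = NA_real_, pvalue = NA_real_,
               log10_pvalue = NA_real_, sigma_g = NA_real_,
               n_snps_used = harmonized$n_snps_used,
               n_snps_in_model = harmonized$n_snps_in_model,
               undefined = TRUE)
  if (nrow(m) == 0) return(structure(base, class = "association_result"))
  ids <- m$variant_id
  assert_that(all(ids %in% colnames(cov_mat)),
              "covariance matrix missing model variants")
  G <- cov_mat[ids, ids, drop = FALSE]
  w <- m$weight
  var_g <- as.numeric(t(w) %*% G %*% w)
  if (var_g <= 0) return(structure(base, class = "association_result"))
  sigma_l <- sqrt(diag(G))
  sigma_g <- sqrt(var_g)
  z <- sum(w * (sigma_l / sigma_g) * (m$beta / m$se))
  lp <- (stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) +
           log(2)) / log(10)
  base$zscore <- z
  base$pvalue <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  base$log10_pvalue <- lp
  base$sigma_g <- sigma_g
  base$undefined <- FALSE
  structure(base, class = "association_result")
}

#' Run the association scan for one cell type
#'
#' Applies [harmonize()] and [spredixcan_z()] to every converged gene
#' model. Genes with undefined scores (no matched SNPs or zero predicted
#' variance) are reported separately and excluded from the result table so
#' they never enter multiple-testing corrections.
#'
#' @param models list of `linear_gene_model`s, or a path to a weight
#'   database written by [export_weights()].
#' @param covariances list of covariance matrices, or a covariance file
#'   path.
#' @param gwas a `gwas_sumstats` data.frame, or a sumstats TSV path.
#' @param drop_ambiguous passed to [harmonize()].
#' @return list with `results` (data.frame: gene_id, cell_type, zscore,
#'   pvalue, log10_pvalue, sigma_g, n_snps_used, n_snps_in_model) and
#'   `undefined` (data.frame of skipped genes with drop counts).
#' @export
run_association <- function(models, covariances, gwas,
                            drop_ambiguous = TRUE) {
  if (is.character(models)) models <- read_weights(models)
  if (is.character(covariances)) covariances <- read_covariance(covariances)
  if (is.character(gwas)) gwas <- read_gwas(gwas)
  models <- Filter(function(m) isTRUE(m$converged), models)
  res <- list(); und <- list()
  for (m in models) {
    h <- harmonize(gwas, m, drop_ambiguous = drop_ambiguous)
    G <- covariances[[m$gene_id]]
    if (is.null(G)) {
      und[[length(und) + 1L]] <- data.frame(
        gene_id = m$gene_id, reason = "no covariance",
        stringsAsFactors = FALSE)
      next
    }
    a <- spredixcan_z(m, h, G)
    if (a$undefined) {
      und[[length(und) + 1L]] <- data.frame(
        gene_id = m$gene_id,
        reason = if (h$n_snps_used == 0) "no matched SNPs"
          else "zero predicted variance", stringsAsFactors = FALSE)
    } else {
      res[[length(res) + 1L]] <- data.frame(
        gene_id = a$gene_id, cell_type = a$cell_type, zscore = a$zscore,
        pvalue = a$pvalue, log10_pvalue = a$log10_pvalue,
        sigma_g = a$sigma_g, n_snps_used = a$n_snps_used,
        n_snps_in_model = a$n_snps_in_model, stringsAsFactors = FALSE)
    }
  }
  list(results = if (length(res)) do.call(rbind, res) else
         data.frame(gene_id = character(0)),
       undefined = if (length(und)) do.call(rbind, und) else
         data.frame(gene_id = character(0), reason = character(0)))
}
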