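# Multi-cell-type statistics: Cauchy (ACAT) p-value combination,
# Bonferroni thresholds, Storey pi1/m1 true-positive estimation,
# precision/recall against a silver-standard gene list, LD-block
# accounting, and cell-type specificity classification.

#' Cauchy (ACAT) combination of p-values
#'
#' `T = sum_i w_i tan((0.5 - p_i) pi) / sum_i w_i`; combined
#' `p = 0.5 - arctan(T)/pi`. Very small p (< 1e-15) use the tangent
#' asymptote `tan((0.5 - p) pi) ~ 1/(p pi)`, and a very large `T` maps
#' back through `p ~ 1/(T pi)`, keeping the combination finite and
#' monotone down to the smallest representable p-values. p-values of
#' exactly 1 are floored to `1 - 1e-16` (the transform diverges at 1).
#' Robust to dependence between the component tests.
#'
#' @param pvalues numeric vector in (0, 1].
#' @param weights optional non-negative weights, not all zero
#'   (default equal).
#' @return combined p-value.
#' @export
acat_combine <- function(pvalues, weights = NULL) {
  assert_that(length(pvalues) >= 1, "empty p-value list")
  assert_that(all(is.finite(pvalues)) && all(pvalues > 0) &&
                all(pvalues <= 1),
              "p-values must lie in (0, 1]; floor zero p upstream")
  w <- weights %||% rep(1, length(pvalues))
  assert_that(length(w) == length(pvalues) && all(w >= 0) && any(w > 0),
              "weights must be non-negative and not all zero")
  p <- pmin(pvalues, 1 - 1e-16)
  # tanpi((0.5 - p)) keeps full precision near both tails; below 1e-15 the
  # tangent asymptote 1/(p*pi) avoids cancellation entirely
  t_i <- numeric(length(p))
  tiny <- p < 1e-15
  t_i[tiny] <- 1 / (p[tiny] * pi)
  t_i[!tiny] <- tanpi(0.5 - p[!tiny])
  T_stat <- sum(w * t_i) / sum(w)
  # complementary inverse for positive T: 0.5 - atan(T)/pi == atan(1/T)/pi,
  # but the right-hand form does not cancel for small combined p
  if (T_stat > 0) atan(1 / T_stat) / pi else 0.5 - atan(T_stat) / pi
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  assert_that(is_count(n_tests), "n_tests must be a count >= 1")
  alpha / n_tests
}

#' Storey estimate of the true-positive proportion (pi1) and count (m1)
#'
#' `pi0(lambda) = #{p > lambda} / ((1 - lambda) n)` evaluated on a lambda
#' grid and smoothed by taking the median (a robust alternative to the
#' canonical spline fit, chosen for its lack of tuning knobs);
#' `pi1 = 1 - pi0` clipped to `[0, 1]`, `m1 = pi1 * n`.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param lambda_grid tuning grid (default `seq(0.05, 0.95, by = 0.05)`).
#' @return object of class `true_positive_estimate`: list with `pi0`,
#'   `pi1`, `m1`, `n`, `lambda_grid`.
#' @export
estimate_pi1 <- function(pvalues, lambda_grid = seq(0.05, 0.95, 0.05)) {
  assert_that(length(pvalues) >= 1, "empty p-value input")
  if (length(pvalues) < 50) {
    warning("fewer than 50 p-values; pi1 estimate will be unstable")
  }
  n <- length(pvalues)
  pi0_l <- vapply(lambda_grid,
                  function(l) sum(pvalues > l) / ((1 - l) * n),
                  numeric(1))
  pi0 <- min(1, max(0, stats::median(pi0_l)))
  pi1 <- 1 - pi0
  structure(list(pi0 = pi0, pi1 = pi1, m1 = pi1 * n, n = n,
                 lambda_grid = lambda_grid),
            class = "true_positive_estimate")
}

#' Precision and recall of a nominated gene set
#'
#' Precision = |nominated intersect silver| / |nominated|; recall =
#' |nominated intersect silver| / |silver|. An empty nominated set gives
#' undefined precision (NA, flagged) and recall 0.
#'
#' @param nominated character vector of nominated genes.
#' @param silver non-empty character vector of silver-standard genes.
#' @return list with `precision`, `recall`, `n_overlap`,
#'   `precision_undefined`.
#' @export
precision_recall <- function(nominated, silver) {
  assert_that(length(silver) > 0, "silver-standard set must be non-empty")
  nominated <- unique(nominated); silver <- unique(silver)
  ov <- length(intersect(nominated, silver))
  if (length(nominated) == 0) {
    return(list(precision = NA_real_, recall = 0, n_overlap = 0L,
                precision_undefined = TRUE))
  }
  list(precision = ov / length(nominated), recall = ov / length(silver),
       n_overlap = ov, precision_undefined = FALSE)
}

#' Read LD blocks from a BED file
#'
#' Minimal 3+-column BED reader (chrom, start, end; 0-based half-open),
#' which is all the block definitions need.
#'
#' @param path BED path.
#' @return data.frame with chromosome, start, end.
#' @export
read_ld_blocks <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 3, "BED needs at least 3 columns")
  data.frame(chromosome = as.character(tab[[1]]), start = tab[[2]],
             end = tab[[3]], stringsAsFactors = FALSE)
}

#' Assign genes to approximately independent LD blocks
#'
#' A gene belongs to the block whose half-open interval `[start, end)`
#' contains its 0-based TSS (`tss - 1`); a TSS exactly at a block's end
#' coordinate therefore belongs to the next block. Blocks must not
#' overlap within a chromosome.
#'
#' @param genes data.frame with gene_id, chromosome, tss (1-based).
#' @param blocks data.frame with chromosome, start, end (0-based
#'   half-open), e.g. from [read_ld_blocks()].
#' @param significant optional character vector of significant gene ids;
#'   enables the distinct-block summary.
#' @return list with `assignment` (data.frame gene_id, block) where block
#'   is `"chrom:start-end"` or NA, `n_unassigned`, and (when
#'   `significant` given) `n_blocks_significant`.
#' @export
assign_ld_blocks <- function(genes, blocks, significant = NULL) {
  for (ch in unique(blocks$chromosome)) {
    b <- blocks[blocks$chromosome == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    assert_that(all(b$end[-nrow(b)] <= b$start[-1] | nrow(b) == 1),
                sprintf("overlapping blocks on chromosome %s", ch))
  }
  block_id <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    pos0 <- genes$tss[i] - 1
    hit <- which(blocks$chromosome == genes$chromosome[i] &
                   blocks$start <= pos0 & pos0 < blocks$end)
    if (length(hit) == 1) {
      block_id[i] <- sprintf("%s:%d-%d", blocks$chromosome[hit],
                             blocks$start[hit], blocks$end[hit])
    }
  }
  assignment <- data.frame(gene_id = genes$gene_id, block = block_id,
                           stringsAsFactors = FALSE)
  out <- list(assignment = assignment,
              n_unassigned = sum(is.na(block_id)))
  if (!is.null(significant)) {
    sig_blocks <- assignment$block[assignment$gene_id %in% significant &
                                     !is.na(assignment$block)]
    out$n_blocks_significant <- length(unique(sig_blocks))
  }
  out
}

#' Classify cell-type specificity of association hits
#'
#' Takes per-(gene, cell type) association p-values. Genes Bonferroni-
#' significant in two or more cell types are `shared`. For a gene
#' significant in exactly one (focal) cell type, the p-values of all
#' other cell types are combined with [acat_combine()]: combined
#' `p < nominal_alpha` makes the gene `cell_type_enriched`, otherwise
#' `cell_type_specific`. Genes missing from some cell types are combined
#' over the available ones (count recorded); a gene with no non-focal
#' p-values at all is classed `cell_type_specific` (no evidence
#' elsewhere).
#'
#' @param results data.frame with columns gene_id, cell_type, pvalue.
#' @param thresholds named numeric vector of per-cell-type Bonferroni
#'   thresholds (names = cell types); a single unnamed value is recycled.
#' @param nominal_alpha nominal significance level (default 0.05).
#' @return data.frame with gene_id, focal_cell_type, class, acat_p_other,
#'   n_other_available; one row per Bonferroni-significant gene.
#' @export
classify_specificity <- function(results, thresholds,
                                 nominal_alpha = 0.05) {
  cts <- unique(results$cell_type)
  assert_that(length(cts) >= 2, "need >= 2 cell types")
  if (is.null(names(thresholds)) && length(thresholds) == 1) {
    thresholds <- stats::setNames(rep(thresholds, length(cts)), cts)
  }
  assert_that(all(cts %in% names(thresholds)),
              "thresholds must cover every cell type")
  results$sig <- results$pvalue < thresholds[results$cell_type]
  sig_genes <- unique(results$gene_id[results$sig])
  rows <- lapply(sig_genes, function(g) {
    sub <- results[results$gene_id == g, , drop = FALSE]
    sig_ct <- sub$cell_type[sub$sig]
    if (length(sig_ct) >= 2) {
      return(data.frame(gene_id = g, focal_cell_type = NA_character_,
                        class = "shared", acat_p_other = NA_real_,
                        n_other_available = length(sig_ct) - 1L,
                        stringsAsFactors = FALSE))
    }
    focal <- sig_ct[1]
    other_p <- sub$pvalue[sub$cell_type != focal]
    if (length(other_p) == 0) {
      cls <- "cell_type_specific"; pc <- NA_real_
    } else {
      pc <- acat_combine(other_p)
      cls <- if (pc < nominal_alpha) "cell_type_enriched"
        else "cell_type_specific"
    }
    data.frame(gene_id = g, focal_cell_type = focal, class = cls,
               acat_p_other = pc, n_other_available = length(other_p),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0),
                      focal_cell_type = character(0),
                      class = character(0), acat_p_other = numeric(0),
                      n_other_available = integer(0)))
  }
  do.call(rbind, rows)
}
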