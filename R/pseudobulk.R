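# Pseudobulk module: cell QC, per-cell-type aggregation to gene x
# individual count matrices, and rank-percentile expression targets.

#' Cell and gene quality-control parameters
#'
#' Defaults follow common single-cell practice: cells with more than
#' 10,000 total UMIs (doublet suspects) or more than 10% mitochondrial
#' reads are removed, cells must express at least 200 genes, and genes must
#' be present in at least 3 cells. Set a threshold to `Inf` (or 0 for the
#' minima) to disable the rule.
#'
#' @param max_total_counts maximum total UMI count per cell (strict `<`).
#' @param max_mito_fraction maximum mitochondrial read fraction (strict).
#' @param min_genes_per_cell minimum expressed genes per cell.
#' @param min_cells_per_gene minimum cells a gene must appear in.
#' @return an object of class `cell_qc_params`.
#' @export
cell_qc_params <- function(max_total_counts = 10000,
                           max_mito_fraction = 0.10,
                           min_genes_per_cell = 200,
                           min_cells_per_gene = 3) {
  assert_that(max_total_counts >= 0 && max_mito_fraction >= 0 &&
                min_genes_per_cell >= 0 && min_cells_per_gene >= 0,
              "all QC thresholds must be >= 0")
  assert_that(max_mito_fraction <= 1, "max_mito_fraction must be in [0,1]")
  structure(list(max_total_counts = max_total_counts,
                 max_mito_fraction = max_mito_fraction,
                 min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene),
            class = "cell_qc_params")
}

#' Quality-control filter for a cell-level count matrix
#'
#' Applies, in order: total-count ceiling (cells kept iff total counts
#' `< max_total_counts`), mitochondrial-fraction ceiling (strict `<`),
#' minimum expressed genes per cell, then the gene-level minimum-cell
#' filter on the surviving cells. Mitochondrial genes are identified by a
#' configurable rowname prefix. A per-rule removal report is attached as
#' attribute `"qc_report"` and emitted as a message.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse), rownames
#'   = gene ids, colnames = cell ids.
#' @param metadata optional cell metadata data.frame with a `cell_id`
#'   column; returned subset alongside when supplied.
#' @param params a [cell_qc_params()].
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return the filtered counts matrix (with `qc_report` attribute), or a
#'   list `(counts, metadata)` when `metadata` is given.
#' @export
qc_filter <- function(counts, metadata = NULL, params = cell_qc_params(),
                      mito_prefix = "MT-") {
  stopifnot(inherits(params, "cell_qc_params"))
  total <- Matrix::colSums(counts)
  mito_rows <- startsWith(rownames(counts) %||% character(0), mito_prefix)
  mito_frac <- if (any(mito_rows)) {
    Matrix::colSums(counts[mito_rows, , drop = FALSE]) / pmax(total, 1)
  } else {
    numeric(ncol(counts))
  }
  genes_per_cell <- Matrix::colSums(counts > 0)
  fail_total <- !(total < params$max_total_counts)
  fail_mito <- !(mito_frac < params$max_mito_fraction)
  if (params$max_mito_fraction >= 1) fail_mito[] <- FALSE
  fail_genes <- genes_per_cell < params$min_genes_per_cell
  keep_cell <- !(fail_total | fail_mito | fail_genes)
  kept <- counts[, keep_cell, drop = FALSE]
  cells_in_gene <- Matrix::rowSums(kept > 0)
  keep_gene <- cells_in_gene >= params$min_cells_per_gene
  report <- list(cells_total = sum(fail_total), cells_mito = sum(fail_mito),
                 cells_min_genes = sum(fail_genes),
                 cells_removed = sum(!keep_cell),
                 genes_removed = sum(!keep_gene))
  if (!any(keep_cell)) {
    stop(sprintf(paste0("qc_filter removed all cells ",
                        "(total-count rule: %d, mito rule: %d, ",
                        "min-genes rule: %d)"),
                 report$cells_total, report$cells_mito,
                 report$cells_min_genes), call. = FALSE)
  }
  out <- kept[keep_gene, , drop = FALSE]
  attr(out, "qc_report") <- report
  message(sprintf("qc_filter: removed %d/%d cells, %d/%d genes",
                  report$cells_removed, ncol(counts),
                  report$genes_removed, nrow(counts)))
  if (is.null(metadata)) return(out)
  md <- metadata[match(colnames(out), metadata$cell_id), , drop = FALSE]
  rownames(md) <- NULL
  list(counts = out, metadata = md)
}

#' Aggregate cells into per-cell-type pseudobulk matrices
#'
#' Sums UMIs over all cells of each (gene, individual, cell type); the sum
#' (rather than the mean) preserves total counts. Individuals contributing
#' zero cells to a cell type are excluded from that cell type's matrix.
#'
#' @param counts genes x cells matrix.
#' @param metadata data.frame with columns `cell_id`, `individual`,
#'   `cell_type`, covering every column of `counts`.
#' @return named list of `pseudobulk_matrix` objects (one per cell type),
#'   each with `counts` (genes x individuals), `cell_type` and `n_cells`.
#' @export
aggregate_pseudobulk <- function(counts, metadata) {
  idx <- match(colnames(counts), metadata$cell_id)
  if (anyNA(idx)) {
    bad <- colnames(counts)[is.na(idx)]
    stop(sprintf("cells missing from metadata: %s%s",
                 paste(utils::head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else ""), call. = FALSE)
  }
  md <- metadata[idx, , drop = FALSE]
  assert_that(!anyNA(md$individual) && !anyNA(md$cell_type),
              "metadata has NA individual or cell_type labels")
  out <- list()
  for (ctl in unique(md$cell_type)) {
    sel <- md$cell_type == ctl
    sub <- counts[, sel, drop = FALSE]
    ind <- factor(md$individual[sel])
    # design matrix cells x individuals; crossprod does the group sum
    design <- Matrix::sparseMatrix(i = seq_len(ncol(sub)),
                                   j = as.integer(ind), x = 1,
                                   dims = c(ncol(sub), nlevels(ind)))
    pb <- as.matrix(sub %*% design)
    colnames(pb) <- levels(ind)
    n_cells <- as.integer(table(ind))
    names(n_cells) <- levels(ind)
    out[[ctl]] <- structure(list(cell_type = ctl, counts = pb,
                                 n_cells = n_cells),
                            class = "pseudobulk_matrix")
  }
  out
}

# Rank-percentile transform of a numeric vector: average ranks for ties,
# then (rank - 1) / (n - 1) so values literally span 0..1.
percentile_transform <- function(x) {
  r <- rank(x, ties.method = "average")
  (r - 1) / (length(x) - 1)
}

#' Across-gene expression percentiles (model targets)
#'
#' Averages each gene's pseudobulk counts across individuals, ranks the
#' averages (ties get the average rank) and maps rank r to
#' `(r - 1) / (G - 1)`, giving percentiles that span exactly 0..1. These
#' are the regression targets for the expression predictor.
#'
#' @param pb a `pseudobulk_matrix`.
#' @return object of class `expression_percentiles`: list with
#'   `cell_type` and named numeric `percentile`.
#' @export
rank_percentile <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  assert_that(nrow(pb$counts) >= 2,
              "rank_percentile needs >= 2 genes (undefined otherwise)")
  means <- rowMeans(pb$counts)
  p <- percentile_transform(means)
  names(p) <- rownames(pb$counts)
  structure(list(cell_type = pb$cell_type, percentile = p),
            class = "expression_percentiles")
}

#' Per-individual expression percentiles
#'
#' Applies the rank-percentile transform within each individual's column
#' independently, giving a genes x individuals percentile matrix. These
#' are the across-individual evaluation targets and the regression targets
#' for the observed-expression elastic-net baseline.
#'
#' @param pb a `pseudobulk_matrix`.
#' @return numeric matrix, genes x individuals, each column spanning 0..1.
#' @export
rank_percentile_per_individual <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  assert_that(nrow(pb$counts) >= 2,
              "rank_percentile needs >= 2 genes (undefined otherwise)")
  apply(pb$counts, 2, percentile_transform)
}

#' Write / read a counts matrix in MatrixMarket format with metadata
#'
#' @param counts genes x cells sparse matrix.
#' @param metadata cell metadata data.frame.
#' @param dir output directory (created if missing); writes
#'   `counts.mtx`, `genes.tsv`, `cells.tsv`, `metadata.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cell_counts <- function(counts, metadata, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cell_counts
#' @export
read_cell_counts <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  dimnames(counts) <- list(readLines(file.path(dir, "genes.tsv")),
                           readLines(file.path(dir, "cells.tsv")))
  metadata <- utils::read.table(file.path(dir, "metadata.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}
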