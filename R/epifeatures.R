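# Epigenomic feature module: TSS-centred window geometry, central-bin
# aggregation, and a pluggable backend interface for feature prediction
# (built-in deterministic oracle; external predictors plug in through the
# same adapter contract).

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `chromosome`, `tss` (1-based), `strand`.
#'
#' @param path TSV path.
#' @return data.frame of gene annotations.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "tss", "strand")
  assert_that(all(need %in% names(ann)),
              paste("gene annotation needs columns:",
                    paste(need, collapse = ", ")))
  assert_that(all(ann$tss >= 1), "tss must be >= 1 (1-based)")
  ann
}

#' Extract the prediction window around a gene's TSS
#'
#' Returns the 0-based half-open interval `[tss - length/2, tss + length/2)`
#' of exactly `length` bp anchored at the printed (1-based) TSS position, so
#' the TSS base is the last base of the left half-window. The default
#' length (196,608 bp) is the input geometry of the upstream
#' sequence-to-epigenome model; its central 896 x 128 bp = 114,688 bp are
#' the predicted bins. Strand is deliberately ignored (windows are centred,
#' not oriented). Truncation at contig edges is reported via the
#' `truncated` flag.
#'
#' @param gene one-row gene annotation (list or data.frame row) with
#'   `gene_id`, `chromosome`, `tss`.
#' @param length window length in bp (even).
#' @param contig_length optional contig length for truncation reporting.
#' @return list with `chromosome`, `start`, `end` (0-based half-open) and
#'   `truncated`.
#' @export
extract_window <- function(gene, length = 196608L, contig_length = NULL) {
  assert_that(length %% 2 == 0, "window length must be even")
  tss <- as.numeric(gene$tss)
  assert_that(is.finite(tss) && tss >= 1, "gene has no valid TSS")
  start <- tss - length / 2
  end <- tss + length / 2
  truncated <- FALSE
  if (start < 0) { start <- 0; truncated <- TRUE }
  if (!is.null(contig_length) && end > contig_length) {
    end <- contig_length; truncated <- TRUE
  }
  list(chromosome = gene$chromosome, start = start, end = end,
       truncated = truncated)
}

#' Aggregate feature-matrix bins into a per-track feature vector
#'
#' Arithmetic mean over the selected bins, per track. The default is the
#' central four bins (447-450, 1-based inclusive) of the 896-bin window:
#' with 896 bins the exact centre falls between bins 448 and 449, and the
#' four-bin neighbourhood is the empirically chosen local TSS context.
#'
#' @param m feature matrix, tracks x 896 bins.
#' @param bins 1-based bin indices (inclusive).
#' @return numeric feature vector of length `nrow(m)`.
#' @export
aggregate_bins <- function(m, bins = CENTRAL_BINS) {
  assert_that(length(bins) >= 1, "empty bin selection")
  assert_that(all(bins >= 1 & bins <= ncol(m)),
              sprintf("bin indices must lie in 1..%d", ncol(m)))
  rowMeans(m[, bins, drop = FALSE])
}

#' Create the built-in oracle feature backend
#'
#' Wraps a synthetic ground truth and genotype panel as an epigenome
#' backend: the reference matrix corresponds to all-reference dosages, and
#' personalized matrices substitute the individual's cis dosages. A fast
#' path returns the aggregated central-bin feature vector directly from
#' the oracle's closed form.
#'
#' @param truth a [sim_truth()].
#' @param panel a `genotype_panel` covering the individuals to personalize.
#' @return an object of class `epigenome_backend`.
#' @export
oracle_backend <- function(truth, panel) {
  stopifnot(inherits(truth, "sim_truth"), inherits(panel, "genotype_panel"))
  dosage_of <- function(gene_id, individual) {
    rows <- gene_variant_rows(truth, gene_id)
    if (is.null(individual)) return(numeric(length(rows)))
    assert_that(individual %in% rownames(panel$dosages),
                sprintf("individual '%s' not in genotype panel", individual))
    as.numeric(panel$dosages[individual, rows])
  }
  structure(list(
    name = "oracle",
    n_tracks = truth$config$n_tracks,
    predict = function(gene_id, individual = NULL) {
      epigenome_oracle(truth, gene_id, dosage_of(gene_id, individual))
    },
    features = function(gene_id, individual = NULL) {
      oracle_feature_vector(truth, gene_id, dosage_of(gene_id, individual))
    }
  ), class = "epigenome_backend")
}

#' Adapter stub for an external sequence-to-epigenome predictor
#'
#' The package does not bundle a deep-learning predictor. An external
#' engine is plugged in by constructing an `epigenome_backend` with a
#' `predict(gene_id, individual)` function that, given the gene's
#' TSS-centred interval and the individual's variant substitutions
#' (`list(interval, substitutions = [(pos, ref, alt, dosage)])`), returns
#' the tracks x 896 matrix. Calling this stub documents the contract and
#' errors.
#'
#' @return never returns; raises an error describing the adapter contract.
#' @export
enformer_backend <- function() {
  stop(paste("no external epigenome predictor is bundled; supply an",
             "'epigenome_backend' whose predict(gene_id, individual)",
             "maps {interval, substitutions:[(pos, ref, alt, dosage)]}",
             "to a tracks x 896 matrix"), call. = FALSE)
}

#' Predict a feature matrix through a backend, with caching
#'
#' Results are memoized per (backend name, gene, individual) in an
#' in-memory cache; identical requests return identical cached values.
#'
#' @param backend an `epigenome_backend`.
#' @param gene_id gene identifier.
#' @param individual individual id, or `NULL` for the reference matrix.
#' @param cache environment used as cache (a package-level default is
#'   shared across calls); pass a fresh `new.env()` to isolate.
#' @return feature matrix, tracks x 896.
#' @export
backend_predict <- function(backend, gene_id, individual = NULL,
                            cache = feature_cache_env) {
  stopifnot(inherits(backend, "epigenome_backend"))
  key <- paste(backend$name, gene_id, individual %||% ".ref", sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  m <- backend$predict(gene_id, individual)
  assert_that(is.matrix(m) && ncol(m) == N_BINS,
              sprintf("backend must return a tracks x %d matrix", N_BINS))
  if (!is.null(cache)) cache[[key]] <- m
  m
}

#' Aggregated feature vector through a backend
#'
#' Uses the backend's closed-form fast path when it provides one,
#' otherwise aggregates the full predicted matrix over `bins`.
#'
#' @inheritParams backend_predict
#' @param bins bin indices passed to [aggregate_bins()].
#' @return numeric feature vector (length = backend track count).
#' @export
backend_features <- function(backend, gene_id, individual = NULL,
                             bins = CENTRAL_BINS) {
  stopifnot(inherits(backend, "epigenome_backend"))
  if (!is.null(backend$features) && identical(bins, CENTRAL_BINS)) {
    return(backend$features(gene_id, individual))
  }
  aggregate_bins(backend_predict(backend, gene_id, individual,
                                 cache = NULL), bins)
}

# Shared default cache for backend_predict().
feature_cache_env <- new.env(parent = emptyenv())

#' Reference feature matrix (genes x tracks) for a gene set
#'
#' Stacks aggregated reference feature vectors for model training.
#'
#' @param backend an `epigenome_backend`.
#' @param gene_ids character vector of gene ids.
#' @return matrix, genes x tracks, rownames = gene ids.
#' @export
reference_feature_matrix <- function(backend, gene_ids) {
  t(vapply(gene_ids, function(g) backend_features(backend, g),
           numeric(backend$n_tracks)))
}
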