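# Expression-predictor module: a compact four-layer MLP mapping aggregated
# epigenomic feature vectors to expression percentiles. Implemented from
# scratch (forward pass, backprop, Adam) -- problem sizes here are a few
# hundred genes by a few thousand features, well within base-R matrix
# arithmetic. Architecture: input -> 64 (ReLU, dropout), three further
# 64 -> 64 hidden layers (ReLU, dropout), then a 64 -> 1 output
# projection. At the full 5,313-track profile this is exactly 352,641
# parameters (~0.4 M).

#' Hyperparameters for the expression predictor
#'
#' @param hidden_dim hidden width (default 64).
#' @param dropout dropout rate after each hidden activation, in `[0, 1)`
#'   (default 0.05).
#' @param weight_decay L2 regularization coefficient (default 5e-4).
#' @param learning_rate Adam step size (default 1e-2; the optimizer,
#'   rate and batch size are implementation choices chosen so training
#'   saturates within 50-80 epochs, surfaced here).
#' @param batch_size mini-batch size (default 32; capped at the training
#'   set size).
#' @param max_epochs training-epoch cap (default 80; training typically
#'   saturates between 50 and 80 epochs).
#' @param patience early-stopping patience on validation MSE (default 10).
#' @param seed RNG seed for initialization and dropout masks.
#' @return object of class `ctpred_hyperparams`.
#' @export
ctpred_hyperparams <- function(hidden_dim = 64L, dropout = 0.05,
                               weight_decay = 5e-4, learning_rate = 1e-2,
                               batch_size = 32L, max_epochs = 80L,
                               patience = 10L, seed = 1L) {
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  assert_that(weight_decay >= 0, "weight_decay must be >= 0")
  assert_that(is_count(max_epochs), "max_epochs must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  structure(list(hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 weight_decay = weight_decay,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "ctpred_hyperparams")
}

#' Split genes into train/validation/test sets by chromosome
#'
#' Chromosomes are shuffled under `seed`, then assigned greedily: each
#' chromosome (in shuffled order) goes to the set with the largest
#' remaining gene-count deficit relative to its target fraction. Whole
#' chromosomes move together, so no gene (nor any sequence overlap between
#' neighbouring genes) can leak across sets.
#'
#' @param genes gene annotation data.frame with `gene_id`, `chromosome`.
#' @param fractions length-3 target fractions (train, validation, test),
#'   summing to 1.
#' @param seed shuffle seed.
#' @return object of class `chromosome_split`: list of `train`,
#'   `validation`, `test` chromosome vectors, the matching gene-id
#'   vectors (`train_genes`, ...), and `seed`.
#' @export
split_by_chromosome <- function(genes, fractions = c(0.7, 0.15, 0.15),
                                seed = 1L) {
  assert_that(length(fractions) == 3 && abs(sum(fractions) - 1) < 1e-8,
              "fractions must be a triple summing to 1")
  chroms <- unique(genes$chromosome)
  assert_that(length(chroms) >= 3,
              "need >= 3 chromosomes to form disjoint splits")
  counts <- table(genes$chromosome)
  order_ <- with_seed(seed, sample(chroms))
  target <- fractions * nrow(genes)
  assigned <- vector("list", 3)
  got <- c(0, 0, 0)
  for (ch in order_) {
    deficit <- target - got
    k <- which.max(deficit)
    assigned[[k]] <- c(assigned[[k]], ch)
    got[k] <- got[k] + counts[[ch]]
  }
  sets <- c("train", "validation", "test")
  out <- stats::setNames(assigned, sets)
  for (s in sets) {
    out[[paste0(s, "_genes")]] <-
      genes$gene_id[genes$chromosome %in% out[[s]]]
  }
  out$seed <- as.integer(seed)
  structure(out, class = "chromosome_split")
}

# He-uniform-ish initialization: N(0, sqrt(2/fan_in)).
init_ctpred_weights <- function(input_dim, hp) {
  h <- hp$hidden_dim
  dims <- rbind(c(input_dim, h), c(h, h), c(h, h), c(h, h), c(h, 1))
  lapply(seq_len(nrow(dims)), function(i) {
    list(W = matrix(stats::rnorm(dims[i, 1] * dims[i, 2],
                                 sd = sqrt(2 / dims[i, 1])),
                    dims[i, 1], dims[i, 2]),
         b = numeric(dims[i, 2]))
  })
}

# Forward pass. Returns prediction vector and, when training, the
# intermediates needed by backprop. Dropout uses inverted scaling so
# evaluation needs no rescaling.
ctpred_forward <- function(layers, X, dropout = 0, training = FALSE) {
  acts <- list(); masks <- list()
  A <- X
  for (i in 1:4) {
    Z <- sweep(A %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    H <- pmax(Z, 0)
    if (training && dropout > 0) {
      m <- matrix(stats::rbinom(length(H), 1, 1 - dropout) / (1 - dropout),
                  nrow(H), ncol(H))
      H <- H * m
      masks[[i]] <- m
    }
    acts[[i]] <- list(Z = Z, H = H, A_in = A)
    A <- H
  }
  yhat <- as.numeric(sweep(A %*% layers[[5]]$W, 2, layers[[5]]$b, "+"))
  list(yhat = yhat, acts = acts, masks = masks, A_last = A)
}

# Backprop of the MSE loss; returns gradients in the same shape as layers.
ctpred_backward <- function(layers, fwd, X, y, dropout = 0) {
  n <- length(y)
  grads <- vector("list", 5)
  delta <- matrix(2 * (fwd$yhat - y) / n, ncol = 1)
  grads[[5]] <- list(W = crossprod(fwd$A_last, delta),
                     b = colSums(delta))
  back <- delta %*% t(layers[[5]]$W)
  for (i in 4:1) {
    if (dropout > 0 && length(fwd$masks) >= i && !is.null(fwd$masks[[i]])) {
      back <- back * fwd$masks[[i]]
    }
    back <- back * (fwd$acts[[i]]$Z > 0)
    grads[[i]] <- list(W = crossprod(fwd$acts[[i]]$A_in, back),
                       b = colSums(back))
    if (i > 1) back <- back %*% t(layers[[i]]$W)
  }
  grads
}

#' Train the expression predictor
#'
#' Mini-batch Adam on the mean-squared-error loss with L2 weight decay,
#' ReLU activations and dropout after every hidden activation. The
#' checkpoint with the best validation MSE within `max_epochs` is kept;
#' training stops early after `patience` epochs without improvement.
#' Fixed seeds make the loss trajectory reproducible.
#'
#' @param features genes x tracks feature matrix (rownames = gene ids).
#' @param targets named numeric vector of expression percentiles (or an
#'   `expression_percentiles` object).
#' @param split a [split_by_chromosome()] result.
#' @param hp a [ctpred_hyperparams()].
#' @param cell_type label stored on the model.
#' @return object of class `ctpred_model` with layers, hyperparameters,
#'   the split, and a per-epoch training log (data.frame).
#' @export
train_ctpred <- function(features, targets, split, hp = ctpred_hyperparams(),
                         cell_type = "unknown") {
  stopifnot(inherits(split, "chromosome_split"),
            inherits(hp, "ctpred_hyperparams"))
  if (inherits(targets, "expression_percentiles")) {
    targets <- targets$percentile
  }
  use <- function(ids) {
    miss <- setdiff(ids, rownames(features))
    miss <- c(miss, setdiff(ids, names(targets)))
    if (length(miss) > 0) {
      stop(sprintf("genes missing a feature vector or target: %s%s",
                   paste(utils::head(unique(miss), 5), collapse = ", "),
                   if (length(unique(miss)) > 5) ", ..." else ""),
           call. = FALSE)
    }
    list(X = features[ids, , drop = FALSE], y = unname(targets[ids]))
  }
  tr <- use(split$train_genes)
  va <- use(split$validation_genes)
  # Standardize inputs on training-set statistics (stored on the model and
  # re-applied at prediction time); raw feature tracks live on arbitrary
  # scales and unscaled inputs slow Adam down badly.
  ctr <- colMeans(tr$X)
  scl <- apply(tr$X, 2, stats::sd)
  scl[scl == 0] <- 1
  tr$X <- scale(tr$X, center = ctr, scale = scl)
  va$X <- scale(va$X, center = ctr, scale = scl)
  with_seed(hp$seed, {
    layers <- init_ctpred_weights(ncol(features), hp)
    mstate <- lapply(layers, function(l) {
      list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
    })
    vstate <- mstate
    best <- list(val = Inf, layers = layers, epoch = 0L)
    log <- data.frame(epoch = integer(0), train_mse = numeric(0),
                      val_mse = numeric(0))
    wait <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    n_tr <- nrow(tr$X)
    bs <- min(hp$batch_size, n_tr)
    for (epoch in seq_len(hp$max_epochs)) {
      perm <- sample.int(n_tr)
      batch_losses <- numeric(0)
      for (b0 in seq(1, n_tr, by = bs)) {
        idx <- perm[b0:min(b0 + bs - 1, n_tr)]
        Xb <- tr$X[idx, , drop = FALSE]
        yb <- tr$y[idx]
        fwd <- ctpred_forward(layers, Xb, hp$dropout, training = TRUE)
        loss <- mean((fwd$yhat - yb)^2)
        if (!is.finite(loss)) {
          stop(sprintf("NaN/Inf training loss at epoch %d", epoch),
               call. = FALSE)
        }
        batch_losses <- c(batch_losses, loss)
        grads <- ctpred_backward(layers, fwd, Xb, yb, hp$dropout)
        t_step <- t_step + 1L
        for (i in seq_along(layers)) {
          gW <- grads[[i]]$W + hp$weight_decay * layers[[i]]$W
          gb <- grads[[i]]$b
          mstate[[i]]$W <- b1 * mstate[[i]]$W + (1 - b1) * gW
          vstate[[i]]$W <- b2 * vstate[[i]]$W + (1 - b2) * gW^2
          mstate[[i]]$b <- b1 * mstate[[i]]$b + (1 - b1) * gb
          vstate[[i]]$b <- b2 * vstate[[i]]$b + (1 - b2) * gb^2
          mhW <- mstate[[i]]$W / (1 - b1^t_step)
          vhW <- vstate[[i]]$W / (1 - b2^t_step)
          mhb <- mstate[[i]]$b / (1 - b1^t_step)
          vhb <- vstate[[i]]$b / (1 - b2^t_step)
          layers[[i]]$W <- layers[[i]]$W -
            hp$learning_rate * mhW / (sqrt(vhW) + eps)
          layers[[i]]$b <- layers[[i]]$b -
            hp$learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      train_mse <- mean(batch_losses)
      val_pred <- ctpred_forward(layers, va$X)$yhat
      val_mse <- mean((val_pred - va$y)^2)
      log <- rbind(log, data.frame(epoch = epoch, train_mse = train_mse,
                                   val_mse = val_mse))
      if (val_mse < best$val - 1e-12) {
        best <- list(val = val_mse, layers = layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hp$patience) break
      }
    }
    structure(list(layers = best$layers, hyperparams = hp,
                   input_dim = ncol(features), center = ctr, scale = scl,
                   cell_type = cell_type, split = split,
                   best_epoch = best$epoch, log = log),
              class = "ctpred_model")
  })
}

#' Number of trainable parameters of a predictor
#'
#' For the full 5,313-track profile this is
#' `5313*64 + 64 + 3*(64*64 + 64) + 64 + 1 = 352,641` (~0.4 M).
#'
#' @param model a `ctpred_model`, or an input dimension (with `hp`).
#' @param hp hyperparameters used when `model` is an input dimension.
#' @return integer parameter count.
#' @export
ctpred_n_params <- function(model, hp = ctpred_hyperparams()) {
  layers <- if (inherits(model, "ctpred_model")) model$layers
    else init_ctpred_weights(as.integer(model), hp)
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Predict expression percentiles from feature vectors
#'
#' Deterministic forward pass (dropout disabled); outputs are raw real
#' values, deliberately not clamped to `[0, 1]`.
#'
#' @param object a `ctpred_model`.
#' @param features feature matrix (genes or individuals as rows) or a
#'   single feature vector.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.ctpred_model <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  assert_that(ncol(features) == object$input_dim,
              sprintf("feature length %d does not match model input %d",
                      ncol(features), object$input_dim))
  if (!is.null(object$center)) {
    features <- scale(features, center = object$center,
                      scale = object$scale)
  }
  out <- ctpred_forward(object$layers, features)$yhat
  names(out) <- rownames(features)
  out
}

#' Construct a predictor that computes an exact linear map
#'
#' Builds a `ctpred_model` whose forward pass returns
#' `sum_j w_j x_j + bias` exactly (ReLU layers kept in their linear regime
#' by a large positive offset that the output bias removes). Used to
#' validate the linearization machinery on noise-free linear predictors,
#' where the cross-validated Spearman correlation must be ~1.
#'
#' @param w numeric weight vector (length = input dimension).
#' @param bias output offset.
#' @param hidden_dim hidden width (default 64).
#' @param offset linear-regime offset; the map is exact while
#'   `|w . x| < offset`.
#' @return a `ctpred_model`.
#' @export
make_linear_ctpred <- function(w, bias = 0, hidden_dim = 64L,
                               offset = 1e3) {
  d <- length(w)
  W1 <- matrix(0, d, hidden_dim); W1[, 1] <- w
  I_h <- diag(hidden_dim)
  layers <- list(
    list(W = W1, b = rep(offset, hidden_dim)),
    list(W = I_h, b = numeric(hidden_dim)),
    list(W = I_h, b = numeric(hidden_dim)),
    list(W = I_h, b = numeric(hidden_dim)),
    list(W = matrix(c(1, rep(0, hidden_dim - 1)), hidden_dim, 1),
         b = bias - offset))
  structure(list(layers = layers, hyperparams = ctpred_hyperparams(),
                 input_dim = d, center = NULL, scale = NULL,
                 cell_type = "linear", split = NULL, best_epoch = 0L,
                 log = NULL),
            class = "ctpred_model")
}

#' Across-gene evaluation: Pearson correlation
#'
#' @param pred,obs numeric vectors over the same genes.
#' @return list with `r`, `p` (two-sided), `n`, and `undefined` flag
#'   (TRUE when either vector has zero variance).
#' @export
evaluate_across_genes <- function(pred, obs) {
  assert_that(length(pred) == length(obs), "length mismatch")
  assert_that(length(pred) >= 3, "need >= 3 genes")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(pred),
                undefined = TRUE))
  }
  ct <- stats::cor.test(pred, obs)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(pred),
       undefined = FALSE)
}

#' Across-individual evaluation: per-gene correlation p-values and m1
#'
#' For each gene, the Pearson correlation between predicted and observed
#' values across individuals and its two-sided p-value. Correlation signs
#' can be unreliable for sequence-based predictors, so genes are ranked by
#' p-value; signed r is still reported. The p-values feed the Storey
#' estimator to give m1, the estimated number of genes truly associated
#' with their predictions.
#'
#' @param pred,obs genes x individuals matrices with matching dimnames.
#' @return list with `per_gene` (data.frame: gene_id, r, p), `n_skipped`
#'   (constant rows), and `m1` / `pi1` from [estimate_pi1()].
#' @export
evaluate_across_individuals <- function(pred, obs) {
  assert_that(ncol(pred) >= 5, "need >= 5 individuals")
  common <- intersect(rownames(pred), rownames(obs))
  assert_that(length(common) > 0, "no shared genes between pred and obs")
  if (!is.null(colnames(pred)) && !is.null(colnames(obs))) {
    pred <- pred[common, colnames(obs), drop = FALSE]
  } else {
    assert_that(ncol(pred) == ncol(obs), "individual columns differ")
    pred <- pred[common, , drop = FALSE]
  }
  obs <- obs[common, , drop = FALSE]
  res <- lapply(common, function(g) {
    x <- pred[g, ]; y <- obs[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
    ct <- stats::cor.test(x, y)
    data.frame(gene_id = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  per_gene <- do.call(rbind, res)
  pi1 <- estimate_pi1(per_gene$p)
  list(per_gene = per_gene, n_skipped = skipped,
       pi1 = pi1$pi1, m1 = pi1$m1)
}

#' Serialize / deserialize a predictor
#'
#' Single-file JSON archive (weights as full-precision arrays).
#'
#' @param model a `ctpred_model`.
#' @param path file path.
#' @return `path` invisibly; `read_ctpred` returns the model.
#' @export
write_ctpred <- function(model, path) {
  stopifnot(inherits(model, "ctpred_model"))
  obj <- list(input_dim = model$input_dim, cell_type = model$cell_type,
              hyperparams = unclass(model$hyperparams),
              best_epoch = model$best_epoch,
              center = model$center, scale = model$scale,
              layers = lapply(model$layers, function(l) {
                list(W = l$W, b = l$b)
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ctpred
#' @export
read_ctpred <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite may simplify the layer list to a data.frame-like structure
  layers <- if (is.data.frame(obj$layers)) {
    lapply(seq_len(nrow(obj$layers)), function(i) {
      list(W = as.matrix(obj$layers$W[[i]]),
           b = as.numeric(obj$layers$b[[i]]))
    })
  } else {
    lapply(obj$layers, function(l) {
      list(W = as.matrix(l$W), b = as.numeric(l$b))
    })
  }
  hp <- structure(obj$hyperparams, class = "ctpred_hyperparams")
  structure(list(layers = layers, hyperparams = hp,
                 input_dim = obj$input_dim,
                 center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale),
                 cell_type = obj$cell_type,
                 split = NULL, best_epoch = obj$best_epoch, log = NULL),
            class = "ctpred_model")
}
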