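# Expression-predictor module: splits, training, prediction, evaluation.

# Clean learnable fixture: percentile of a linear feature score.
linear_task <- function(n = 400, d = 53, n_chrom = 8, seed = 1) {
  memo(sprintf("lintask_%d_%d_%d", n, d, seed), {
    set.seed(seed)
    X <- matrix(rnorm(n * d), n, d,
                dimnames = list(sprintf("g%04d", 1:n), NULL))
    w <- rnorm(d) / sqrt(d)
    y <- (rank(as.numeric(X %*% w)) - 1) / (n - 1)
    names(y) <- rownames(X)
    genes <- data.frame(gene_id = rownames(X),
                        chromosome = as.character(rep_len(1:n_chrom, n)))
    list(X = X, y = y, w = w, genes = genes,
         split = split_by_chromosome(genes, seed = 2))
  })
}

test_that("split_by_chromosome: forced case, disjointness, greedy oracle", {
  g3 <- data.frame(gene_id = paste0("g", 1:30),
                   chromosome = as.character(rep(1:3, each = 10)))
  s3 <- split_by_chromosome(g3, fractions = c(1/3, 1/3, 1/3), seed = 1)
  expect_equal(sort(c(s3$train, s3$validation, s3$test)),
               c("1", "2", "3"))
  expect_length(s3$train, 1)

  set.seed(5)
  g22 <- data.frame(
    gene_id = paste0("g", 1:800),
    chromosome = as.character(sample(1:22, 800, TRUE,
                                     prob = 22:1)))
  s22 <- split_by_chromosome(g22, seed = 7)
  expect_length(intersect(s22$train_genes, s22$test_genes), 0)
  expect_length(intersect(s22$train_genes, s22$validation_genes), 0)
  expect_setequal(c(s22$train_genes, s22$validation_genes,
                    s22$test_genes), g22$gene_id)

  # independent re-implementation of the greedy rule
  counts <- table(g22$chromosome)
  order_ <- celltwas:::with_seed(7, sample(unique(g22$chromosome)))
  target <- c(0.7, 0.15, 0.15) * nrow(g22)
  got <- list(character(0), character(0), character(0))
  have <- c(0, 0, 0)
  for (ch in order_) {
    k <- which.max(target - have)
    got[[k]] <- c(got[[k]], ch)
    have[k] <- have[k] + counts[[ch]]
  }
  expect_equal(s22$train, got[[1]])
  expect_equal(s22$validation, got[[2]])
  expect_equal(s22$test, got[[3]])

  expect_error(split_by_chromosome(g3[g3$chromosome != "3", ]),
               ">= 3 chromosomes")
  expect_error(split_by_chromosome(g3, fractions = c(0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("parameter count matches the architecture exactly", {
  expect_equal(ctpred_n_params(5313L), 352641L)
  expect_equal(ctpred_n_params(5313L),
               5313 * 64 + 64 + 3 * (64 * 64 + 64) + 64 + 1)
  expect_equal(ctpred_n_params(53L), 53 * 64 + 64 + 3 * 4160 + 65)
})

test_that("training learns a constant and recovers a linear map", {
  # constant-function case: zero-variance features, constant 0.5 target
  nX <- matrix(0, 60, 5, dimnames = list(sprintf("g%02d", 1:60), NULL))
  y <- rep(0.5, 60); names(y) <- rownames(nX)
  genes <- data.frame(gene_id = rownames(nX),
                      chromosome = as.character(rep_len(1:4, 60)))
  sp <- split_by_chromosome(genes, seed = 1)
  mod <- train_ctpred(nX, y, sp, ctpred_hyperparams(seed = 2, dropout = 0))
  expect_lt(min(mod$log$val_mse), 1e-3)

  # linear-map recovery on held-out chromosomes
  task <- linear_task()
  m <- train_ctpred(task$X, task$y, task$split,
                    ctpred_hyperparams(seed = 5))
  pr <- predict(m, task$X[task$split$test_genes, ])
  expect_gte(cor(pr, task$y[task$split$test_genes]), 0.9)
  expect_true(all(diff(range(m$log$epoch)) >= 0))

  # permutation null: shuffled targets give |r| < 0.1
  y_shuf <- celltwas:::with_seed(9, sample(task$y))
  names(y_shuf) <- names(task$y)
  m0 <- train_ctpred(task$X, y_shuf, task$split,
                     ctpred_hyperparams(seed = 5))
  pr0 <- predict(m0, task$X[task$split$test_genes, ])
  expect_lt(abs(cor(pr0, y_shuf[task$split$test_genes])), 0.1)
})

test_that("training reproducibility and error paths", {
  task <- linear_task(n = 120, d = 10, seed = 3)
  hp <- ctpred_hyperparams(seed = 11, max_epochs = 12)
  m1 <- train_ctpred(task$X, task$y, task$split, hp)
  m2 <- train_ctpred(task$X, task$y, task$split, hp)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$layers, m2$layers)

  # missing gene keys are reported
  expect_error(train_ctpred(task$X[-1, ], task$y, task$split, hp),
               "missing a feature vector")
  # non-finite features abort with the epoch index
  Xbad <- task$X; Xbad[3, 1] <- Inf
  expect_error(train_ctpred(Xbad, task$y, task$split, hp),
               "epoch")
})

test_that("prediction: degenerate model, determinism, hand-computed pass", {
  hp <- ctpred_hyperparams(hidden_dim = 3L)
  # all-zero weights: output equals the final bias
  layers <- celltwas:::with_seed(1, celltwas:::init_ctpred_weights(2, hp))
  for (i in 1:5) layers[[i]]$W[] <- 0
  layers[[5]]$b <- 0.77
  mod <- structure(list(layers = layers, hyperparams = hp, input_dim = 2,
                        center = NULL, scale = NULL, cell_type = "x",
                        best_epoch = 0L),
                   class = "ctpred_model")
  expect_equal(unname(predict(mod, rbind(c(1, 2), c(-3, 5)))),
               c(0.77, 0.77))

  # hand-built 2-track toy model: forward pass vs explicit arithmetic
  l <- list(
    list(W = matrix(c(1, 0, 0.5, -1, 0.2, 0.3), 2, 3), b = c(0.1, 0, -0.2)),
    list(W = diag(3), b = rep(0.05, 3)),
    list(W = diag(3), b = numeric(3)),
    list(W = diag(3), b = numeric(3)),
    list(W = matrix(c(1, -2, 0.5), 3, 1), b = 0.25))
  modh <- structure(list(layers = l, hyperparams = hp, input_dim = 2,
                         center = NULL, scale = NULL, cell_type = "x",
                         best_epoch = 0L),
                    class = "ctpred_model")
  x <- c(0.4, -1.2)
  h <- pmax(c(x %*% l[[1]]$W) + l[[1]]$b, 0)
  h <- pmax(h + 0.05, 0); h <- pmax(h, 0); h <- pmax(h, 0)
  want <- sum(h * c(1, -2, 0.5)) + 0.25
  expect_equal(unname(predict(modh, x)), want)

  # determinism and gene-order invariance
  task <- linear_task(n = 120, d = 10, seed = 3)
  m <- train_ctpred(task$X, task$y, task$split,
                    ctpred_hyperparams(seed = 4, max_epochs = 10))
  p1 <- predict(m, task$X)
  expect_identical(p1, predict(m, task$X))
  perm <- celltwas:::with_seed(2, sample(nrow(task$X)))
  expect_equal(unname(predict(m, task$X[perm, ])), unname(p1[perm]))

  expect_error(predict(m, matrix(0, 2, 7)), "does not match")
})

test_that("make_linear_ctpred computes the exact linear map", {
  set.seed(6)
  w <- rnorm(10); X <- matrix(rnorm(50), 5, 10)
  m <- make_linear_ctpred(w, bias = 0.3)
  expect_equal(unname(predict(m, X)), as.numeric(X %*% w) + 0.3,
               tolerance = 1e-10)
  expect_equal(ctpred_n_params(m), ctpred_n_params(10L))
})

test_that("large weight decay shrinks weights toward zero", {
  task <- linear_task(n = 120, d = 10, seed = 3)
  small <- train_ctpred(task$X, task$y, task$split,
                        ctpred_hyperparams(seed = 4, weight_decay = 0,
                                           max_epochs = 20))
  big <- train_ctpred(task$X, task$y, task$split,
                      ctpred_hyperparams(seed = 4, weight_decay = 50,
                                         max_epochs = 20))
  norm_of <- function(m) {
    sum(vapply(m$layers, function(l) sum(l$W^2), numeric(1)))
  }
  expect_lt(norm_of(big), 0.1 * norm_of(small))
})

test_that("evaluate_across_genes: identities and textbook oracle", {
  x <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(evaluate_across_genes(x, x)$r, 1)
  expect_equal(evaluate_across_genes(-x + 1, x)$r, -1)

  set.seed(12)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  got <- evaluate_across_genes(a, b)
  r_text <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_text)
  tstat <- r_text * sqrt(48 / (1 - r_text^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), 48))

  # affine invariance of |r|
  expect_equal(abs(evaluate_across_genes(2 * a + 3, b)$r), abs(got$r))
  expect_true(evaluate_across_genes(rep(1, 5), c(1, 2, 3, 4, 5))$undefined)
  expect_error(evaluate_across_genes(1:2, 1:2), ">= 3")
})

test_that("evaluate_across_individuals: null, signal, mixture recovery", {
  set.seed(13)
  n_ind <- 30
  mk <- function(n_genes, rho) {
    obs <- matrix(rnorm(n_genes * n_ind), n_genes, n_ind,
                  dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
    pred <- rho * obs + sqrt(1 - rho^2) *
      matrix(rnorm(n_genes * n_ind), n_genes, n_ind)
    dimnames(pred) <- dimnames(obs)
    list(pred = pred, obs = obs)
  }
  null <- mk(200, 0)
  ev0 <- suppressWarnings(evaluate_across_individuals(null$pred, null$obs))
  expect_lt(ev0$pi1, 0.12)
  expect_gt(ks.test(ev0$per_gene$p, "punif")$p.value, 0.01)

  sig <- mk(100, 0.995)
  ev1 <- evaluate_across_individuals(sig$pred, sig$obs)
  expect_gt(ev1$m1, 90)

  # 200-gene mixture: 50 true (strong), 150 null
  strong <- mk(50, 0.9); noise <- mk(150, 0)
  pred <- rbind(strong$pred, noise$pred)
  obs <- rbind(strong$obs, noise$obs)
  rownames(pred) <- rownames(obs) <- sprintf("m%03d", 1:200)
  ev <- evaluate_across_individuals(pred, obs)
  expect_gt(ev$m1, 30)
  expect_lt(ev$m1, 75)

  # constant rows are skipped and counted
  pred2 <- pred; pred2[1, ] <- 1
  ev2 <- evaluate_across_individuals(pred2, obs)
  expect_equal(ev2$n_skipped, 1L)
})

test_that("model serialization round trip preserves predictions", {
  task <- linear_task(n = 120, d = 10, seed = 3)
  m <- train_ctpred(task$X, task$y, task$split,
                    ctpred_hyperparams(seed = 4, max_epochs = 8))
  f <- tempfile(fileext = ".json")
  write_ctpred(m, f)
  back <- read_ctpred(f)
  expect_equal(predict(back, task$X), predict(m, task$X))
})
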