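make_tiny_batch <- function(B = 3L, L = 12L, seed = 42L) {
  set.seed(seed)
  X <- array(0, c(B, L, 4L))
  for (b in seq_len(B)) for (l in seq_len(L)) X[b, l, sample.int(4L, 1L)] <- 1
  X
}

test_that("backpropagated gradients match finite differences", {
  cfg <- predictor_config(n_blocks = 2L, filters = 3L, kernel_width = 5L,
                          gru_units = 4L, dense_units = 3L, seed = 7L)
  params <- motifsyntax:::nn_init_params(cfg, 4L)
  X <- make_tiny_batch()
  set.seed(1); y <- rnorm(3L)
  fw <- motifsyntax:::nn_forward(params, cfg, X, keep = TRUE)
  gr <- motifsyntax:::nn_backward(params, cfg, fw, 2 * (fw$yhat - y) / 3)
  lossfun <- function(p)
    mean((motifsyntax:::nn_forward(p, cfg, X)$yhat - y)^2)
  set_leaf <- function(pp, pa, val) {
    if (length(pa) == 1L) pp[[pa]] <- val
    else pp[[pa[1L]]] <- set_leaf(pp[[pa[1L]]], pa[-1L], val)
    pp
  }
  flat_paths <- function(p, pre = integer()) {
    if (is.list(p))
      unlist(lapply(seq_along(p), function(i) flat_paths(p[[i]], c(pre, i))),
             recursive = FALSE)
    else list(pre)
  }
  set.seed(2)
  eps <- 1e-5
  for (pa in flat_paths(params)) {
    pv <- params; gv <- gr
    for (i in pa) { pv <- pv[[i]]; gv <- gv[[i]] }
    for (j in sample(length(pv), min(3L, length(pv)))) {
      up <- pv; up[j] <- up[j] + eps
      dn <- pv; dn[j] <- dn[j] - eps
      num <- (lossfun(set_leaf(params, pa, up)) -
                lossfun(set_leaf(params, pa, dn))) / (2 * eps)
      expect_equal(gv[j], num, tolerance = 1e-4,
                   label = paste("grad at", paste(pa, collapse = "/"), j))
    }
  }
})

test_that("model construction is deterministic and guards its geometry", {
  cfg <- predictor_config(n_blocks = 2L, filters = 8L, gru_units = 8L,
                          dense_units = 8L, seed = 3L)
  m1 <- build_predictor(cfg, 30L)
  m2 <- build_predictor(cfg, 30L)
  probe <- rand_rna(5L, 30L)
  expect_identical(predict(m1, probe), predict(m2, probe))

  expect_error(predictor_config(n_blocks = 10L), "n_blocks")
  ## 4 blocks of width-5 convs over pools of 2 need 68 input positions
  expect_error(build_predictor(predictor_config(n_blocks = 4L), 50L), "68")
})

test_that("n_blocks is the only architecture difference between variants", {
  c4 <- predictor_config(n_blocks = 4L, seed = 1L)
  c6 <- predictor_config(n_blocks = 6L, seed = 1L)
  expect_equal(c4[setdiff(names(c4), "n_blocks")],
               c6[setdiff(names(c6), "n_blocks")])
  expect_equal(c(c4$n_blocks, c6$n_blocks), c(4L, 6L))
})

test_that("training is seed-deterministic and fits constant labels", {
  set.seed(31)
  ds <- labeled_seqs(sprintf("c%03d", 1:300), rand_rna(300L, 20L),
                     rep(0, 300L))
  cfg <- predictor_config(n_blocks = 1L, filters = 8L, gru_units = 8L,
                          dense_units = 8L, batch_size = 32L,
                          learning_rate = 3e-3,
                          max_epochs = 25L, patience = 25L, seed = 9L)
  m1 <- train_predictor(build_predictor(cfg, 20L), ds[1:250], ds[251:300])
  m2 <- train_predictor(build_predictor(cfg, 20L), ds[1:250], ds[251:300])
  expect_identical(m1$training_log, m2$training_log)
  ## constant target: MSE collapses toward zero within the first epochs
  expect_lt(m1$training_log$val_loss[10L], 0.02)
  expect_lt(min(m1$training_log$val_loss), 5e-3)
})

test_that("conv activations are retrievable, shaped, and non-negative", {
  cfg <- predictor_config(n_blocks = 2L, filters = 6L, gru_units = 4L,
                          dense_units = 4L, seed = 5L)
  m <- build_predictor(cfg, 24L)
  ds <- labeled_seqs(c("x", "y"), rand_rna(2L, 24L), c(0, 0))
  a1 <- layer_activations(m, 1L, ds)
  a2 <- layer_activations(m, 2L, ds)
  expect_equal(dim(a1), c(2L, 24L, 6L))
  expect_equal(dim(a2), c(2L, 12L, 6L))
  expect_true(all(a1 >= 0) && all(a2 >= 0))
})

test_that("evaluation metrics agree with an independent reimplementation", {
  set.seed(17)
  obs <- rnorm(100L)
  pred <- obs + rnorm(100L, 0, 0.5)
  seqs <- rand_rna(100L, 15L)
  lookup <- stats::setNames(pred, seqs)
  m <- oracle_model(function(s) unname(lookup[s]))
  ds <- labeled_seqs(sprintf("e%03d", 1:100), seqs, obs)
  got <- evaluate_predictor(m, ds)
  ## straightforward reference formulas
  expect_equal(got$r, sum(scale(pred) * scale(obs)) / 99)
  expect_equal(got$r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_equal(got$mse, mean((obs - pred)^2))

  ident <- oracle_model(function(s) unname(stats::setNames(obs, seqs)[s]))
  perfect <- evaluate_predictor(ident, ds)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mse, 0)
  shifted <- evaluate_predictor(oracle_model(
    function(s) unname(stats::setNames(obs + 2, seqs)[s])), ds)
  expect_equal(shifted$r, 1)
  expect_lt(shifted$r2, 1)
})

test_that("a planted k-mer count is learnable and shuffled labels are not", {
  set.seed(71)
  n <- 5000L
  seqs <- rand_rna(n, 50L)
  plant <- sample(c(TRUE, FALSE), n, replace = TRUE)
  pos <- sample(0:44, n, replace = TRUE)
  for (i in which(plant))
    substr(seqs[i], pos[i] + 1L, pos[i] + 6L) <- "GGACUA"
  counts <- vapply(gregexpr("GGACUA", seqs, fixed = TRUE),
                   function(g) sum(g > 0), numeric(1L))
  ds <- labeled_seqs(sprintf("k%04d", 1:n), seqs, counts)
  sp <- split_dataset(ds, seed = 71L)
  cfg <- predictor_config(n_blocks = 2L, filters = 16L, gru_units = 16L,
                          dense_units = 16L, batch_size = 128L,
                          learning_rate = 2e-3,
                          max_epochs = 30L, patience = 6L, seed = 71L)
  m <- train_predictor(build_predictor(cfg, 50L), sp$train, sp$val)
  expect_gt(evaluate_predictor(m, sp$val)$r, 0.9)

  ## permutation null: same training on shuffled labels learns nothing
  set.seed(72)
  shuf <- ds
  shuf$label <- sample(shuf$label)
  spn <- split_dataset(shuf, seed = 71L)
  spn$train <- spn$train[1:1000]
  cfgn <- predictor_config(n_blocks = 1L, filters = 8L, gru_units = 8L,
                           dense_units = 8L, batch_size = 256L,
                           max_epochs = 5L, patience = 5L, seed = 73L)
  mn <- train_predictor(build_predictor(cfgn, 50L), spn$train, spn$val)
  r_null <- evaluate_predictor(mn, spn$val)$r
  expect_lt(abs(r_null), 0.1)
})

test_that("training aborts with a diagnostic on divergence", {
  set.seed(51)
  ## labels near the double-precision ceiling overflow the squared loss
  ds <- labeled_seqs(sprintf("d%03d", 1:200), rand_rna(200L, 16L),
                     rnorm(200L, 0, 1e200))
  cfg <- predictor_config(n_blocks = 1L, filters = 4L, gru_units = 4L,
                          dense_units = 4L, batch_size = 64L,
                          max_epochs = 3L, seed = 1L)
  expect_error(train_predictor(build_predictor(cfg, 16L),
                               ds[1:150], ds[151:200]),
               "diverged|non-finite")
})

test_that("dropout, weight decay and shift augmentation train deterministically", {
  set.seed(91)
  seqs <- rand_rna(400L, 30L)
  has <- grepl("GGACU", seqs, fixed = TRUE)
  labs <- as.numeric(has) + rnorm(400L, 0, 0.1)
  ds <- labeled_seqs(sprintf("g%03d", 1:400), seqs, labs)
  cfg <- predictor_config(n_blocks = 1L, filters = 8L, gru_units = 8L,
                          dense_units = 8L, batch_size = 64L,
                          learning_rate = 3e-3, max_epochs = 8L,
                          patience = 8L, dropout = 0.2, conv_dropout = 0.1,
                          weight_decay = 1e-3, augment_shift = 6L, seed = 92L)
  m1 <- train_predictor(build_predictor(cfg, 30L), ds[1:320], ds[321:400])
  m2 <- train_predictor(build_predictor(cfg, 30L), ds[1:320], ds[321:400])
  expect_identical(m1$training_log, m2$training_log)
  ## loss decreases despite the stochastic regularization
  expect_lt(m1$training_log$val_loss[8L], m1$training_log$val_loss[1L])
  ## predictions are dropout-free and deterministic
  expect_identical(predict(m1, ds[1:5]), predict(m1, ds[1:5]))
})
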