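## Shared helpers: random sequences, closed-form oracle "models" for the
## mutagenesis machinery, and lazily computed heavy fixtures reused
## across files.

rand_rna <- function(n, L) {
  m <- matrix(sample(c("A", "C", "G", "U"), n * L, replace = TRUE), n, L)
  apply(m, 1L, paste, collapse = "")
}

## an oracle model is any object with a predict() method mapping a
## character vector of sequences to numbers; the mutagenesis code only
## relies on that contract
oracle_model <- function(f) structure(list(f = f), class = "test_oracle")
predict.test_oracle <- function(object, newdata, ...) {
  if (!is.character(newdata)) newdata <- newdata$sequence
  object$f(newdata)
}
.S3method("predict", "test_oracle", predict.test_oracle)

## presence-based oracle: y = sum(e_m * present) + e_ab * both(first two)
presence_oracle <- function(consensi, effects, e_ab = 0) {
  oracle_model(function(seqs) {
    P <- vapply(consensi, function(cs) grepl(cs, seqs, fixed = TRUE),
                logical(length(seqs)))
    if (is.vector(P)) P <- t(as.matrix(P))
    y <- as.numeric(P %*% effects)
    if (e_ab != 0) y <- y + e_ab * (P[, 1L] & P[, 2L])
    y
  })
}

## exact probability that a uniform random L-mer contains no AUG, via
## the prefix automaton of the pattern (states: matched prefix 0, A, AU)
uaug_survival_exact <- function(L) {
  T <- matrix(0, 3L, 3L)
  T[1, 1] <- 3 / 4; T[1, 2] <- 1 / 4          # '' -> A or stay
  T[2, 1] <- 2 / 4; T[2, 2] <- 1 / 4; T[2, 3] <- 1 / 4  # 'A'
  T[3, 1] <- 2 / 4; T[3, 2] <- 1 / 4          # 'AU' (G would complete)
  v <- c(1, 0, 0)
  for (i in seq_len(L)) v <- as.numeric(v %*% T)
  sum(v)
}

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## 5,000 random 50-mers, half carrying a planted PUF element (UGUAAAUA);
## labels y = 1 * present + N(0, 0.3) (effect > 2 SD of noise); a small
## two-block model trained on it. Its layer-2 receptive field (14 nt)
## spans the 8-mer. Used for planted-motif recovery and contribution
## sign consistency.
planted_fixture <- function() fixture("planted", function() {
  set.seed(401)
  n <- 5000L
  seqs <- rand_rna(n, 50L)
  carry <- seq_len(n) <= n / 2
  pos <- sample(0:42, n, replace = TRUE)
  for (i in which(carry))
    substr(seqs[i], pos[i] + 1L, pos[i] + 8L) <- "UGUAAAUA"
  labels <- as.numeric(carry) + rnorm(n, 0, 0.3)
  ds <- labeled_seqs(sprintf("p%04d", seq_len(n)), seqs, labels)
  sp <- split_dataset(ds, seed = 401L)
  cfg <- predictor_config(n_blocks = 2L, filters = 16L, gru_units = 16L,
                          dense_units = 16L, batch_size = 256L,
                          max_epochs = 15L, patience = 4L, seed = 401L)
  model <- train_predictor(build_predictor(cfg, 50L), sp$train, sp$val)
  list(model = model, split = sp, data = ds, carry = carry)
})

## benchmark runs shared between the acceptance criteria and the
## designed-vs-random superiority property
designed_benchmark <- function(seed) fixture(paste0("designed", seed), function() {
  spec <- simulation_spec(20000L, "designed", dense_interactions = TRUE,
                          seed = seed)
  recovery_benchmark(spec, max_clusters = 8L)
})
random_benchmark <- function(seed) fixture(paste0("random", seed), function() {
  spec <- simulation_spec(20000L, "random", dense_interactions = TRUE,
                          seed = seed)
  recovery_benchmark(spec, max_clusters = 8L)
})
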