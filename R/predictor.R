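#' Configuration for the sequence-to-function predictor
#'
#' The predictor is a hybrid convolutional-recurrent network: `n_blocks`
#' intermediate blocks (layer normalization, width-`kernel_width`
#' convolution with `filters` neurons, ReLU, width-`pool_width` max
#' pooling), followed by a GRU whose final hidden state feeds a dense ReLU
#' layer and a linear scalar output. Half-life style models use 6 blocks
#' and mean-ribosome-load style models 4; the simulation benchmark uses 3.
#'
#' Defaults (64 filters, kernel 5, pool 2, 64 GRU/dense units, Adam with
#' learning rate 1e-3, batch 128, early-stopping patience 5) are a
#' desk-trainable operating point for the model class; none of them is
#' architectural dogma and all are plain config fields.
#'
#' @param n_blocks number of intermediate blocks, 1-8.
#' @param filters convolutional neurons per block.
#' @param kernel_width odd convolution width (same padding).
#' @param pool_width max-pool width and stride.
#' @param gru_units,dense_units recurrent and dense layer sizes.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs,patience training length and early-stopping patience
#'   (epochs without validation improvement).
#' @param weight_decay decoupled (AdamW-style) weight decay applied to
#'   weight matrices (not biases or layer-norm gains).
#' @param dropout dropout rate on the recurrent summary and dense hidden
#'   layer during training (inverted scaling; inference is dropout-free).
#' @param conv_dropout dropout rate on the post-ReLU convolutional
#'   activations of every block (training only); useful against
#'   memorization on small datasets.
#' @param augment_shift stochastic shift augmentation: during training
#'   each sequence is placed at a uniform-random offset in 0..`augment_shift`
#'   (left-padded with zero rows). Motif-syntax labels are position-free,
#'   so the shift is label-preserving; it suppresses positional
#'   memorization on small datasets.
#' @param seed integer controlling parameter initialization and data order.
#' @param use_tracks encode codon-frame/splice channels (6 input channels).
#' @return object of class `"predictor_config"`.
#' @export
predictor_config <- function(n_blocks = 4L, filters = 64L, kernel_width = 5L,
                             pool_width = 2L, gru_units = 64L,
                             dense_units = 64L, learning_rate = 1e-3,
                             batch_size = 128L, max_epochs = 50L,
                             patience = 5L, weight_decay = 0, dropout = 0,
                             conv_dropout = 0, augment_shift = 0L,
                             seed = 1L, use_tracks = FALSE) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L || n_blocks > 8L)
    stop("n_blocks must be in 1..8, got ", n_blocks, call. = FALSE)
  if (kernel_width %% 2L != 1L || kernel_width < 3L)
    stop("kernel_width must be odd and >= 3", call. = FALSE)
  if (pool_width < 1L) stop("pool_width must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(list(n_blocks = n_blocks, filters = as.integer(filters),
                 kernel_width = as.integer(kernel_width),
                 pool_width = as.integer(pool_width),
                 gru_units = as.integer(gru_units),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, dropout = dropout,
                 conv_dropout = conv_dropout,
                 augment_shift = as.integer(augment_shift),
                 seed = as.integer(seed),
                 use_tracks = isTRUE(use_tracks)),
            class = "predictor_config")
}

#' Receptive field of a convolutional layer
#'
#' Exact window of input positions that can influence one activation of
#' layer `layer_index` (the post-ReLU output of that block's convolution),
#' from the standard composition of convolution and pooling: a width-K
#' same-padded convolution grows the field by `(K-1) * jump` and a
#' width-P pool grows it by `(P-1) * jump` before multiplying the jump
#' by P.
#'
#' @param x a `predictor_config` or fitted model.
#' @param layer_index 1-based convolutional block index.
#' @return list with `width`, `stride` (input positions per unit step of
#'   the layer), and `offset` (start of the window for layer position 0;
#'   negative near the left edge because of same padding).
#' @export
receptive_field <- function(x, layer_index) {
  cfg <- if (inherits(x, "seqfun_model")) x$config else x
  stopifnot(inherits(cfg, "predictor_config"))
  layer_index <- as.integer(layer_index)
  if (layer_index < 1L || layer_index > cfg$n_blocks)
    stop("layer_index must be in 1..", cfg$n_blocks, call. = FALSE)
  K <- cfg$kernel_width; P <- cfg$pool_width
  p <- (K - 1L) %/% 2L
  S <- 1L; O <- 0L; R <- 1L
  for (i in seq_len(layer_index)) {
    Rc <- R + (K - 1L) * S
    Oc <- O - p * S
    if (i == layer_index)
      return(list(width = Rc, stride = S, offset = Oc))
    R <- Rc + (P - 1L) * S
    O <- Oc
    S <- S * P
  }
}

#' Build an untrained sequence-to-function predictor
#'
#' Parameter initialization is fully determined by `config$seed`; the
#' returned model predicts (badly) and exposes per-layer activations, but
#' is meant to be passed to [train_predictor()].
#'
#' @param config a [predictor_config()].
#' @param seq_length length of the (padded) input sequences the model is
#'   intended for; the receptive field of the last convolution must fit.
#' @param n_channels 4 (ACGU) or 6 (with annotation tracks).
#' @return object of class `"seqfun_model"`.
#' @export
build_predictor <- function(config, seq_length, n_channels = 4L) {
  stopifnot(inherits(config, "predictor_config"))
  rf <- receptive_field(config, config$n_blocks)
  if (rf$width > seq_length)
    stop("receptive field of last conv layer (", rf$width,
         ") exceeds sequence length (", seq_length, ")", call. = FALSE)
  L <- seq_length
  for (i in seq_len(config$n_blocks)) {
    L <- L %/% config$pool_width
    if (L < 1L)
      stop("sequence length ", seq_length, " collapses to zero after block ",
           i, " pooling", call. = FALSE)
  }
  params <- nn_init_params(config, n_channels)
  structure(list(config = config, params = params,
                 seq_length = as.integer(seq_length),
                 n_channels = as.integer(n_channels),
                 training_log = NULL, trained = FALSE),
            class = "seqfun_model")
}

#' Train a predictor by minibatch Adam with early stopping
#'
#' Minimizes mean squared error on the scalar label. The learning rate
#' is halved whenever the validation MSE has not improved for 5 epochs
#' (reduce-on-plateau, floored at an eighth of the configured rate), and
#' training stops when it has not improved for `patience` epochs (or at
#' `max_epochs`); the parameters from the best validation epoch are
#' kept. All randomness (shuffling)
#' is controlled by `config$seed`, so a fixed seed and fixed data give
#' an identical training log.
#'
#' @param model an untrained model from [build_predictor()].
#' @param train_set,val_set [labeled_seqs()] sets.
#' @param verbose print per-epoch losses.
#' @return the trained `"seqfun_model"` (training log in
#'   `model$training_log`).
#' @export
train_predictor <- function(model, train_set, val_set, verbose = FALSE) {
  stopifnot(inherits(model, "seqfun_model"))
  if (!length(train_set) || !length(val_set))
    stop("training and validation sets must be non-empty", call. = FALSE)
  cfg <- model$config
  Xtr <- encode_set(train_set, use_tracks = cfg$use_tracks)
  ytr <- train_set$label
  Xval <- encode_set(val_set, use_tracks = cfg$use_tracks)
  yval <- val_set$label
  lens_tr <- attr(Xtr, "lengths")
  n <- dim(Xtr)[1L]
  params <- model$params
  state <- adam_init(params)
  best <- list(val = Inf, params = params, wait = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  lr <- cfg$learning_rate
  stale <- 0L
  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    tr_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      B <- length(idx)
      xb <- Xtr[idx, , , drop = FALSE]
      lens_b <- lens_tr[idx]
      if (cfg$augment_shift > 0L) {
        sh <- sample.int(cfg$augment_shift + 1L, B, replace = TRUE) - 1L
        L0 <- dim(xb)[2L]
        xs <- array(0, c(B, L0 + cfg$augment_shift, dim(xb)[3L]))
        for (bi in seq_len(B))
          xs[bi, (sh[bi] + 1L):(sh[bi] + L0), ] <- xb[bi, , ]
        xb <- xs
        lens_b <- lens_b + sh
      }
      fw <- nn_forward(params, cfg, xb, lens = lens_b, keep = TRUE,
                       dropout = cfg$dropout,
                       conv_dropout = cfg$conv_dropout)
      err <- fw$yhat - ytr[idx]
      loss <- mean(err * err)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate", call. = FALSE)
      tr_loss <- tr_loss + loss * B
      grads <- nn_backward(params, cfg, fw, 2 * err / B)
      up <- adam_step(params, grads, state, lr, wd = cfg$weight_decay)
      params <- up$params
      state <- up$state
    }
    pv <- predict_encoded(params, cfg, Xval)
    val_loss <- mean((pv - yval)^2)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss / n,
                                 val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      tr_loss / n, val_loss))
    if (val_loss < best$val - 1e-7) {
      best <- list(val = val_loss, params = params, wait = 0L)
      stale <- 0L
    } else {
      best$wait <- best$wait + 1L
      stale <- stale + 1L
      if (best$wait >= cfg$patience) break
      ## gentle reduce-on-plateau; the floor keeps enough step size for
      ## late feature-learning breakthroughs on small datasets
      if (stale >= 5L && lr > cfg$learning_rate / 8) {
        lr <- max(lr * 0.5, cfg$learning_rate / 8)
        stale <- 0L
      }
    }
  }
  model$params <- best$params
  model$training_log <- log
  model$trained <- TRUE
  model
}

predict_encoded <- function(params, cfg, X, chunk = 1024L) {
  n <- dim(X)[1L]
  lens <- attr(X, "lengths")
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx] <- nn_forward(params, cfg, X[idx, , , drop = FALSE],
                           lens = lens[idx])$yhat
  }
  out
}

#' Predict labels for new sequences
#'
#' Deterministic given fixed parameters and input.
#'
#' @param object a `"seqfun_model"`.
#' @param newdata a [labeled_seqs()] set, a character vector of sequences,
#'   or a pre-encoded `(n, L, C)` array.
#' @param ... unused.
#' @return numeric vector of predictions on the label scale.
#' @export
predict.seqfun_model <- function(object, newdata, ...) {
  X <- if (is.array(newdata) && length(dim(newdata)) == 3L) newdata
  else if (is.character(newdata))
    encode_set(labeled_seqs(paste0("q", seq_along(newdata)), newdata,
                            rep(0, length(newdata))),
               use_tracks = FALSE)
  else encode_set(newdata, use_tracks = object$config$use_tracks)
  predict_encoded(object$params, object$config, X)
}

#' Evaluate a predictor on a held-out set
#'
#' @param model trained `"seqfun_model"`.
#' @param test_set [labeled_seqs()] set disjoint from training data.
#' @return list with Pearson `r`, `r2` (1 - SSres/SStot) and `mse`, all on
#'   the raw label scale.
#' @export
evaluate_predictor <- function(model, test_set) {
  pred <- predict(model, test_set)
  obs <- test_set$label
  list(r = cor(pred, obs),
       r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
       mse = mean((obs - pred)^2))
}

#' Per-position activations of a convolutional layer
#'
#' Returns the post-ReLU activations of every neuron of one block's
#' convolution (before pooling), the quantity consumed by seqlet
#' extraction and contribution analysis. Activations are non-negative by
#' construction.
#'
#' @param model a `"seqfun_model"`.
#' @param layer_index 1-based block index.
#' @param data [labeled_seqs()] set or encoded array.
#' @param chunk sequences per forward chunk.
#' @return array `(n, positions_at_layer, filters)`.
#' @export
layer_activations <- function(model, layer_index, data, chunk = 512L) {
  cfg <- model$config
  stopifnot(layer_index >= 1L, layer_index <= cfg$n_blocks)
  X <- if (is.array(data)) data
  else encode_set(data, use_tracks = cfg$use_tracks)
  n <- dim(X)[1L]
  lens <- attr(X, "lengths")
  out <- NULL
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    fw <- nn_forward(model$params, cfg, X[idx, , , drop = FALSE],
                     lens = lens[idx], keep_acts = TRUE)
    a <- fw$acts[[layer_index]]
    if (is.null(out)) out <- array(0, c(n, dim(a)[2L], dim(a)[3L]))
    out[idx, , ] <- a
  }
  out
}

#' Deterministic train/validation/test split by id hash
#'
#' Records are assigned by hashing `paste(id, seed)`, so the split is
#' stable under reordering and reproducible across runs.
#'
#' @param x a [labeled_seqs()] set.
#' @param fractions length-3 positive weights for train/val/test.
#' @param seed split seed.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(x, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  fr <- cumsum(fractions / sum(fractions))
  u <- vapply(paste(x$id, seed), fnv1a32, numeric(1L)) / 4294967296
  grp <- findInterval(u, fr[1:2]) + 1L
  list(train = x[grp == 1L], val = x[grp == 2L], test = x[grp == 3L])
}

#' @export
print.seqfun_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<seqfun_model> %d block(s) x %d filters (kernel %d, ",
                     "pool %d), GRU %d, dense %d; input %dnt x %dch; %s\n"),
              cfg$n_blocks, cfg$filters, cfg$kernel_width, cfg$pool_width,
              cfg$gru_units, cfg$dense_units, x$seq_length, x$n_channels,
              if (x$trained) sprintf("trained (%d epochs, best val MSE %.4g)",
                                     nrow(x$training_log),
                                     min(x$training_log$val_loss))
              else "untrained"))
  invisible(x)
}

#' @export
summary.seqfun_model <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("training log (last epochs):\n")
    print(utils::tail(object$training_log, 5L), row.names = FALSE)
  }
  for (i in seq_len(object$config$n_blocks)) {
    rf <- receptive_field(object, i)
    cat(sprintf("  conv block %d: receptive field %d nt, stride %d\n",
                i, rf$width, rf$stride))
  }
  invisible(object)
}

#' @export
plot.seqfun_model <- function(x, ...) {
  if (!x$trained) stop("nothing to plot: model is untrained", call. = FALSE)
  log <- x$training_log
  graphics::matplot(log$epoch, cbind(log$train_loss, log$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.seqfun_model <- function(object, data, ...) {
  data$label - predict(object, data)
}
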