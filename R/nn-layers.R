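## Internal neural-network engine.
##
## The predictor is a stack of (layer norm -> same-padded 1-D convolution ->
## ReLU -> max pool) blocks, a GRU read over the pooled frames, and a dense
## ReLU head with a linear scalar output. Gradients are derived by hand and
## verified against finite differences in the test suite.
##
## Layout: a batch of activations at length L with C channels lives in a
## (B*L) x C matrix whose rows are ordered batch-fastest (row = b + B*(l-1)).
## A shift of the position index is then a contiguous row-range copy, which
## makes the im2col convolution and the max-pool plain memcpy + BLAS work.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_init_params <- function(cfg, n_channels) {
  set.seed(cfg$seed)
  K <- cfg$kernel_width; Fn <- cfg$filters
  H <- cfg$gru_units; D <- cfg$dense_units
  gaus <- function(n, m, s) matrix(rnorm(n * m, 0, s), n, m)
  blocks <- vector("list", cfg$n_blocks)
  C_in <- n_channels
  for (i in seq_len(cfg$n_blocks)) {
    blocks[[i]] <- list(
      lng = rep(1, C_in), lnb = rep(0, C_in),
      W = gaus(K * C_in, Fn, sqrt(2 / (K * C_in))),
      b = rep(0, Fn))
    C_in <- Fn
  }
  gru <- list(
    Uz = gaus(Fn, H, sqrt(1 / Fn)), Ur = gaus(Fn, H, sqrt(1 / Fn)),
    Uh = gaus(Fn, H, sqrt(1 / Fn)),
    Wz = gaus(H, H, sqrt(1 / H)), Wr = gaus(H, H, sqrt(1 / H)),
    Wh = gaus(H, H, sqrt(1 / H)),
    bz = rep(0, H), br = rep(0, H), bh = rep(0, H))
  list(blocks = blocks, gru = gru,
       Wd = gaus(H, D, sqrt(2 / H)), bd = rep(0, D),
       wo = gaus(D, 1, sqrt(1 / D)), bo = 0)
}

## im2col for a same-padded width-K convolution; M is (B*Lc) x C.
## Column block k holds the input shifted by s = k-1-p positions, zero
## outside the sequence.
conv_cols <- function(M, B, Lc, C, K) {
  p <- (K - 1L) %/% 2L
  n <- B * Lc
  Xc <- matrix(0, n, K * C)
  for (k in seq_len(K)) {
    s <- k - 1L - p
    cols <- ((k - 1L) * C + 1L):(k * C)
    if (s == 0L) Xc[, cols] <- M
    else if (s > 0L) Xc[1L:(n - B * s), cols] <- M[(B * s + 1L):n, ]
    else Xc[(B * (-s) + 1L):n, cols] <- M[1L:(n + B * s), ]
  }
  Xc
}

conv_cols_backward <- function(dXc, B, Lc, C, K) {
  p <- (K - 1L) %/% 2L
  n <- B * Lc
  dM <- matrix(0, n, C)
  for (k in seq_len(K)) {
    s <- k - 1L - p
    cols <- ((k - 1L) * C + 1L):(k * C)
    if (s == 0L) dM <- dM + dXc[, cols]
    else if (s > 0L)
      dM[(B * s + 1L):n, ] <- dM[(B * s + 1L):n, ] + dXc[1L:(n - B * s), cols]
    else
      dM[1L:(n + B * s), ] <- dM[1L:(n + B * s), ] + dXc[(B * (-s) + 1L):n, cols]
  }
  dM
}

## row indices of pool-slot q (1..P) for a (B, Lc) layout pooled to Lo
pool_rows <- function(B, Lo, P, q) {
  rep((seq_len(Lo) - 1L) * P + q - 1L, each = B) * B + seq_len(B)
}

## Forward pass. keep = TRUE stores layer caches for backprop;
## keep_acts = TRUE returns post-ReLU conv activations (pre-pool) per
## block as (B, L, F) arrays, the quantity neuron interpretation consumes.
nn_forward <- function(params, cfg, X, lens = NULL, keep = FALSE,
                       keep_acts = FALSE, dropout = 0, conv_dropout = 0) {
  d <- dim(X); B <- d[1L]; L <- d[2L]
  if (is.null(lens)) lens <- attr(X, "lengths")
  if (is.null(lens)) lens <- rep(L, B)
  P <- cfg$pool_width; K <- cfg$kernel_width
  M <- matrix(X, B * L, d[3L])  # (b,l)-major rows: b fastest
  Lc <- L; C <- d[3L]
  lens_cur <- lens
  caches <- if (keep) vector("list", cfg$n_blocks)
  acts <- if (keep_acts) vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    bl <- params$blocks[[i]]
    n <- B * Lc
    ## layer norm over channels, per (sequence, position)
    mu <- rowMeans(M)
    xc <- M - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + 1e-5)
    xhat <- xc * inv
    y <- xhat * rep(bl$lng, each = n) + rep(bl$lnb, each = n)
    ## convolution + ReLU, padded positions masked to zero
    Xc <- conv_cols(y, B, Lc, C, K)
    Z <- Xc %*% bl$W + rep(bl$b, each = n)
    if (any(lens_cur < Lc))
      Z <- Z * (rep(seq_len(Lc), each = B) <= lens_cur)
    R <- pmax(Z, 0)
    mask <- if (keep) R > 0
    Fn <- ncol(R)
    if (keep_acts) acts[[i]] <- array(R, c(B, Lc, Fn))
    cmask <- NULL
    if (conv_dropout > 0) {
      cmask <- (matrix(runif(n * Fn), n) >= conv_dropout) / (1 - conv_dropout)
      R <- R * cmask
    }
    ## max pool (width P, stride P); trailing remainder positions dropped
    Lo <- Lc %/% P
    Ymax <- R[pool_rows(B, Lo, P, 1L), , drop = FALSE]
    pidx <- matrix(1L, B * Lo, Fn)
    if (P > 1L) for (q in 2:P) {
      cand <- R[pool_rows(B, Lo, P, q), , drop = FALSE]
      upd <- cand > Ymax
      Ymax[upd] <- cand[upd]
      pidx[upd] <- q
    }
    if (keep)
      caches[[i]] <- list(xhat = xhat, inv = inv, Xc = Xc, mask = mask,
                          cmask = cmask, pidx = pidx, Lc = Lc, C = C)
    M <- Ymax
    Lc <- Lo
    C <- Fn
    lens_cur <- pmax(1L, lens_cur %/% P)
  }
  ## GRU over pooled frames; final hidden state is the sequence summary
  g <- params$gru
  Tn <- Lc; Fn <- C; H <- ncol(g$Uz)
  h <- matrix(0, B, H)
  gcache <- if (keep) list(xs = vector("list", Tn), hprev = vector("list", Tn),
                           z = vector("list", Tn), r = vector("list", Tn),
                           hh = vector("list", Tn))
  for (t in seq_len(Tn)) {
    xt <- M[((t - 1L) * B + 1L):(t * B), , drop = FALSE]
    z <- sigmoid(xt %*% g$Uz + h %*% g$Wz + rep(g$bz, each = B))
    r <- sigmoid(xt %*% g$Ur + h %*% g$Wr + rep(g$br, each = B))
    hh <- tanh(xt %*% g$Uh + (r * h) %*% g$Wh + rep(g$bh, each = B))
    hn <- (1 - z) * h + z * hh
    if (keep) {
      gcache$xs[[t]] <- xt; gcache$hprev[[t]] <- h
      gcache$z[[t]] <- z; gcache$r[[t]] <- r; gcache$hh[[t]] <- hh
    }
    h <- hn
  }
  ## inverted dropout on the sequence summary and the dense hidden layer
  ## (training only; predictions always run with dropout = 0)
  hd <- h
  dm1 <- NULL; dm2 <- NULL
  if (dropout > 0) {
    dm1 <- matrix(runif(length(h)) >= dropout, nrow(h)) / (1 - dropout)
    hd <- h * dm1
  }
  d1p <- hd %*% params$Wd + rep(params$bd, each = B)
  d1 <- d1p * (d1p > 0)
  d1d <- d1
  if (dropout > 0) {
    dm2 <- matrix(runif(length(d1)) >= dropout, nrow(d1)) / (1 - dropout)
    d1d <- d1 * dm2
  }
  yhat <- drop(d1d %*% params$wo) + params$bo
  out <- list(yhat = yhat)
  if (keep)
    out <- c(out, list(caches = caches, gcache = gcache, h = h, hd = hd,
                       d1 = d1, d1d = d1d, d1p = d1p, dm1 = dm1, dm2 = dm2,
                       B = B, Tn = Tn, Fn = Fn))
  if (keep_acts) out$acts <- acts
  out
}

nn_backward <- function(params, cfg, fw, dy) {
  B <- fw$B; Tn <- fw$Tn; Fn <- fw$Fn
  g <- params$gru; H <- ncol(g$Uz)
  grads <- list(blocks = vector("list", cfg$n_blocks), gru = NULL)
  ## head
  dd1d <- outer(dy, drop(params$wo))
  if (!is.null(fw$dm2)) dd1d <- dd1d * fw$dm2
  dd1 <- dd1d * (fw$d1p > 0)
  grads$wo <- crossprod(fw$d1d, dy)
  grads$bo <- sum(dy)
  grads$Wd <- crossprod(fw$hd, dd1)
  grads$bd <- colSums(dd1)
  dh <- dd1 %*% t(params$Wd)
  if (!is.null(fw$dm1)) dh <- dh * fw$dm1
  ## GRU backward through time
  zg <- function(a, b) matrix(0, a, b)
  gg <- list(Uz = zg(Fn, H), Ur = zg(Fn, H), Uh = zg(Fn, H),
             Wz = zg(H, H), Wr = zg(H, H), Wh = zg(H, H),
             bz = rep(0, H), br = rep(0, H), bh = rep(0, H))
  dM <- matrix(0, B * Tn, Fn)
  gc <- fw$gcache
  for (t in rev(seq_len(Tn))) {
    xt <- gc$xs[[t]]; hprev <- gc$hprev[[t]]
    z <- gc$z[[t]]; r <- gc$r[[t]]; hh <- gc$hh[[t]]
    dz <- dh * (hh - hprev)
    dhh <- dh * z
    dhprev <- dh * (1 - z)
    dhh_pre <- dhh * (1 - hh * hh)
    gg$Uh <- gg$Uh + crossprod(xt, dhh_pre)
    gg$Wh <- gg$Wh + crossprod(r * hprev, dhh_pre)
    gg$bh <- gg$bh + colSums(dhh_pre)
    drh <- dhh_pre %*% t(g$Wh)
    dr <- drh * hprev
    dhprev <- dhprev + drh * r
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    gg$Uz <- gg$Uz + crossprod(xt, dz_pre)
    gg$Wz <- gg$Wz + crossprod(hprev, dz_pre)
    gg$bz <- gg$bz + colSums(dz_pre)
    gg$Ur <- gg$Ur + crossprod(xt, dr_pre)
    gg$Wr <- gg$Wr + crossprod(hprev, dr_pre)
    gg$br <- gg$br + colSums(dr_pre)
    dhprev <- dhprev + dz_pre %*% t(g$Wz) + dr_pre %*% t(g$Wr)
    dM[((t - 1L) * B + 1L):(t * B), ] <-
      dhh_pre %*% t(g$Uh) + dz_pre %*% t(g$Uz) + dr_pre %*% t(g$Ur)
    dh <- dhprev
  }
  grads$gru <- gg
  ## conv blocks, last to first
  P <- cfg$pool_width; K <- cfg$kernel_width
  dY <- dM
  for (i in rev(seq_len(cfg$n_blocks))) {
    ca <- fw$caches[[i]]
    bl <- params$blocks[[i]]
    Lc <- ca$Lc; C <- ca$C; n <- B * Lc
    Fi <- ncol(dY)
    Lo <- nrow(dY) %/% B
    ## unpool: route gradient to the argmax slot
    dR <- matrix(0, n, Fi)
    for (q in seq_len(P))
      dR[pool_rows(B, Lo, P, q), ] <- dY * (ca$pidx == q)
    if (!is.null(ca$cmask)) dR <- dR * ca$cmask
    dZ <- dR * ca$mask
    grads$blocks[[i]] <- list(
      lng = NULL, lnb = NULL,
      W = crossprod(ca$Xc, dZ), b = colSums(dZ))
    dXc <- dZ %*% t(bl$W)
    dy_ln <- conv_cols_backward(dXc, B, Lc, C, K)
    ## layer norm backward
    dxhat <- dy_ln * rep(bl$lng, each = n)
    grads$blocks[[i]]$lng <- colSums(dy_ln * ca$xhat)
    grads$blocks[[i]]$lnb <- colSums(dy_ln)
    rm1 <- rowMeans(dxhat)
    rm2 <- rowMeans(dxhat * ca$xhat)
    dY <- ca$inv * (dxhat - rm1 - ca$xhat * rm2)
  }
  grads[names(params)]
}

## Adam optimizer over the nested parameter list
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, wd = 0) {
  state$t <- state$t + 1L
  t <- state$t
  step_rec <- function(p, g, m, v, decay) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- step_rec(p[[k]], g[[k]], m[[k]], v[[k]], decay)
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      pn <- p - lr * mh / (sqrt(vh) + eps)
      if (decay && is.matrix(p)) pn <- pn - lr * wd * pn
      list(p = pn, m = m, v = v)
    }
  }
  r <- step_rec(params, grads, state$m, state$v, wd > 0)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
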