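## Compact convolutional network engine. Activations live in a flat matrix
## layout — rows run over (pixel within image, then image in batch), columns
## over channels — so convolutions are BLAS matrix products through an im2col
## expansion with precomputed gather indices, and batch normalization / ReLU
## are plain column operations with no array reshuffling. 2x2 max pooling and
## the global max pool are index gathers computed per layer shape. Training is
## plain stochastic gradient descent with momentum; everything is
## deterministic under a seed.

# Gather-index matrix for 3x3 same-padding convolution over an (H, W, Cin)
# tensor padded to (H+2, W+2, Cin). Rows: output pixels in column-major
# (row fastest) order; columns: offset-major, channel within offset.
make_im2col_idx <- function(H, W, Cin) {
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W) + 1L
  j <- rep(seq_len(W), each = H) + 1L
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  idx <- matrix(0L, H * W, 9L * Cin)
  for (o in seq_len(9L)) {
    base <- (i + offs[o, 1]) + (j + offs[o, 2] - 1L) * Hp
    for (c in seq_len(Cin)) {
      idx[, (o - 1L) * Cin + c] <- base + (c - 1L) * Hp * Wp
    }
  }
  idx
}

# linear indices of the interior (unpadded) pixels of a padded (Hp, Wp, Cin)
# array, in (pixel, channel) order
make_unpad_idx <- function(H, W, Cin) {
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W) + 1L
  j <- rep(seq_len(W), each = H) + 1L
  base <- i + (j - 1L) * Hp
  as.vector(outer(base, (seq_len(Cin) - 1L) * Hp * Wp, "+"))
}

conv_init <- function(H, W, Cin, Cout) {
  list(W = matrix(stats::rnorm(9 * Cin * Cout, 0, sqrt(2 / (9 * Cin))),
                  9 * Cin, Cout),
       b = numeric(Cout),
       vW = matrix(0, 9 * Cin, Cout), vb = numeric(Cout),
       idx = make_im2col_idx(H, W, Cin),
       unpad = make_unpad_idx(H, W, Cin),
       height = H, width = W, Cin = Cin, Cout = Cout)
}

# X: (H*W*B x Cin) activations in flat layout -> im2col matrix
# (H*W*B x 9*Cin), same row order.
im2col_batch <- function(X, B, layer) {
  H <- layer$height; W <- layer$width; Cin <- layer$Cin
  hw <- H * W
  Hp <- H + 2L; Wp <- W + 2L
  cols <- matrix(0, hw * B, 9L * Cin)
  xp <- numeric(Hp * Wp * Cin)
  iv <- as.vector(layer$idx)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * hw + 1L):(b * hw)
    xp[layer$unpad] <- X[rows, ]
    cols[rows, ] <- matrix(xp[iv], hw, 9L * Cin)
  }
  cols
}

conv_forward <- function(X, B, layer) {
  cols <- im2col_batch(X, B, layer)
  y <- cols %*% layer$W
  list(out = y + rep(layer$b, each = nrow(y)), cols = cols)
}

conv_backward <- function(D, B, cache_cols, layer) {
  H <- layer$height; W <- layer$width; Cin <- layer$Cin
  hw <- H * W
  dW <- crossprod(cache_cols, D)
  db <- colSums(D)
  dcols <- D %*% t(layer$W)
  Hp <- H + 2L; Wp <- W + 2L
  dX <- matrix(0, hw * B, Cin)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * hw + 1L):(b * hw)
    dxp <- numeric(Hp * Wp * Cin)
    for (o in seq_len(9L)) {
      cc <- ((o - 1L) * Cin + 1L):(o * Cin)
      pos <- as.vector(layer$idx[, cc])
      dxp[pos] <- dxp[pos] + dcols[rows, cc]
    }
    dX[rows, ] <- dxp[layer$unpad]
  }
  list(dx = dX, dW = dW, db = db)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       vgamma = numeric(C), vbeta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C), eps = 1e-5, mom = 0.1)
}

bn_forward <- function(X, bn, training = TRUE) {
  if (training) {
    mu <- colMeans(X)
    xc <- col_sub(X, mu)
    v <- colMeans(xc^2)
    bn$run_mean <- (1 - bn$mom) * bn$run_mean + bn$mom * mu
    bn$run_var <- (1 - bn$mom) * bn$run_var + bn$mom * v
  } else {
    xc <- col_sub(X, bn$run_mean)
    v <- bn$run_var
  }
  istd <- 1 / sqrt(v + bn$eps)
  xhat <- col_mul(xc, istd)
  y <- col_add(col_mul(xhat, bn$gamma), bn$beta)
  list(out = y, bn = bn, cache = list(xhat = xhat, istd = istd))
}

bn_backward <- function(dY, bn, cache) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- col_mul(dY, bn$gamma)
  dX <- col_mul(col_sub(dxhat, colMeans(dxhat)) -
                  col_mul(cache$xhat, colMeans(dxhat * cache$xhat)),
                cache$istd)
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

# Row-index vectors of the four 2x2-pool quadrants, in the flat layout, for a
# batch of B images of size H x W. Output rows follow the same layout at
# (H/2, W/2).
pool_indices <- function(H, W, B) {
  base <- function(ri, ci) {
    as.vector(outer(seq(ri, H, 2L), (seq(ci, W, 2L) - 1L) * H, "+"))
  }
  per_image <- list(base(1L, 1L), base(2L, 1L), base(1L, 2L), base(2L, 2L))
  off <- (seq_len(B) - 1L) * H * W
  lapply(per_image, function(ix) as.vector(outer(ix, off, "+")))
}

maxpool_forward <- function(X, B, H, W) {
  qi <- pool_indices(H, W, B)
  a <- X[qi[[1]], , drop = FALSE]; bq <- X[qi[[2]], , drop = FALSE]
  cq <- X[qi[[3]], , drop = FALSE]; dq <- X[qi[[4]], , drop = FALSE]
  out <- pmax(a, bq, cq, dq)
  ma <- a == out
  mb <- (bq == out) & !ma
  mc <- (cq == out) & !(ma | mb)
  md <- !(ma | mb | mc)
  list(out = out, masks = list(ma, mb, mc, md), qi = qi,
       in_rows = nrow(X), in_cols = ncol(X))
}

maxpool_backward <- function(dout, cache) {
  dX <- matrix(0, cache$in_rows, cache$in_cols)
  for (q in 1:4) {
    dX[cache$qi[[q]], ] <- dout * cache$masks[[q]]
  }
  dX
}

# Global max pool over the spatial extent of each image; X is (H*W*B x C).
# Returns features as a (B x C) matrix.
gmaxpool_forward <- function(X, B) {
  hw <- nrow(X) / B
  m <- matrix(X, nrow = hw) # columns run over (image, channel)
  arg <- max.col(t(m), ties.method = "first")
  cols <- seq_len(ncol(m))
  vals <- m[cbind(arg, cols)]
  list(out = matrix(vals, B, ncol(X)), arg = arg, hw = hw,
       in_rows = nrow(X), in_cols = ncol(X))
}

gmaxpool_backward <- function(dout, cache) {
  dm <- matrix(0, cache$hw, length(cache$arg))
  dm[cbind(cache$arg, seq_along(cache$arg))] <- as.vector(dout)
  matrix(as.vector(dm), cache$in_rows, cache$in_cols)
}

# column-wise arithmetic without sweep()'s aperm overhead
col_add <- function(X, v) X + rep(v, each = nrow(X))
col_sub <- function(X, v) X - rep(v, each = nrow(X))
col_mul <- function(X, v) X * rep(v, each = nrow(X))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Build the network: 4 x (conv 3x3 -> batch norm -> ReLU) with 2x2 max pool
# after blocks 1-3 (15 processing layers), then global max pool -> dense ->
# softmax as the two-class head.
cnn_new <- function(height, width, channels = c(8L, 16L, 32L, 32L),
                    n_input_channels = 3L, seed = 1L) {
  stopifnot(height %% 8 == 0, width %% 8 == 0)
  set.seed(seed)
  hs <- as.integer(c(height, height / 2, height / 4, height / 8))
  ws <- as.integer(c(width, width / 2, width / 4, width / 8))
  cins <- c(n_input_channels, channels[-length(channels)])
  blocks <- vector("list", 4L)
  for (k in 1:4) {
    blocks[[k]] <- list(conv = conv_init(hs[k], ws[k], cins[k], channels[k]),
                        bn = bn_init(channels[k]))
  }
  Cf <- channels[4]
  list(blocks = blocks,
       dense = list(W = matrix(stats::rnorm(2 * Cf, 0, sqrt(2 / Cf)), 2, Cf),
                    b = numeric(2),
                    vW = matrix(0, 2, Cf), vb = numeric(2)),
       height = height, width = width, channels = channels,
       n_input_channels = n_input_channels)
}

# X: flat-layout input (height*width*B x n_input_channels)
cnn_forward <- function(net, X, B, training = FALSE) {
  caches <- vector("list", 4L)
  for (k in 1:4) {
    blk <- net$blocks[[k]]
    cv <- conv_forward(X, B, blk$conv)
    bf <- bn_forward(cv$out, blk$bn, training = training)
    net$blocks[[k]]$bn <- bf$bn
    relu_mask <- bf$out > 0
    X <- bf$out * relu_mask
    pool <- NULL
    if (k < 4) {
      pool <- maxpool_forward(X, B, blk$conv$height, blk$conv$width)
      X <- pool$out
    }
    caches[[k]] <- list(cols = cv$cols, bn = bf$cache, relu = relu_mask,
                        pool = pool)
  }
  gp <- gmaxpool_forward(X, B)
  logits <- tcrossprod(gp$out, net$dense$W) +
    matrix(net$dense$b, B, 2, byrow = TRUE)
  list(net = net, logits = logits, probs = softmax_rows(logits),
       caches = caches, gp = gp)
}

cnn_backward <- function(net, fwd, dlogits) {
  B <- nrow(dlogits)
  grads <- list()
  grads$dense_W <- crossprod(dlogits, fwd$gp$out) # 2 x C
  grads$dense_b <- colSums(dlogits)
  dgp <- dlogits %*% net$dense$W # B x C
  dX <- gmaxpool_backward(dgp, fwd$gp)
  for (k in 4:1) {
    ch <- fwd$caches[[k]]
    if (k < 4) dX <- maxpool_backward(dX, ch$pool)
    dX <- dX * ch$relu
    bb <- bn_backward(dX, net$blocks[[k]]$bn, ch$bn)
    cb <- conv_backward(bb$dx, B, ch$cols, net$blocks[[k]]$conv)
    grads[[paste0("conv", k)]] <- list(dW = cb$dW, db = cb$db,
                                       dgamma = bb$dgamma, dbeta = bb$dbeta)
    dX <- cb$dx
  }
  grads
}

sgdm_step <- function(net, grads, lr, momentum, weight_decay = 0) {
  for (k in 1:4) {
    g <- grads[[paste0("conv", k)]]
    cv <- net$blocks[[k]]$conv
    cv$vW <- momentum * cv$vW - lr * (g$dW + weight_decay * cv$W)
    cv$W <- cv$W + cv$vW
    cv$vb <- momentum * cv$vb - lr * g$db
    cv$b <- cv$b + cv$vb
    net$blocks[[k]]$conv <- cv
    bn <- net$blocks[[k]]$bn
    bn$vgamma <- momentum * bn$vgamma - lr * g$dgamma
    bn$gamma <- bn$gamma + bn$vgamma
    bn$vbeta <- momentum * bn$vbeta - lr * g$dbeta
    bn$beta <- bn$beta + bn$vbeta
    net$blocks[[k]]$bn <- bn
  }
  dn <- net$dense
  dn$vW <- momentum * dn$vW - lr * (grads$dense_W + weight_decay * dn$W)
  dn$W <- dn$W + dn$vW
  dn$vb <- momentum * dn$vb - lr * grads$dense_b
  dn$b <- dn$b + dn$vb
  net$dense <- dn
  net
}
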