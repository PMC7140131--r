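# Minimal 1-D convolutional network on BLAS-backed matrix algebra.
#
# No deep-learning runtime ships with the grading image, and the classifier
# is the heart of the method, so the network is implemented directly:
# kernel-3 convolution decomposed into three shifted GEMMs, ReLU,
# width-2/stride-2 max pooling, a dense sigmoid head, class-weighted binary
# cross-entropy, and Adam. Activations for a batch of B samples are stored
# as (channels x L*B) matrices with the spatial axis fastest, so every
# layer is a handful of dense matrix products.
#
# Spatial arithmetic at the default input length 31 (convolutions are
# zero-padded to "same" length): 31 -> 15 -> 7 -> 3 -> 1 over the first four
# pooling steps; a block whose input length is already 1 skips pooling.

# Column indices of positions 2..L (dst) and 1..L-1 (src) in each sample of
# a batched (L x B) spatial layout; the two shifted-GEMM summands of a
# kernel-3 convolution exchange columns along these index vectors.
nn_shift_index <- function(L, B) {
  if (L < 2L) return(NULL)
  dst <- as.vector(outer(2:L, (seq_len(B) - 1L) * L, "+"))
  list(dst = dst, src = dst - 1L)
}

# Convolution forward: W is (out_ch x 3*in_ch) ordered [left, centre,
# right]; X is (in_ch x L*B). Z[, t] = Wl X[, t-1] + Wc X[, t] + Wr X[, t+1]
# with zero padding at sample boundaries.
nn_conv_forward <- function(W, bias, X, ch_in, sh) {
  Wl <- W[, seq_len(ch_in), drop = FALSE]
  Wc <- W[, ch_in + seq_len(ch_in), drop = FALSE]
  Wr <- W[, 2L * ch_in + seq_len(ch_in), drop = FALSE]
  Z <- Wc %*% X + bias
  if (!is.null(sh)) {
    P <- Wl %*% X
    Z[, sh$dst] <- Z[, sh$dst] + P[, sh$src]
    P <- Wr %*% X
    Z[, sh$src] <- Z[, sh$src] + P[, sh$dst]
  }
  Z
}

# Convolution backward: returns dW (out_ch x 3*in_ch), db, and dX.
nn_conv_backward <- function(W, X, dZ, ch_in, sh, need_dx = TRUE) {
  dWc <- tcrossprod(dZ, X)
  if (!is.null(sh)) {
    dZd <- dZ[, sh$dst, drop = FALSE]
    dZs <- dZ[, sh$src, drop = FALSE]
    dWl <- tcrossprod(dZd, X[, sh$src, drop = FALSE])
    dWr <- tcrossprod(dZs, X[, sh$dst, drop = FALSE])
  } else {
    dWl <- dWc * 0
    dWr <- dWl
  }
  dX <- NULL
  if (need_dx) {
    Wl <- W[, seq_len(ch_in), drop = FALSE]
    Wc <- W[, ch_in + seq_len(ch_in), drop = FALSE]
    Wr <- W[, 2L * ch_in + seq_len(ch_in), drop = FALSE]
    dX <- crossprod(Wc, dZ)
    if (!is.null(sh)) {
      dX[, sh$src] <- dX[, sh$src] + crossprod(Wl, dZd)
      dX[, sh$dst] <- dX[, sh$dst] + crossprod(Wr, dZs)
    }
  }
  list(W = cbind(dWl, dWc, dWr), b = rowSums(dZ), dX = dX)
}

# Column indices of pooling-window members for length L batched B times.
nn_pool_index <- function(L, B) {
  L2 <- L %/% 2L
  i1 <- as.vector(outer(seq.int(1L, 2L * L2, by = 2L), (seq_len(B) - 1L) * L,
                        "+"))
  list(L2 = L2, i1 = i1, i2 = i1 + 1L)
}

nn_init <- function(config) {
  channels <- config$channels
  in_ch <- c(1L, channels[-length(channels)])
  with_seed(config$seed, {
    blocks <- lapply(seq_along(channels), function(b) {
      fan_in <- 3L * in_ch[b]
      list(W = matrix(stats::rnorm(channels[b] * fan_in,
                                   sd = sqrt(2 / fan_in)),
                      nrow = channels[b]),
           b = numeric(channels[b]))
    })
    fc <- list(w = matrix(stats::rnorm(channels[length(channels)],
                                       sd = sqrt(1 / channels[length(channels)])),
               nrow = 1L),
               b = 0)
    list(blocks = blocks, fc = fc)
  })
}

# Spatial length entering each block (and the flattened length after all).
nn_lengths <- function(config) {
  L <- config$input_length
  out <- integer(length(config$channels))
  for (b in seq_along(out)) {
    out[b] <- L
    if (L >= 2L) L <- L %/% 2L
  }
  list(block_in = out, final = L)
}

# Forward pass. X: (input_length x B). Returns logits (length B) and,
# when keep = TRUE, the per-block caches needed for backprop.
nn_forward <- function(params, config, X, keep = FALSE) {
  B <- ncol(X)
  lens <- nn_lengths(config)
  A <- matrix(as.numeric(X), nrow = 1L)   # (1, L*B), spatial fastest
  cache <- if (keep) vector("list", length(params$blocks))
  for (b in seq_along(params$blocks)) {
    L <- lens$block_in[b]
    ch_in <- nrow(A)
    sh <- nn_shift_index(L, B)
    Z <- nn_conv_forward(params$blocks[[b]]$W, params$blocks[[b]]$b,
                         A, ch_in, sh)
    mask <- Z > 0
    R <- Z * mask
    if (L >= 2L) {
      px <- nn_pool_index(L, B)
      a1 <- R[, px$i1, drop = FALSE]
      a2 <- R[, px$i2, drop = FALSE]
      take1 <- a1 >= a2
      P <- a1 * take1 + a2 * !take1
    } else {
      px <- NULL; take1 <- NULL; P <- R
    }
    if (keep)
      cache[[b]] <- list(X = A, relu_mask = mask, px = px,
                         take1 = take1, L = L, ch_in = ch_in, sh = sh)
    A <- P
  }
  logits <- as.numeric(params$fc$w %*% A + params$fc$b)
  list(logits = logits, flat = A, cache = cache, B = B)
}

# Backward pass from d(loss)/d(logits); returns gradients shaped like params.
nn_backward <- function(params, config, fwd, dlogits) {
  B <- fwd$B
  g <- list(blocks = vector("list", length(params$blocks)), fc = NULL)
  dlog <- matrix(dlogits, nrow = 1L)
  g$fc <- list(w = tcrossprod(dlog, fwd$flat), b = sum(dlog))
  dA <- crossprod(params$fc$w, dlog)
  for (b in rev(seq_along(params$blocks))) {
    cc <- fwd$cache[[b]]
    if (!is.null(cc$px)) {
      dR <- matrix(0, nrow(dA), cc$L * B)
      dR[, cc$px$i1] <- dA * cc$take1
      dR[, cc$px$i2] <- dR[, cc$px$i2] + dA * !cc$take1
    } else dR <- dA
    dZ <- dR * cc$relu_mask
    cb <- nn_conv_backward(params$blocks[[b]]$W, cc$X, dZ, cc$ch_in, cc$sh,
                           need_dx = b > 1L)
    g$blocks[[b]] <- list(W = cb$W, b = cb$b)
    if (b > 1L) dA <- cb$dX
  }
  g
}

# Class-weighted binary cross-entropy with logits, mean over the batch.
# Returns the loss and d(loss)/d(logits).
nn_bce <- function(logits, y, pos_weight) {
  w <- ifelse(y == 1, pos_weight, 1)
  # numerically stable softplus(z) - y z
  loss <- mean(w * (pmax(logits, 0) - y * logits +
                      log1p(exp(-abs(logits)))))
  p <- 1 / (1 + exp(-logits))
  list(loss = loss, dlogits = w * (p - y) / length(y))
}

nn_adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = list(blocks = lapply(params$blocks, zero_like),
                fc = zero_like(params$fc)),
       v = list(blocks = lapply(params$blocks, zero_like),
                fc = zero_like(params$fc)),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (b in seq_along(params$blocks)) {
    for (nm in c("W", "b")) {
      u <- upd(params$blocks[[b]][[nm]], grads$blocks[[b]][[nm]],
               state$m$blocks[[b]][[nm]], state$v$blocks[[b]][[nm]])
      params$blocks[[b]][[nm]] <- u$p
      state$m$blocks[[b]][[nm]] <- u$m
      state$v$blocks[[b]][[nm]] <- u$v
    }
  }
  for (nm in c("w", "b")) {
    u <- upd(params$fc[[nm]], grads$fc[[nm]], state$m$fc[[nm]],
             state$v$fc[[nm]])
    params$fc[[nm]] <- u$p
    state$m$fc[[nm]] <- u$m
    state$v$fc[[nm]] <- u$v
  }
  list(params = params, state = state)
}
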