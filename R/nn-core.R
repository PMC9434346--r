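# Small training framework for the two networks: batched 4-d tensors
# (H, W, C, N), stride-1 same-padded convolutions (C++ kernels), batch
# normalisation, ReLU, 2x2 max pooling, nearest upsampling, fully connected
# heads, and plain SGD with momentum.  Deliberately minimal: only what the
# clip classifier and the encoder-decoder segmenter need.

nn_conv_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))  # He initialisation
  list(w = array(rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

nn_bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c))
}

nn_fc_init <- function(nin, nout) {
  list(w = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nout, nin),
       b = numeric(nout))
}

nn_bn_fwd <- function(bn, x, training, momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[3]
  y <- x
  xhat <- x
  mu <- numeric(C); va <- numeric(C)
  for (c in seq_len(C)) {
    xs <- x[, , c, , drop = FALSE]
    if (training) {
      mu[c] <- mean(xs); va[c] <- mean((xs - mu[c])^2)
    } else {
      mu[c] <- bn$rm[c]; va[c] <- bn$rv[c]
    }
    xh <- (xs - mu[c]) / sqrt(va[c] + eps)
    xhat[, , c, ] <- xh
    y[, , c, ] <- bn$gamma[c] * xh + bn$beta[c]
  }
  if (training) {
    bn$rm <- (1 - momentum) * bn$rm + momentum * mu
    bn$rv <- (1 - momentum) * bn$rv + momentum * va
  }
  list(y = y, bn = bn, cache = list(xhat = xhat, va = va, eps = eps))
}

nn_bn_bwd <- function(bn, cache, gout) {
  C <- dim(gout)[3]
  gx <- gout
  ggamma <- numeric(C); gbeta <- numeric(C)
  for (c in seq_len(C)) {
    g <- gout[, , c, , drop = FALSE]
    xh <- cache$xhat[, , c, , drop = FALSE]
    m <- length(g)
    ggamma[c] <- sum(g * xh)
    gbeta[c] <- sum(g)
    gxh <- g * bn$gamma[c]
    gx[, , c, ] <- (gxh - mean(gxh) - xh * mean(gxh * xh)) /
      sqrt(cache$va[c] + cache$eps)
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# conv -> batchnorm -> ReLU
nn_block_fwd <- function(blk, x, training) {
  z <- .cpp_conv2d_fwd(x, blk$conv$w, blk$conv$b)
  bnout <- nn_bn_fwd(blk$bn, z, training)
  a <- bnout$y
  a[a < 0] <- 0
  list(y = a, blk = within_bn(blk, bnout$bn),
       cache = list(x = x, bncache = bnout$cache, act = a))
}

within_bn <- function(blk, bn) { blk$bn <- bn; blk }

nn_block_bwd <- function(blk, cache, gout) {
  gout[cache$act <= 0] <- 0
  bnb <- nn_bn_bwd(blk$bn, cache$bncache, gout)
  cb <- .cpp_conv2d_bwd(cache$x, blk$conv$w, bnb$gx)
  list(gx = cb$gx,
       grads = list(conv = list(w = cb$gw, b = cb$gb),
                    bn = list(gamma = bnb$ggamma, beta = bnb$gbeta)))
}

# Channel concatenation / split for skip connections.
nn_cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

nn_split_ch <- function(g, c1) {
  C <- dim(g)[3]
  list(a = g[, , seq_len(c1), , drop = FALSE],
       b = g[, , (c1 + 1):C, , drop = FALSE])
}

# SGD with momentum over arbitrarily nested parameter lists.  `state` is a
# velocity pytree of the same shape (NULL on first call).
nn_sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                        scale = 1) {
  if (is.list(params)) {
    if (is.null(state)) state <- vector("list", length(params))
    for (i in seq_along(params)) {
      nm <- names(params)[i]
      if (!is.null(nm) && nm %in% c("rm", "rv")) next  # BN running stats
      if (is.null(grads[[i]])) next
      st <- nn_sgd_step(params[[i]], grads[[i]], state[[i]], lr, momentum,
                        scale)
      params[[i]] <- st$params
      state[[i]] <- st$state
    }
    return(list(params = params, state = state))
  }
  if (is.null(state)) state <- params * 0
  state <- momentum * state + grads * scale
  params <- params - lr * state
  list(params = params, state = state)
}

# Pixelwise weighted softmax cross-entropy on logits (H, W, K, N).
# `labels` is an integer array/matrix (H, W[, N]) with values 0..K-1.
nn_softmax_ce <- function(logits, labels, class_weights = NULL) {
  d <- dim(logits); K <- d[3]
  m <- matrix(aperm(logits, c(3, 1, 2, 4)), nrow = K)
  m <- sweep(m, 2, apply(m, 2, max))
  em <- exp(m)
  p <- sweep(em, 2, colSums(em), "/")
  lab <- as.integer(labels) + 1L
  if (is.null(class_weights)) class_weights <- rep(1, K)
  wvec <- class_weights[lab]
  idx <- cbind(lab, seq_along(lab))
  loss <- -sum(wvec * log(pmax(p[idx], 1e-12))) / sum(wvec)
  g <- sweep(p, 2, wvec, "*")
  g[idx] <- g[idx] - wvec
  g <- g / sum(wvec)
  glogits <- aperm(array(g, c(K, d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(loss = loss, grad = glogits, prob = p)
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))
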