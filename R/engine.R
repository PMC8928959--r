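# Minimal dense-network engine: stacks of dense -> batch-norm -> activation
# -> dropout blocks, trained with RMSprop. Everything operates on plain
# matrices; all randomness comes from the current R RNG stream so whole
# training runs are reproducible from one seed.

BN_EPS <- 1e-3      # batch-norm variance floor
BN_MOMENTUM <- 0.99 # running-statistics update weight
RMS_RHO <- 0.9
RMS_EPS <- 1e-7
CE_EPS <- 1e-12

# Glorot-uniform initialized stack. `widths` includes input and output;
# hidden blocks get batch-norm + dropout, the output layer is plain
# dense + `out_act`.
nn_init_stack <- function(widths, out_act, dropout = 0, use_bn = TRUE) {
  n_layer <- length(widths) - 1L
  blocks <- vector("list", n_layer)
  for (i in seq_len(n_layer)) {
    d_in <- widths[i]; d_out <- widths[i + 1L]
    if (d_in < 1L || d_out < 1L) stop("non-positive layer width", call. = FALSE)
    lim <- sqrt(6 / (d_in + d_out))
    hidden <- i < n_layer
    blocks[[i]] <- list(
      W = matrix(runif(d_in * d_out, -lim, lim), d_in, d_out),
      b = numeric(d_out),
      act = if (hidden) "relu" else out_act,
      bn = hidden && use_bn,
      dropout = if (hidden) dropout else 0,
      gamma = if (hidden && use_bn) rep(1, d_out) else NULL,
      beta = if (hidden && use_bn) numeric(d_out) else NULL,
      run_mean = if (hidden && use_bn) numeric(d_out) else NULL,
      run_var = if (hidden && use_bn) rep(1, d_out) else NULL
    )
  }
  blocks
}

nn_activate <- function(z, act) {
  switch(act,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = {
      e <- exp(z - apply(z, 1L, max))
      e / rowSums(e)
    },
    linear = z,
    stop("unknown activation ", act))
}

# Forward pass. Returns output, per-block caches for backprop, and the
# stack itself (running batch-norm statistics are updated when training).
nn_forward <- function(stack, x, training = FALSE) {
  caches <- vector("list", length(stack))
  a <- x
  m <- nrow(a)
  for (i in seq_along(stack)) {
    blk <- stack[[i]]
    z <- a %*% blk$W
    z <- sweep(z, 2L, blk$b, "+")
    cache <- list(x_in = a)
    if (blk$bn) {
      if (training && m > 1L) {
        mu <- colMeans(z)
        v <- colMeans(z^2) - mu^2  # population variance
        stack[[i]]$run_mean <- BN_MOMENTUM * blk$run_mean + (1 - BN_MOMENTUM) * mu
        stack[[i]]$run_var <- BN_MOMENTUM * blk$run_var + (1 - BN_MOMENTUM) * v
      } else {
        mu <- blk$run_mean
        v <- blk$run_var
      }
      sdv <- sqrt(v + BN_EPS)
      zhat <- sweep(sweep(z, 2L, mu, "-"), 2L, sdv, "/")
      z <- sweep(sweep(zhat, 2L, blk$gamma, "*"), 2L, blk$beta, "+")
      cache$zhat <- zhat
      cache$sdv <- sdv
      cache$bn_batch <- training && m > 1L
    }
    a <- nn_activate(z, blk$act)
    cache$z <- z
    cache$a <- a
    if (training && blk$dropout > 0) {
      keep <- 1 - blk$dropout
      mask <- matrix((runif(length(a)) < keep) / keep, nrow(a), ncol(a))
      a <- a * mask
      cache$mask <- mask
    }
    caches[[i]] <- cache
  }
  list(out = a, caches = caches, stack = stack)
}

# Backward pass. `d_out` is the gradient w.r.t. the stack output; when
# `pre_activation = TRUE` it is the gradient w.r.t. the last layer's
# pre-activation (used for the fused softmax + cross-entropy gradient).
# Returns gradient w.r.t. the input and per-block parameter gradients.
nn_backward <- function(stack, caches, d_out, pre_activation = FALSE) {
  grads <- vector("list", length(stack))
  da <- d_out
  for (i in rev(seq_along(stack))) {
    blk <- stack[[i]]
    cache <- caches[[i]]
    if (!is.null(cache$mask)) da <- da * cache$mask
    dz <- if (i == length(stack) && pre_activation) {
      da
    } else {
      switch(blk$act,
        relu = da * (cache$z > 0),
        sigmoid = da * cache$a * (1 - cache$a),
        linear = da,
        softmax = stop("softmax gradient must be fused with cross-entropy"))
    }
    g <- list()
    if (blk$bn) {
      g$gamma <- colSums(dz * cache$zhat)
      g$beta <- colSums(dz)
      dzhat <- sweep(dz, 2L, blk$gamma, "*")
      if (isTRUE(cache$bn_batch)) {
        m <- nrow(dz)
        dz <- sweep(dzhat, 2L, colMeans(dzhat), "-") -
          cache$zhat * matrix(colMeans(dzhat * cache$zhat), m, ncol(dz), byrow = TRUE)
        dz <- sweep(dz, 2L, cache$sdv, "/")
      } else {
        dz <- sweep(dzhat, 2L, cache$sdv, "/")
      }
    }
    g$W <- crossprod(cache$x_in, dz)
    g$b <- colSums(dz)
    grads[[i]] <- g
    da <- tcrossprod(dz, blk$W)
  }
  list(d_in = da, grads = grads)
}

nn_init_opt <- function(stack) {
  lapply(stack, function(blk) {
    s <- list(W = blk$W * 0, b = blk$b * 0)
    if (blk$bn) {
      s$gamma <- blk$gamma * 0
      s$beta <- blk$beta * 0
    }
    s
  })
}

nn_rmsprop_update <- function(stack, grads, opt, lr) {
  for (i in seq_along(stack)) {
    for (p in names(opt[[i]])) {
      g <- grads[[i]][[p]]
      v <- RMS_RHO * opt[[i]][[p]] + (1 - RMS_RHO) * g^2
      opt[[i]][[p]] <- v
      stack[[i]][[p]] <- stack[[i]][[p]] - lr * g / (sqrt(v) + RMS_EPS)
    }
  }
  list(stack = stack, opt = opt)
}

nn_stack_params <- function(stack) {
  sum(vapply(stack, function(blk) {
    length(blk$W) + length(blk$b) + length(blk$gamma) + length(blk$beta)
  }, numeric(1L)))
}

# ---- joint encoder / decoder / classifier model --------------------------

# Forward through all three heads; `y_onehot` may be NULL at inference.
lse_forward <- function(net, x, training = FALSE) {
  enc <- nn_forward(net$encoder, x, training)
  dec <- nn_forward(net$decoder, enc$out, training)
  clf <- nn_forward(net$classifier, enc$out, training)
  net$encoder <- enc$stack
  net$decoder <- dec$stack
  net$classifier <- clf$stack
  list(net = net, latent = enc$out, decoded = dec$out, prob = clf$out,
       caches = list(enc = enc$caches, dec = dec$caches, clf = clf$caches))
}

lse_losses <- function(x, y_onehot, decoded, prob) {
  mse <- mean((x - decoded)^2)
  ce <- -mean(rowSums(y_onehot * log(pmax(prob, CE_EPS))))
  c(decoder = mse, classifier = ce)
}

# One RMSprop step on a minibatch under L = lambda*MSE + (1-lambda)*CE.
lse_train_step <- function(net, opt, x, y_onehot, lambda, lr) {
  fw <- lse_forward(net, x, training = TRUE)
  net <- fw$net
  m <- nrow(x); d <- ncol(x)
  losses <- lse_losses(x, y_onehot, fw$decoded, fw$prob)

  d_decoded <- lambda * 2 * (fw$decoded - x) / (m * d)
  bw_dec <- nn_backward(net$decoder, fw$caches$dec, d_decoded)
  d_logits <- (1 - lambda) * (fw$prob - y_onehot) / m
  bw_clf <- nn_backward(net$classifier, fw$caches$clf, d_logits, pre_activation = TRUE)
  bw_enc <- nn_backward(net$encoder, fw$caches$enc, bw_dec$d_in + bw_clf$d_in)

  up <- nn_rmsprop_update(net$encoder, bw_enc$grads, opt$encoder, lr)
  net$encoder <- up$stack; opt$encoder <- up$opt
  up <- nn_rmsprop_update(net$decoder, bw_dec$grads, opt$decoder, lr)
  net$decoder <- up$stack; opt$decoder <- up$opt
  up <- nn_rmsprop_update(net$classifier, bw_clf$grads, opt$classifier, lr)
  net$classifier <- up$stack; opt$classifier <- up$opt

  list(net = net, opt = opt, losses = losses)
}

# Inference-mode losses on a whole set.
lse_evaluate <- function(net, x, y_onehot) {
  fw <- lse_forward(net, x, training = FALSE)
  lse_losses(x, y_onehot, fw$decoded, fw$prob)
}

# Shuffled minibatch index list; a trailing singleton is merged into the
# previous batch so batch-norm always sees >= 2 samples.
make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1L, n)])
  last <- length(batches)
  if (last > 1L && length(batches[[last]]) < 2L) {
    batches[[last - 1L]] <- c(batches[[last - 1L]], batches[[last]])
    batches[[last]] <- NULL
  }
  batches
}

# Stratified validation split: returns validation row indices.
stratified_val_idx <- function(y, fraction) {
  if (fraction <= 0) return(integer(0))
  unlist(lapply(unique(y), function(cl) {
    rows <- which(y == cl)
    n_val <- max(1L, floor(length(rows) * fraction))
    sample(rows, n_val)
  }), use.names = FALSE)
}
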