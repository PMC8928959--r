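#' Layer plan of the joint encoder-decoder-classifier network
#'
#' Derives the dense-layer widths from the width multiplier `N`, the CKSAAP
#' gap `k` (input width `400 * (k + 1)`) and the latent dimension. The
#' encoder narrows through hidden widths `10N, 5N, 2N` to the latent layer;
#' the decoder is its exact mirror; the classifier reads the latent code
#' through two hidden layers of `2N` units into a 2-unit softmax.
#'
#' @param k CKSAAP gap parameter (fixes the input width).
#' @param N Width multiplier (1, 5 or 10 in the reference configurations;
#'   any positive integer is accepted).
#' @param latent_dim Latent-space dimension (LV).
#' @return A list with `encoder`, `decoder` and `classifier` width vectors
#'   (input and output widths included) and `n_features`.
#' @examples
#' deeplse_architecture(k = 6, N = 5, latent_dim = 6)
#' @export
deeplse_architecture <- function(k, N = 5L, latent_dim = 6L) {
  k <- as.integer(k); N <- as.integer(N); latent_dim <- as.integer(latent_dim)
  if (N < 1L) stop("N must be a positive integer", call. = FALSE)
  if (latent_dim < 1L) stop("latent_dim must be >= 1", call. = FALSE)
  d <- 400L * (k + 1L)
  hidden <- c(10L, 5L, 2L) * N
  list(encoder = c(d, hidden, latent_dim),
       decoder = c(latent_dim, rev(hidden), d),
       classifier = c(latent_dim, 2L * N, 2L * N, 2L),
       n_features = d)
}

#' Convex combination of reconstruction and classification loss
#'
#' `lambda * decoder_loss + (1 - lambda) * classification_loss`. With the
#' default `lambda = 0.99` training attention is overwhelmingly on
#' reconstruction, which is what squeezes class structure into a compact
#' latent space rather than letting the classifier dominate.
#'
#' @param decoder_loss Non-negative reconstruction loss (MSE).
#' @param classification_loss Non-negative cross-entropy loss.
#' @param lambda Mixing weight in `[0, 1]`.
#' @return The combined loss.
#' @export
combined_loss <- function(decoder_loss, classification_loss, lambda = 0.99) {
  if (!is.finite(decoder_loss) || !is.finite(classification_loss)) {
    stop("losses must be finite", call. = FALSE)
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  lambda * decoder_loss + (1 - lambda) * classification_loss
}

#' Fit the joint latent-space encoder / classifier model
#'
#' Trains an autoencoder and a 2-class softmax classifier head together on
#' a CKSAAP feature matrix. The encoder compresses the
#' `400 * (k + 1)`-dimensional descriptor into `latent_dim` sigmoid units,
#' a mirrored decoder reconstructs the input, and the classifier reads the
#' class label off the latent code. Both objectives are minimized jointly
#' under the convex loss [combined_loss()] with RMSprop; hidden layers are
#' ReLU with batch normalization and dropout (order: dense, batch-norm,
#' activation, dropout). Early stopping monitors the combined loss on an
#' internal stratified validation split and restores the best-epoch
#' weights.
#'
#' All randomness — weight initialization, the validation split, minibatch
#' shuffling and dropout masks — derives from `seed`, so identical calls
#' reproduce identical models, histories and predictions.
#'
#' @param x Numeric feature matrix (rows = sequences); normalized CKSAAP
#'   features lie in `[0, 1]`, matching the sigmoid decoder output.
#' @param y Binary labels (0 = non-antioxidant, 1 = antioxidant); both
#'   classes must be present.
#' @param N Width multiplier of the architecture, see
#'   [deeplse_architecture()].
#' @param latent_dim Latent-space dimension (LV).
#' @param lambda Mixing weight of [combined_loss()], default 0.99.
#' @param dropout Dropout rate between hidden dense layers, default 0.3.
#' @param epochs Maximum training epochs, default 1000.
#' @param patience Early-stopping tolerance in epochs, default 100.
#' @param batch_size Minibatch size, default 32.
#' @param validation_fraction Fraction of the training rows held out (per
#'   class) for early-stopping monitoring, default 0.1. Set to 0 to monitor
#'   the training loss instead.
#' @param learning_rate RMSprop learning rate, default 0.001.
#' @param seed Integer seed controlling every random choice.
#' @param verbose Print a line every 50 epochs.
#' @return An object of class `"deeplse"` with the learned network, the
#'   configuration, the per-epoch loss `history` (train and validation
#'   decoder / classifier / combined losses), `best_epoch`, and the
#'   training data (`x`, `y`).
#' @seealso [predict.deeplse()], [reconstruct()], [encode_latent()],
#'   [run_trials()]
#' @examples
#' set.seed(1)
#' dat <- generate_proteins(n_pos = 30, n_neg = 60, length_range = c(50, 80),
#'                          effect_size = 5, seed = 7)
#' x <- cksaap_encode(dat, k = 1)
#' fit <- deeplse(x, dat$label, N = 2, latent_dim = 2, epochs = 15,
#'                patience = 15, seed = 1)
#' fit
#' @export
deeplse <- function(x, y, N = 5L, latent_dim = 6L, lambda = 0.99,
                    dropout = 0.3, epochs = 1000L, patience = 100L,
                    batch_size = 32L, validation_fraction = 0.1,
                    learning_rate = 0.001, seed = 1L, verbose = FALSE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  if (patience > epochs) patience <- epochs
  k_attr <- attr(x, "k")
  if (ncol(x) %% 400L == 0L && is.null(k_attr)) k_attr <- ncol(x) / 400L - 1L

  widths <- list(encoder = c(ncol(x), c(10L, 5L, 2L) * as.integer(N), as.integer(latent_dim)),
                 decoder = c(as.integer(latent_dim), rev(c(10L, 5L, 2L) * as.integer(N)), ncol(x)),
                 classifier = c(as.integer(latent_dim), 2L * as.integer(N), 2L * as.integer(N), 2L))

  fit <- with_seed(seed, {
    net <- list(encoder = nn_init_stack(widths$encoder, "sigmoid", dropout),
                decoder = nn_init_stack(widths$decoder, "sigmoid", dropout),
                classifier = nn_init_stack(widths$classifier, "softmax", dropout))
    opt <- list(encoder = nn_init_opt(net$encoder),
                decoder = nn_init_opt(net$decoder),
                classifier = nn_init_opt(net$classifier))

    val_idx <- stratified_val_idx(y, validation_fraction)
    has_val <- length(val_idx) > 0L
    tr_idx <- if (has_val) setdiff(seq_len(nrow(x)), val_idx) else seq_len(nrow(x))
    x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
    x_val <- x[val_idx, , drop = FALSE]; y_val <- y[val_idx]
    onehot <- function(yy) cbind(1 - yy, yy)

    hist_rows <- vector("list", epochs)
    best <- list(loss = Inf, net = NULL, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(epochs)) {
      batches <- make_batches(nrow(x_tr), batch_size)
      tr_losses <- c(decoder = 0, classifier = 0)
      for (b in batches) {
        step <- lse_train_step(net, opt, x_tr[b, , drop = FALSE],
                               onehot(y_tr[b]), lambda, learning_rate)
        net <- step$net; opt <- step$opt
        tr_losses <- tr_losses + step$losses * length(b)
      }
      tr_losses <- tr_losses / nrow(x_tr)
      val_losses <- if (has_val) lse_evaluate(net, x_val, onehot(y_val)) else tr_losses
      mon <- combined_loss(val_losses[["decoder"]], val_losses[["classifier"]], lambda)
      hist_rows[[epoch]] <- c(epoch = epoch,
                              train_decoder = tr_losses[["decoder"]],
                              train_classifier = tr_losses[["classifier"]],
                              train_combined = combined_loss(tr_losses[["decoder"]],
                                                             tr_losses[["classifier"]], lambda),
                              val_decoder = val_losses[["decoder"]],
                              val_classifier = val_losses[["classifier"]],
                              val_combined = mon)
      if (mon < best$loss) {
        best <- list(loss = mon, net = net, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
      if (verbose && epoch %% 50L == 0L) {
        message(sprintf("epoch %d: combined val loss %.6f (best %.6f @ %d)",
                        epoch, mon, best$loss, best$epoch))
      }
    }
    list(net = best$net, best_epoch = best$epoch,
         history = as.data.frame(do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1L))])),
         val_idx = sort(val_idx))
  })

  structure(list(
    net = fit$net,
    config = list(N = as.integer(N), latent_dim = as.integer(latent_dim),
                  k = k_attr, lambda = lambda, dropout = dropout,
                  epochs = as.integer(epochs), patience = as.integer(patience),
                  batch_size = as.integer(batch_size),
                  validation_fraction = validation_fraction,
                  learning_rate = learning_rate, seed = as.integer(seed)),
    widths = widths,
    history = fit$history,
    best_epoch = fit$best_epoch,
    validation_rows = fit$val_idx,
    feature_names = colnames(x),
    x = x, y = y
  ), class = "deeplse")
}

check_newdata <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$widths$encoder[1L]) {
    stop("feature width ", ncol(newdata), " does not match the model input width ",
         object$widths$encoder[1L], call. = FALSE)
  }
  newdata
}

#' Predict from a fitted latent-space encoder model
#'
#' Inference is deterministic: dropout is off and batch normalization uses
#' its running statistics.
#'
#' @param object A `"deeplse"` fit.
#' @param newdata Feature matrix with the model's input width; defaults to
#'   the training data.
#' @param type `"class"` for hard 0/1 labels (softmax tie at 0.5 resolves
#'   to the majority class 0), `"prob"` for the two class probabilities,
#'   `"latent"` for the latent codes, `"decoded"` for the reconstruction.
#' @param ... Unused.
#' @return A vector (`"class"`) or matrix (other types).
#' @export
predict.deeplse <- function(object, newdata = object$x,
                            type = c("class", "prob", "latent", "decoded"), ...) {
  type <- match.arg(type)
  newdata <- check_newdata(object, newdata)
  fw <- lse_forward(object$net, newdata, training = FALSE)
  switch(type,
    prob = {
      p <- fw$prob
      colnames(p) <- c("negative", "positive")
      rownames(p) <- rownames(newdata)
      p
    },
    class = as.integer(fw$prob[, 2L] > 0.5),
    latent = {
      z <- fw$latent
      rownames(z) <- rownames(newdata)
      z
    },
    decoded = {
      d <- fw$decoded
      dimnames(d) <- dimnames(newdata)
      d
    })
}

#' Latent-space codes of a fitted model
#'
#' @inheritParams predict.deeplse
#' @return Matrix of latent coordinates, rows aligned with `newdata`.
#' @export
encode_latent <- function(object, newdata = object$x) {
  predict(object, newdata, type = "latent")
}

#' Decoder reconstruction and residual
#'
#' @inheritParams predict.deeplse
#' @return List with `decoded` (the reconstruction `X' = Dec(Enc(X))`) and
#'   `residual` (`X - X'`).
#' @export
reconstruct <- function(object, newdata = object$x) {
  newdata <- check_newdata(object, newdata)
  decoded <- predict(object, newdata, type = "decoded")
  list(decoded = decoded, residual = newdata - decoded)
}

#' @export
residuals.deeplse <- function(object, newdata = object$x, ...) {
  reconstruct(object, newdata)$residual
}

#' @export
fitted.deeplse <- function(object, ...) {
  predict(object, type = "prob")
}

#' @export
coef.deeplse <- function(object, ...) {
  lapply(object$net, function(stack) lapply(stack, function(blk) {
    out <- list(W = blk$W, b = blk$b)
    if (blk$bn) {
      out$gamma <- blk$gamma
      out$beta <- blk$beta
    }
    out
  }))
}

#' @export
print.deeplse <- function(x, ...) {
  cfg <- x$config
  cat("Joint latent-space encoder/classifier (deeplse)\n")
  cat(sprintf("  encoder    %s\n", paste(x$widths$encoder, collapse = " -> ")))
  cat(sprintf("  decoder    %s\n", paste(x$widths$decoder, collapse = " -> ")))
  cat(sprintf("  classifier %s (softmax)\n", paste(x$widths$classifier, collapse = " -> ")))
  cat(sprintf("  lambda = %.3g, dropout = %.2f, N = %d, latent_dim = %d\n",
              cfg$lambda, cfg$dropout, cfg$N, cfg$latent_dim))
  cat(sprintf("  trained %d epoch(s), best epoch %d (val combined loss %.6f)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_combined[x$best_epoch]))
  invisible(x)
}

#' @export
summary.deeplse <- function(object, ...) {
  cc <- confusion_counts(object$y, predict(object, type = "class"))
  out <- list(fit = object,
              n_parameters = sum(vapply(object$net, nn_stack_params, numeric(1L))),
              training_metrics = classification_metrics(cc))
  class(out) <- "summary.deeplse"
  out
}

#' @export
print.summary.deeplse <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d trainable parameters (incl. batch-norm scale/shift)\n",
              x$n_parameters))
  m <- x$training_metrics
  cat(sprintf("  training-set Sn %.3f  Sp %.3f  BACC %.3f  MCC %.3f\n",
              m$sensitivity, m$specificity, m$balanced_accuracy, m$mcc))
  invisible(x)
}

#' Plot the training history of a fitted model
#'
#' Shows train and validation combined loss per epoch with the restored
#' best epoch marked.
#'
#' @param x A `"deeplse"` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.deeplse <- function(x, ...) {
  h <- x$history
  matplot(h$epoch, cbind(h$train_combined, h$val_combined), type = "l",
          lty = 1, col = c("grey40", "firebrick"),
          xlab = "epoch", ylab = "combined loss", ...)
  abline(v = x$best_epoch, lty = 3)
  legend("topright", c("train", "validation"), lty = 1,
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint is a self-describing RDS container holding the learned
#' weights, the full configuration (including the seed) and the feature
#' column names.
#'
#' @param object A `"deeplse"` fit.
#' @param path File path.
#' @return `save_deeplse` returns `path` invisibly; `load_deeplse` the fit.
#' @export
save_deeplse <- function(object, path) {
  stopifnot(inherits(object, "deeplse"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_deeplse
#' @export
load_deeplse <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "deeplse")) stop("not a deeplse checkpoint", call. = FALSE)
  object
}
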