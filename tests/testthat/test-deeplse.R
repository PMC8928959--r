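test_that("layer plans reproduce the reference configurations", {
  a5 <- deeplse_architecture(k = 6, N = 5, latent_dim = 6)
  expect_equal(a5$encoder, c(2800, 50, 25, 10, 6))
  expect_equal(a5$decoder, c(6, 10, 25, 50, 2800))
  expect_equal(a5$classifier, c(6, 10, 10, 2))

  expect_equal(deeplse_architecture(6, 1, 6)$encoder, c(2800, 10, 5, 2, 6))
  expect_equal(deeplse_architecture(6, 1, 6)$classifier, c(6, 2, 2, 2))
  expect_equal(deeplse_architecture(6, 10, 6)$encoder, c(2800, 100, 50, 20, 6))
  expect_equal(deeplse_architecture(6, 10, 6)$classifier, c(6, 20, 20, 2))

  expect_error(deeplse_architecture(2, 0, 4), "positive")
  expect_error(deeplse_architecture(2, 5, 0), ">= 1")
})

test_that("combined loss is the convex mixture with boundary behavior", {
  expect_equal(combined_loss(1, 1, 0.99), 1)
  expect_equal(combined_loss(0, 2, 0.99), 0.02)
  set.seed(3)
  for (i in 1:10) {
    x <- runif(1, 0, 5); y <- runif(1, 0, 5)
    expect_equal(combined_loss(x, y, 1), x)
    expect_equal(combined_loss(x, y, 0), y)
  }
  expect_error(combined_loss(1, 1, 1.2), "lambda")
  expect_error(combined_loss(Inf, 1, 0.5), "finite")
})

test_that("backpropagation matches finite-difference gradients", {
  # tiny joint network, dropout off, deterministic batch
  set.seed(77)
  x <- matrix(runif(6 * 8), 6, 8)
  y <- cbind(1 - c(1, 0, 1, 0, 0, 1), c(1, 0, 1, 0, 0, 1))
  lambda <- 0.7
  net <- list(encoder = aoplse:::nn_init_stack(c(8, 4, 3, 2, 2), "sigmoid", 0),
              decoder = aoplse:::nn_init_stack(c(2, 2, 3, 4, 8), "sigmoid", 0),
              classifier = aoplse:::nn_init_stack(c(2, 3, 3, 2), "softmax", 0))

  loss_at <- function(net) {
    fw <- aoplse:::lse_forward(net, x, training = TRUE)
    l <- aoplse:::lse_losses(x, y, fw$decoded, fw$prob)
    lambda * l[["decoder"]] + (1 - lambda) * l[["classifier"]]
  }

  fw <- aoplse:::lse_forward(net, x, training = TRUE)
  d_decoded <- lambda * 2 * (fw$decoded - x) / (6 * 8)
  bw_dec <- aoplse:::nn_backward(net$decoder, fw$caches$dec, d_decoded)
  d_logits <- (1 - lambda) * (fw$prob - y) / 6
  bw_clf <- aoplse:::nn_backward(net$classifier, fw$caches$clf, d_logits,
                                 pre_activation = TRUE)
  bw_enc <- aoplse:::nn_backward(net$encoder, fw$caches$enc,
                                 bw_dec$d_in + bw_clf$d_in)
  grads <- list(encoder = bw_enc$grads, decoder = bw_dec$grads,
                classifier = bw_clf$grads)

  eps <- 1e-6
  for (stack_name in names(net)) {
    for (blk in c(1L, length(net[[stack_name]]))) {
      for (par in c("W", "gamma")) {
        if (is.null(net[[stack_name]][[blk]][[par]])) next
        for (pick in 1:3) {
          idx <- sample(length(net[[stack_name]][[blk]][[par]]), 1)
          plus <- net; plus[[stack_name]][[blk]][[par]][idx] <-
            plus[[stack_name]][[blk]][[par]][idx] + eps
          minus <- net; minus[[stack_name]][[blk]][[par]][idx] <-
            minus[[stack_name]][[blk]][[par]][idx] - eps
          numeric_grad <- (loss_at(plus) - loss_at(minus)) / (2 * eps)
          expect_equal(grads[[stack_name]][[blk]][[par]][idx], numeric_grad,
                       tolerance = 1e-4,
                       info = sprintf("%s block %d %s", stack_name, blk, par))
        }
      }
    }
  }
})

test_that("parameter counts follow the widths law", {
  d <- quick_dataset(n_pos = 15, n_neg = 30, seed = 2)
  fit <- quick_fit(d, epochs = 2)
  w <- fit$widths
  expected <- 0
  for (stack in w) {
    nl <- length(stack) - 1
    for (i in seq_len(nl)) {
      expected <- expected + stack[i] * stack[i + 1] + stack[i + 1]  # W + b
      if (i < nl) expected <- expected + 2 * stack[i + 1]            # gamma + beta
    }
  }
  expect_equal(summary(fit)$n_parameters, expected)
})

test_that("identical config and data give identical histories and predictions", {
  d <- quick_dataset(n_pos = 25, n_neg = 60, seed = 5)
  f1 <- quick_fit(d, seed = 9, epochs = 8)
  f2 <- quick_fit(d, seed = 9, epochs = 8)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, type = "prob"), predict(f2, type = "prob"))
  f3 <- quick_fit(d, seed = 10, epochs = 8)
  expect_false(identical(f1$history, f3$history))
})

test_that("lambda boundaries decouple the heads: untouched weights stay at init", {
  d <- quick_dataset(n_pos = 20, n_neg = 40, seed = 6)
  # lambda = 1: zero classifier gradient, so its weights are whatever
  # initialization produced, regardless of how long we train
  short <- quick_fit(d, epochs = 2, lambda = 1, seed = 4)
  long <- quick_fit(d, epochs = 8, lambda = 1, seed = 4)
  for (i in seq_along(short$net$classifier)) {
    expect_identical(short$net$classifier[[i]]$W, long$net$classifier[[i]]$W)
  }
  expect_false(identical(short$net$encoder[[1]]$W, long$net$encoder[[1]]$W))

  # lambda = 0: pure classification, decoder frozen at its initialization
  short0 <- quick_fit(d, epochs = 2, lambda = 0, seed = 4)
  long0 <- quick_fit(d, epochs = 8, lambda = 0, seed = 4)
  for (i in seq_along(short0$net$decoder)) {
    expect_identical(short0$net$decoder[[i]]$W, long0$net$decoder[[i]]$W)
  }
  expect_false(identical(short0$net$encoder[[1]]$W, long0$net$encoder[[1]]$W))
})

test_that("early stopping restores a best epoch no worse than epoch 1", {
  d <- quick_dataset(n_pos = 25, n_neg = 60, seed = 8)
  fit <- quick_fit(d, epochs = 30, seed = 2)
  expect_lte(fit$history$val_combined[fit$best_epoch], fit$history$val_combined[1])
  expect_lte(nrow(fit$history), 30)
  # patience cuts training short when nothing improves
  fit_stop <- quick_fit(d, epochs = 50, seed = 2, patience = 3)
  expect_lte(nrow(fit_stop$history), 50)
})

test_that("inference is deterministic and respects output contracts", {
  d <- quick_dataset(n_pos = 20, n_neg = 40, seed = 3)
  fit <- quick_fit(d, epochs = 10)
  p1 <- predict(fit, d$x, type = "prob")
  p2 <- predict(fit, d$x, type = "prob")
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, nrow(d$x)), tolerance = 1e-12)
  expect_true(all(p1 >= 0))

  z <- predict(fit, d$x, type = "latent")
  expect_equal(dim(z), c(nrow(d$x), 3L))
  expect_true(all(z >= 0 & z <= 1))  # sigmoid latent

  rec <- reconstruct(fit, d$x)
  expect_equal(dim(rec$decoded), dim(d$x))
  expect_true(all(rec$decoded > 0 & rec$decoded < 1))
  expect_equal(rec$residual + rec$decoded, d$x, ignore_attr = TRUE)
  expect_equal(residuals(fit), rec$residual, ignore_attr = TRUE)

  cls <- predict(fit, d$x, type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
  expect_equal(cls, as.integer(p1[, "positive"] > 0.5))
})

test_that("invalid inputs are rejected up front", {
  d <- quick_dataset(n_pos = 15, n_neg = 30, seed = 4)
  expect_error(deeplse(d$x, rep(1, nrow(d$x)), epochs = 2), "both classes")
  expect_error(deeplse(d$x, d$y[-1], epochs = 2), "length")
  xbad <- d$x; xbad[1, 1] <- NA
  expect_error(deeplse(xbad, d$y, epochs = 2), "finite")
  expect_error(deeplse(d$x, d$y, lambda = 2, epochs = 2), "lambda")

  fit <- quick_fit(d, epochs = 2)
  expect_error(predict(fit, d$x[, 1:100]), "width")
  expect_error(encode_latent(fit, d$x[, 1:10]), "width")
})

test_that("planted signal is recovered and vanishes under label shuffling", {
  d <- quick_dataset(n_pos = 100, n_neg = 300, effect_size = 5, seed = 31)
  idx <- seq_len(nrow(d$x))
  test_rows <- c(1:30, 101:190)  # 30 pos / 90 neg held out
  train_rows <- setdiff(idx, test_rows)

  baccs <- vapply(1:3, function(s) {
    fit <- deeplse(d$x[train_rows, ], d$y[train_rows], N = 5, latent_dim = 4,
                   epochs = 120, patience = 120, batch_size = 16, seed = s)
    cc <- confusion_counts(d$y[test_rows],
                           predict(fit, d$x[test_rows, ], type = "class"))
    classification_metrics(cc)$balanced_accuracy
  }, numeric(1))
  expect_gte(max(baccs), 0.9)
  expect_gte(mean(baccs), 0.85)

  set.seed(99)
  y_shuf <- sample(d$y[train_rows])
  fit_shuf <- deeplse(d$x[train_rows, ], y_shuf, N = 5, latent_dim = 4,
                      epochs = 60, patience = 60, batch_size = 16, seed = 1)
  cc <- confusion_counts(d$y[test_rows],
                         predict(fit_shuf, d$x[test_rows, ], type = "class"))
  bacc_shuf <- classification_metrics(cc)$balanced_accuracy
  expect_gte(bacc_shuf, 0.35)
  expect_lte(bacc_shuf, 0.65)
})

test_that("model checkpoints round-trip through disk", {
  d <- quick_dataset(n_pos = 15, n_neg = 30, seed = 12)
  fit <- quick_fit(d, epochs = 3)
  f <- tempfile(fileext = ".rds")
  save_deeplse(fit, f)
  back <- load_deeplse(f)
  expect_identical(predict(back, d$x, type = "prob"),
                   predict(fit, d$x, type = "prob"))
  expect_identical(back$config, fit$config)
})
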