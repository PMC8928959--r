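#' Test-set metrics of one fitted model
#'
#' @param fit A `"deeplse"` fit.
#' @param xtest,ytest Held-out features and binary labels.
#' @return One-row data frame: the [classification_metrics()] columns plus
#'   `roc_auc`, `pr_auc` and reconstruction `mse_db`.
#' @export
evaluate_model <- function(fit, xtest, ytest) {
  prob <- predict(fit, xtest, type = "prob")[, "positive"]
  pred <- as.integer(prob > 0.5)
  rep <- classification_metrics(confusion_counts(ytest, pred))
  rec <- reconstruct(fit, xtest)
  out <- cbind(as.data.frame(rep),
               roc_auc = roc_auc(prob, ytest),
               pr_auc = pr_auc(prob, ytest),
               mse_db = mse_db(xtest, rec$decoded))
  rownames(out) <- NULL
  out
}

#' Repeated training trials with seed-offset reproducibility
#'
#' Trains `n_trials` models on the same split, trial `t` using seed
#' `base_seed + t`, and aggregates every test-set metric as mean and
#' standard deviation. Metrics undefined in a trial (zero-denominator
#' cases) are skipped in the aggregate with a count, never coerced to 0.
#'
#' @param xtrain,ytrain Training features and labels.
#' @param xtest,ytest Held-out features and labels.
#' @param n_trials Number of independent trials (>= 1).
#' @param base_seed Base seed; trial seeds are `base_seed + 1 .. + n`.
#' @param ... Model options passed to [deeplse()] (e.g. `N`, `latent_dim`,
#'   `epochs`).
#' @return An object of class `"trial_result"`: list with `trials` (one
#'   row per trial, including the seed used) and `summary` (from
#'   [aggregate_metrics()]).
#' @export
run_trials <- function(xtrain, ytrain, xtest, ytest, n_trials = 20L,
                       base_seed = 0L, ...) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    fit <- deeplse(xtrain, ytrain, seed = base_seed + t, ...)
    rows[[t]] <- cbind(trial = t, seed = base_seed + t,
                       evaluate_model(fit, xtest, ytest))
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials,
                 summary = aggregate_metrics(trials[, -(1:2)])),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(nrow(x$trials), "trial(s); test-set aggregates:\n")
  s <- x$summary
  keep <- s$metric %in% c("balanced_accuracy", "mcc", "youden", "roc_auc",
                          "pr_auc", "mse_db")
  print(s[keep, ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Ablation grid over the CKSAAP gap and the latent dimension
#'
#' Encodes the train/test records once per `k`, then runs
#' [run_trials()] for every `(k, LV)` cell of the grid with a shared
#' `base_seed`, so the whole table is reproducible from one seed. The
#' best cell maximizes mean balanced accuracy; ties break toward the
#' smaller `k`, then the smaller latent dimension (the cheaper model).
#'
#' @param train_records,test_records Labeled record data frames.
#' @param k_values Gaps to sweep (reference grid 1..9).
#' @param lv_values Latent dimensions to sweep (reference grid 2..9).
#' @param N Width multiplier held fixed during the sweep (default 5).
#' @param n_trials Trials per cell.
#' @param base_seed Base seed shared by all cells.
#' @param ... Further model options for [deeplse()].
#' @return An object of class `"ablation_result"`: list with `cells`
#'   (per-cell aggregate rows), `trials` (every per-trial record, from
#'   which the aggregates are exactly recomputable) and `best`
#'   (`k`, `latent_dim`, mean BACC).
#' @export
run_ablation <- function(train_records, test_records, k_values = 1:9,
                         lv_values = 2:9, N = 5L, n_trials = 20L,
                         base_seed = 0L, ...) {
  if (length(k_values) == 0L || length(lv_values) == 0L) {
    stop("empty ablation grid", call. = FALSE)
  }
  cell_rows <- list()
  trial_rows <- list()
  for (k in k_values) {
    xtr <- cksaap_encode(train_records, k = k)
    xte <- cksaap_encode(test_records, k = k)
    for (lv in lv_values) {
      tr <- run_trials(xtr, train_records$label, xte, test_records$label,
                       n_trials = n_trials, base_seed = base_seed,
                       N = N, latent_dim = lv, ...)
      s <- tr$summary
      pick <- function(metric, what) s[[what]][s$metric == metric]
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        k = k, latent_dim = lv, n_trials = n_trials,
        bacc_mean = pick("balanced_accuracy", "mean"),
        bacc_sd = pick("balanced_accuracy", "sd"),
        mcc_mean = pick("mcc", "mean"), mcc_sd = pick("mcc", "sd"),
        youden_mean = pick("youden", "mean"), youden_sd = pick("youden", "sd"),
        roc_auc_mean = pick("roc_auc", "mean"), roc_auc_sd = pick("roc_auc", "sd"),
        pr_auc_mean = pick("pr_auc", "mean"), pr_auc_sd = pick("pr_auc", "sd"),
        mse_db_mean = pick("mse_db", "mean"), mse_db_sd = pick("mse_db", "sd"),
        n_undefined = sum(s$n_undefined))
      trial_rows[[length(trial_rows) + 1L]] <- cbind(k = k, latent_dim = lv,
                                                     tr$trials)
    }
  }
  cells <- do.call(rbind, cell_rows)
  best_i <- order(-cells$bacc_mean, cells$k, cells$latent_dim)[1L]
  structure(list(cells = cells,
                 trials = do.call(rbind, trial_rows),
                 best = cells[best_i, c("k", "latent_dim", "bacc_mean")]),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cells <- x$cells
  ks <- sort(unique(cells$k)); lvs <- sort(unique(cells$latent_dim))
  m <- matrix("", length(ks), length(lvs),
              dimnames = list(paste0("k=", ks), paste0("LV=", lvs)))
  for (i in seq_len(nrow(cells))) {
    m[paste0("k=", cells$k[i]), paste0("LV=", cells$latent_dim[i])] <-
      sprintf("%.3f±%.3f", cells$bacc_mean[i], cells$bacc_sd[i])
  }
  cat("Mean ± sd balanced accuracy over", cells$n_trials[1L], "trial(s):\n")
  print(m, quote = FALSE)
  cat(sprintf("best cell: k=%d, LV=%d (mean BACC %.3f)\n",
              x$best$k, x$best$latent_dim, x$best$bacc_mean))
  invisible(x)
}

#' Score an all-positive independent sequence set
#'
#' Encodes known antioxidant sequences with the model's gap parameter,
#' predicts each, and reports the per-record outcome together with the
#' correct count and accuracy — the bookkeeping used for independent-set
#' verification tables.
#'
#' @param object A `"deeplse"` fit.
#' @param records Validated record data frame of known positives.
#' @param k CKSAAP gap; defaults to the gap the model was trained with.
#' @return An object of class `"independent_eval"`: list with `table`
#'   (`id`, `predicted`, `correct`), `correct`, `total` and
#'   `accuracy_pct`.
#' @export
evaluate_independent <- function(object, records, k = object$config$k) {
  if (nrow(records) == 0L) stop("no records to evaluate", call. = FALSE)
  if (is.null(k)) stop("the model does not record k; pass it explicitly", call. = FALSE)
  x <- cksaap_encode(records, k = k)
  pred <- predict(object, x, type = "class")
  score <- score_outcomes(pred == 1L)
  structure(c(list(table = data.frame(id = records$id, predicted = pred,
                                      correct = pred == 1L)),
              score),
            class = "independent_eval")
}

#' Tally correct/total/accuracy from per-record outcomes
#'
#' @param correct Logical vector: was each known positive identified?
#' @return List with `correct`, `total` and `accuracy_pct`
#'   (percent, one decimal as conventionally printed).
#' @export
score_outcomes <- function(correct) {
  correct <- as.logical(correct)
  if (length(correct) == 0L || anyNA(correct)) {
    stop("outcomes must be non-empty TRUE/FALSE", call. = FALSE)
  }
  list(correct = sum(correct), total = length(correct),
       accuracy_pct = round(100 * mean(correct), 1))
}

#' @export
print.independent_eval <- function(x, ...) {
  marks <- ifelse(x$table$correct, "✓", "✗")
  cat(paste(sprintf("  %-12s %s", x$table$id, marks), collapse = "\n"), "\n")
  cat(sprintf("%d of %d independent antioxidant proteins identified (%.1f%%)\n",
              x$correct, x$total, x$accuracy_pct))
  invisible(x)
}

# classifier-only network head trained on frozen latent codes
fit_classifier_head <- function(z, y, N = 5L, epochs = 200L, patience = 30L,
                                batch_size = 32L, dropout = 0.3,
                                validation_fraction = 0.1,
                                learning_rate = 0.001, seed = 1L) {
  onehot <- function(yy) cbind(1 - yy, yy)
  with_seed(seed, {
    stack <- nn_init_stack(c(ncol(z), 2L * N, 2L * N, 2L), "softmax", dropout)
    opt <- nn_init_opt(stack)
    val_idx <- stratified_val_idx(y, validation_fraction)
    tr_idx <- if (length(val_idx)) setdiff(seq_len(nrow(z)), val_idx) else seq_len(nrow(z))
    best <- list(loss = Inf, stack = stack)
    wait <- 0L
    for (epoch in seq_len(epochs)) {
      for (b in make_batches(length(tr_idx), batch_size)) {
        rows <- tr_idx[b]
        fw <- nn_forward(stack, z[rows, , drop = FALSE], training = TRUE)
        stack <- fw$stack
        yb <- onehot(y[rows])
        bw <- nn_backward(stack, fw$caches, (fw$out - yb) / length(rows),
                          pre_activation = TRUE)
        up <- nn_rmsprop_update(stack, bw$grads, opt, learning_rate)
        stack <- up$stack; opt <- up$opt
      }
      eval_rows <- if (length(val_idx)) val_idx else tr_idx
      p <- nn_forward(stack, z[eval_rows, , drop = FALSE], training = FALSE)$out
      ce <- -mean(rowSums(onehot(y[eval_rows]) * log(pmax(p, CE_EPS))))
      if (ce < best$loss) {
        best <- list(loss = ce, stack = stack)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    best$stack
  })
}

predict_head <- function(stack, z) {
  nn_forward(stack, z, training = FALSE)$out[, 2L]
}

#' Compare joint training against frozen-autoencoder baselines
#'
#' Trains (1) the joint model and (2) a conventional autoencoder of
#' identical architecture (`lambda = 1`, reconstruction only) on the same
#' data and seed. The autoencoder's latent codes are then frozen and three
#' classifiers are fitted on them: the same MLP head architecture, a
#' radial-basis-kernel SVM (cost 1000, balanced class weights), and a
#' Gaussian naive Bayes classifier with equal (0.5, 0.5) class priors.
#' All four models are scored on the identical test split, and the latent
#' 1D-PCA-GCNR separability of the two autoencoders is reported.
#'
#' @param xtrain,ytrain,xtest,ytest Train/test features and labels.
#' @param N,latent_dim Architecture, see [deeplse()].
#' @param lambda Mixing weight of the joint model (default 0.99).
#' @param seed Seed shared by both trainings.
#' @param bins Histogram bins for the GCNR scores.
#' @param ... Further options for [deeplse()] (e.g. `epochs`, `patience`).
#' @return An object of class `"baseline_comparison"`: list with `metrics`
#'   (rows: joint model, AE+MLP, AE+SVM, AE+NB), `latent_gcnr`
#'   (named: `deeplse`, `ae`) and the two fits.
#' @export
baseline_ae_comparison <- function(xtrain, ytrain, xtest, ytest,
                                   N = 5L, latent_dim = 6L, lambda = 0.99,
                                   seed = 1L, bins = 100L, ...) {
  joint <- deeplse(xtrain, ytrain, N = N, latent_dim = latent_dim,
                   lambda = lambda, seed = seed, ...)
  ae <- deeplse(xtrain, ytrain, N = N, latent_dim = latent_dim,
                lambda = 1, seed = seed, ...)
  ztr <- encode_latent(ae, xtrain)
  zte <- encode_latent(ae, xtest)

  head_stack <- fit_classifier_head(ztr, ytrain, N = N, seed = seed)
  p_mlp <- predict_head(head_stack, zte)

  wts <- length(ytrain) / (2 * table(factor(ytrain, levels = c(0L, 1L))))
  svm_fit <- e1071::svm(x = ztr, y = factor(ytrain, levels = c(0L, 1L)),
                        kernel = "radial", cost = 1000,
                        class.weights = setNames(as.numeric(wts), names(wts)))
  pred_svm <- as.integer(as.character(predict(svm_fit, zte)))

  nb_fit <- e1071::naiveBayes(x = as.data.frame(ztr),
                              y = factor(ytrain, levels = c(0L, 1L)))
  raw <- predict(nb_fit, as.data.frame(zte), type = "raw")
  # refit the posterior to equal (0.5, 0.5) class priors
  prior <- as.numeric(nb_fit$apriori) / sum(nb_fit$apriori)
  eq <- sweep(raw, 2L, prior, "/")
  p_nb <- eq[, 2L] / rowSums(eq)

  metric_row <- function(pred) {
    as.data.frame(classification_metrics(confusion_counts(ytest, pred)))
  }
  metrics <- cbind(method = c("DeepLSE (joint)", "AE + MLP", "AE + SVM", "AE + NB"),
                   rbind(metric_row(predict(joint, xtest, type = "class")),
                         metric_row(as.integer(p_mlp > 0.5)),
                         metric_row(pred_svm),
                         metric_row(as.integer(p_nb > 0.5))))
  latent_gcnr <- c(
    deeplse = pca1d_gcnr(encode_latent(joint, xtest), ytest, bins, "latent")$gcnr,
    ae = pca1d_gcnr(zte, ytest, bins, "latent")$gcnr)
  structure(list(metrics = metrics, latent_gcnr = latent_gcnr,
                 joint = joint, ae = ae),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cols <- c("method", "sensitivity", "specificity", "accuracy",
            "balanced_accuracy", "mcc", "f1", "youden")
  print(x$metrics[, cols], row.names = FALSE, digits = 3)
  cat(sprintf("latent 1D-PCA-GCNR: joint %.3f vs conventional AE %.3f\n",
              x$latent_gcnr[["deeplse"]], x$latent_gcnr[["ae"]]))
  invisible(x)
}
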