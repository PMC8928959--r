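# Independent oracles used across the suite.

# naive double-loop pair counter, deliberately unrelated to the package's
# vectorized CKSAAP implementation
cksaap_bruteforce <- function(seq, k, normalize = TRUE) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  alpha <- aoplse::AA_ALPHABET
  pair_names <- as.vector(t(outer(alpha, alpha, paste0)))
  out <- numeric(0)
  for (j in 0:k) {
    block <- setNames(numeric(400), pair_names)
    npos <- L - j - 1L
    if (npos >= 1L) {
      for (i in seq_len(npos)) {
        pair <- paste0(chars[i], chars[i + j + 1L])
        block[pair] <- block[pair] + 1
      }
      if (normalize) block <- block / npos
    }
    names(block) <- paste0("j", j, "_", names(block))
    out <- c(out, block)
  }
  out
}

random_aa_seq <- function(L) {
  paste(sample(aoplse::AA_ALPHABET, L, replace = TRUE), collapse = "")
}

# independent transcription of the confusion-matrix statistics, written
# directly from their defining formulas
metrics_transcription <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sn <- safe(tp, tp + fn)
  sp <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  acc <- (tp + tn) / n
  mccd <- sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tp + fn) * sqrt(tn + fp)
  mcc <- if (mccd == 0) NA_real_ else (tp * tn - fp * fn) / mccd
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  list(sensitivity = sn, specificity = sp, precision = prec, accuracy = acc,
       mcc = mcc,
       balanced_accuracy = if (is.na(sn) || is.na(sp)) NA_real_ else (sn + sp) / 2,
       youden = if (is.na(sn) || is.na(sp)) NA_real_ else sn + sp - 1,
       f1 = if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_ else
         2 * prec * sn / (prec + sn),
       po = po, pe = pe,
       kappa = if (pe == 1) NA_real_ else (po - pe) / (1 - pe))
}

# tiny quick-to-fit dataset + model for the model-interface tests
quick_dataset <- function(n_pos = 40, n_neg = 120, effect_size = 5, seed = 42,
                          k = 1) {
  dat <- aoplse::generate_proteins(n_pos = n_pos, n_neg = n_neg,
                                   length_range = c(50, 120),
                                   effect_size = effect_size, seed = seed)
  list(records = dat, x = aoplse::cksaap_encode(dat, k = k), y = dat$label)
}

quick_fit <- function(d, seed = 1, epochs = 60, patience = epochs, ...) {
  aoplse::deeplse(d$x, d$y, N = 2, latent_dim = 3, epochs = epochs,
                  patience = patience, seed = seed, ...)
}
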