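#' Default planted motif set for the synthetic generator
#'
#' Three residue pairs at gaps 0, 2 and 6, so that an ablation over the
#' CKSAAP gap parameter k has signal at small gaps and a detectable
#' optimum once k reaches 6.
#'
#' @return Data frame with columns `first`, `second`, `gap`, `weight`.
#' @export
default_motifs <- function() {
  data.frame(first = c("C", "H", "W"),
             second = c("C", "E", "Y"),
             gap = c(0L, 2L, 6L),
             weight = c(1, 1, 1),
             stringsAsFactors = FALSE)
}

#' Generate a labeled synthetic protein dataset with planted pair motifs
#'
#' Emulates a two-class benchmark of the shape used for antioxidant
#' protein prediction: a small positive class and a roughly six-fold
#' larger negative class of sequences over the 20-letter alphabet with
#' lengths in `length_range`. Negative sequences are drawn i.i.d. from
#' `background`. Positive sequences start from the same background and
#' then have motif pairs planted: for each motif `(a, b, gap, weight)` a
#' Poisson-distributed number of anchor positions (mean
#' `effect_size * weight * L / 100` for a sequence of length `L`) is
#' chosen and the residues at the anchor and at `anchor + gap + 1` are
#' overwritten with `a` and `b`. Planting overwrites rather than inserts,
#' so sequence length is identical in distribution between classes and
#' cannot act as a confound. `effect_size = 0` plants nothing: the two
#' classes are then statistically identical.
#'
#' @param n_pos,n_neg Class sizes (defaults 200 and 1240, the training
#'   split shape of the reference benchmark).
#' @param length_range Integer pair of min/max sequence length (default
#'   50-600); the minimum must be at least the largest motif gap + 2.
#' @param motif_pairs Data frame as [default_motifs()].
#' @param effect_size Non-negative scaling of all planting rates (default
#'   5, a strongly recoverable signal; 0 gives the null).
#' @param background Length-20 residue sampling probabilities in
#'   [AA_ALPHABET] order (default uniform).
#' @param seed Integer seed; the dataset is fully reproducible.
#' @return A labeled record data frame (`id`, `sequence`, `label`) with
#'   positives first.
#' @examples
#' dat <- generate_proteins(n_pos = 5, n_neg = 10, length_range = c(50, 60),
#'                          seed = 1)
#' table(dat$label)
#' @export
generate_proteins <- function(n_pos = 200L, n_neg = 1240L,
                              length_range = c(50L, 600L),
                              motif_pairs = default_motifs(),
                              effect_size = 5,
                              background = rep(1 / 20, 20L),
                              seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length(background) == 20L, effect_size >= 0)
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1", call. = FALSE)
  max_gap <- if (nrow(motif_pairs) > 0L) max(motif_pairs$gap) else 0L
  if (length_range[1L] < max_gap + 2L) {
    stop("minimum length ", length_range[1L], " cannot host a motif at gap ",
         max_gap, call. = FALSE)
  }
  if (!all(motif_pairs$first %in% AA_ALPHABET) ||
      !all(motif_pairs$second %in% AA_ALPHABET)) {
    stop("motif residues must be standard amino-acid letters", call. = FALSE)
  }

  with_seed(seed, {
    draw_seq <- function(L) sample(AA_ALPHABET, L, replace = TRUE, prob = background)
    lens_pos <- sample(length_range[1L]:length_range[2L], n_pos, replace = TRUE)
    lens_neg <- sample(length_range[1L]:length_range[2L], n_neg, replace = TRUE)

    pos <- vapply(lens_pos, function(L) {
      s <- draw_seq(L)
      for (m in seq_len(nrow(motif_pairs))) {
        gap <- motif_pairs$gap[m]
        n_plant <- rpois(1L, effect_size * motif_pairs$weight[m] * L / 100)
        if (n_plant > 0L) {
          anchors <- sample.int(L - gap - 1L, n_plant, replace = TRUE)
          s[anchors] <- motif_pairs$first[m]
          s[anchors + gap + 1L] <- motif_pairs$second[m]
        }
      }
      paste(s, collapse = "")
    }, character(1L))
    neg <- vapply(lens_neg, function(L) paste(draw_seq(L), collapse = ""), character(1L))

    data.frame(
      id = c(sprintf("POS%04d", seq_len(n_pos)), sprintf("NEG%04d", seq_len(n_neg))),
      sequence = c(pos, neg),
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      stringsAsFactors = FALSE)
  })
}

#' Stratified train/test split with exact per-class training counts
#'
#' @param records Labeled record data frame.
#' @param n_pos_train,n_neg_train Exact per-class training counts; the
#'   remaining records form the test set.
#' @param seed Integer seed for the random partition.
#' @return List with `train` and `test` record data frames; no record
#'   appears in both.
#' @examples
#' dat <- generate_proteins(n_pos = 10, n_neg = 20, length_range = c(50, 60),
#'                          seed = 1)
#' sp <- make_benchmark_splits(dat, 8, 16, seed = 2)
#' nrow(sp$test)  # 2 + 4
#' @export
make_benchmark_splits <- function(records, n_pos_train, n_neg_train, seed = 1L) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  pos_rows <- which(records$label == 1L)
  neg_rows <- which(records$label == 0L)
  if (n_pos_train > length(pos_rows) || n_neg_train > length(neg_rows)) {
    stop("requested training counts exceed available records per class", call. = FALSE)
  }
  with_seed(seed, {
    tr <- c(sample(pos_rows, n_pos_train), sample(neg_rows, n_neg_train))
    list(train = records[sort(tr), , drop = FALSE],
         test = records[setdiff(seq_len(nrow(records)), tr), , drop = FALSE])
  })
}

#' Materialize the default benchmark-shaped synthetic dataset on disk
#'
#' Writes one FASTA per class plus the `id<TAB>label` table into `dir`.
#'
#' @param dir Output directory (created if missing).
#' @param ... Passed to [generate_proteins()].
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_fixtures <- function(dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dat <- generate_proteins(...)
  paths <- c(positive = file.path(dir, "positive.fasta"),
             negative = file.path(dir, "negative.fasta"),
             labels = file.path(dir, "labels.tsv"))
  write_fasta(dat[dat$label == 1L, ], paths[["positive"]])
  write_fasta(dat[dat$label == 0L, ], paths[["negative"]])
  utils::write.table(dat[, c("id", "label")], paths[["labels"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}
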