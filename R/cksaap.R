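#' Composition of k-spaced amino-acid pairs (CKSAAP) for one sequence
#'
#' For every gap `j` in `0..k`, counts occurrences of each of the 400
#' ordered residue pairs `(s[i], s[i + j + 1])` over all positions
#' `i = 1..L-j-1` (overlapping occurrences all count). The `k + 1` blocks of
#' 400 values are concatenated in order `j = 0..k`, giving a vector of
#' length `400 * (k + 1)`. Within a block, pairs are ordered AA, AC, ...,
#' YY under the canonical alphabet [AA_ALPHABET]; entry names follow the
#' `j{gap}_{pair}` convention (e.g. `j0_AA`, `j2_CY`), which is part of the
#' feature-file format.
#'
#' With `normalize = TRUE` (the default) block `j` is divided by the number
#' of available positions `L - j - 1`, so entries are pair frequencies in
#' `[0, 1]` and each block sums to 1 whenever the sequence is long enough.
#' A sequence shorter than `j + 2` has no pair at gap `j`: that block is
#' all zeros and a warning is issued.
#'
#' @param sequence A validated amino-acid string over the standard
#'   20-letter alphabet (see [validate_sequences()]).
#' @param k Maximum gap (non-negative integer). Values above 9 are allowed
#'   but warned about, as descriptor width grows as `400 * (k + 1)`.
#' @param normalize Divide counts by the number of positions (default
#'   `TRUE`); `FALSE` returns raw counts.
#' @return Named numeric vector of length `400 * (k + 1)` with attributes
#'   `k` and `sequence_length`.
#' @examples
#' v <- cksaap("ACDA", k = 1)
#' v[v > 0]
#' @export
cksaap <- function(sequence, k = 6L, normalize = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  if (k > 9L) warning("k = ", k, " is beyond the usual 0..9 range; descriptor width is ",
                      400L * (k + 1L), call. = FALSE)
  code <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], AA_ALPHABET)
  if (anyNA(code)) {
    stop("invalid letter(s) at position(s) ",
         paste(head(which(is.na(code)), 5L), collapse = ","),
         "; validate sequences first", call. = FALSE)
  }
  L <- length(code)
  out <- numeric(400L * (k + 1L))
  short <- integer(0)
  for (j in 0:k) {
    npos <- L - j - 1L
    if (npos < 1L) {
      short <- c(short, j)
      next
    }
    first <- code[seq_len(npos)]
    second <- code[seq_len(npos) + j + 1L]
    counts <- tabulate(20L * (first - 1L) + second, nbins = 400L)
    if (normalize) counts <- counts / npos
    out[(400L * j + 1L):(400L * (j + 1L))] <- counts
  }
  if (length(short) > 0L) {
    warning("sequence of length ", L, " has no pair at gap(s) ",
            paste(short, collapse = ","), "; block(s) set to zero", call. = FALSE)
  }
  names(out) <- cksaap_colnames(k)
  attr(out, "k") <- k
  attr(out, "sequence_length") <- L
  out
}

#' Column names of the CKSAAP descriptor
#'
#' @param k Maximum gap.
#' @return Character vector `j0_AA`, `j0_AC`, ..., ordered as the blocks of
#'   [cksaap()].
#' @export
cksaap_colnames <- function(k) {
  pairs <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  as.vector(vapply(0:k, function(j) paste0("j", j, "_", pairs), character(400L)))
}

#' Encode a set of sequences as a CKSAAP feature matrix
#'
#' @param x A record data frame (with `id` and `sequence` columns) or a
#'   character vector of sequences.
#' @param k Maximum gap, see [cksaap()].
#' @param normalize See [cksaap()].
#' @return Numeric matrix, one row per input sequence in input order,
#'   `400 * (k + 1)` named columns, row names taken from record ids where
#'   available.
#' @examples
#' cksaap_encode(c("ACDA", "MKVW"), k = 1)[, c("j0_AC", "j1_AD")]
#' @export
cksaap_encode <- function(x, k = 6L, normalize = TRUE) {
  if (is.data.frame(x)) {
    seqs <- x$sequence
    ids <- x$id
  } else {
    seqs <- as.character(x)
    ids <- names(x)
  }
  if (length(seqs) == 0L) stop("no sequences to encode", call. = FALSE)
  mat <- t(vapply(seqs, function(s) as.vector(cksaap(s, k = k, normalize = normalize)),
                  numeric(400L * (as.integer(k) + 1L)), USE.NAMES = FALSE))
  colnames(mat) <- cksaap_colnames(k)
  rownames(mat) <- ids
  attr(mat, "k") <- as.integer(k)
  mat
}

#' Write / read a CKSAAP feature matrix as CSV
#'
#' The CSV carries record ids in the first column (`id`) and the
#' `j{gap}_{pair}` descriptor columns after it.
#'
#' @param mat Feature matrix from [cksaap_encode()].
#' @param path CSV file path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the matrix with the `k` attribute restored.
#' @export
write_features <- function(mat, path) {
  df <- data.frame(id = rownames(mat) %||% seq_len(nrow(mat)), mat,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  k <- ncol(mat) / 400L - 1L
  if (k != round(k)) stop("not a CKSAAP matrix: ", ncol(mat), " columns", call. = FALSE)
  attr(mat, "k") <- as.integer(k)
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
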