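#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a data frame of protein
#' records. Sequence lines belonging to one header are concatenated and all
#' whitespace is stripped; the input record order is preserved.
#'
#' @param path Path to a FASTA file, or a character vector of FASTA lines.
#' @param label Optional class label (0 = non-antioxidant, 1 = antioxidant)
#'   applied to every record, e.g. when positives and negatives are shipped
#'   as separate files. `NULL` leaves labels `NA`.
#' @return A data frame with columns `id` (character), `sequence`
#'   (character) and `label` (integer, possibly `NA`).
#' @seealso [validate_sequences()], [write_fasta()], [read_label_table()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp1", "MKV", ">sp2", "ACDE", "FGH"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, label = NULL) {
  lines <- if (length(path) == 1L && !startsWith(path[1L], ">") && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (!is.null(label)) {
    label <- as.integer(label)
    stopifnot(length(label) == 1L, label %in% c(0L, 1L))
  }
  keep <- nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("malformed FASTA: sequence data before first '>' header at line ",
         line_no[1L], call. = FALSE)
  }
  grp <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- sub("\\s.*$", "", ids)  # first whitespace-delimited token
  if (any(!nzchar(ids))) {
    stop("malformed FASTA: empty record id at line ",
         line_no[is_header][!nzchar(ids)][1L], call. = FALSE)
  }
  seqs <- vapply(split(lines[!is_header], factor(grp[!is_header], levels = seq_along(ids))),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1L))
  data.frame(id = ids, sequence = unname(seqs),
             label = if (is.null(label)) NA_integer_ else label,
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with `id` and `sequence` columns, as returned
#'   by [read_fasta()] or [generate_proteins()].
#' @param path Output file path.
#' @param width Line width for wrapping sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a tab-separated label table
#'
#' Expects a header line `id<TAB>label` with labels in \{0, 1\}
#' (1 = antioxidant).
#'
#' @param path Path to the TSV file.
#' @return Data frame with character `id` and integer `label`.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer"))
  if (!identical(names(tab), c("id", "label"))) {
    stop("label table must have header 'id<TAB>label'", call. = FALSE)
  }
  if (!all(tab$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  tab
}

#' Attach labels from a label table to parsed records
#'
#' @param records Data frame from [read_fasta()].
#' @param labels Data frame from [read_label_table()].
#' @return `records` with the `label` column filled in.
#' @export
label_records <- function(records, labels) {
  idx <- match(records$id, labels$id)
  if (anyNA(idx)) {
    stop("no label for record(s): ",
         paste(head(records$id[is.na(idx)], 5L), collapse = ", "), call. = FALSE)
  }
  records$label <- labels$label[idx]
  records
}

#' Validate protein sequences against the standard amino-acid alphabet
#'
#' Lowercase letters are uppercased first. Any remaining character outside
#' the 20 standard letters (for example B, J, O, U, X, Z, gaps, `*`) is
#' handled according to `policy`.
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param policy `"error"` (default) rejects the dataset, naming offending
#'   records and positions; `"strip"` removes offending characters;
#'   `"drop"` discards offending records entirely.
#' @return The validated records (uppercased; possibly fewer rows under
#'   `"drop"`, possibly shorter sequences under `"strip"`).
#' @examples
#' recs <- data.frame(id = "p1", sequence = "acdx")
#' validate_sequences(recs, policy = "strip")  # sequence becomes "ACD"
#' @export
validate_sequences <- function(records, policy = c("error", "strip", "drop")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  seqs <- toupper(records$sequence)
  ok_pat <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  bad <- grepl(ok_pat, seqs)
  if (any(bad)) {
    if (policy == "error") {
      msgs <- vapply(which(bad)[seq_len(min(sum(bad), 5L))], function(i) {
        pos <- gregexpr(ok_pat, seqs[i])[[1L]]
        letters_bad <- substring(seqs[i], pos, pos)
        sprintf("%s: position(s) %s (letter(s) %s)", records$id[i],
                paste(pos, collapse = ","), paste(letters_bad, collapse = ","))
      }, character(1L))
      stop("non-standard amino-acid letters in ", sum(bad), " record(s):\n  ",
           paste(msgs, collapse = "\n  "), call. = FALSE)
    } else if (policy == "strip") {
      seqs[bad] <- gsub(ok_pat, "", seqs[bad])
    } else {
      records <- records[!bad, , drop = FALSE]
      seqs <- seqs[!bad]
    }
  }
  if (any(!nzchar(seqs))) {
    stop("validation left ", sum(!nzchar(seqs)), " empty sequence(s)", call. = FALSE)
  }
  records$sequence <- seqs
  rownames(records) <- NULL
  records
}

#' Read a labeled two-class dataset from positive and negative FASTA files
#'
#' @param positive_path FASTA of antioxidant (positive, label 1) sequences.
#' @param negative_path FASTA of non-antioxidant (negative, label 0)
#'   sequences.
#' @param policy Validation policy, see [validate_sequences()].
#' @return A labeled, validated record data frame with unique ids.
#' @export
read_labeled_fasta <- function(positive_path, negative_path,
                               policy = c("error", "strip", "drop")) {
  recs <- rbind(read_fasta(positive_path, label = 1L),
                read_fasta(negative_path, label = 0L))
  if (anyDuplicated(recs$id)) {
    stop("duplicate record ids across classes: ",
         paste(head(unique(recs$id[duplicated(recs$id)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  validate_sequences(recs, policy = match.arg(policy))
}
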