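# Sequence record sets and FASTA IO.
#
# A seq_set is a plain data.frame (id, desc, seq) with an "alphabet"
# attribute; readers validate strictly and refuse to repair malformed input.

NUC_CHARS <- strsplit("ACGTURYSWKMBDHVN-.", "")[[1]]
AA_CHARS  <- strsplit("ACDEFGHIKLMNPQRSTVWYX*-.", "")[[1]]

#' Construct a sequence record set
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of sequences (non-empty).
#' @param desc optional descriptions (recycled).
#' @param alphabet `"nucleotide"` or `"amino-acid"`. Nucleotide sequences may
#'   use IUPAC ambiguity codes; amino-acid sequences may use `X` and `*`.
#'   Alignment gap characters `-` and `.` are accepted in both.
#' @return A data.frame of class `seq_set` with columns id, desc, seq.
#' @export
seq_set <- function(id, seq, desc = "", alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id); seq <- as.character(seq)
  if (length(id) != length(seq))
    stop_condition("id and seq lengths differ", "wolbpan_format")
  if (anyDuplicated(id))
    stop_condition(sprintf("duplicate sequence id: %s",
                           id[duplicated(id)][1]), "wolbpan_format")
  if (any(!nzchar(seq)))
    stop_condition(sprintf("empty sequence for id: %s",
                           id[!nzchar(seq)][1]), "wolbpan_format")
  allowed <- if (alphabet == "nucleotide") NUC_CHARS else AA_CHARS
  for (i in seq_along(seq)) {
    chars <- unique(strsplit(toupper(seq[i]), "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop_condition(sprintf("record '%s' violates %s alphabet (offending: %s)",
                             id[i], alphabet, paste(bad, collapse = "")),
                     "wolbpan_format")
  }
  desc <- rep_len(as.character(desc), length(id))
  out <- data.frame(id = id, desc = desc, seq = toupper(seq),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", class(out))
  out
}

#' Read a FASTA file into a validated sequence set
#'
#' Record order is preserved; the first whitespace-delimited token of each
#' header is the id, the remainder the description. Duplicate ids, empty
#' sequences and alphabet violations are format errors, never repaired.
#'
#' @param path path to an (optionally gzipped) FASTA file.
#' @param alphabet `"nucleotide"` or `"amino-acid"` (see [seq_set()]).
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path))
    stop_condition(sprintf("no such file: %s", path), "wolbpan_io")
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(ids, as.character(x), descs, alphabet = alphabet)
}

#' Write a sequence set as FASTA
#'
#' Line wrapping is normalized to `width` characters so that
#' `write_fasta(read_fasta(f))` is byte-identical on canonical content.
#'
#' @param x a [seq_set()] or named character vector.
#' @param path output path.
#' @param width wrap width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x) && !is.null(names(x)))
    x <- data.frame(id = names(x), desc = "", seq = unname(x),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d %s record(s)\n", nrow(x), attr(x, "alphabet")))
  n <- min(nrow(x), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %s (%d)\n", x$id[i], nchar(x$seq[i])))
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}
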