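# Read-vs-reference alignment records (SAM and PAF text dialects).
#
# An aln_record stores the ordered runs of alignment events
# (match "=", mismatch "X", ambiguous "M", insertion "I", deletion "D"),
# the NM-style edit distance when present (NM convention: mismatches +
# inserted bases + deleted bases), and a parsed cs:Z: difference string when
# present. These are the inputs of the gap-compressed divergence filter.

CIGAR_RE <- "([0-9]+)([MIDNSHP=X])"

parse_cigar_runs <- function(cigar) {
  m <- gregexpr(CIGAR_RE, cigar)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar))
    stop_condition(sprintf("malformed CIGAR: %s", cigar), "wolbpan_format")
  toks <- regmatches(cigar, gregexpr(CIGAR_RE, cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

# Parse a minimap2 cs:Z: difference string into event runs and the implied
# edit distance. Ops: ":n" identical run, "*ab" substitution, "+seq"
# insertion, "-seq" deletion, "=SEQ" identical run (long form).
parse_cs_string <- function(cs) {
  toks <- regmatches(cs, gregexpr(
    ":[0-9]+|\\*[a-zA-Z]{2}|\\+[a-zA-Z]+|-[a-zA-Z]+|=[A-Za-z]+", cs))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cs))
    stop_condition(sprintf("malformed cs string: %s", cs), "wolbpan_format")
  op <- character(0); len <- integer(0)
  for (t in toks) {
    tag <- substr(t, 1, 1)
    if (tag == ":") { op <- c(op, "="); len <- c(len, as.integer(substr(t, 2, nchar(t)))) }
    else if (tag == "=") { op <- c(op, "="); len <- c(len, nchar(t) - 1L) }
    else if (tag == "*") { op <- c(op, "X"); len <- c(len, 1L) }
    else if (tag == "+") { op <- c(op, "I"); len <- c(len, nchar(t) - 1L) }
    else { op <- c(op, "D"); len <- c(len, nchar(t) - 1L) }
  }
  # collapse adjacent runs of the same op (consecutive * substitutions)
  r <- rle(op)
  runs <- data.frame(op = r$values,
                     len = as.integer(tapply(len, rep(seq_along(r$values), r$lengths), sum)),
                     stringsAsFactors = FALSE)
  nm <- sum(runs$len[runs$op %in% c("X", "I", "D")])
  list(runs = runs, implied_nm = nm)
}

new_aln_record <- function(read_id, target_id, runs, edit_distance = NA_integer_,
                           mapped = TRUE, primary = TRUE, strand = "+",
                           cs = NA_character_) {
  if (nrow(runs) && any(runs$len < 1L))
    stop_condition("alignment run with length < 1", "wolbpan_format")
  structure(list(read_id = read_id, target_id = target_id, runs = runs,
                 edit_distance = edit_distance, mapped = mapped,
                 primary = primary, strand = strand, cs = cs),
            class = "aln_record")
}

#' @export
print.aln_record <- function(x, ...) {
  cat(sprintf("aln_record %s -> %s [%s%s] %s NM=%s\n", x$read_id, x$target_id,
              if (x$mapped) "mapped" else "unmapped",
              if (x$primary) "" else ",secondary",
              paste0(x$runs$len, x$runs$op, collapse = ""),
              x$edit_distance), ...)
  invisible(x)
}

sam_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (!length(hit)) NA_character_ else sub("^[A-Za-z0-9]+:[A-Za-z]:", "", hit[1])
}

parse_sam_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L)
    stop_condition("SAM line with fewer than 11 fields", "wolbpan_format")
  flag <- as.integer(f[2])
  mapped <- bitwAnd(flag, 4L) == 0L
  primary <- bitwAnd(flag, 256L) == 0L && bitwAnd(flag, 2048L) == 0L
  strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
  cigar <- f[6]; seq <- f[10]
  runs <- if (!mapped || cigar == "*") {
    data.frame(op = character(0), len = integer(0), stringsAsFactors = FALSE)
  } else {
    r <- parse_cigar_runs(cigar)
    if (seq != "*") {
      qlen <- sum(r$len[r$op %in% c("M", "I", "S", "=", "X")])
      if (qlen != nchar(seq))
        stop_condition(sprintf(
          "read %s: CIGAR implies query length %d but SEQ has %d bases",
          f[1], qlen, nchar(seq)), "wolbpan_format")
    }
    r[r$op %in% c("M", "I", "D", "=", "X"), , drop = FALSE]
  }
  nm <- sam_tag(f[-(1:11)], "NM")
  cs <- sam_tag(f[-(1:11)], "cs")
  finish_record(f[1], f[3], runs, nm, cs, mapped, primary, strand)
}

parse_paf_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 12L)
    stop_condition("PAF line with fewer than 12 fields", "wolbpan_format")
  tags <- if (length(f) > 12L) f[13:length(f)] else character(0)
  tp <- sam_tag(tags, "tp")
  primary <- is.na(tp) || tp == "P"
  cg <- sam_tag(tags, "cg")
  nm <- sam_tag(tags, "NM")
  cs <- sam_tag(tags, "cs")
  runs <- if (!is.na(cg)) {
    r <- parse_cigar_runs(cg)
    r[r$op %in% c("M", "I", "D", "=", "X"), , drop = FALSE]
  } else data.frame(op = character(0), len = integer(0), stringsAsFactors = FALSE)
  finish_record(f[1], f[6], runs, nm, cs, mapped = TRUE, primary = primary,
                strand = f[5])
}

finish_record <- function(read_id, target_id, runs, nm, cs, mapped, primary,
                          strand) {
  nm <- if (is.na(nm)) NA_integer_ else as.integer(nm)
  if (!is.na(cs)) {
    parsed <- parse_cs_string(cs)
    if (!is.na(nm) && parsed$implied_nm != nm)
      stop_condition(sprintf(
        "read %s: cs string implies edit distance %d but NM is %d",
        read_id, parsed$implied_nm, nm), "wolbpan_format")
    if (is.na(nm)) nm <- parsed$implied_nm
    # cs resolves ambiguous M runs into explicit =/X runs
    if (nrow(runs) == 0L || any(runs$op == "M")) runs <- parsed$runs
  }
  new_aln_record(read_id, target_id, runs, edit_distance = nm, mapped = mapped,
                 primary = primary, strand = strand, cs = cs)
}

#' Read alignment records from SAM or PAF text
#'
#' Parses per-record event runs (match/mismatch/insertion/deletion), the
#' NM-style edit distance when present, and the minimap2 `cs:Z:` difference
#' string when present (a `cs` string resolves ambiguous `M` CIGAR runs into
#' explicit match/mismatch runs; a disagreement between a parsed `cs` string
#' and an `NM` tag is a format error). Unmapped records are flagged rather
#' than dropped. Records whose divergence cannot be determined (plain `M`
#' CIGAR with neither `NM` nor `cs`) are parsed but flagged indeterminate by
#' [gap_compressed_divergence()].
#'
#' @param path path to the alignment file.
#' @param dialect `"sam"` or `"paf"`.
#' @return A list of `aln_record` objects (class `aln_records`).
#' @export
read_alignment_records <- function(path, dialect = c("sam", "paf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_condition(sprintf("no such file: %s", path), "wolbpan_io")
  lines <- readLines(path)
  if (dialect == "sam") lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, if (dialect == "sam") parse_sam_line else parse_paf_line)
  class(out) <- "aln_records"
  out
}
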