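# Center-star multiple alignment of orthogroup members and single-copy
# ortholog supermatrix export.

aa_substitution_matrix <- local({
  cache <- NULL
  function(match = 1, mismatch = -1) {
    if (!is.null(cache)) return(cache)
    letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
    m <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- match
    cache <<- m
    m
  }
})

# Global (Needleman-Wunsch) alignment of amino-acid strings `bs` against
# one string `a` under match +1 / mismatch -1 and affine gaps: a gap of
# length L costs 2 + L (open 2, extend 1). Vectorized over `bs`; returns a
# list of gapped string pairs.
global_align_many <- function(a, bs) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(bs),
    Biostrings::AAString(a), type = "global",
    substitutionMatrix = aa_substitution_matrix(),
    gapOpening = 2, gapExtension = 1)
  # reconstruct gapped strings from ranges + indel sets: equivalent to
  # alignedPattern()/alignedSubject() but without their per-element
  # S4 extraction cost (verified against them in the test suite)
  pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
  ps <- Biostrings::start(pat); pe <- Biostrings::end(pat)
  ss <- Biostrings::start(sub); se <- Biostrings::end(sub)
  dels <- Biostrings::deletion(Biostrings::indel(aln))
  inss <- Biostrings::insertion(Biostrings::indel(aln))
  scores <- Biostrings::score(aln)
  na <- nchar(a)
  # ranges are in the ungapped coordinates of the aligned (clipped) region:
  # a block of `width` gaps is inserted before ungapped position `start`
  insert_gaps <- function(seq, ranges) {
    if (!length(ranges)) return(seq)
    starts <- BiocGenerics::start(ranges)
    widths <- BiocGenerics::width(ranges)
    pieces <- character(0); prev <- 1L
    for (j in seq_along(starts)) {
      pieces <- c(pieces, substr(seq, prev, starts[j] - 1L),
                  strrep("-", widths[j]))
      prev <- starts[j]
    }
    paste0(paste(pieces, collapse = ""), substr(seq, prev, nchar(seq)))
  }
  lapply(seq_along(bs), function(i) {
    nb <- nchar(bs[[i]])
    core_p <- insert_gaps(substr(bs[[i]], ps[i], pe[i]), dels[[i]])
    core_s <- insert_gaps(substr(a, ss[i], se[i]), inss[[i]])
    lead_p <- if (ss[i] > 1L) strrep("-", ss[i] - 1L)
              else substr(bs[[i]], 1L, ps[i] - 1L)
    lead_s <- if (ss[i] > 1L) substr(a, 1L, ss[i] - 1L)
              else strrep("-", ps[i] - 1L)
    trail_p <- if (se[i] < na) strrep("-", na - se[i])
               else substr(bs[[i]], pe[i] + 1L, nb)
    trail_s <- if (se[i] < na) substr(a, se[i] + 1L, na)
               else strrep("-", nb - pe[i])
    list(a = paste0(lead_s, core_s, trail_s),
         b = paste0(lead_p, core_p, trail_p),
         score = scores[i])
  })
}

global_align <- function(a, b) global_align_many(a, b)[[1]]

#' Align an orthogroup by the center-star method
#'
#' The center is the member maximizing its summed pairwise k-mer similarity
#' to all others (ties broken by smallest gene id); every other member is
#' globally aligned to the center (match +1, mismatch -1, gap open -2, gap
#' extend -1) and the pairwise alignments are merged under the
#' once-a-gap-always-a-gap rule. Rows are returned in canonical (sorted gene
#' id) order, so column content is invariant to input row order. A
#' single-member group is returned unaligned.
#'
#' @param members named character vector of amino-acid sequences (names =
#'   gene ids), or an [orthogroup()] (its sequences must then be supplied via
#'   `seqs`).
#' @param k k-mer size for center selection (default 4).
#' @return Named character vector of equal-length aligned rows.
#' @export
align_orthogroup <- function(members, k = 4L) {
  stopifnot(is.character(members), !is.null(names(members)))
  members <- members[order(names(members))]
  if (length(members) == 1L) return(members)

  n <- length(members)
  counts <- lapply(members, function(m)
    if (nchar(m) < k) NULL else kmer_count_vec(m, k))
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- if (is.null(counts[[i]]) || is.null(counts[[j]])) 0
         else multiset_jaccard(counts[[i]], counts[[j]])
    sim[i, j] <- s; sim[j, i] <- s
  }
  center <- which.max(rowSums(sim))  # first index = smallest id on ties
  cseq <- members[[center]]
  others <- setdiff(seq_len(n), center)

  # per member: insertion counts before each center position (1..nc+1) and
  # the member characters grouped per center slot
  nc <- nchar(cseq)
  ins_counts <- matrix(0L, nrow = length(others), ncol = nc + 1L)
  member_slots <- vector("list", length(others))
  alns <- if (length(others)) global_align_many(cseq, unname(members[others]))
          else list()
  for (oi in seq_along(others)) {
    aln <- alns[[oi]]
    ca <- strsplit(aln$a, "")[[1]]; ma <- strsplit(aln$b, "")[[1]]
    cpos <- cumsum(ca != "-")                 # center residue index per column
    slot <- ifelse(ca == "-", cpos + 1L, cpos)  # insertions attach before next residue
    ins <- ca == "-"
    slots <- vector("list", nc + 1L)
    for (p in seq_len(nc + 1L)) slots[[p]] <- list(ins = character(0), res = NA_character_)
    for (col in seq_along(ca)) {
      p <- slot[col]
      if (ins[col]) slots[[p]]$ins <- c(slots[[p]]$ins, ma[col])
      else slots[[p]]$res <- ma[col]
    }
    ins_counts[oi, ] <- vapply(slots, function(s) length(s$ins), integer(1))
    member_slots[[oi]] <- slots
  }
  master_ins <- apply(ins_counts, 2L, max)
  if (length(others) == 0L) master_ins <- rep(0L, nc + 1L)

  build_row <- function(slots, is_center = FALSE) {
    out <- character(0)
    cres <- strsplit(cseq, "")[[1]]
    for (p in seq_len(nc + 1L)) {
      block <- if (is_center) character(0) else slots[[p]]$ins
      pad <- master_ins[p] - length(block)
      out <- c(out, block, rep("-", pad))
      if (p <= nc)
        out <- c(out, if (is_center) cres[p] else (slots[[p]]$res %||% "-"))
    }
    paste(out, collapse = "")
  }

  rows <- character(n)
  rows[center] <- build_row(NULL, is_center = TRUE)
  for (oi in seq_along(others)) {
    slots <- member_slots[[oi]]
    # replace NA residues (deleted center positions) by gaps
    for (p in seq_len(nc)) if (is.na(slots[[p]]$res)) slots[[p]]$res <- "-"
    rows[others[oi]] <- build_row(slots)
  }
  names(rows) <- names(members)
  rows
}

#' Concatenate single-copy ortholog alignments into a supermatrix
#'
#' Per-strain concatenation of SCO alignments in fixed orthogroup order,
#' plus a partition table recording each orthogroup's column interval
#' (0-based, half-open) for downstream phylogenetics tools.
#'
#' @param sco_alignments named list (orthogroup id -> named aligned rows with
#'   gene-id names).
#' @param orthogroups the [orthogroup()] objects (used to map genes to
#'   strains); only those whose ids appear in `sco_alignments` are used.
#' @param strains strain order of the output rows.
#' @return A list with `alignment` (named character vector, one row per
#'   strain) and `partitions` (data.frame og_id, start, end).
#' @export
export_supermatrix <- function(sco_alignments, orthogroups, strains) {
  if (length(sco_alignments) == 0L)
    stop_condition("no single-copy orthogroups", "wolbpan_parameter")
  og_by_id <- stats::setNames(orthogroups,
                              vapply(orthogroups, function(o) o$og_id, character(1)))
  rows <- stats::setNames(rep("", length(strains)), strains)
  parts <- data.frame(og_id = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  offset <- 0L
  for (og_id in names(sco_alignments)) {
    aln <- sco_alignments[[og_id]]
    og <- og_by_id[[og_id]]
    if (is.null(og))
      stop_condition(sprintf("unknown orthogroup id '%s'", og_id),
                     "wolbpan_parameter")
    w <- unique(nchar(aln))
    if (length(w) != 1L)
      stop_condition(sprintf("ragged alignment in %s", og_id), "wolbpan_format")
    for (s in strains) {
      gene <- og$members[[s]] %||% character(0)
      if (length(gene) != 1L || !gene %in% names(aln))
        stop_condition(sprintf("orthogroup %s lacks a single aligned row for strain '%s'",
                               og_id, s), "wolbpan_parameter")
      rows[[s]] <- paste0(rows[[s]], aln[[gene]])
    }
    parts <- rbind(parts, data.frame(og_id = og_id, start = offset,
                                     end = offset + w, stringsAsFactors = FALSE))
    offset <- offset + w
  }
  list(alignment = rows, partitions = parts)
}
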