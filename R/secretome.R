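# Secretome classification: signal-peptide and transmembrane-segment
# heuristics on Kyte-Doolittle hydropathy, the classification rule
# (signal peptide + transmembrane domain -> membrane-bound; signal peptide
# alone -> secreted; otherwise other), and orthogroup-level aggregation.
# External predictor tables, when provided, always override the heuristics.

#' Kyte-Doolittle hydropathy values
#'
#' @format Named numeric vector over the 20 amino acids.
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Per-residue hydropathy profile
#'
#' Centered moving average of Kyte-Doolittle residue hydropathy; windows are
#' truncated at the sequence ends. Unknown residues (X, gaps, stops)
#' contribute 0 with a warning.
#'
#' @param protein amino-acid string.
#' @param window window size in residues (default 19, the canonical
#'   transmembrane-scan width).
#' @return Numeric vector, one value per residue (1-based positions).
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window)
    stop_condition("sequence shorter than hydropathy window",
                   "wolbpan_parameter")
  vals <- unname(KD_HYDROPATHY[chars])
  if (anyNA(vals)) {
    warning(sprintf("%d unknown residue(s) treated as hydropathy 0",
                    sum(is.na(vals))))
    vals[is.na(vals)] <- 0
  }
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(vals))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Predict an N-terminal signal peptide (built-in heuristic)
#'
#' A protein is called signal-peptide-positive when (i) at least one
#' positively charged residue (K/R) occurs in positions 1-5 (the n-region)
#' and (ii) a stretch of at least `min_stretch` consecutive positions within
#' positions 3-25 has window-7 mean hydropathy above `threshold` (the
#' h-region). The cleavage position is the first small residue (A, G, S)
#' within positions 18-35 after the hydrophobic stretch. This heuristic
#' stands in for neural-network signal-peptide predictors; external
#' predictor tables take precedence when supplied to [classify_proteins()].
#'
#' @param protein amino-acid string (proteins shorter than 25 residues are
#'   called negative with note `"too-short"`).
#' @param threshold hydropathy cutoff (default 1.6).
#' @param min_stretch minimum hydrophobic stretch length (default 7).
#' @return A list with `flag`, `cleavage` (position or `NA`), `note`.
#' @export
predict_signal_peptide <- function(protein, threshold = 1.6, min_stretch = 7L) {
  n <- nchar(protein)
  if (n < 25L)
    return(list(flag = FALSE, cleavage = NA_integer_, note = "too-short"))
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  charged <- any(chars[1:5] %in% c("K", "R"))
  h7 <- hydropathy_profile(protein, window = 7L)
  region <- 3:min(25L, n)
  ok <- h7[region] > threshold
  r <- rle(ok)
  run_end <- NA_integer_
  if (any(r$values & r$lengths >= min_stretch)) {
    idx <- which(r$values & r$lengths >= min_stretch)[1]
    run_end <- region[1] - 1L + sum(r$lengths[seq_len(idx)])
  }
  flag <- charged && !is.na(run_end)
  cleavage <- NA_integer_
  if (flag) {
    lo <- max(18L, run_end + 1L); hi <- min(35L, n)
    if (lo <= hi) {
      small <- which(chars[lo:hi] %in% c("A", "G", "S"))
      if (length(small)) cleavage <- lo + small[1] - 1L
    }
  }
  list(flag = flag, cleavage = cleavage, note = NA_character_)
}

#' Predict transmembrane segments (built-in heuristic)
#'
#' Maximal runs of at least `min_run` consecutive residues whose window-19
#' mean hydropathy exceeds `threshold`; runs separated by fewer than
#' `merge_gap` residues are merged first. Runs overlapping `exclude_region`
#' (typically the predicted signal peptide, itself hydrophobic) are
#' discarded so that secreted proteins are not forced into the
#' membrane-bound class.
#'
#' @param protein amino-acid string.
#' @param window hydropathy window (default 19).
#' @param threshold hydropathy cutoff (default 1.6).
#' @param min_run minimum segment length in residues (default 15).
#' @param merge_gap merge runs separated by fewer than this many residues
#'   (default 5).
#' @param exclude_region optional `c(start, end)` (1-based, inclusive)
#'   interval whose overlapping runs are dropped.
#' @return data.frame with columns start, end (1-based inclusive residue
#'   intervals); zero rows when no segment is found.
#' @export
predict_tm_segments <- function(protein, window = 19L, threshold = 1.6,
                                min_run = 15L, merge_gap = 5L,
                                exclude_region = NULL) {
  empty <- data.frame(start = integer(0), end = integer(0))
  if (nchar(protein) < window) return(empty)
  h <- hydropathy_profile(protein, window = window)
  ok <- h > threshold
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge segments separated by < merge_gap residues
  if (nrow(seg) > 1L) {
    keep <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg$start[i] - keep$end[nrow(keep)] - 1L < merge_gap)
        keep$end[nrow(keep)] <- seg$end[i]
      else keep <- rbind(keep, seg[i, ])
    }
    seg <- keep
  }
  seg <- seg[seg$end - seg$start + 1L >= min_run, , drop = FALSE]
  if (!is.null(exclude_region) && nrow(seg)) {
    overlaps <- seg$start <= exclude_region[2] & seg$end >= exclude_region[1]
    seg <- seg[!overlaps, , drop = FALSE]
  }
  rownames(seg) <- NULL
  seg
}

#' Classify a protein from signal-peptide and transmembrane evidence
#'
#' The rule: signal peptide with at least one transmembrane segment ->
#' membrane-bound; signal peptide without a transmembrane segment ->
#' secreted; no signal peptide -> other. Total and deterministic;
#' membrane-bound and secreted are mutually exclusive by construction.
#'
#' @param sp_flag logical signal-peptide call.
#' @param tm_segments a segment data.frame from [predict_tm_segments()] or a
#'   non-negative segment count.
#' @return One of `"membrane-bound"`, `"secreted"`, `"other"`.
#' @export
classify_protein <- function(sp_flag, tm_segments) {
  n_tm <- if (is.data.frame(tm_segments)) nrow(tm_segments)
          else as.integer(tm_segments)
  stopifnot(n_tm >= 0L)
  if (!isTRUE(sp_flag)) "other"
  else if (n_tm >= 1L) "membrane-bound"
  else "secreted"
}

#' Orthogroup-level class by majority vote
#'
#' Ties are broken by the fixed precedence membrane-bound > secreted >
#' other.
#'
#' @param member_classes character vector of member protein classes.
#' @return A list with `class` and `tally` (named vote counts).
#' @export
classify_orthogroup <- function(member_classes) {
  stopifnot(length(member_classes) >= 1L)
  levels <- c("membrane-bound", "secreted", "other")
  tally <- table(factor(member_classes, levels = levels))
  winner <- levels[which.max(tally)]  # which.max honors the precedence order
  list(class = winner, tally = stats::setNames(as.integer(tally), levels))
}

#' Classify every protein in a sequence set
#'
#' Uses the built-in hydropathy heuristics unless an external predictor
#' table row is available for a gene, in which case the table always wins
#' and `evidence_source` records `"external-table"`.
#'
#' @param proteins a [seq_set()] of amino-acid sequences.
#' @param predictor_table optional data.frame from
#'   [read_predictor_tables()].
#' @param sp_threshold,tm_threshold hydropathy cutoffs (default 1.6).
#' @return data.frame with columns gene, has_signal_peptide, n_tm_segments,
#'   class, evidence_source.
#' @export
classify_proteins <- function(proteins, predictor_table = NULL,
                              sp_threshold = 1.6, tm_threshold = 1.6) {
  out <- data.frame(gene = proteins$id,
                    has_signal_peptide = FALSE, n_tm_segments = 0L,
                    class = "other", evidence_source = "builtin-heuristic",
                    stringsAsFactors = FALSE)
  ext <- if (is.null(predictor_table)) character(0) else predictor_table$gene
  for (i in seq_len(nrow(proteins))) {
    g <- proteins$id[i]
    if (g %in% ext) {
      row <- predictor_table[predictor_table$gene == g, ]
      sp <- row$has_signal_peptide[1]; n_tm <- row$n_tm_segments[1]
      out$evidence_source[i] <- "external-table"
    } else {
      pred <- predict_signal_peptide(proteins$seq[i], threshold = sp_threshold)
      sp <- pred$flag
      excl <- if (sp) c(1L, max(25L, pred$cleavage %||% 25L, na.rm = TRUE)) else NULL
      if (sp && is.na(excl[2])) excl[2] <- 25L
      seg <- predict_tm_segments(proteins$seq[i], threshold = tm_threshold,
                                 exclude_region = excl)
      n_tm <- nrow(seg)
    }
    out$has_signal_peptide[i] <- sp
    out$n_tm_segments[i] <- n_tm
    out$class[i] <- classify_protein(sp, n_tm)
  }
  out
}
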