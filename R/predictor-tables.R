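# External signal-peptide / transmembrane predictor table ingestion.
#
# Accepts both classic short-format outputs (SignalP-style rows with a
# prediction label and probability; TMHMM-style rows with PredHel=N) and
# generic TSVs with configurable column positions, since tool versions vary.

#' Read external signal-peptide and transmembrane predictor tables
#'
#' Gene ids are taken from the first column. The signal-peptide table needs
#' either a prediction label column (anything starting with `SP` counts as a
#' signal-peptide call, `OTHER`/`NO` as none) or a probability column
#' (thresholded at `sp_prob_threshold`). The transmembrane table needs either
#' a `PredHel=N` token or a numeric predicted-helix-count column. Genes
#' present in only one table default to (no signal peptide) / (0 segments)
#' with a warning.
#'
#' @param sp_path path to the signal-peptide TSV (or `NULL`).
#' @param tm_path path to the transmembrane TSV (or `NULL`).
#' @param sp_prob_threshold probability cutoff for a signal-peptide call
#'   (default 0.5).
#' @param sp_col,tm_col optional explicit column index holding the
#'   probability/label (sp) or helix count (tm); by default columns are
#'   scanned.
#' @return A data.frame with columns gene, has_signal_peptide, n_tm_segments.
#' @export
read_predictor_tables <- function(sp_path = NULL, tm_path = NULL,
                                  sp_prob_threshold = 0.5,
                                  sp_col = NULL, tm_col = NULL) {
  read_rows <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    strsplit(lines, "[\t ]+")
  }
  sp <- list(); tm <- list()
  if (!is.null(sp_path)) {
    for (f in read_rows(sp_path)) {
      if (f[1] %in% c("ID", "name", "gene")) next  # header row
      flag <- NA
      if (!is.null(sp_col)) {
        v <- f[sp_col]
        flag <- parse_sp_cell(v, sp_prob_threshold)
      } else {
        for (v in f[-1]) {
          flag <- parse_sp_cell(v, sp_prob_threshold)
          if (!is.na(flag)) break
        }
      }
      if (is.na(flag))
        stop_condition(sprintf(
          "signal-peptide row for '%s' has no parseable call or probability",
          f[1]), "wolbpan_format")
      sp[[f[1]]] <- flag
    }
  }
  if (!is.null(tm_path)) {
    for (f in read_rows(tm_path)) {
      if (f[1] %in% c("ID", "name", "gene")) next
      n <- NA_integer_
      hel <- grep("^PredHel=", f, value = TRUE)
      if (length(hel)) {
        n <- suppressWarnings(as.integer(sub("^PredHel=", "", hel[1])))
      } else {
        cells <- if (!is.null(tm_col)) f[tm_col] else f[-1]
        for (v in cells) {
          vn <- suppressWarnings(as.numeric(v))
          if (!is.na(vn) && vn == floor(vn)) { n <- as.integer(vn); break }
        }
      }
      if (is.na(n))
        stop_condition(sprintf(
          "transmembrane row for '%s' has no parseable helix count", f[1]),
          "wolbpan_format")
      tm[[f[1]]] <- n
    }
  }
  genes <- sort(unique(c(names(sp), names(tm))))
  only_sp <- setdiff(names(sp), names(tm))
  only_tm <- setdiff(names(tm), names(sp))
  if (!is.null(sp_path) && !is.null(tm_path) && (length(only_sp) || length(only_tm)))
    warning(sprintf(
      "%d gene(s) absent from one predictor table; defaulting to no-signal/0-segments",
      length(only_sp) + length(only_tm)))
  data.frame(
    gene = genes,
    has_signal_peptide = vapply(genes, function(g) isTRUE(sp[[g]]), logical(1)),
    n_tm_segments = vapply(genes, function(g) tm[[g]] %||% 0L, integer(1)),
    stringsAsFactors = FALSE)
}

parse_sp_cell <- function(v, threshold) {
  if (grepl("^SP", v)) return(TRUE)
  if (v %in% c("OTHER", "NO", "N")) return(FALSE)
  if (v %in% c("YES", "Y")) return(TRUE)
  vn <- suppressWarnings(as.numeric(v))
  if (!is.na(vn) && vn >= 0 && vn <= 1) return(vn > threshold)
  NA
}
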