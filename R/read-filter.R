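# Pre-polishing read hygiene: duplicate removal and the gap-compressed
# mismatch-ratio filter applied to short-read alignments before polishing.

#' Remove duplicate reads
#'
#' Keeps the first occurrence of each key (read id or full sequence) and
#' drops later occurrences, preserving input order otherwise.
#'
#' @param records a [seq_set()] of reads.
#' @param key `"id"` or `"sequence"`.
#' @return A list with elements `retained` (a [seq_set()]) and `removed`
#'   (count of dropped duplicates).
#' @export
dedup_reads <- function(records, key = c("id", "sequence")) {
  key <- match.arg(key)
  values <- if (key == "id") records$id else records$seq
  dup <- duplicated(values)
  retained <- records[!dup, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "alphabet") <- attr(records, "alphabet")
  class(retained) <- class(records)
  list(retained = retained, removed = sum(dup))
}

#' Gap-compressed divergence of an alignment record
#'
#' Computes `r = (n_mismatch + n_gap_opens) / (n_match + n_mismatch +
#' n_gap_opens)` where each insertion or deletion run counts as one gap-open
#' event regardless of its length (the "gap-compressed" convention of modern
#' long-read aligners). Mismatches come from explicit `X` runs when the CIGAR
#' uses `=`/`X`; when an `NM` edit distance is present, additional mismatches
#' implied by `NM` beyond the explicit runs are derived as
#' `NM - inserted_bases - deleted_bases - explicit_X` and carved out of
#' ambiguous `M` runs when such runs exist.
#'
#' @param record an `aln_record` from [read_alignment_records()].
#' @return The divergence as a fraction in `[0, 1]`.
#' @section Errors: an unmapped record or one whose mismatch count cannot be
#'   determined (plain `M` CIGAR, no `NM`, no `cs`) signals a condition of
#'   class `wolbpan_indeterminate`; an `NM` implying negative mismatches
#'   signals `wolbpan_inconsistent`.
#' @export
gap_compressed_divergence <- function(record) {
  if (!record$mapped || nrow(record$runs) == 0L)
    stop_condition(sprintf("read %s: unmapped or empty alignment",
                           record$read_id), "wolbpan_indeterminate")
  runs <- record$runs
  n_eq <- sum(runs$len[runs$op == "="])
  n_m <- sum(runs$len[runs$op == "M"])
  n_x <- sum(runs$len[runs$op == "X"])
  ins_b <- sum(runs$len[runs$op == "I"])
  del_b <- sum(runs$len[runs$op == "D"])
  gap_opens <- sum(runs$op %in% c("I", "D"))
  if (!is.na(record$edit_distance)) {
    extra <- record$edit_distance - ins_b - del_b - n_x
    if (extra < 0L)
      stop_condition(sprintf(
        "read %s: NM=%d smaller than gap bases + explicit mismatches",
        record$read_id, record$edit_distance), "wolbpan_inconsistent")
    mm <- n_x + extra
    match <- n_eq + max(0L, n_m - extra)
  } else if (n_m == 0L) {
    mm <- n_x
    match <- n_eq
  } else {
    stop_condition(sprintf(
      "read %s: divergence-indeterminate (M runs without NM or cs)",
      record$read_id), "wolbpan_indeterminate")
  }
  denom <- match + mm + gap_opens
  if (denom == 0L)
    stop_condition(sprintf("read %s: no alignment events", record$read_id),
                   "wolbpan_indeterminate")
  (mm + gap_opens) / denom
}

is_divergence_determinate <- function(record) {
  !inherits(tryCatch(gap_compressed_divergence(record),
                     wolbpan_indeterminate = function(e) e), "condition")
}

#' Filter alignment records by gap-compressed divergence
#'
#' Retains primary mapped records whose gap-compressed divergence does not
#' exceed `threshold` (a record at exactly the threshold is retained: the
#' removal rule is strictly greater-than). Unmapped and
#' divergence-indeterminate records are excluded from the retained set and
#' counted separately; secondary/supplementary alignments are ignored
#' entirely so each read is judged by its primary alignment only.
#'
#' @param records an `aln_records` list (or plain list of `aln_record`s).
#' @param threshold divergence cutoff in `[0, 1]`; default 0.04.
#' @return A list with `retained` (aln_records) and `report`, a
#'   `filter_report` whose counts reconcile to the number of primary input
#'   records.
#' @export
filter_by_divergence <- function(records, threshold = 0.04) {
  stopifnot(threshold >= 0, threshold <= 1)
  primary <- Filter(function(r) r$primary, records)
  n_secondary <- length(records) - length(primary)
  retained <- list(); n_unmapped <- 0L; n_indet <- 0L; n_failed <- 0L
  for (r in primary) {
    if (!r$mapped) { n_unmapped <- n_unmapped + 1L; next }
    d <- tryCatch(gap_compressed_divergence(r),
                  wolbpan_indeterminate = function(e) NA_real_)
    if (is.na(d)) { n_indet <- n_indet + 1L; next }
    if (d > threshold) n_failed <- n_failed + 1L
    else retained[[length(retained) + 1L]] <- r
  }
  if (n_indet > 0L)
    warning(sprintf("%d divergence-indeterminate record(s) dropped", n_indet))
  class(retained) <- "aln_records"
  report <- structure(list(
    n_input = length(primary),
    n_duplicates_removed = 0L,
    n_unmapped = n_unmapped,
    n_indeterminate = n_indet,
    n_failed_threshold = n_failed,
    n_retained = length(retained),
    n_secondary_ignored = n_secondary,
    threshold = threshold), class = "filter_report")
  list(retained = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d input, %d retained (threshold %.4g), %d over threshold,\n  %d unmapped, %d indeterminate, %d duplicate(s), %d secondary ignored\n",
    x$n_input, x$n_retained, x$threshold, x$n_failed_threshold, x$n_unmapped,
    x$n_indeterminate, x$n_duplicates_removed, x$n_secondary_ignored))
  invisible(x)
}

filter_report_df <- function(x) {
  data.frame(metric = c("n_input", "n_duplicates_removed", "n_unmapped",
                        "n_indeterminate", "n_failed_threshold", "n_retained",
                        "n_secondary_ignored", "threshold"),
             value = c(x$n_input, x$n_duplicates_removed, x$n_unmapped,
                       x$n_indeterminate, x$n_failed_threshold, x$n_retained,
                       x$n_secondary_ignored, x$threshold),
             stringsAsFactors = FALSE)
}
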