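# Simulated read-vs-reference alignment records with known gap-compressed
# divergence, emitted in both SAM and PAF text dialects.

#' Simulate alignment records with known gap-compressed divergences
#'
#' Each record is built from a fixed total number of gap-compressed events
#' (matches + mismatches + gap opens). The requested divergence `d` is
#' realized as `n_diff = round(d * n_events)` difference events (a random
#' split of mismatches and indel runs of 1-3 bp, each separated by at least
#' one match run), so the realized divergence `n_diff / n_events` is within
#' `0.5 / n_events` of the request and is recorded exactly in the truth
#' table. Records carry `=`/`X` CIGARs, `NM` tags and `cs` difference
#' strings, in both SAM and PAF dialects.
#'
#' @param n_reads number of reads.
#' @param divergence_values requested divergences in `[0, 1)` (recycled
#'   across reads).
#' @param seed integer seed.
#' @param n_events_range range of total gap-compressed events per read
#'   (default 120-240).
#' @return A list with `records` (parsed `aln_records`), `sam` and `paf`
#'   (character vectors of file lines, including the SAM header), and
#'   `truth` (data.frame read_id, requested, realized).
#' @export
simulate_alignment_records <- function(n_reads, divergence_values, seed = 1L,
                                       n_events_range = c(120L, 240L)) {
  if (any(divergence_values < 0 | divergence_values >= 1))
    stop_condition("divergences must be in [0, 1)", "wolbpan_parameter")
  req <- rep_len(divergence_values, n_reads)
  sam <- character(n_reads); paf <- character(n_reads)
  truth <- data.frame(read_id = sprintf("read%05d", seq_len(n_reads)),
                      requested = req, realized = NA_real_,
                      stringsAsFactors = FALSE)
  ref_len <- 10 * n_events_range[2]
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:ref\tLN:%d", ref_len))
  for (i in seq_len(n_reads)) {
    r <- with_seed(hash_id(seed, "read", i), {
      n_events <- n_events_range[1] +
        sample.int(n_events_range[2] - n_events_range[1] + 1L, 1L) - 1L
      n_diff <- round(req[i] * n_events)
      n_match <- n_events - n_diff
      # every difference event needs a preceding match run of >= 1
      if (n_match < n_diff)
        stop_condition("divergence too high to realize: each difference event needs a separating match (requested > 0.5)",
                       "wolbpan_parameter")
      n_mm <- if (n_diff) stats::rbinom(1L, n_diff, 0.6) else 0L
      types <- if (n_diff) sample(c(rep("X", n_mm),
                                    sample(c("I", "D"), n_diff - n_mm,
                                           replace = TRUE)))
               else character(0)
      gap_lens <- ifelse(types == "X", 1L, sample(1:3, length(types),
                                                  replace = TRUE))
      # split matches into n_diff + 1 runs, first n_diff of length >= 1
      extra <- n_match - n_diff
      add <- if (n_diff + 1L > 0L) stats::rmultinom(1L, extra,
                                                    rep(1, n_diff + 1L))[, 1]
             else integer(0)
      match_runs <- c(rep(1L, n_diff), 0L) + add
      ops <- character(0); lens <- integer(0)
      for (j in seq_len(n_diff)) {
        ops <- c(ops, "=", types[j]); lens <- c(lens, match_runs[j], gap_lens[j])
      }
      if (match_runs[n_diff + 1L] > 0L) {
        ops <- c(ops, "="); lens <- c(lens, match_runs[n_diff + 1L])
      }
      list(ops = ops, lens = lens, n_events = n_events, n_diff = n_diff)
    })
    ops <- r$ops; lens <- r$lens
    truth$realized[i] <- r$n_diff / r$n_events
    cigar <- paste0(lens, ops, collapse = "")
    q_len <- sum(lens[ops %in% c("=", "X", "I")])
    t_len <- sum(lens[ops %in% c("=", "X", "D")])
    nm <- sum(lens[ops %in% c("X", "I", "D")])
    cs <- paste(vapply(seq_along(ops), function(j) switch(ops[j],
      "=" = sprintf(":%d", lens[j]),
      "X" = paste(rep("*ca", lens[j]), collapse = ""),
      "I" = paste0("+", strrep("a", lens[j])),
      "D" = paste0("-", strrep("c", lens[j]))), character(1)), collapse = "")
    seq <- strrep("A", q_len)
    sam[i] <- sprintf("%s\t0\tref\t1\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tcs:Z:%s",
                      truth$read_id[i], cigar, seq, nm, cs)
    paf[i] <- sprintf(
      "%s\t%d\t0\t%d\t+\tref\t%d\t0\t%d\t%d\t%d\t60\ttp:A:P\tNM:i:%d\tcg:Z:%s\tcs:Z:%s",
      truth$read_id[i], q_len, q_len, ref_len, t_len,
      sum(lens[ops == "="]), sum(lens[ops %in% c("=", "X", "I", "D")]), nm,
      cigar, cs)
  }
  records <- lapply(sam, parse_sam_line)
  class(records) <- "aln_records"
  list(records = records, sam = c(header, sam), paf = paf, truth = truth)
}

#' Write SAM or PAF lines to disk
#'
#' @param lines character vector of file lines (e.g. the `sam`/`paf`
#'   elements of [simulate_alignment_records()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
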