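# Genome-level statistics: length, GC content, windowed GC/GC-skew profiles
# over circular genomes, with deviation-from-average tracks.

#' Construct a genome record
#'
#' @param id sequence/strain identifier.
#' @param seq nucleotide sequence (IUPAC codes accepted; non-empty).
#' @param circular logical; circular chromosomes wrap windows past the end.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, seq, circular = TRUE) {
  set <- seq_set(id, seq, alphabet = "nucleotide")
  structure(list(id = id, seq = set$seq[1], circular = isTRUE(circular)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record %s: %d bp%s\n", x$id, nchar(x$seq),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

as_genome_seq <- function(x) {
  if (inherits(x, "genome_record")) x$seq else toupper(as.character(x))
}

base_indicators <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  list(chars = chars,
       A = chars == "A", C = chars == "C", G = chars == "G", T = chars == "T")
}

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; IUPAC ambiguity codes are excluded from both
#' numerator and denominator rather than counted fractionally.
#'
#' @param x a `genome_record` or nucleotide string.
#' @return The GC fraction.
#' @section Errors: a sequence with zero unambiguous bases signals a
#'   condition of class `wolbpan_undefined`.
#' @export
#' @examples
#' gc_content("ACGT")   # 0.5
#' gc_content("ACGN")   # 2/3
gc_content <- function(x) {
  b <- base_indicators(as_genome_seq(x))
  n <- sum(b$A) + sum(b$C) + sum(b$G) + sum(b$T)
  if (n == 0L)
    stop_condition("GC content undefined: no unambiguous bases",
                   "wolbpan_undefined")
  (sum(b$G) + sum(b$C)) / n
}

#' GC skew of a nucleotide sequence
#'
#' `(G - C) / (G + C)`, the replication-strand asymmetry statistic whose sign
#' structure flips at the origin and terminus of replication in most
#' bacterial chromosomes. Returns `NA` when `G + C = 0`.
#'
#' @param x a `genome_record` or nucleotide string.
#' @return The skew in `[-1, 1]`, or `NA`.
#' @export
gc_skew <- function(x) {
  b <- base_indicators(as_genome_seq(x))
  g <- sum(b$G); c <- sum(b$C)
  if (g + c == 0L) return(NA_real_)
  (g - c) / (g + c)
}

#' Windowed GC-content or GC-skew profile
#'
#' Slides a window of `window` bp along the genome at `step` bp. For
#' circular genomes windows wrap past the end (internal representation:
#' `end > genome length`; [write_track()] splits such windows into two lines).
#' With `deviation = TRUE` the genome-wide value of the metric is subtracted
#' from every window (the "deviation from the average for the entire
#' sequence" convention of circular genome viewers) and stored in the
#' `genome_mean` attribute. A window with no informative bases (`G + C = 0`
#' for skew; no unambiguous bases for GC) records `NA`, not zero.
#'
#' @param genome a `genome_record` (or nucleotide string).
#' @param metric `"gc_content"` or `"gc_skew"`.
#' @param window window size in bp (default 10000).
#' @param step step size in bp (default 1000; must not exceed `window`).
#' @param circular override the record's circularity flag.
#' @param deviation subtract the genome-wide metric value from each window.
#' @return A data.frame of class `window_track` with columns seqid, start,
#'   end, value, n (the count of informative bases per window — the weight
#'   under which windowed means reconcile with the genome-wide value), plus
#'   attributes `window`, `step`, `metric`, `genome_mean`, `genome_length`,
#'   `circular`.
#' @export
windowed_profile <- function(genome, metric = c("gc_content", "gc_skew"),
                             window = 10000L, step = 1000L, circular = NULL,
                             deviation = FALSE) {
  metric <- match.arg(metric)
  seq <- as_genome_seq(genome)
  id <- if (inherits(genome, "genome_record")) genome$id else "seq"
  L <- nchar(seq)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || window > L)
    stop_condition("window must be in [1, genome length]", "wolbpan_parameter")
  if (step < 1L || step > window)
    stop_condition("step must be in [1, window]", "wolbpan_parameter")
  circular <- circular %||%
    (if (inherits(genome, "genome_record")) genome$circular else FALSE)

  b <- base_indicators(seq)
  csum <- function(v) c(0, cumsum(v))
  cg <- csum(b$G); cc <- csum(b$C); cacgt <- csum(b$A | b$C | b$G | b$T)
  count_range <- function(cs, s, e) {  # 0-based half-open, e may exceed L
    if (e <= L) cs[e + 1L] - cs[s + 1L]
    else (cs[L + 1L] - cs[s + 1L]) + cs[e - L + 1L]
  }

  starts <- seq.int(0L, L - 1L, by = step)
  if (!circular) starts <- starts[starts + window <= L]
  ends <- starts + window
  g <- vapply(seq_along(starts), function(i) count_range(cg, starts[i], ends[i]), numeric(1))
  c_ <- vapply(seq_along(starts), function(i) count_range(cc, starts[i], ends[i]), numeric(1))
  nb <- vapply(seq_along(starts), function(i) count_range(cacgt, starts[i], ends[i]), numeric(1))

  if (metric == "gc_content") {
    value <- ifelse(nb > 0, (g + c_) / nb, NA_real_)
    weight <- nb
    genome_mean <- gc_content(seq)
  } else {
    value <- ifelse(g + c_ > 0, (g - c_) / (g + c_), NA_real_)
    weight <- g + c_
    genome_mean <- gc_skew(seq)
  }
  if (deviation) value <- value - genome_mean

  out <- data.frame(seqid = id, start = starts, end = ends, value = value,
                    n = weight, stringsAsFactors = FALSE)
  attr(out, "window") <- window; attr(out, "step") <- step
  attr(out, "metric") <- metric; attr(out, "deviation") <- deviation
  attr(out, "genome_mean") <- genome_mean
  attr(out, "genome_length") <- L; attr(out, "circular") <- circular
  class(out) <- c("window_track", class(out))
  out
}

#' Genome summary statistics
#'
#' Length, GC content (percent, two decimals, rounded half-up — the precision
#' used in genome-announcement tables), per-base counts, ambiguity count and
#' circularity.
#'
#' @param genome a `genome_record`.
#' @return A list of class `genome_summary`.
#' @export
genome_summary <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  b <- base_indicators(genome$seq)
  counts <- c(A = sum(b$A), C = sum(b$C), G = sum(b$G), T = sum(b$T))
  n_amb <- nchar(genome$seq) - sum(counts)
  structure(list(
    id = genome$id,
    length_bp = nchar(genome$seq),
    gc_percent = round_half_up(100 * gc_content(genome$seq), 2),
    base_counts = counts,
    n_ambiguous = n_amb,
    circular = genome$circular), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("%s: %s bp%s, GC %.2f%%, ambiguous bases %d\n", x$id,
              format(x$length_bp, big.mark = ","),
              if (x$circular) " (circular)" else "", x$gc_percent,
              x$n_ambiguous))
  invisible(x)
}
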