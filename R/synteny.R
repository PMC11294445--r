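# Pairwise synteny between circular genomes: exact k-mer anchors, greedy
# collinear-block chaining, and breakpoint reporting. A desk-scale,
# deterministic stand-in for whole-genome aligners and dotplot tools:
# sufficient to localize planted rearrangements; externally computed PAF can
# be ingested via read_alignment_records() for fidelity.

kmer_positions <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Exact shared k-mer anchors between two genomes
#'
#' Finds all exact shared k-mers between genome `a` and both strands of
#' genome `b`. k-mers occurring more than `max_occurrence` times in either
#' genome (counting both strands of `b`) are discarded — IS-element-rich
#' endosymbiont genomes would otherwise produce a quadratic blowup of
#' repeat anchors. Runs of overlapping consecutive anchors on the same
#' (anti-)diagonal are merged into maximal exact matches. Reverse-strand
#' anchors report forward-strand coordinates of the reverse-complemented
#' interval in `b`.
#'
#' @param genome_a,genome_b `genome_record`s or nucleotide strings.
#' @param k k-mer size in bp (default 15).
#' @param max_occurrence repeat-copy cap (default 4).
#' @return data.frame of class `anchor_set`: pos_a, pos_b (0-based starts),
#'   length (bp), strand (`"+"`/`"-"`), sorted by (pos_a, pos_b).
#' @export
kmer_anchors <- function(genome_a, genome_b, k = 15L, max_occurrence = 4L) {
  a <- as_genome_seq(genome_a); b <- as_genome_seq(genome_b)
  La <- nchar(a); Lb <- nchar(b)
  if (La < k || Lb < k)
    stop_condition("genomes must be at least k bp long", "wolbpan_parameter")
  ka <- kmer_positions(a, k)
  kb_f <- kmer_positions(b, k)
  kb_r <- kmer_positions(revcomp(b), k)
  ta <- table(ka)
  tb <- table(c(kb_f, kb_r))
  eligible <- intersect(names(ta)[ta <= max_occurrence],
                        names(tb)[tb <= max_occurrence])
  shared <- intersect(intersect(names(ta), names(tb)), eligible)
  if (!length(shared)) return(empty_anchors())

  pos_of <- function(kmers, keys) {
    hit <- kmers %in% keys
    split(which(hit) - 1L, factor(kmers[hit], levels = keys))
  }
  pa <- pos_of(ka, shared)
  pf <- pos_of(kb_f, shared)
  pr <- pos_of(kb_r, shared)

  pair_up <- function(pb_list, strand) {
    na <- lengths(pa); nb <- lengths(pb_list)
    keep <- na > 0L & nb > 0L
    if (!any(keep)) return(NULL)
    ia <- unlist(mapply(function(x, m) rep(x, each = m), pa[keep], nb[keep],
                        SIMPLIFY = FALSE), use.names = FALSE)
    ib <- unlist(mapply(function(x, m) rep(x, times = m), pb_list[keep], na[keep],
                        SIMPLIFY = FALSE), use.names = FALSE)
    data.frame(pos_a = ia, pos_b = ib, strand = strand,
               stringsAsFactors = FALSE)
  }
  fwd <- pair_up(pf, "+")
  rev_ <- pair_up(pr, "-")
  if (!is.null(rev_)) rev_$pos_b <- Lb - rev_$pos_b - k  # forward-strand start

  merge_runs <- function(df, strand) {
    if (is.null(df) || !nrow(df)) return(NULL)
    diag <- if (strand == "+") df$pos_b - df$pos_a else df$pos_a + df$pos_b
    ord <- order(diag, df$pos_a)
    df <- df[ord, ]; diag <- diag[ord]
    new_run <- c(TRUE, diff(df$pos_a) != 1L | diff(diag) != 0L)
    run <- cumsum(new_run)
    starts_a <- tapply(df$pos_a, run, min)
    lens <- tapply(df$pos_a, run, length) + k - 1L
    starts_b <- tapply(df$pos_b, run, min)
    data.frame(pos_a = as.integer(starts_a), pos_b = as.integer(starts_b),
               length = as.integer(lens), strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(merge_runs(fwd, "+"), merge_runs(rev_, "-"))
  if (is.null(out) || !nrow(out)) return(empty_anchors())
  out <- out[order(out$pos_a, out$pos_b), ]
  rownames(out) <- NULL
  attr(out, "genome_lengths") <- c(a = La, b = Lb)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("anchor_set", class(out))
  out
}

empty_anchors <- function() {
  out <- data.frame(pos_a = integer(0), pos_b = integer(0),
                    length = integer(0), strand = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("anchor_set", class(out))
  out
}

#' Chain anchors into collinear synteny blocks
#'
#' Greedy chaining of strand-consistent anchors that are monotone in both
#' genomes (decreasing in `b` on the `-` strand) with inter-anchor gaps of
#' at most `max_gap` bp in both genomes. Blocks with fewer than
#' `min_anchors` anchors are dropped. On circular genomes the first and last
#' blocks are merged across the origin when they are mutually extendable
#' (same strand, adjacent in both genomes modulo length); the merged block
#' is represented with `end_a > length(a)`.
#'
#' @param anchors an `anchor_set` from [kmer_anchors()].
#' @param max_gap maximum inter-anchor gap in bp (default 5000).
#' @param min_anchors minimum anchors per block (default 3).
#' @param max_diag_drift maximum allowed difference between the genome-a and
#'   genome-b inter-anchor gaps (default 1000 bp): consecutive anchors of a
#'   collinear block sit on nearby (anti-)diagonals, drifting only by the
#'   size of local indels; chance anchors far off the diagonal are rejected
#'   rather than absorbed into a real block.
#' @param min_length minimum block span in genome a (default 200 bp):
#'   blocks built purely from chance k-mer matches never reach this span,
#'   while genuine collinear blocks far exceed it.
#' @param genome_lengths named/ordered lengths `c(a, b)`; defaults to the
#'   attribute carried by `anchors` (needed only for circular merging).
#' @param circular merge blocks across the origin of replication.
#' @return data.frame of class `synteny_blocks`: start_a, end_a, start_b,
#'   end_b (0-based half-open), strand, n_anchors, ordered by start_a.
#' @export
chain_anchors <- function(anchors, max_gap = 5000L, min_anchors = 3L,
                          max_diag_drift = 1000L, min_length = 200L,
                          genome_lengths = NULL, circular = FALSE) {
  genome_lengths <- genome_lengths %||% attr(anchors, "genome_lengths")
  k <- attr(anchors, "k") %||% (if (nrow(anchors)) min(anchors$length) else 1L)
  blocks <- NULL
  for (str in c("+", "-")) {
    an <- anchors[anchors$strand == str, , drop = FALSE]
    if (!nrow(an)) next
    an <- an[order(an$pos_a, an$pos_b), , drop = FALSE]
    seeds <- pmax(1L, an$length - k + 1L)  # constituent exact k-mer seeds
    open <- list()
    # on flush, strip weak terminal anchors sitting far from the chain body:
    # a chance anchor near the block diagonal must not stretch the block
    # boundary past the true breakpoint
    flush <- function(cur) {
      it <- cur$items
      total <- sum(vapply(it, function(x) x$seeds, numeric(1)))
      repeat {
        n_it <- length(it)
        if (n_it < 2L) break
        gap_head <- it[[2L]]$a0 - (it[[1L]]$a0 + it[[1L]]$len)
        if (it[[1L]]$seeds <= 0.05 * total && gap_head > 5L * k) {
          it <- it[-1L]; next
        }
        gap_tail <- it[[n_it]]$a0 - (it[[n_it - 1L]]$a0 + it[[n_it - 1L]]$len)
        if (it[[n_it]]$seeds <= 0.05 * total && gap_tail > 5L * k) {
          it <- it[-n_it]; next
        }
        break
      }
      a_start <- min(vapply(it, function(x) x$a0, numeric(1)))
      a_end <- max(vapply(it, function(x) x$a0 + x$len, numeric(1)))
      b_start <- min(vapply(it, function(x) x$b0, numeric(1)))
      b_end <- max(vapply(it, function(x) x$b0 + x$len, numeric(1)))
      data.frame(start_a = a_start, end_a = a_end, start_b = b_start,
                 end_b = b_end, strand = str,
                 n_anchors = sum(vapply(it, function(x) x$seeds, numeric(1))),
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(an))) {
      a0 <- an$pos_a[i]; b0 <- an$pos_b[i]; len <- an$length[i]
      # retire chains this anchor (and all later ones) can no longer extend
      if (length(open)) {
        dead <- vapply(open, function(cur) a0 - cur$end_a > max_gap, logical(1))
        for (cur in open[dead]) blocks <- rbind(blocks, flush(cur))
        open <- open[!dead]
      }
      # extend the strongest open chain that accepts this anchor; chance
      # anchors open weak chains of their own instead of breaking real ones
      accept <- vapply(open, function(cur) {
        gap_a <- a0 - cur$end_a
        if (gap_a < -(len - 1L)) return(FALSE)
        if (str == "+") {
          gap_b <- b0 - cur$end_b
          gap_b <= max_gap && gap_b >= -(len - 1L) && b0 >= cur$last_b &&
            abs(gap_a - gap_b) <= max_diag_drift
        } else {
          gap_b <- cur$start_b - (b0 + len)
          gap_b <= max_gap && gap_b >= -(len - 1L) && b0 <= cur$last_b &&
            abs(gap_a - gap_b) <= max_diag_drift
        }
      }, logical(1))
      item <- list(a0 = a0, b0 = b0, len = len, seeds = seeds[i])
      if (any(accept)) {
        pick <- which(accept)[which.max(vapply(open[accept],
                                               function(cur) cur$n, numeric(1)))]
        cur <- open[[pick]]
        cur$end_a <- max(cur$end_a, a0 + len)
        cur$start_b <- min(cur$start_b, b0)
        cur$end_b <- max(cur$end_b, b0 + len)
        cur$last_b <- b0
        cur$n <- cur$n + seeds[i]
        cur$items[[length(cur$items) + 1L]] <- item
        open[[pick]] <- cur
      } else {
        open[[length(open) + 1L]] <- list(
          start_a = a0, end_a = a0 + len, start_b = b0, end_b = b0 + len,
          last_b = b0, n = seeds[i], items = list(item))
      }
    }
    for (cur in open) blocks <- rbind(blocks, flush(cur))
  }
  if (is.null(blocks)) blocks <- data.frame(
    start_a = integer(0), end_a = integer(0), start_b = integer(0),
    end_b = integer(0), strand = character(0), n_anchors = integer(0),
    stringsAsFactors = FALSE)
  blocks <- blocks[blocks$n_anchors >= min_anchors &
                     blocks$end_a - blocks$start_a >= min_length, ,
                   drop = FALSE]
  blocks <- blocks[order(blocks$start_a, blocks$start_b), , drop = FALSE]
  rownames(blocks) <- NULL
  # resolve genome-a overlaps, strongest block first: overlaps up to k bp
  # (boundary-anchor wobble at rearrangement breakpoints) are trimmed from
  # the weaker block; larger clashes (chance-anchor chains nesting inside a
  # genuine block) drop the weaker block
  if (nrow(blocks) > 1L) {
    ord <- order(-blocks$n_anchors, blocks$start_a)
    kept <- integer(0)
    for (i in ord) {
      drop <- FALSE
      for (j in kept) {
        ov <- min(blocks$end_a[i], blocks$end_a[j]) -
          max(blocks$start_a[i], blocks$start_a[j])
        if (ov <= 0) next
        if (ov > k) { drop <- TRUE; break }
        if (blocks$start_a[i] >= blocks$start_a[j])
          blocks$start_a[i] <- blocks$end_a[j]
        else blocks$end_a[i] <- blocks$start_a[j]
        if (blocks$end_a[i] - blocks$start_a[i] < k) { drop <- TRUE; break }
      }
      if (!drop) kept <- c(kept, i)
    }
    blocks <- blocks[sort(kept), , drop = FALSE]
    rownames(blocks) <- NULL
  }

  if (circular && nrow(blocks) >= 2L && !is.null(genome_lengths)) {
    La <- genome_lengths[[1]]; Lb <- genome_lengths[[2]]
    first <- blocks[1, ]; last <- blocks[nrow(blocks), ]
    if (first$strand == last$strand) {
      gap_a <- (first$start_a + La) - last$end_a
      gap_b <- if (first$strand == "+") (first$start_b + Lb) - last$end_b
               else (last$start_b + Lb) - first$end_b
      if (gap_a >= 0 && gap_a <= max_gap && gap_b >= 0 && gap_b <= max_gap) {
        merged <- last
        merged$end_a <- first$end_a + La
        if (first$strand == "+") merged$end_b <- first$end_b + Lb
        else merged$start_b <- first$start_b  # wraps downward in b
        merged$n_anchors <- last$n_anchors + first$n_anchors
        blocks <- rbind(blocks[-c(1, nrow(blocks)), , drop = FALSE], merged)
        blocks <- blocks[order(blocks$start_a), , drop = FALSE]
        rownames(blocks) <- NULL
      }
    }
  }
  attr(blocks, "genome_lengths") <- genome_lengths
  class(blocks) <- c("synteny_blocks", class(blocks))
  blocks
}

#' Report breakpoints between adjacent synteny blocks
#'
#' Boundaries between consecutive blocks in genome-a order, including the
#' circular adjacency between the last and first block. Each breakpoint
#' carries the flanking block indices and whether the strand changes across
#' it (a strand change marks an inversion boundary). A single block yields
#' no breakpoints.
#'
#' @param blocks a `synteny_blocks` data.frame (non-overlapping in genome
#'   a).
#' @param genome_lengths lengths `c(a, b)`; defaults to the attribute on
#'   `blocks`.
#' @return data.frame: position (genome-a coordinate), left_block,
#'   right_block, strand_change, gap_a; ordered by position.
#' @export
breakpoint_report <- function(blocks, genome_lengths = NULL) {
  genome_lengths <- genome_lengths %||% attr(blocks, "genome_lengths")
  empty <- data.frame(position = integer(0), left_block = integer(0),
                      right_block = integer(0), strand_change = logical(0),
                      gap_a = integer(0), stringsAsFactors = FALSE)
  if (nrow(blocks) <= 1L) return(empty)
  La <- genome_lengths[[1]]
  blocks <- blocks[order(blocks$start_a), , drop = FALSE]
  n <- nrow(blocks)
  # overlap check in genome a (wrap-spanning last block checked against first)
  for (i in seq_len(n - 1L))
    if (blocks$end_a[i] > blocks$start_a[i + 1L])
      stop_condition("overlapping blocks in genome a", "wolbpan_parameter")
  if (blocks$end_a[n] > La && (blocks$end_a[n] - La) > blocks$start_a[1])
    stop_condition("overlapping blocks in genome a (circular wrap)",
                   "wolbpan_parameter")
  rows <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    pos <- blocks$end_a[i] %% La
    gap <- if (i == n) (blocks$start_a[j] + La) - blocks$end_a[i]
           else blocks$start_a[j] - blocks$end_a[i]
    data.frame(position = as.integer(pos), left_block = i, right_block = j,
               strand_change = blocks$strand[i] != blocks$strand[j],
               gap_a = as.integer(gap), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# PAF-like serialization of anchors (dotplot substrate).
write_anchors_paf <- function(anchors, path, name_a = "a", name_b = "b",
                              genome_lengths = NULL) {
  genome_lengths <- genome_lengths %||% attr(anchors, "genome_lengths") %||% c(0L, 0L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(anchors))) {
    writeLines(sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60",
                       name_a, genome_lengths[[1]], anchors$pos_a[i],
                       anchors$pos_a[i] + anchors$length[i], anchors$strand[i],
                       name_b, genome_lengths[[2]], anchors$pos_b[i],
                       anchors$pos_b[i] + anchors$length[i],
                       anchors$length[i], anchors$length[i]), con)
  }
  invisible(path)
}
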