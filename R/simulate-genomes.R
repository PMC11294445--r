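# Circular genome assembly for simulated strains: per-family gene sequences
# separated by intergenic spacers with an imposed GC-skew origin, plus
# planted rearrangements with recorded breakpoints.

# Random sub-streams are keyed by family ids and by the flanking families of
# each intergenic spacer (never by strain), so two strains with identical
# gene content assemble byte-identical genomes apart from planted
# rearrangements — the property the synteny closed loop relies on.

family_gene_seq <- function(family, seed, gene_length, gc_mean) {
  with_seed(hash_id(seed, "gene_seq", family), {
    p <- c(A = (1 - gc_mean) / 2, C = gc_mean / 2, G = gc_mean / 2,
           T = (1 - gc_mean) / 2)
    paste(sample(names(p), gene_length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Assemble circular genomes from gene content
#'
#' Each strain's genome is the concatenation, in family-id order, of shared
#' per-family gene sequences separated by intergenic spacers. Intergenic
#' bases impose a GC skew: taking positions clockwise from the origin, the
#' per-strand G probability is `p_mean * (1 + skew_amplitude)` on the half
#' of the chromosome approaching the origin and `p_mean * (1 -
#' skew_amplitude)` on the half leaving it, so the windowed skew flips sign
#' at the origin (and at the terminus opposite it), as in real bacterial
#' chromosomes. Planted inversions are applied per strain and their
#' breakpoint coordinates recorded.
#'
#' @param gene_sets named list (strain -> character vector of family ids).
#' @param intergenic_mean mean intergenic spacer length in bp (default 300).
#' @param skew_amplitude GC-skew amplitude in `[0, 1]` (default 0.6).
#' @param origin_position origin of replication as a fraction of genome
#'   length (default 0.25).
#' @param rearrangements optional list of
#'   `list(strain =, type = "inversion", start =, length =)` with `start`
#'   in bp on the unrearranged genome; overlapping rearrangements on one
#'   strain are a parameter error.
#' @param seed integer seed.
#' @param gene_length gene length in bp (default 600).
#' @param gc_mean genome-wide GC fraction (default 0.35, typical of
#'   AT-rich endosymbiont genomes).
#' @return A list with `genomes` (strain -> [genome_record()]), `truth`
#'   (list: origin_bp per strain, genome lengths, breakpoints data.frame
#'   strain/type/start/end, gene layout data.frame).
#' @export
assemble_genomes <- function(gene_sets, intergenic_mean = 300L,
                             skew_amplitude = 0.6, origin_position = 0.25,
                             rearrangements = NULL, seed = 1L,
                             gene_length = 600L, gc_mean = 0.35) {
  if (skew_amplitude < 0 || skew_amplitude > 1)
    stop_condition("skew_amplitude must be in [0, 1]", "wolbpan_parameter")
  if (origin_position < 0 || origin_position >= 1)
    stop_condition("origin_position must be in [0, 1)", "wolbpan_parameter")
  strains <- names(gene_sets)
  genomes <- list(); origin_bp <- integer(0); lengths <- integer(0)
  layout_rows <- list()
  for (strain in strains) {
    fams <- sort(gene_sets[[strain]])
    genes <- vapply(fams, family_gene_seq, character(1), seed = seed,
                    gene_length = gene_length, gc_mean = gc_mean)
    # spacer lengths keyed by flanking families (strain-independent)
    flank <- c("ORI", fams)
    ig_len <- vapply(seq_along(flank), function(i) {
      nxt <- if (i < length(flank)) flank[i + 1L] else "ORI"
      with_seed(hash_id(seed, "ig_len", flank[i], nxt),
                50L + stats::rpois(1L, intergenic_mean - 50L))
    }, integer(1))
    L <- sum(nchar(genes)) + sum(ig_len)
    ori <- as.integer(floor(origin_position * L))
    # layout pass: record positions, then generate skewed intergenic bases
    parts <- character(0); pos <- 0L
    for (i in seq_along(flank)) {
      nxt <- if (i < length(flank)) flank[i + 1L] else "ORI"
      ig <- intergenic_seq(ig_len[i], pos, L, ori, skew_amplitude, gc_mean,
                           seed, flank[i], nxt)
      parts <- c(parts, ig); pos <- pos + ig_len[i]
      if (i <= length(fams)) {
        layout_rows[[length(layout_rows) + 1L]] <- data.frame(
          strain = strain, family = fams[i], start = pos,
          end = pos + nchar(genes[i]), stringsAsFactors = FALSE)
        parts <- c(parts, genes[i]); pos <- pos + nchar(genes[i])
      }
    }
    genomes[[strain]] <- paste(parts, collapse = "")
    origin_bp[strain] <- ori
    lengths[strain] <- L
  }

  bp_rows <- list()
  if (!is.null(rearrangements)) {
    for (strain in strains) {
      rs <- Filter(function(r) r$strain == strain, rearrangements)
      if (!length(rs)) next
      iv <- do.call(rbind, lapply(rs, function(r)
        c(start = r$start, end = r$start + r$length)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop_condition(sprintf("overlapping rearrangements on strain %s",
                               strain), "wolbpan_parameter")
      g <- genomes[[strain]]
      for (r in rs) {
        s <- r$start; e <- r$start + r$length
        if (s < 0 || e > nchar(g))
          stop_condition("rearrangement outside genome", "wolbpan_parameter")
        type <- r$type %||% "inversion"
        if (type != "inversion")
          stop_condition(sprintf("unsupported rearrangement type '%s'", type),
                         "wolbpan_parameter")
        g <- paste0(substr(g, 1L, s), revcomp(substr(g, s + 1L, e)),
                    substr(g, e + 1L, nchar(g)))
        bp_rows[[length(bp_rows) + 1L]] <- data.frame(
          strain = strain, type = type, start = s, end = e,
          stringsAsFactors = FALSE)
      }
      genomes[[strain]] <- g
    }
  }
  breakpoints <- if (length(bp_rows)) do.call(rbind, bp_rows)
                 else data.frame(strain = character(0), type = character(0),
                                 start = integer(0), end = integer(0),
                                 stringsAsFactors = FALSE)
  records <- lapply(strains, function(s)
    genome_record(s, genomes[[s]], circular = TRUE))
  names(records) <- strains
  list(genomes = records,
       truth = list(origin_bp = origin_bp, lengths = lengths,
                    breakpoints = breakpoints,
                    layout = do.call(rbind, layout_rows)))
}

# skewed intergenic spacer; positions are 0-based genome coordinates
intergenic_seq <- function(n, start_pos, L, ori, amplitude, gc_mean, seed,
                           left, right) {
  if (n <= 0L) return("")
  with_seed(hash_id(seed, "ig_seq", left, right), {
    u_gc <- stats::runif(n); u_base <- stats::runif(n)
    pos <- start_pos + seq_len(n) - 1L
    d <- (pos - ori) %% L
    s <- ifelse(d < L / 2, -amplitude, amplitude)  # leaving vs approaching origin
    is_gc <- u_gc < gc_mean
    p_g <- (1 + s) / 2
    bases <- ifelse(is_gc, ifelse(u_base < p_g, "G", "C"),
                    ifelse(u_base < 0.5, "A", "T"))
    paste(bases, collapse = "")
  })
}
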