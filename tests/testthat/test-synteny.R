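# k-mer anchors, collinear-block chaining and breakpoint reporting.

test_that("identical genomes give one full-length main-diagonal anchor", {
  set.seed(6)
  g <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  an <- kmer_anchors(g, g, k = 15)
  main <- an[an$strand == "+", ]
  expect_equal(main$pos_a[1], 0L)
  expect_equal(main$length[1], 5000L)
  # reverse complement: full-length anchor on the minus strand
  an_rc <- kmer_anchors(g, revcomp(g), k = 15)
  minus <- an_rc[an_rc$strand == "-", ]
  expect_equal(minus$pos_a[which.max(minus$length)], 0L)
  expect_equal(max(minus$length), 5000L)
})

test_that("anchor sets are symmetric under genome swap", {
  set.seed(13)
  a <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  b <- paste0(substr(a, 1001, 3000), revcomp(substr(a, 1, 1000)))
  ab <- kmer_anchors(a, b, k = 15)
  ba <- kmer_anchors(b, a, k = 15)
  swapped <- data.frame(pos_a = ba$pos_b, pos_b = ba$pos_a,
                        length = ba$length, strand = ba$strand,
                        stringsAsFactors = FALSE)
  swapped <- swapped[order(swapped$pos_a, swapped$pos_b), ]
  rownames(swapped) <- NULL
  expect_equal(swapped, as.data.frame(ab)[names(swapped)])
})

test_that("chaining merges collinear anchors and drops sparse ones", {
  an <- data.frame(pos_a = c(0L, 100L, 200L), pos_b = c(0L, 100L, 200L),
                   length = c(50L, 50L, 50L), strand = "+",
                   stringsAsFactors = FALSE)
  class(an) <- c("anchor_set", class(an))
  attr(an, "k") <- 50L
  bl <- chain_anchors(an, max_gap = 100L, min_anchors = 3L)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$start_a, 0L); expect_equal(bl$end_a, 250L)
  # anchors farther apart than max_gap never chain
  an2 <- an; an2$pos_a <- c(0L, 10000L, 20000L); an2$pos_b <- an2$pos_a
  expect_equal(nrow(chain_anchors(an2, max_gap = 100L, min_anchors = 2L)), 0L)
  # chaining is invariant to anchor input order
  bl2 <- chain_anchors(an[c(3, 1, 2), ], max_gap = 100L, min_anchors = 3L)
  expect_equal(as.data.frame(bl), as.data.frame(bl2))
})

test_that("a planted inversion yields two strand-change breakpoints at truth", {
  gs <- list(A = sprintf("fam%04d", 1:60), B = sprintf("fam%04d", 1:60))
  inv <- list(strain = "B", type = "inversion", start = 20000L,
              length = 10000L)
  asm <- assemble_genomes(gs, rearrangements = list(inv), seed = 27)
  an <- kmer_anchors(asm$genomes$A, asm$genomes$B, k = 15)
  bl <- chain_anchors(an, circular = TRUE)
  bps <- breakpoint_report(bl)
  sc <- bps[bps$strand_change, ]
  expect_equal(nrow(sc), 2L)
  L <- unname(asm$truth$lengths["A"])
  truth <- c(20000L, 30000L)
  for (p in sc$position)
    expect_lte(min(circ_dist(p, truth, L)), 14)  # within k - 1 bp
})

test_that("breakpoint reporting orders boundaries and rejects overlap", {
  blocks <- data.frame(start_a = c(0L, 5000L), end_a = c(5000L, 9000L),
                       start_b = c(0L, 5000L), end_b = c(5000L, 9000L),
                       strand = c("+", "-"), n_anchors = c(10L, 10L),
                       stringsAsFactors = FALSE)
  bps <- breakpoint_report(blocks, genome_lengths = c(9000L, 9000L))
  expect_equal(bps$position, c(0L, 5000L))
  expect_true(all(bps$strand_change))
  # single block -> no breakpoints
  expect_equal(nrow(breakpoint_report(blocks[1, ],
                                      genome_lengths = c(9000L, 9000L))), 0L)
  bad <- blocks; bad$start_a[2] <- 4000L
  expect_error(breakpoint_report(bad, genome_lengths = c(9000L, 9000L)),
               class = "wolbpan_parameter")
})
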