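# Orthogroup inference, SCO extraction, PAV matrices, center-star
# alignments and the SCO supermatrix.

test_that("k-mer multiset Jaccard similarity matches hand enumeration", {
  expect_equal(pairwise_similarity("ACDEFGH", "ACDEFGH"), 1)
  expect_equal(pairwise_similarity("ACDEFGH", "ACDEFGY", k = 4), 3 / 5)
  expect_equal(pairwise_similarity("AAAAAA", "CCCCCC", k = 4), 0)
  expect_equal(pairwise_similarity("ACDEFGH", "ACDEFGY", k = 4),
               pairwise_similarity("ACDEFGY", "ACDEFGH", k = 4))
  expect_error(pairwise_similarity("AC", "ACDE", k = 4),
               class = "wolbpan_too_short")
})

test_that("identical proteomes yield one two-member orthogroup per gene", {
  p1 <- seq_set(c("a1", "a2"), c("MKKLLIVASDFG", "MNPQRSTVWYAC"),
                alphabet = "amino-acid")
  p2 <- seq_set(c("b1", "b2"), c("MKKLLIVASDFG", "MNPQRSTVWYAC"),
                alphabet = "amino-acid")
  ogs <- infer_orthogroups(list(s1 = p1, s2 = p2))
  expect_length(ogs, 2L)
  expect_true(all(vapply(ogs, function(o) sum(lengths(o$members)) == 2L,
                         logical(1))))
  # min_score = 1 on diverged sequences leaves every gene a singleton
  p3 <- seq_set(c("c1", "c2"), c("MKKWWIVASDFG", "MNPQRSTVWYAC"),
                alphabet = "amino-acid")
  ogs2 <- infer_orthogroups(list(s1 = p1, s2 = p3), min_score = 1)
  counts <- vapply(ogs2, function(o) sum(lengths(o$members)), integer(1))
  expect_true(sum(counts == 2L) == 1L)  # only the identical pair clusters
  expect_error(infer_orthogroups(list(s1 = p1, s2 = p1[0, ])),
               "s2", class = "wolbpan_parameter")
})

test_that("orthogroups partition the input genes", {
  sim <- simulate_strain_set(n_strains = 4, n_clades = 2, n_core = 25,
                             n_accessory = 10, n_reads = 10, inversions = 0,
                             seed = 17)
  ogs <- infer_orthogroups(sim$proteomes)
  genes <- sort(unlist(lapply(ogs, function(o)
    unlist(o$members, use.names = FALSE))))
  all_genes <- sort(unlist(lapply(sim$proteomes, function(p) p$id),
                           use.names = FALSE))
  expect_identical(genes, all_genes)
  # invariant to strain enumeration order
  ogs_rev <- infer_orthogroups(rev(sim$proteomes))
  members <- function(x) lapply(x, function(o)
    sort(unlist(o$members, use.names = FALSE)))
  expect_identical(members(ogs), members(ogs_rev))
})

test_that("SCO extraction keeps exactly-one-copy-everywhere groups", {
  strains <- c("s1", "s2", "s3")
  og1 <- orthogroup("OG1", list(s1 = "a", s2 = "b", s3 = "c"))
  og2 <- orthogroup("OG2", list(s1 = c("d", "e"), s2 = "f", s3 = "g"))
  og3 <- orthogroup("OG3", list(s1 = "h", s2 = character(0), s3 = "i"))
  expect_equal(extract_scos(list(og1, og2, og3), strains), "OG1")
})

test_that("PAV matrices hold copy counts in fixed strain order", {
  strains <- c("s1", "s2", "s3")
  ogs <- list(orthogroup("OG2", list(s1 = c("d", "e"), s2 = "f", s3 = "g")),
              orthogroup("OG1", list(s1 = "a", s2 = character(0), s3 = "c")))
  pav <- build_pav(ogs, strains)
  expect_equal(rownames(pav), c("OG1", "OG2"))  # sorted, deterministic
  expect_equal(unname(unclass(pav)["OG2", ]), c(2L, 1L, 1L))
  expect_equal(unname(unclass(pav)["OG1", ]), c(1L, 0L, 1L))
  og_bad <- orthogroup("OGX", list(s9 = "z"))
  expect_error(build_pav(list(og_bad), strains), class = "wolbpan_parameter")
})

test_that("center-star alignment is optimal on small cases and order-invariant", {
  aln <- align_orthogroup(c(g1 = "ACDE", g2 = "ACE"))
  m <- do.call(rbind, strsplit(unname(aln), ""))
  expect_equal(ncol(m), 4L)
  expect_equal(sum(m[1, ] == m[2, ]), 3L)          # 3 match columns
  expect_equal(sum(m == "-"), 1L)                  # one deletion column
  # pairwise score equals the exhaustive-DP optimum
  expect_equal(score_gapped_pair(aln[["g1"]], aln[["g2"]]),
               oracle_global_score("ACDE", "ACE"))

  aln_id <- align_orthogroup(c(x = "MKLV", y = "MKLV"))
  expect_false(any(grepl("-", aln_id, fixed = TRUE)))

  set.seed(2)
  seqs <- stats::setNames(replicate(5, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40, TRUE),
    collapse = "")), paste0("g", 1:5))
  a1 <- align_orthogroup(seqs)
  a2 <- align_orthogroup(seqs[c(3, 1, 5, 2, 4)])
  expect_identical(a1, a2[names(a1)])
  expect_equal(length(unique(nchar(a1))), 1L)
  # single member comes back unaligned
  expect_identical(align_orthogroup(seqs[1]), seqs[1])
})

test_that("pairwise global alignments match the exhaustive DP score", {
  set.seed(12)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    a <- paste(sample(aa, sample(4:18, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(4:18, 1), TRUE), collapse = "")
    g <- wolbpan:::global_align(a, b)
    expect_equal(score_gapped_pair(g$a, g$b), oracle_global_score(a, b),
                 info = paste(a, b))
  }
})

test_that("supermatrix concatenates SCO alignments with partition intervals", {
  strains <- c("s1", "s2")
  og1 <- orthogroup("OG1", list(s1 = "a1", s2 = "a2"))
  og2 <- orthogroup("OG2", list(s1 = "b1", s2 = "b2"))
  alns <- list(OG1 = c(a1 = strrep("M", 10), a2 = strrep("K", 10)),
               OG2 = c(b1 = strrep("A", 20), b2 = strrep("C", 20)))
  sm <- export_supermatrix(alns, list(og1, og2), strains)
  expect_equal(unname(nchar(sm$alignment)), c(30L, 30L))
  expect_equal(names(sm$alignment), strains)
  expect_equal(sm$partitions$start, c(0L, 10L))
  expect_equal(sm$partitions$end, c(10L, 30L))
  expect_error(export_supermatrix(list(), list(), strains),
               "no single-copy", class = "wolbpan_parameter")
  og3 <- orthogroup("OG3", list(s1 = "c1"))
  expect_error(export_supermatrix(list(OG3 = c(c1 = "MM")), list(og3), strains),
               class = "wolbpan_parameter")
})
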