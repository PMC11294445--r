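# Duplicate removal and the gap-compressed mismatch-ratio filter.

test_that("dedup keeps first occurrences by id or by sequence", {
  reads <- seq_set(c("a", "b", "a2"), c("ACGT", "GGGG", "ACGT"),
                   alphabet = "nucleotide")
  reads$id <- c("a", "b", "a")  # force a duplicate id past construction
  r <- dedup_reads(reads, key = "id")
  expect_equal(r$retained$id, c("a", "b"))
  expect_equal(r$removed, 1L)

  r2 <- dedup_reads(seq_set(c("a", "b", "c"), c("AC", "GG", "TT"),
                            alphabet = "nucleotide"), key = "id")
  expect_equal(r2$removed, 0L)

  # same sequence under different ids; brute-force pairwise comparison agrees
  reads3 <- seq_set(c("x", "y", "z"), c("ACGT", "ACGT", "GGTT"),
                    alphabet = "nucleotide")
  r3 <- dedup_reads(reads3, key = "sequence")
  dup_brute <- sum(vapply(seq_len(3), function(i)
    any(vapply(seq_len(i - 1), function(j) reads3$seq[i] == reads3$seq[j],
               logical(1))), logical(1)))
  expect_equal(r3$removed, dup_brute)
  expect_equal(r3$retained$id, c("x", "z"))
})

test_that("gap-compressed divergence matches hand-computed examples", {
  mk <- function(ops, lens, nm = NA_integer_)
    wolbpan:::new_aln_record("r", "t", data.frame(op = ops, len = lens),
                             edit_distance = nm)
  # 100 matches + 4 mismatches, no gaps -> 4/104
  expect_equal(gap_compressed_divergence(mk(c("=", "X"), c(100L, 4L))),
               4 / 104)
  # 50=,3D,50= with NM 5: inferred mismatches 2, one gap open -> 3/103
  expect_equal(gap_compressed_divergence(mk(c("=", "D", "="),
                                            c(50L, 3L, 50L), nm = 5L)),
               3 / 103)
  # perfect alignment
  expect_equal(gap_compressed_divergence(mk("=", 200L)), 0)
  # NM smaller than gap bases is inconsistent
  expect_error(gap_compressed_divergence(mk(c("=", "D", "="),
                                            c(50L, 3L, 50L), nm = 2L)),
               class = "wolbpan_inconsistent")
})

test_that("divergence equals a raw-difference-string oracle on 1000 simulated records", {
  sim <- simulate_alignment_records(1000, seq(0.002, 0.2, by = 0.002),
                                    seed = 101)
  d_impl <- vapply(sim$records, gap_compressed_divergence, numeric(1))
  d_oracle <- vapply(sim$records, function(r) oracle_divergence_from_cs(r$cs),
                     numeric(1))
  expect_equal(d_impl, d_oracle, tolerance = 1e-12)
})

test_that("the boundary record at exactly the threshold is retained", {
  # 96 matches + 4 mismatches -> exactly 0.04
  rec <- wolbpan:::new_aln_record("r", "t",
                                  data.frame(op = c("=", "X"), len = c(96L, 4L)))
  expect_equal(gap_compressed_divergence(rec), 0.04)
  res <- filter_by_divergence(list(rec), threshold = 0.04)
  expect_equal(res$report$n_retained, 1L)  # removal rule is strictly 'exceeding'
})

test_that("threshold zero retains only perfect alignments", {
  sim <- simulate_alignment_records(60, c(0, 0.02, 0.05), seed = 5)
  res <- filter_by_divergence(sim$records, threshold = 0)
  expect_equal(res$report$n_retained, sum(sim$truth$realized == 0))
})

test_that("retained sets nest monotonically and report counts reconcile", {
  sim <- simulate_alignment_records(300, seq(0.005, 0.12, by = 0.005),
                                    seed = 31)
  ids_at <- function(t) vapply(filter_by_divergence(sim$records, t)$retained,
                               function(r) r$read_id, character(1))
  r01 <- ids_at(0.01); r04 <- ids_at(0.04); r10 <- ids_at(0.1)
  expect_true(all(r01 %in% r04))
  expect_true(all(r04 %in% r10))

  res <- filter_by_divergence(sim$records, 0.04)
  rep <- res$report
  expect_equal(rep$n_input,
               rep$n_unmapped + rep$n_indeterminate + rep$n_failed_threshold +
                 rep$n_retained + rep$n_duplicates_removed)
})

test_that("unmapped, indeterminate and secondary records are set aside", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("r1\t0\tref\t1\t60\t10=\t*\t0\t0\tAAAAAAAAAA\t*",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*",
               "r3\t0\tref\t1\t60\t10M\t*\t0\t0\tAAAAAAAAAA\t*",
               "r4\t256\tref\t1\t60\t10=\t*\t0\t0\tAAAAAAAAAA\t*"), f)
  recs <- read_alignment_records(f, "sam")
  expect_warning(res <- filter_by_divergence(recs, 0.04), "indeterminate")
  expect_equal(res$report$n_input, 3L)  # secondary r4 judged by primary only
  expect_equal(res$report$n_secondary_ignored, 1L)
  expect_equal(res$report$n_unmapped, 1L)
  expect_equal(res$report$n_indeterminate, 1L)
  expect_equal(res$report$n_retained, 1L)
})
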