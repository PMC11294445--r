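# Per-column Shannon entropy, variable-site flags, class summaries and
# effector reports.

test_that("column entropy matches direct evaluation", {
  expect_equal(column_entropy(c("A", "A", "A", "A")), 0)
  expect_equal(column_entropy(c("A", "A", "V", "V")), 1)
  expect_equal(column_entropy(c("A", "A", "A", "V", "V")),
               -(0.6 * log2(0.6) + 0.4 * log2(0.4)))
  expect_equal(round(column_entropy(c("A", "A", "A", "V", "V")), 4), 0.971)
  # gaps and X are excluded from frequencies: effective column is (A, A, V)
  expect_equal(column_entropy(c("A", "-", "A", "X", "V")),
               -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3)))
  # below minimum coverage -> undefined
  expect_true(is.na(column_entropy(c("A", "-", "-", "-"))))
  expect_true(is.na(column_entropy(c("-", "-"))))
})

test_that("entropy equals the frequency-table oracle on random columns", {
  set.seed(71)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "X")
  for (i in 1:500) {
    col <- sample(aa, sample(2:12, 1), replace = TRUE)
    expect_equal(column_entropy(col), oracle_entropy(col), tolerance = 1e-12)
  }
})

test_that("profiles flag variable columns and honor the threshold", {
  aln <- c(r1 = "AAAA", r2 = "AAAA", r3 = "AAAA")
  expect_equal(entropy_profile(aln)$n_variable, 0L)
  aln2 <- c(r1 = "AVKL", r2 = "AVKV", r3 = "ACKL")
  p <- entropy_profile(aln2)
  expect_equal(p$variable_flags, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(p$n_variable, 2L)
  expect_equal(p$fraction_variable, 0.5)
  # a threshold above log2(20) can never be exceeded
  expect_equal(entropy_profile(aln2, variable_threshold = log2(20) + 1)$n_variable, 0L)
  # n_variable is non-increasing in the threshold
  ths <- c(0, 0.5, 1, 1.5)
  ns <- vapply(ths, function(t) entropy_profile(aln2, t)$n_variable, integer(1))
  expect_true(all(diff(ns) <= 0))
  # row permutation leaves entropies unchanged
  p2 <- entropy_profile(aln2[c(3, 1, 2)])
  expect_equal(p$column_entropies, p2$column_entropies)
  expect_error(entropy_profile(c(a = "AAA", b = "AAAA")),
               class = "wolbpan_format")
})

test_that("planted variable columns are recovered exactly", {
  tree <- sample_strain_tree(6, 2, seed = 19)
  for (nv in c(0L, 3L, 17L)) {
    fam <- simulate_family_alignment("famT", tree, length = 80,
                                     n_variable = nv, seed = nv + 1)
    p <- entropy_profile(fam$alignment)
    expect_equal(p$n_variable, nv)
    expect_equal(which(p$variable_flags), as.integer(fam$variable_columns))
  }
})

test_that("class summaries use the even-count median rule", {
  mk <- function(id, nv, len = 100L) {
    flags <- rep(FALSE, len); if (nv > 0) flags[seq_len(nv)] <- TRUE
    structure(list(og_id = id, column_entropies = as.numeric(flags),
                   column_coverage = rep(3L, len), variable_flags = flags,
                   n_variable = nv, fraction_variable = nv / len,
                   length = len), class = "entropy_profile")
  }
  profiles <- list(a = mk("a", 0L), b = mk("b", 1L), c = mk("c", 5L),
                   d = mk("d", 13L), e = mk("e", 14L))
  classes <- c(a = "other", b = "other", c = "other",
               d = "secreted", e = "secreted")
  vs <- summarize_variability(profiles, classes)
  pc <- vs$per_class
  expect_equal(pc$median_n_variable[pc$class == "other"], 1)
  expect_equal(pc$median_n_variable[pc$class == "secreted"], 13.5)
  expect_equal(pc$median_n_variable[pc$class == "all"], 5)
  # zero-variable orthogroups: counted separately, absent from the histogram
  expect_equal(vs$n_zero_variable_orthogroups, 1L)
  expect_false(any(vs$histogram$n_variable == 0))
  expect_equal(sum(pc$n_orthogroups[pc$class != "all"]), length(profiles))
  expect_error(summarize_variability(list(), classes),
               class = "wolbpan_parameter")
})

test_that("effector reports use the full alignment length as denominator", {
  tree <- sample_strain_tree(5, 1, seed = 3)
  fam <- simulate_family_alignment("tomO-like", tree, length = 200,
                                   n_variable = 20, seed = 4)
  profiles <- list(OG1 = entropy_profile(fam$alignment, og_id = "OG1"))
  labels <- c(OG1 = "toxic manipulator of oogenesis TomO")
  rep <- effector_report(profiles, "TomO", labels = labels)
  expect_equal(rep$n_variable, 20L)
  expect_equal(rep$alignment_length, 200L)
  expect_equal(rep$percent_variable, 10L)
  expect_warning(empty <- effector_report(profiles, "WalE1", labels = labels))
  expect_equal(nrow(empty), 0L)
})
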