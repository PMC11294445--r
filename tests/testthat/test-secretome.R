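# Hydropathy heuristics, the membrane/secreted/other rule, and
# orthogroup-level aggregation.

test_that("hydropathy profile averages the Kyte-Doolittle scale", {
  expect_equal(hydropathy_profile(strrep("L", 30)), rep(3.8, 30))
  expect_equal(hydropathy_profile(strrep("R", 30)), rep(-4.5, 30))
  # centered window-5 value at the 4th residue of LLLLLRRRRR:
  # mean(3.8, 3.8, 3.8, 3.8, -4.5) = 2.14
  h <- hydropathy_profile("LLLLLRRRRR", window = 5L)
  expect_equal(h[4], (3.8 * 4 - 4.5) / 5)
  expect_equal(h[4], 2.14)
  # truncated end windows
  expect_equal(h[1], mean(c(3.8, 3.8, 3.8)))
  expect_warning(hydropathy_profile(strrep("LXLLLLLLLL", 3), window = 5L),
                 "unknown")
})

test_that("classification rule is total and mutually exclusive", {
  expect_equal(classify_protein(TRUE, 2L), "membrane-bound")
  expect_equal(classify_protein(TRUE, 0L), "secreted")
  expect_equal(classify_protein(FALSE, 3L), "other")
  # exhaustively over a grid of the rule's input space
  for (sp in c(TRUE, FALSE)) for (n in 0:6) {
    cls <- classify_protein(sp, n)
    expect_equal(cls == "membrane-bound", sp && n >= 1)
    expect_equal(cls == "secreted", sp && n == 0)
    expect_equal(cls == "other", !sp)
  }
})

test_that("soluble polar proteins carry no predicted features", {
  body <- random_polar_body(150, seed = 21)
  expect_false(predict_signal_peptide(body)$flag)
  expect_equal(nrow(predict_tm_segments(body)), 0L)
  poly_ser <- strrep("S", 60)
  expect_false(predict_signal_peptide(poly_ser)$flag)
  sp_short <- predict_signal_peptide(strrep("L", 20))
  expect_false(sp_short$flag)
  expect_equal(sp_short$note, "too-short")
})

test_that("planted features close the loop through the built-in classifier", {
  body <- random_polar_body(140, seed = 33)
  sec <- plant_protein_features(body, "secreted", seed = 1)
  mem <- plant_protein_features(body, "membrane-bound", seed = 1)
  oth <- plant_protein_features(body, "other", seed = 1)

  sp <- predict_signal_peptide(sec$sequence)
  expect_true(sp$flag)
  # signal-peptide hydrophobicity must not count as a transmembrane domain
  seg <- predict_tm_segments(sec$sequence,
                             exclude_region = c(1L, max(25L, sp$cleavage,
                                                        na.rm = TRUE)))
  expect_equal(nrow(seg), 0L)

  sp_m <- predict_signal_peptide(mem$sequence)
  expect_true(sp_m$flag)
  seg_m <- predict_tm_segments(mem$sequence,
                               exclude_region = c(1L, max(25L, sp_m$cleavage,
                                                          na.rm = TRUE)))
  expect_gte(nrow(seg_m), 1L)
  expect_gt(seg_m$start[1], 25L)  # segment lies beyond the signal region

  proteins <- seq_set(c("s", "m", "o"),
                      c(sec$sequence, mem$sequence, oth$sequence),
                      alphabet = "amino-acid")
  cls <- classify_proteins(proteins)
  expect_equal(cls$class, c("secreted", "membrane-bound", "other"))
  expect_true(all(cls$evidence_source == "builtin-heuristic"))
  expect_error(plant_protein_features("SSS", "secreted", seed = 1),
               class = "wolbpan_parameter")
})

test_that("external predictor tables always override the heuristics", {
  body <- random_polar_body(120, seed = 8)
  sec <- plant_protein_features(body, "secreted", seed = 2)
  proteins <- seq_set(c("g1", "g2"), c(sec$sequence, body),
                      alphabet = "amino-acid")
  ext <- data.frame(gene = "g1", has_signal_peptide = FALSE,
                    n_tm_segments = 0L, stringsAsFactors = FALSE)
  cls <- classify_proteins(proteins, predictor_table = ext)
  expect_equal(cls$class[cls$gene == "g1"], "other")  # table wins over heuristic
  expect_equal(cls$evidence_source[cls$gene == "g1"], "external-table")
  expect_equal(cls$evidence_source[cls$gene == "g2"], "builtin-heuristic")
})

test_that("orthogroup class is a majority vote with fixed tie precedence", {
  expect_equal(classify_orthogroup(c("secreted", "secreted", "other"))$class,
               "secreted")
  expect_equal(classify_orthogroup(c("membrane-bound", "secreted"))$class,
               "membrane-bound")
  expect_equal(classify_orthogroup(c("secreted", "other"))$class, "secreted")
  expect_equal(classify_orthogroup("other")$class, "other")
  tal <- classify_orthogroup(c("other", "other", "secreted"))$tally
  expect_equal(unname(tal), c(0L, 1L, 2L))
})
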