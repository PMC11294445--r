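# The synthetic strain-set generator and its ground-truth manifest.

test_that("strain trees have the requested clade structure", {
  tr <- sample_strain_tree(2, 1, seed = 1)
  expect_length(tr$phylo$tip.label, 2L)
  expect_equal(unname(unique(tr$clades)), "C1")

  tr2 <- sample_strain_tree(8, 2, seed = 7)
  sizes <- table(tr2$clades)
  expect_equal(sum(sizes), 8L)
  expect_length(sizes, 2L)
  # monophyly checked by enumeration of the tree's bipartitions (ape)
  for (cl in unique(tr2$clades))
    expect_true(ape::is.monophyletic(tr2$phylo,
                                     names(tr2$clades)[tr2$clades == cl]))
  expect_true(all(tr2$phylo$edge.length >= 0))
  # identical seed -> identical Newick string
  expect_identical(tr2$newick, sample_strain_tree(8, 2, seed = 7)$newick)
  expect_false(identical(tr2$newick, sample_strain_tree(8, 2, seed = 8)$newick))
  expect_error(sample_strain_tree(1, 1, seed = 1), class = "wolbpan_parameter")
  expect_error(sample_strain_tree(4, 5, seed = 1), class = "wolbpan_parameter")
})

test_that("gene content truth obeys its limiting cases and event log", {
  tr <- sample_strain_tree(6, 2, seed = 5)
  # gains at the root only, no loss -> all-true PAV
  gc0 <- simulate_gene_content(tr, n_core = 5, n_accessory = 7,
                               gain_rate = 0, loss_rate = 0, seed = 2,
                               accessory_root_prob = 1)
  expect_true(all(gc0$pav_truth))
  # no accessory families -> all-true core-only table
  gc1 <- simulate_gene_content(tr, n_core = 5, n_accessory = 0, seed = 2)
  expect_equal(dim(gc1$pav_truth), c(5L, 6L))
  expect_true(all(gc1$pav_truth))

  # replaying the recorded event log along the tree reproduces the PAV row
  gc2 <- simulate_gene_content(tr, n_core = 0, n_accessory = 40,
                               gain_rate = 0.8, loss_rate = 0.5, seed = 9)
  edges <- gc2$edges
  root <- attr(edges, "root")
  strains <- tr$phylo$tip.label
  for (fam in rownames(gc2$pav_truth)) {
    ev <- gc2$events[gc2$events$family == fam, ]
    state <- rep(NA, max(c(edges$parent, edges$child)))
    # the log fixes every state given the root; try both root states and
    # require that one of them reproduces the truth row exactly
    state[root] <- TRUE
    for (i in seq_len(nrow(edges))) {
      p <- edges$parent[i]; ch <- edges$child[i]
      s <- state[p]
      hit <- ev[ev$edge == i, ]
      if (nrow(hit)) s <- hit$type == "gain"
      state[ch] <- s
    }
    replayed_if_root_present <- state[seq_along(strains)]
    state[root] <- FALSE
    for (i in seq_len(nrow(edges))) {
      p <- edges$parent[i]; ch <- edges$child[i]
      s <- state[p]
      hit <- ev[ev$edge == i, ]
      if (nrow(hit)) s <- hit$type == "gain"
      state[ch] <- s
    }
    replayed_if_root_absent <- state[seq_along(strains)]
    truth <- unname(gc2$pav_truth[fam, ])
    expect_true(identical(truth, replayed_if_root_present) ||
                  identical(truth, replayed_if_root_absent), info = fam)
  }
  expect_error(simulate_gene_content(tr, 5, 5, gain_rate = -1, seed = 1),
               class = "wolbpan_parameter")
})

test_that("a gain on a clade stem branch marks exactly that clade", {
  tr <- sample_strain_tree(8, 2, seed = 21)
  gc <- simulate_gene_content(tr, n_core = 0, n_accessory = 200,
                              gain_rate = 0.6, loss_rate = 0.1, seed = 13,
                              accessory_root_prob = 0)
  edges <- gc$edges
  # find families whose single event is one gain on an internal branch
  singles <- names(which(table(gc$events$family) == 1))
  checked <- 0L
  for (fam in singles) {
    ev <- gc$events[gc$events$family == fam, ]
    if (ev$type != "gain") next
    tips_below <- if (ev$child <= length(tr$phylo$tip.label))
      tr$phylo$tip.label[ev$child]
    else ape::extract.clade(tr$phylo, ev$child)$tip.label
    expect_setequal(colnames(gc$pav_truth)[gc$pav_truth[fam, ]], tips_below)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("family alignments vary only at designated columns", {
  tr <- sample_strain_tree(5, 1, seed = 2)
  fam <- simulate_family_alignment("f1", tr, length = 60, n_variable = 8,
                                   seed = 3)
  m <- do.call(rbind, strsplit(unname(fam$alignment), ""))
  poly <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  expect_identical(as.integer(poly), as.integer(fam$variable_columns))
  # boundary cases
  f0 <- simulate_family_alignment("f2", tr, length = 30, n_variable = 0,
                                  seed = 3)
  expect_length(unique(f0$alignment), 1L)
  fmax <- simulate_family_alignment("f3", tr, length = 20, n_variable = 20,
                                    seed = 3)
  expect_length(fmax$variable_columns, 20L)
  expect_error(simulate_family_alignment("f4", tr, length = 10,
                                         n_variable = 11, seed = 1),
               class = "wolbpan_parameter")
})

test_that("simulated alignment records realize their requested divergences", {
  sim <- simulate_alignment_records(40, c(0, 0.05), seed = 3,
                                    n_events_range = c(100L, 100L))
  # divergence 0: no mismatches, no gaps
  r0 <- sim$records[[1]]
  expect_equal(sum(r0$runs$op %in% c("X", "I", "D")), 0L)
  # divergence 0.05 on a 100-event alignment: exactly 5 difference events
  r5 <- sim$records[[2]]
  n_diff <- sum(r5$runs$op == "X" & r5$runs$len > 0) * 0 +
    sum(r5$runs$len[r5$runs$op == "X"]) + sum(r5$runs$op %in% c("I", "D"))
  expect_equal(n_diff, 5L)
  expect_equal(sim$truth$realized[2], 0.05)
  # realized always within 1/(alignment length) of requested
  sim2 <- simulate_alignment_records(100, seq(0.01, 0.2, 0.01), seed = 4)
  expect_true(all(abs(sim2$truth$realized - sim2$truth$requested) <=
                    1 / 100))
  expect_error(simulate_alignment_records(5, c(0.5, 1.2), seed = 1),
               class = "wolbpan_parameter")
})

test_that("genome assembly plants origin skew and honors determinism", {
  gs <- list(A = sprintf("fam%04d", 1:40), B = sprintf("fam%04d", 1:40))
  asm1 <- assemble_genomes(gs, seed = 5)
  asm2 <- assemble_genomes(gs, seed = 5)
  expect_identical(asm1$genomes$A$seq, asm2$genomes$A$seq)
  # identical gene content -> identical genomes across strains
  expect_identical(asm1$genomes$A$seq, asm1$genomes$B$seq)
  expect_false(identical(asm1$genomes$A$seq,
                         assemble_genomes(gs, seed = 6)$genomes$A$seq))
  # zero skew amplitude: windowed skew has no systematic sign structure
  asm0 <- assemble_genomes(gs[1], skew_amplitude = 0, seed = 5)
  tr <- windowed_profile(asm0$genomes$A, "gc_skew", window = 5000L,
                         step = 5000L)
  expect_lt(abs(mean(tr$value, na.rm = TRUE)), 0.05)
  # overlapping rearrangements are a parameter error
  bad <- list(list(strain = "A", type = "inversion", start = 1000L, length = 5000L),
              list(strain = "A", type = "inversion", start = 3000L, length = 5000L))
  expect_error(assemble_genomes(gs, rearrangements = bad, seed = 5),
               class = "wolbpan_parameter")
})

test_that("the strain-set manifest is complete and byte-reproducible", {
  sim1 <- simulate_strain_set(n_strains = 4, n_clades = 2, n_core = 12,
                              n_accessory = 6, n_reads = 20, inversions = 1,
                              seed = 77)
  sim2 <- simulate_strain_set(n_strains = 4, n_clades = 2, n_core = 12,
                              n_accessory = 6, n_reads = 20, inversions = 1,
                              seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_strain_set(sim1, d1); write_strain_set(sim2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)

  # every emitted gene appears in the truth manifest and vice versa
  emitted <- sort(unlist(lapply(sim1$proteomes, function(p) p$id),
                         use.names = FALSE))
  expect_identical(emitted, sort(sim1$class_truth$gene))
  pav <- sim1$content$pav_truth
  from_pav <- sort(unlist(lapply(colnames(pav), function(s)
    sprintf("%s_%s", rownames(pav)[pav[, s]], s)), use.names = FALSE))
  expect_identical(emitted, from_pav)
  # every emitted read has a truth divergence and vice versa
  expect_setequal(vapply(sim1$reads$records, function(r) r$read_id,
                         character(1)), sim1$reads$truth$read_id)
})
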