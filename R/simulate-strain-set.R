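# Top-level synthetic strain-set generator: ties together the tree, gene
# content, family alignments, planted protein classes, circular genomes and
# alignment records into one object with a complete ground-truth manifest.

#' Simulate a complete strain set with known ground truth
#'
#' Generates, from one integer seed, a rooted strain tree with clade
#' structure, gene family presence/absence along it, per-family protein
#' alignments with planted variable columns, planted protein classes
#' (secreted / membrane-bound / other via [plant_protein_features()]),
#' circular genomes with an imposed GC-skew origin and optional planted
#' inversions, and read alignment records with known gap-compressed
#' divergences. Every emitted gene, read and genome appears in the truth
#' manifest and vice versa; identical seeds and parameters reproduce
#' identical output.
#'
#' @param n_strains,n_clades tree shape (defaults 8 strains, 2 clades).
#' @param n_core,n_accessory family counts (defaults 240 core + 60
#'   accessory = 300 families).
#' @param gain_rate,loss_rate,accessory_root_prob gene-content dynamics
#'   (see [simulate_gene_content()]).
#' @param body_length protein body length in residues (default 120).
#' @param max_variable maximum planted variable-column count per family
#'   (uniform 0..max; default 12).
#' @param class_probs probabilities of (other, secreted, membrane-bound)
#'   per family (default 0.7/0.15/0.15 — secreted and membrane proteins are
#'   minority classes, as in real endosymbiont proteomes).
#' @param n_reads,read_divergences alignment-record simulation (defaults:
#'   400 reads, divergences drawn from {0.005, 0.01, ..., 0.1}).
#' @param inversions number of planted 10-kb inversions in the second
#'   strain's genome (default 1).
#' @param intergenic_mean,skew_amplitude,origin_position,gene_length,gc_mean
#'   genome assembly parameters (see [assemble_genomes()]).
#' @param seed integer seed driving every sub-stream.
#' @return An object of class `strain_set_sim`; see Details.
#' @details The returned list contains `tree`, `content` (gene-content
#'   truth), `families` (data.frame id, type, class, n_variable),
#'   `alignments` (family -> named rows per strain present),
#'   `variable_columns` (family -> 1-based column indices),
#'   `proteomes` (strain -> [seq_set()], gene ids `<family>_<strain>`),
#'   `class_truth` (data.frame strain, gene, family, class), `genomes`,
#'   `genome_truth`, `reads` (from [simulate_alignment_records()]), and
#'   `seed`.
#' @export
simulate_strain_set <- function(n_strains = 8L, n_clades = 2L,
                                n_core = 240L, n_accessory = 60L,
                                gain_rate = 0.5, loss_rate = 0.3,
                                accessory_root_prob = 0.5,
                                body_length = 120L, max_variable = 12L,
                                class_probs = c(other = 0.7, secreted = 0.15,
                                                `membrane-bound` = 0.15),
                                n_reads = 400L,
                                read_divergences = seq(0.005, 0.1, by = 0.005),
                                inversions = 1L,
                                intergenic_mean = 300L, skew_amplitude = 0.6,
                                origin_position = 0.25, gene_length = 600L,
                                gc_mean = 0.35, seed = 1L) {
  tree <- sample_strain_tree(n_strains, n_clades, seed = hash_id(seed, "tree"))
  content <- simulate_gene_content(tree, n_core, n_accessory,
                                   gain_rate = gain_rate,
                                   loss_rate = loss_rate,
                                   seed = seed,
                                   accessory_root_prob = accessory_root_prob)
  strains <- tree$phylo$tip.label
  families <- content$families
  families$class <- NA_character_
  families$n_variable <- NA_integer_

  alignments <- list(); variable_columns <- list()
  class_rows <- list()
  prot_rows <- stats::setNames(lapply(strains, function(s) list()), strains)
  classes <- names(class_probs)
  for (fi in seq_len(nrow(families))) {
    fam <- families$id[fi]
    h <- hash_id(seed, "family_plan", fam)
    plan <- with_seed(h, {
      list(class = sample(classes, 1L, prob = class_probs),
           n_var = sample(0:max_variable, 1L))
    })
    families$class[fi] <- plan$class
    families$n_variable[fi] <- plan$n_var
    body <- simulate_family_alignment(fam, tree, length = body_length,
                                      n_variable = plan$n_var, seed = seed,
                                      alphabet = AA_POLAR)
    # plant identical class features on every row so alignment columns stay
    # 1:1 and the feature region is invariant; variable-column truth shifts
    # by the planted prefix/insert lengths
    planted <- lapply(strains, function(s)
      plant_protein_features(body$alignment[[s]], plan$class,
                             seed = hash_id(seed, "features", fam)))
    names(planted) <- strains
    shift <- function(cols) {
      if (plan$class == "other") return(cols)
      sig <- 22L
      if (plan$class == "secreted") return(cols + sig)
      mid <- body_length %/% 2L
      ifelse(cols <= mid, cols + sig, cols + sig + 28L)
    }
    variable_columns[[fam]] <- shift(body$variable_columns)
    present <- strains[content$pav_truth[fam, ]]
    rows <- vapply(planted, function(p) p$sequence, character(1))[present]
    names(rows) <- sprintf("%s_%s", fam, present)
    alignments[[fam]] <- rows
    for (s in present) {
      gene <- sprintf("%s_%s", fam, s)
      prot_rows[[s]][[gene]] <- rows[[gene]]
      class_rows[[length(class_rows) + 1L]] <- data.frame(
        strain = s, gene = gene, family = fam, class = plan$class,
        stringsAsFactors = FALSE)
    }
  }
  proteomes <- lapply(strains, function(s) {
    genes <- prot_rows[[s]]
    seq_set(names(genes), unlist(genes, use.names = FALSE),
            alphabet = "amino-acid")
  })
  names(proteomes) <- strains

  rearr <- NULL
  if (inversions > 0L && length(strains) >= 2L) {
    target <- strains[2]
    glen_est <- length(content$gene_sets[[target]]) *
      (gene_length + intergenic_mean)
    inv_len <- as.integer(min(10000L, glen_est %/% 4L))
    rearr <- lapply(seq_len(inversions), function(i)
      list(strain = target, type = "inversion",
           start = as.integer(floor(glen_est * (0.2 + 0.5 * (i - 1) / max(1, inversions)))),
           length = inv_len))
  }
  gen <- assemble_genomes(content$gene_sets,
                          intergenic_mean = intergenic_mean,
                          skew_amplitude = skew_amplitude,
                          origin_position = origin_position,
                          rearrangements = rearr, seed = seed,
                          gene_length = gene_length, gc_mean = gc_mean)
  reads <- simulate_alignment_records(n_reads, read_divergences, seed = seed)

  structure(list(
    tree = tree, content = content, families = families,
    alignments = alignments, variable_columns = variable_columns,
    proteomes = proteomes,
    class_truth = do.call(rbind, class_rows),
    genomes = gen$genomes, genome_truth = gen$truth,
    reads = reads, seed = seed), class = "strain_set_sim")
}

#' @export
print.strain_set_sim <- function(x, ...) {
  cat(sprintf(
    "strain_set_sim (seed %d): %d strains, %d families, %d reads\n",
    x$seed, length(x$proteomes), nrow(x$families),
    nrow(x$reads$truth)))
  invisible(x)
}

#' Write a simulated strain set and its truth manifest to disk
#'
#' Emits genomes (FASTA, one record per strain), per-strain proteomes
#' (FASTA, headers `strain|gene`), per-family alignments (aligned FASTA),
#' the strain tree (Newick), read alignments (SAM and PAF), the truth
#' tables (TSV) and a JSON summary of the simulation parameters and truth
#' file inventory.
#'
#' @param sim a [simulate_strain_set()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_strain_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "proteomes"), showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  strains <- names(sim$proteomes)

  genome_df <- data.frame(
    id = strains, desc = "",
    seq = vapply(strains, function(s) sim$genomes[[s]]$seq, character(1)),
    stringsAsFactors = FALSE)
  write_fasta(genome_df, file.path(dir, "genomes.fasta"))
  for (s in strains) {
    p <- sim$proteomes[[s]]
    out <- p
    out$id <- sprintf("%s|%s", s, p$id)
    write_fasta(out, file.path(dir, "proteomes", paste0(s, ".faa")))
  }
  for (fam in names(sim$alignments))
    if (length(sim$alignments[[fam]]))  # families lost everywhere have no rows
      write_fasta(sim$alignments[[fam]],
                  file.path(dir, "alignments", paste0(fam, ".afa")))
  writeLines(sim$tree$newick, file.path(dir, "tree.nwk"))
  write_alignment_lines(sim$reads$sam, file.path(dir, "reads.sam"))
  write_alignment_lines(sim$reads$paf, file.path(dir, "reads.paf"))

  pav <- sim$content$pav_truth
  write_tsv(data.frame(family = rownames(pav),
                       as.data.frame(pav + 0L, check.names = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(dir, "truth_pav.tsv"))
  write_tsv(sim$families, file.path(dir, "truth_families.tsv"))
  write_tsv(sim$class_truth, file.path(dir, "truth_classes.tsv"))
  write_tsv(sim$reads$truth, file.path(dir, "truth_read_divergence.tsv"))
  write_tsv(data.frame(
    family = names(sim$variable_columns),
    columns = vapply(sim$variable_columns, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE), file.path(dir, "truth_variable_columns.tsv"))
  write_tsv(sim$genome_truth$breakpoints, file.path(dir, "truth_breakpoints.tsv"))
  write_tsv(data.frame(strain = strains,
                       length = unname(sim$genome_truth$lengths[strains]),
                       origin_bp = unname(sim$genome_truth$origin_bp[strains]),
                       stringsAsFactors = FALSE),
            file.path(dir, "truth_genomes.tsv"))
  manifest <- list(
    seed = sim$seed,
    n_strains = length(strains),
    n_families = nrow(sim$families),
    n_reads = nrow(sim$reads$truth),
    clades = as.list(sim$tree$clades),
    files = list(
      genomes = "genomes.fasta", tree = "tree.nwk",
      proteomes = sprintf("proteomes/%s.faa", strains),
      reads_sam = "reads.sam", reads_paf = "reads.paf"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "truth_manifest.json"))
  invisible(dir)
}
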