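# Protein-level simulation: family alignments with planted variable columns
# and planted signal-peptide / transmembrane features.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# polar/charged alphabet used for protein "bodies": guaranteed not to form
# hydrophobic stretches, so planted features are the only classifier signal
AA_POLAR <- c("S", "T", "G", "N", "Q", "E", "D", "K", "R", "P")
AA_HYDROPHOBIC <- c("L", "I", "V", "F")

random_residues <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate a protein family alignment with planted variable columns
#'
#' A root sequence is evolved down the strain tree; substitutions (uniform
#' replacement among the 20 amino acids) are placed only in the
#' `n_variable` designated columns, so every other column is invariant by
#' construction and the designated set is the exact ground truth for
#' variable-site recovery. With `ensure_variable = TRUE` (forced-variability
#' mode) any designated column that happens to end up monomorphic at the
#' leaves is given a second state in one leaf, so the realized variable-site
#' count equals the planted count exactly.
#'
#' @param family_id family identifier (drives the random sub-stream).
#' @param tree a [sample_strain_tree()] result.
#' @param length alignment length in columns.
#' @param n_variable number of designated variable columns (0 to `length`).
#' @param seed integer seed.
#' @param sub_prob per-branch substitution probability at a designated
#'   column (default 0.5).
#' @param ensure_variable force >= 2 states per designated column.
#' @param alphabet root-sequence alphabet (defaults to all 20 amino acids).
#' @return A list with `alignment` (named character vector, one ungapped row
#'   per strain) and `variable_columns` (sorted 1-based column indices).
#' @export
simulate_family_alignment <- function(family_id, tree, length, n_variable,
                                      seed = 1L, sub_prob = 0.5,
                                      ensure_variable = TRUE,
                                      alphabet = AA20) {
  length <- as.integer(length); n_variable <- as.integer(n_variable)
  if (n_variable < 0L || n_variable > length)
    stop_condition("n_variable must be in [0, length]", "wolbpan_parameter")
  phylo <- tree$phylo
  strains <- phylo$tip.label
  edges <- tree_edges(phylo)
  root <- attr(edges, "root")
  nnode <- max(c(edges$parent, edges$child))
  with_seed(hash_id(seed, "family_alignment", family_id), {
    var_cols <- sort(sample(length, n_variable))
    seqs <- vector("list", nnode)
    seqs[[root]] <- strsplit(random_residues(length, alphabet), "")[[1]]
    for (i in seq_len(nrow(edges))) {
      s <- seqs[[edges$parent[i]]]
      if (length(var_cols)) {
        hit <- var_cols[stats::runif(n_variable) < sub_prob]
        if (length(hit)) s[hit] <- sample(AA20, length(hit), replace = TRUE)
      }
      seqs[[edges$child[i]]] <- s
    }
    rows <- do.call(rbind, seqs[seq_along(strains)])
    rownames(rows) <- strains
    if (ensure_variable && length(var_cols)) {
      for (col in var_cols) {
        if (length(unique(rows[, col])) < 2L) {
          r <- sample(nrow(rows), 1L)
          rows[r, col] <- sample(setdiff(AA20, rows[r, col]), 1L)
        }
      }
    }
    list(alignment = apply(rows, 1L, paste, collapse = ""),
         variable_columns = var_cols)
  })
}

#' Plant signal-peptide / transmembrane features into a protein body
#'
#' Modifies a (polar, soluble) body sequence so the built-in secretome
#' heuristics must classify it as the target class:
#' * `secreted`: a 22-residue N-terminal signal segment (hydrophobic
#'   residues from A/L/I/V/F with a charged residue at position 2) is
#'   prepended; the body contributes no transmembrane-character stretch.
#' * `membrane-bound`: the signal segment plus one internal strongly
#'   hydrophobic segment of `tm_length` residues (drawn from L/I/V/F;
#'   default 28, comfortably containing a 19-residue transmembrane core)
#'   inserted at the middle of the body.
#' * `other`: the body is returned unchanged.
#'
#' @param sequence amino-acid body string (>= 30 residues for feature
#'   planting).
#' @param target_class one of `"membrane-bound"`, `"secreted"`, `"other"`.
#' @param seed integer seed.
#' @param signal_length signal-segment length (default 22).
#' @param tm_length hydrophobic-segment length (default 28).
#' @return A list with `sequence`, `class`, `signal_region` (`c(start,end)`
#'   or `NULL`), `tm_region` (`c(start,end)` or `NULL`).
#' @export
plant_protein_features <- function(sequence, target_class, seed = 1L,
                                   signal_length = 22L, tm_length = 28L) {
  target_class <- match.arg(target_class,
                            c("membrane-bound", "secreted", "other"))
  if (target_class == "other")
    return(list(sequence = sequence, class = "other",
                signal_region = NULL, tm_region = NULL))
  if (nchar(sequence) < 30L)
    stop_condition("body sequence shorter than planted feature length",
                   "wolbpan_parameter")
  with_seed(hash_id(seed, "plant", target_class), {
    sig <- c(sample(c("A", "L", "I", "V", "F"), 1L),
             sample(c("K", "R"), 1L),
             sample(c("A", "L", "I", "V", "F"), signal_length - 2L,
                    replace = TRUE))
    sig <- paste(sig, collapse = "")
    if (target_class == "secreted") {
      out <- paste0(sig, sequence)
      list(sequence = out, class = "secreted",
           signal_region = c(1L, signal_length), tm_region = NULL)
    } else {
      mid <- nchar(sequence) %/% 2L
      tm <- random_residues(tm_length, AA_HYDROPHOBIC)
      out <- paste0(sig, substr(sequence, 1L, mid), tm,
                    substr(sequence, mid + 1L, nchar(sequence)))
      tm_start <- signal_length + mid + 1L
      list(sequence = out, class = "membrane-bound",
           signal_region = c(1L, signal_length),
           tm_region = c(tm_start, tm_start + tm_length - 1L))
    }
  })
}
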