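# Strain tree simulation and gene gain/loss along its branches.

#' Sample a rooted strain tree with clade ("supergroup") structure
#'
#' Strains are partitioned into `n_clades` groups of near-equal size; each
#' clade is grown as a random rooted bifurcating subtree and the clade
#' subtrees are joined by a random bifurcating backbone, so every clade is
#' monophyletic by construction. Branch lengths (expected substitutions per
#' site) are drawn uniformly on [0.02, 0.15], emulating the supergroup
#' structure of endosymbiont phylogenies at congeneric divergence scales.
#'
#' @param n_strains number of strains (>= 2).
#' @param n_clades number of clades (1 to `n_strains`).
#' @param seed integer seed; identical calls are byte-identical.
#' @return An object of class `strain_tree`: list with `phylo` (an
#'   [ape::phylo] tree), `clades` (named character vector strain -> clade
#'   label), `newick`.
#' @export
sample_strain_tree <- function(n_strains, n_clades, seed) {
  if (n_strains < 2L)
    stop_condition("n_strains must be >= 2", "wolbpan_parameter")
  if (n_clades < 1L || n_clades > n_strains)
    stop_condition("n_clades must be in [1, n_strains]", "wolbpan_parameter")
  n_strains <- as.integer(n_strains); n_clades <- as.integer(n_clades)
  strains <- sprintf("S%02d", seq_len(n_strains))
  sizes <- rep(n_strains %/% n_clades, n_clades)
  extra <- n_strains %% n_clades
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- rep(sprintf("C%d", seq_len(n_clades)), sizes)
  clades <- stats::setNames(assignment, strains)

  newick <- with_seed(seed, {
    blen <- function() stats::runif(1, 0.02, 0.15)
    join_random <- function(frags) {
      while (length(frags) > 1L) {
        pick <- sample(length(frags), 2L)
        merged <- sprintf("(%s:%.6f,%s:%.6f)", frags[pick[1]], blen(),
                          frags[pick[2]], blen())
        frags <- c(frags[-pick], merged)
      }
      frags
    }
    subtrees <- vapply(split(strains, factor(assignment, unique(assignment))),
                       join_random, character(1))
    paste0(join_random(unname(subtrees)), ";")
  })
  phylo <- ape::read.tree(text = newick)
  structure(list(phylo = phylo, clades = clades, newick = newick),
            class = "strain_tree")
}

#' @export
print.strain_tree <- function(x, ...) {
  cat(sprintf("strain_tree: %d strains in %d clade(s)\n",
              length(x$clades), length(unique(x$clades))))
  invisible(x)
}

# edge table in preorder (parents before children)
tree_edges <- function(phylo) {
  e <- phylo$edge
  df <- data.frame(parent = e[, 1], child = e[, 2],
                   length = phylo$edge.length,
                   is_tip = e[, 2] <= length(phylo$tip.label),
                   label = ifelse(e[, 2] <= length(phylo$tip.label),
                                  phylo$tip.label[e[, 2]], NA_character_),
                   stringsAsFactors = FALSE)
  root <- setdiff(df$parent, df$child)[1]
  done <- root; ord <- integer(0); remaining <- seq_len(nrow(df))
  while (length(remaining)) {
    ready <- remaining[df$parent[remaining] %in% done]
    ord <- c(ord, ready)
    done <- c(done, df$child[ready])
    remaining <- setdiff(remaining, ready)
  }
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "root") <- root
  df
}

#' Simulate gene family gain and loss along a strain tree
#'
#' Core families are present in every strain. Each accessory family starts
#' at the root as present with probability `accessory_root_prob` and then
#' flips state along each branch at most once: an absent family is gained
#' with probability `1 - exp(-gain_rate * branch_length)`, a present family
#' lost with probability `1 - exp(-loss_rate * branch_length)` (at most one
#' Poisson event per family per branch — simple and analytically
#' checkable). All events are logged and the resulting presence-absence
#' truth table is part of the simulation manifest. A gain on a clade's stem
#' branch with no later events makes the family present in exactly that
#' clade's leaves, producing the clade-specific presence-absence patterns
#' seen in real strain panels.
#'
#' @param tree a [sample_strain_tree()] result.
#' @param n_core,n_accessory family counts (>= 0).
#' @param gain_rate,loss_rate per-branch event rates (>= 0).
#' @param seed integer seed.
#' @param accessory_root_prob probability an accessory family is present at
#'   the root (default 0.5).
#' @return A list with `gene_sets` (strain -> character vector of family
#'   ids present), `pav_truth` (logical family x strain matrix), `events`
#'   (data.frame family, edge, parent, child, type), `families`
#'   (data.frame id, type), `edges` (the preorder edge table).
#' @export
simulate_gene_content <- function(tree, n_core, n_accessory, gain_rate = 0.5,
                                  loss_rate = 0.3, seed = 1L,
                                  accessory_root_prob = 0.5) {
  if (gain_rate < 0 || loss_rate < 0)
    stop_condition("rates must be >= 0", "wolbpan_parameter")
  if (n_core < 0 || n_accessory < 0)
    stop_condition("family counts must be >= 0", "wolbpan_parameter")
  phylo <- tree$phylo
  strains <- phylo$tip.label
  fam_core <- if (n_core) sprintf("fam%04d", seq_len(n_core)) else character(0)
  fam_acc <- if (n_accessory) sprintf("fam%04d", n_core + seq_len(n_accessory))
             else character(0)
  families <- data.frame(id = c(fam_core, fam_acc),
                         type = rep(c("core", "accessory"), c(n_core, n_accessory)),
                         stringsAsFactors = FALSE)
  pav <- matrix(FALSE, nrow = nrow(families), ncol = length(strains),
                dimnames = list(families$id, strains))
  if (n_core) pav[fam_core, ] <- TRUE
  edges <- tree_edges(phylo)
  root <- attr(edges, "root")
  nnode <- max(c(edges$parent, edges$child))
  event_rows <- list()
  for (fam in fam_acc) {
    res <- with_seed(hash_id(seed, "gene_content", fam), {
      states <- rep(NA, nnode)
      states[root] <- stats::runif(1) < accessory_root_prob
      rows <- list()
      for (i in seq_len(nrow(edges))) {
        p <- edges$parent[i]; ch <- edges$child[i]; len <- edges$length[i]
        s <- states[p]
        if (!s && stats::runif(1) < 1 - exp(-gain_rate * len)) {
          s <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, edge = i, parent = p, child = ch, type = "gain",
            stringsAsFactors = FALSE)
        } else if (s && stats::runif(1) < 1 - exp(-loss_rate * len)) {
          s <- FALSE
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, edge = i, parent = p, child = ch, type = "loss",
            stringsAsFactors = FALSE)
        }
        states[ch] <- s
      }
      list(states = states, rows = rows)
    })
    event_rows <- c(event_rows, res$rows)
    pav[fam, ] <- res$states[seq_along(strains)]
  }
  events <- if (length(event_rows)) do.call(rbind, event_rows)
            else data.frame(family = character(0), edge = integer(0),
                            parent = integer(0), child = integer(0),
                            type = character(0), stringsAsFactors = FALSE)
  gene_sets <- lapply(strains, function(s) families$id[pav[, s]])
  names(gene_sets) <- strains
  list(gene_sets = gene_sets, pav_truth = pav, events = events,
       families = families, edges = edges)
}
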