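# Orthogroup inference across strains.
#
# Lightweight reciprocal-best-hit (RBH) inference: proteins are fingerprinted
# by amino-acid k-mer multisets, scored by multiset Jaccard similarity,
# best-hit edges are kept per ordered strain pair, reciprocal edges form a
# graph whose connected components are the orthogroups. This replaces an
# external MCL-based orthology tool at desk scale; externally computed
# orthogroup tables can be ingested with read_orthogroup_table() instead.

protein_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, 1:n, k:nchar(seq))
}

#' k-mer multiset Jaccard similarity of two proteins
#'
#' Fingerprints both sequences as multisets of overlapping amino-acid k-mers
#' and returns the multiset Jaccard index (sum of per-k-mer minimum counts
#' over sum of maximum counts). Symmetric, 1 for identical sequences, 0 for
#' disjoint fingerprints.
#'
#' @param protein_a,protein_b amino-acid strings.
#' @param k word size (default 4).
#' @return Similarity in `[0, 1]`.
#' @section Errors: a sequence shorter than `k` signals a condition of class
#'   `wolbpan_too_short`.
#' @export
#' @examples
#' pairwise_similarity("ACDEFGH", "ACDEFGY", k = 4)  # 3/5
pairwise_similarity <- function(protein_a, protein_b, k = 4L) {
  if (nchar(protein_a) < k || nchar(protein_b) < k)
    stop_condition(sprintf("sequence shorter than k = %d", k),
                   "wolbpan_too_short")
  multiset_jaccard(kmer_count_vec(protein_a, k), kmer_count_vec(protein_b, k))
}

kmer_count_vec <- function(seq, k) {
  r <- rle(sort(protein_kmers(seq, k)))
  stats::setNames(r$lengths, r$values)
}

multiset_jaccard <- function(ka, kb) {
  common <- intersect(names(ka), names(kb))
  inter <- sum(pmin(ka[common], kb[common]))
  union <- sum(ka) + sum(kb) - inter
  as.numeric(inter / union)
}

# Occurrence-indexed k-mer keys: the i-th occurrence of a k-mer within one
# protein becomes key "<kmer>#i", so binary set intersection of keys equals
# the multiset k-mer intersection exactly.
occurrence_keys <- function(kmers) {
  if (!length(kmers)) return(character(0))
  ord <- order(kmers)
  r <- rle(kmers[ord])
  idx <- unlist(lapply(r$lengths, seq_len), use.names = FALSE)
  keys <- paste0(kmers[ord], "#", idx)
  keys[order(ord)]
}

#' Infer orthogroups by reciprocal best hits
#'
#' For every ordered pair of strains, each gene's best hit (highest
#' [pairwise_similarity()], score at least `min_score`, ties broken by the
#' lexicographically smallest gene id) is recorded; reciprocal best-hit
#' edges are kept and orthogroups are the connected components of the
#' resulting graph. Genes without any reciprocal hit become singleton
#' orthogroups. Output is invariant to strain enumeration order.
#'
#' @param proteomes named list (strain id -> [seq_set()] of proteins). Gene
#'   ids must be globally unique.
#' @param min_score minimum similarity for a best-hit edge (default 0.2).
#' @param k k-mer word size (default 4).
#' @return A list of [orthogroup()] objects, ids `OG0000001...` assigned in
#'   order of each group's smallest gene id, with a `strains` attribute.
#' @export
infer_orthogroups <- function(proteomes, min_score = 0.2, k = 4L) {
  stopifnot(is.list(proteomes), length(proteomes) >= 2L)
  strains <- names(proteomes)
  for (s in strains)
    if (nrow(proteomes[[s]]) == 0L)
      stop_condition(sprintf("empty proteome for strain '%s'", s),
                     "wolbpan_parameter")
  genes <- unlist(lapply(proteomes, function(p) p$id), use.names = FALSE)
  if (anyDuplicated(genes))
    stop_condition(sprintf("gene id '%s' occurs in more than one proteome",
                           genes[duplicated(genes)][1]), "wolbpan_format")
  gene_strain <- rep(strains, vapply(proteomes, nrow, integer(1)))
  seqs <- unlist(lapply(proteomes, function(p) p$seq), use.names = FALSE)

  # sparse gene x occurrence-indexed-kmer incidence matrix
  keys <- lapply(seqs, function(s) occurrence_keys(protein_kmers(s, k)))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  i <- rep(seq_along(genes), lengths(keys))
  j <- match(unlist(keys, use.names = FALSE), all_keys)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(genes), length(all_keys)))
  inter <- Matrix::tcrossprod(X)
  sizes <- Matrix::rowSums(X)
  trip <- as.data.frame(Matrix::summary(inter))
  trip <- trip[trip$i != trip$j, , drop = FALSE]
  # tcrossprod of X is symmetric and stored as one triangle; restore both
  # directed orientations so best hits exist for every source gene
  trip <- rbind(trip, data.frame(i = trip$j, j = trip$i, x = trip$x))
  jac <- trip$x / (sizes[trip$i] + sizes[trip$j] - trip$x)
  cross <- gene_strain[trip$i] != gene_strain[trip$j]
  ok <- cross & jac >= min_score
  cand <- data.frame(from = trip$i[ok], to = trip$j[ok], score = jac[ok])

  edges <- character(0)
  if (nrow(cand)) {
    # best hit per (source gene, target strain); tie -> smallest target gene id
    ord <- order(genes[cand$from], gene_strain[cand$to], -cand$score,
                 genes[cand$to])
    cand <- cand[ord, , drop = FALSE]
    first <- !duplicated(paste(cand$from, gene_strain[cand$to], sep = "\r"))
    best <- cand[first, , drop = FALSE]
    key_fwd <- paste(best$from, best$to, sep = "\r")
    key_rev <- paste(best$to, best$from, sep = "\r")
    recip <- key_fwd %in% key_rev
    edges <- best[recip, c("from", "to")]
  }

  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  if (is.data.frame(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(as.matrix(edges)))
  comp <- igraph::components(g)$membership

  groups <- split(seq_along(genes), comp)
  min_gene <- vapply(groups, function(ix) min(genes[ix]), character(1))
  groups <- groups[order(min_gene)]
  ogs <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ix <- groups[[gi]]
    members <- lapply(strains, function(s) sort(genes[ix][gene_strain[ix] == s]))
    names(members) <- strains
    ogs[[gi]] <- orthogroup(sprintf("OG%07d", gi), members)
  }
  attr(ogs, "strains") <- strains
  ogs
}

#' Extract single-copy orthologs
#'
#' Returns the ids of orthogroups with exactly one member gene in every
#' strain — the SCOs used as the basis for strain phylogenies.
#'
#' @param orthogroups list of [orthogroup()] objects.
#' @param strains strain ids that must each contribute exactly one gene.
#' @return Character vector of orthogroup ids.
#' @export
extract_scos <- function(orthogroups, strains) {
  keep <- vapply(orthogroups, function(o) {
    counts <- vapply(strains, function(s) length(o$members[[s]] %||% character(0)),
                     integer(1))
    all(counts == 1L)
  }, logical(1))
  vapply(orthogroups[keep], function(o) o$og_id, character(1))
}

#' Build a presence-absence variation (PAV) matrix
#'
#' One row per orthogroup (sorted by id), one column per strain in the
#' declared order; cells hold gene copy counts (presence = count >= 1).
#'
#' @param orthogroups list of [orthogroup()] objects.
#' @param strains fixed strain column order.
#' @return An integer matrix of class `pav_matrix` (rows = orthogroup ids,
#'   columns = strains).
#' @export
build_pav <- function(orthogroups, strains) {
  ids <- vapply(orthogroups, function(o) o$og_id, character(1))
  ord <- order(ids)
  orthogroups <- orthogroups[ord]; ids <- ids[ord]
  m <- matrix(0L, nrow = length(ids), ncol = length(strains),
              dimnames = list(ids, strains))
  for (i in seq_along(orthogroups)) {
    o <- orthogroups[[i]]
    extra <- setdiff(names(o$members), strains)
    if (length(extra))
      stop_condition(sprintf("orthogroup %s has member strain '%s' not in the declared strain list",
                             o$og_id, extra[1]), "wolbpan_parameter")
    for (s in names(o$members)) m[i, s] <- length(o$members[[s]])
  }
  class(m) <- c("pav_matrix", class(m))
  m
}

pav_presence <- function(pav) unclass(pav) >= 1L
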