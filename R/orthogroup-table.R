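# Orthogroup containers and the OrthoFinder-style Orthogroups.tsv dialect.

#' Construct an orthogroup
#'
#' An orthogroup is the set of genes, across strains, descended from a single
#' gene in the strains' last common ancestor. Here it is a strain-to-genes
#' mapping plus an optional protein alignment whose rows map 1:1 to member
#' genes.
#'
#' @param og_id orthogroup identifier.
#' @param members named list, strain id -> character vector of gene ids
#'   (possibly empty per strain).
#' @param alignment optional named character vector (one equal-length row per
#'   member gene, names = gene ids).
#' @return An object of class `orthogroup`.
#' @export
orthogroup <- function(og_id, members, alignment = NULL) {
  stopifnot(is.list(members), !is.null(names(members)))
  genes <- unlist(members, use.names = FALSE)
  if (length(genes) < 1L)
    stop_condition(sprintf("orthogroup %s has no members", og_id),
                   "wolbpan_parameter")
  if (!is.null(alignment)) {
    if (length(unique(nchar(alignment))) != 1L)
      stop_condition("alignment rows have unequal lengths", "wolbpan_format")
    if (!setequal(names(alignment), genes))
      stop_condition("alignment rows do not map 1:1 to member genes",
                     "wolbpan_format")
  }
  structure(list(og_id = og_id, members = members, alignment = alignment),
            class = "orthogroup")
}

#' @export
print.orthogroup <- function(x, ...) {
  n <- sum(lengths(x$members))
  cat(sprintf("orthogroup %s: %d gene(s) across %d strain(s)%s\n", x$og_id, n,
              sum(lengths(x$members) > 0),
              if (is.null(x$alignment)) "" else " [aligned]"))
  invisible(x)
}

#' Read an OrthoFinder-style orthogroup table
#'
#' Consumes the `Orthogroup<TAB>strain...` TSV dialect in which each cell is a
#' comma-space-separated gene list and empty cells denote absence. A gene id
#' occurring in two orthogroups is a format error.
#'
#' @param path path to the TSV file (header row required).
#' @return A list of [orthogroup()] objects with a `strains` attribute giving
#'   the fixed column order.
#' @export
read_orthogroup_table <- function(path) {
  if (!file.exists(path))
    stop_condition(sprintf("no such file: %s", path), "wolbpan_io")
  lines <- readLines(path)
  if (length(lines) < 1L)
    stop_condition("orthogroup table lacks a header row", "wolbpan_format")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  strains <- header[-1]
  if (length(strains) < 1L)
    stop_condition("orthogroup table has no strain columns", "wolbpan_format")
  seen <- new.env(parent = emptyenv())
  ogs <- vector("list", length(lines) - 1L)
  for (i in seq_along(ogs)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    length(f) <- length(strains) + 1L
    f[is.na(f)] <- ""
    members <- lapply(f[-1], function(cell) {
      if (!nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(members) <- strains
    for (g in unlist(members, use.names = FALSE)) {
      if (!is.null(seen[[g]]))
        stop_condition(sprintf("gene '%s' appears in orthogroups %s and %s",
                               g, seen[[g]], f[[1]]), "wolbpan_format")
      seen[[g]] <- f[[1]]
    }
    ogs[[i]] <- orthogroup(f[[1]], members)
  }
  attr(ogs, "strains") <- strains
  ogs
}

#' Write orthogroups in the OrthoFinder table dialect
#'
#' @param ogs list of [orthogroup()] objects.
#' @param path output path.
#' @param strains strain column order; defaults to the `strains` attribute of
#'   `ogs` or the union of member strains (sorted).
#' @return `path`, invisibly.
#' @export
write_orthogroup_table <- function(ogs, path, strains = NULL) {
  strains <- strains %||% attr(ogs, "strains") %||%
    sort(unique(unlist(lapply(ogs, function(o) names(o$members)))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("Orthogroup", strains), collapse = "\t"), con)
  for (o in ogs) {
    cells <- vapply(strains, function(s)
      paste(o$members[[s]] %||% character(0), collapse = ", "), character(1))
    writeLines(paste(c(o$og_id, cells), collapse = "\t"), con)
  }
  invisible(path)
}
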