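# Per-column Shannon entropy of orthogroup protein alignments, variable-site
# counting, class-wise variability summaries, and per-effector reports.

alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop_condition("ragged alignment: rows have unequal lengths",
                   "wolbpan_format")
  do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum(p_a * log2(p_a))` over the amino acids observed in the column,
#' with frequencies computed over non-gap, non-X residues (`-`, `.`, `X` and
#' `*` are excluded). A column with fewer than `min_coverage` informative
#' residues is undefined (`NA`) — this keeps indel-rich columns represented
#' by a single residue from being called variable.
#'
#' @param column character vector of single residues (with gaps).
#' @param min_coverage minimum informative residues (default 2).
#' @return Entropy in bits (`0` to `log2(20)`), or `NA` when undefined.
#' @export
#' @examples
#' column_entropy(c("A", "A", "V", "V"))      # 1 bit
#' column_entropy(c("A", "A", "A", "V", "V")) # 0.971 bits
column_entropy <- function(column, min_coverage = 2L) {
  if (!length(column))
    stop_condition("empty alignment column", "wolbpan_parameter")
  res <- toupper(column)
  res <- res[!res %in% c("-", ".", "X", "*")]
  if (length(res) < min_coverage) return(NA_real_)
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

#' Entropy profile of an orthogroup alignment
#'
#' Computes per-column Shannon entropies and flags a column as a variable
#' site when its entropy exceeds `variable_threshold` (the default 0 flags
#' any column with at least two distinct observed residues).
#'
#' @param alignment named character vector of equal-length rows (or a
#'   character matrix).
#' @param variable_threshold entropy cutoff in bits (default 0).
#' @param min_coverage minimum informative residues per column (default 2).
#' @param og_id optional orthogroup id carried in the result.
#' @return A list of class `entropy_profile` with fields og_id,
#'   column_entropies, column_coverage, variable_flags, n_variable,
#'   fraction_variable, length.
#' @export
entropy_profile <- function(alignment, variable_threshold = 0,
                            min_coverage = 2L, og_id = NA_character_) {
  m <- alignment_matrix(alignment)
  ent <- apply(m, 2L, column_entropy, min_coverage = min_coverage)
  cov <- apply(m, 2L, function(col) sum(!col %in% c("-", ".", "X", "*")))
  flags <- !is.na(ent) & ent > variable_threshold
  structure(list(
    og_id = og_id,
    column_entropies = unname(ent),
    column_coverage = unname(cov),
    variable_flags = unname(flags),
    n_variable = sum(flags),
    fraction_variable = sum(flags) / ncol(m),
    length = ncol(m)), class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy_profile %s: %d columns, %d variable site(s) (%.1f%%)\n",
              x$og_id, x$length, x$n_variable, 100 * x$fraction_variable))
  invisible(x)
}

even_median <- function(x) {
  # median with the even-count rule made explicit: mean of the two central
  # order statistics, so half-integer medians (e.g. {13,14} -> 13.5) are
  # representable
  if (!length(x)) return(NA_real_)
  s <- sort(x); n <- length(s)
  if (n %% 2L == 1L) as.numeric(s[(n + 1L) %/% 2L])
  else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' Summarize variable-site counts by protein class
#'
#' Produces per-class orthogroup counts and median variable-site counts
#' (classes membrane-bound / secreted / other plus an `"all"` aggregate), a
#' histogram table of variable-site counts per class, and the count of
#' zero-variable orthogroups. Zero-variable orthogroups contribute to the
#' medians but are excluded from the histogram and counted separately,
#' matching the usual display convention for such distributions.
#'
#' @param profiles named list of [entropy_profile()]s (names = orthogroup
#'   ids).
#' @param orthogroup_classes named character vector, orthogroup id -> class.
#' @return A list of class `variability_summary` with `per_class`
#'   (data.frame class, n_orthogroups, median_n_variable, n_zero_variable),
#'   `histogram` (data.frame class, n_variable, count; zero-variable rows
#'   omitted), and `n_zero_variable_orthogroups`.
#' @export
summarize_variability <- function(profiles, orthogroup_classes) {
  if (!length(profiles))
    stop_condition("empty profile set", "wolbpan_parameter")
  ids <- names(profiles) %||% vapply(profiles, function(p) p$og_id, character(1))
  nv <- vapply(profiles, function(p) p$n_variable, numeric(1))
  cls <- unname(orthogroup_classes[ids])
  if (anyNA(cls))
    stop_condition("every profile needs a class label", "wolbpan_parameter")
  levels <- c("all", "membrane-bound", "secreted", "other")
  rows <- lapply(levels, function(cl) {
    x <- if (cl == "all") nv else nv[cls == cl]
    data.frame(class = cl, n_orthogroups = length(x),
               median_n_variable = even_median(x),
               n_zero_variable = sum(x == 0),
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  hist_rows <- lapply(levels, function(cl) {
    x <- if (cl == "all") nv else nv[cls == cl]
    x <- x[x > 0]
    if (!length(x)) return(NULL)
    t <- table(x)
    data.frame(class = cl, n_variable = as.integer(names(t)),
               count = as.integer(t), stringsAsFactors = FALSE)
  })
  structure(list(per_class = per_class,
                 histogram = do.call(rbind, hist_rows),
                 n_zero_variable_orthogroups = sum(nv == 0)),
            class = "variability_summary")
}

#' @export
print.variability_summary <- function(x, ...) {
  cat("variability_summary\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("zero-variable orthogroups (excluded from histogram): %d\n",
              x$n_zero_variable_orthogroups))
  invisible(x)
}

#' Variable-site report for named effector-like orthogroups
#'
#' Matches `name_patterns` (regular expressions) against orthogroup
#' annotation labels and reports, per matched orthogroup, the number of
#' variable sites, the full alignment length (the denominator includes
#' gap-containing columns) and the percentage rounded to the nearest whole
#' percent.
#'
#' @param profiles named list of [entropy_profile()]s.
#' @param name_patterns character vector of regular expressions.
#' @param labels optional named character vector (orthogroup id ->
#'   annotation label); defaults to the profile names themselves.
#' @return data.frame with columns orthogroup, label, alignment_length,
#'   n_variable, percent_variable. Empty (with a warning) when nothing
#'   matches.
#' @export
effector_report <- function(profiles, name_patterns, labels = NULL) {
  ids <- names(profiles)
  labels <- labels %||% stats::setNames(ids, ids)
  hit <- vapply(ids, function(id) {
    lab <- labels[[id]] %||% id
    any(vapply(name_patterns, grepl, logical(1), x = lab, ignore.case = TRUE))
  }, logical(1))
  if (!any(hit)) {
    warning("no orthogroup matched the given name patterns")
    return(data.frame(orthogroup = character(0), label = character(0),
                      alignment_length = integer(0), n_variable = integer(0),
                      percent_variable = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(ids[hit], function(id) {
    p <- profiles[[id]]
    data.frame(orthogroup = id, label = labels[[id]] %||% id,
               alignment_length = p$length, n_variable = p$n_variable,
               percent_variable = as.integer(round_half_up(100 * p$fraction_variable, 0)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
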