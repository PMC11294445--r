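# Internal helpers: seeded sub-streams, small string utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable integer hash of identifiers
#'
#' Deterministic djb2-style hash reduced modulo 2^31 - 1, used to derive
#' independent random sub-streams per strain/family/read from one root seed so
#' that simulation output does not depend on iteration order.
#'
#' @param ... atomic values concatenated into the hash key.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @keywords internal
hash_id <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Reverse complement of a nucleotide string
#'
#' @param x character scalar over the IUPAC nucleotide alphabet.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' revcomp("ACGGT")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

stop_condition <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "wolbpan_error")))
}

format_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

# Deterministic TSV writer (no quoting surprises, fixed EOLs).
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(seq_len(ncol(df)), function(j) {
      col <- df[[j]]
      if (is.numeric(col) && !is.integer(col)) format_num(col)
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
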