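# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (frequency tables, raw difference
# strings, exhaustive DP) rather than calling the implementation paths they
# check.

# Shannon entropy of a residue column: frequency table + formula.
oracle_entropy <- function(column, min_coverage = 2L) {
  res <- toupper(column)
  res <- res[!res %in% c("-", ".", "X", "*")]
  if (length(res) < min_coverage) return(NA_real_)
  freqs <- as.numeric(table(res)) / length(res)
  -sum(freqs * log2(freqs))
}

# Gap-compressed divergence recomputed from the raw cs difference string.
oracle_divergence_from_cs <- function(cs) {
  toks <- regmatches(cs, gregexpr(":[0-9]+|\\*[a-z]{2}|\\+[a-z]+|-[a-z]+", cs))[[1]]
  match <- 0L; mm <- 0L; gaps <- 0L
  for (t in toks) {
    tag <- substr(t, 1, 1)
    if (tag == ":") match <- match + as.integer(substr(t, 2, nchar(t)))
    else if (tag == "*") mm <- mm + 1L
    else gaps <- gaps + 1L
  }
  (mm + gaps) / (match + mm + gaps)
}

# Optimal global alignment score by exhaustive dynamic programming with
# affine gaps costing open + extend * length (2 + L), match +1, mismatch -1.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                open = 2, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (av[i] == bv[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                            Ix[i, j + 1] - extend)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                            Iy[i + 1, j] - extend)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Score of a pairwise alignment given as two gapped rows, same cost model.
score_gapped_pair <- function(x, y, match = 1, mismatch = -1,
                              open = 2, extend = 1) {
  xv <- strsplit(x, "")[[1]]; yv <- strsplit(y, "")[[1]]
  stopifnot(length(xv) == length(yv))
  s <- 0; in_gap_x <- FALSE; in_gap_y <- FALSE
  for (i in seq_along(xv)) {
    if (xv[i] == "-") {
      s <- s - extend - (if (!in_gap_x) open else 0)
      in_gap_x <- TRUE; in_gap_y <- FALSE
    } else if (yv[i] == "-") {
      s <- s - extend - (if (!in_gap_y) open else 0)
      in_gap_y <- TRUE; in_gap_x <- FALSE
    } else {
      s <- s + (if (xv[i] == yv[i]) match else mismatch)
      in_gap_x <- FALSE; in_gap_y <- FALSE
    }
  }
  s
}

random_polar_body <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("S", "T", "G", "N", "Q", "E", "D", "K", "R", "P"), n,
               replace = TRUE), collapse = "")
}

# circular distance between two coordinates on a genome of length L
circ_dist <- function(x, y, L) {
  d <- abs(x - y) %% L
  pmin(d, L - d)
}
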