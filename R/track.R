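# BED-like window-track serialization (0-based, half-open coordinates).

#' Write a window track as a BED-like TSV
#'
#' Columns are seqid, start, end, value, window id. Coordinates are 0-based
#' and half-open. A wrap-around window on a circular genome (internal
#' representation `end > genome length`) is emitted as two lines sharing the
#' same window id. Values are printed with 6 decimals; missing values as
#' `NA`.
#'
#' @param track a `window_track` from [windowed_profile()], or a data.frame
#'   with columns seqid, start, end, value (sorted by start).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  if (is.unsorted(track$start))
    stop_condition("track windows must be sorted by start", "wolbpan_parameter")
  glen <- attr(track, "genome_length") %||% Inf
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(track))) {
    id <- sprintf("w%06d", i)
    s <- track$start[i]; e <- track$end[i]
    v <- format_num(track$value[i])
    if (e > glen) {
      writeLines(sprintf("%s\t%d\t%d\t%s\t%s", track$seqid[i], s, glen, v, id), con)
      writeLines(sprintf("%s\t%d\t%d\t%s\t%s", track$seqid[i], 0L, e - glen, v, id), con)
    } else {
      writeLines(sprintf("%s\t%d\t%d\t%s\t%s", track$seqid[i], s, e, v, id), con)
    }
  }
  invisible(path)
}

#' Read a track TSV written by [write_track()]
#'
#' Lines sharing a window id (a wrap-around window split in two) are rejoined
#' into one window with `end > genome length` when `genome_length` is given.
#'
#' @param path input path.
#' @param genome_length optional circular genome length used to rejoin
#'   wrap-around windows.
#' @return A data.frame with columns seqid, start, end, value, id.
#' @export
read_track <- function(path, genome_length = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("seqid", "start", "end", "value", "id"),
                          na.strings = "NA")
  if (!is.null(genome_length) && anyDuplicated(df$id)) {
    split_ids <- unique(df$id[duplicated(df$id)])
    keep <- !duplicated(df$id)
    for (w in split_ids) {
      parts <- df[df$id == w, ]
      i <- which(keep & df$id == w)
      df$start[i] <- max(parts$start)
      df$end[i] <- genome_length + min(parts$end[parts$start == 0])
    }
    df <- df[keep, ]
    rownames(df) <- NULL
  }
  df
}
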