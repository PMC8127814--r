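#' Read / write reference-anchored alignments (MAF, UCSC dialect)
#'
#' Each block is a data.frame of rows `(species, seqname, start, size,
#' strand, src_size, text)` with the reference species as the first row.
#' MAF "s" line sources of the form `species.seqname` are split on the
#' first dot. Minus-strand rows keep the MAF convention (start is an
#' offset on the reverse-complemented source); the normalized
#' forward-strand interval is available via [row_forward_interval()].
#'
#' @param path file path.
#' @return list of `AlignmentBlock` data.frames (empty list for an empty
#'   file).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, k) {
    if (is.null(cur) || length(cur) == 0L) return(NULL)
    df <- do.call(rbind, cur)
    if (length(unique(nchar(df$text))) != 1L)
      stop("row length mismatch within MAF block ", k)
    ok <- nchar(gsub("-", "", df$text, fixed = TRUE)) == df$size
    if (!all(ok))
      stop("ungapped size disagrees with text in MAF block ", k)
    class(df) <- c("AlignmentBlock", "data.frame")
    df
  }
  k <- 0L
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      k <- k + 1L
      b <- flush(cur, k - 1L)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list()
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L) stop("malformed MAF s-line: ", ln)
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      sp <- if (dot > 0) substr(src, 1L, dot - 1L) else src
      sq <- if (dot > 0) substr(src, dot + 1L, nchar(src)) else src
      cur[[length(cur) + 1L]] <- data.frame(
        species = sp, seqname = sq, start = as.integer(f[3]),
        size = as.integer(f[4]), strand = f[5],
        src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE)
    }
  }
  b <- flush(cur, k)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' @rdname read_maf
#' @param blocks list of `AlignmentBlock`s.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a score=0", con)
    writeLines(sprintf("s %s.%s %d %d %s %d %s", b$species, b$seqname,
                       b$start, b$size, b$strand, b$src_size, b$text), con)
  }
  invisible(path)
}

#' Forward-strand source interval of one alignment row
#'
#' For "+" rows this is `[start, start+size)`. For "-" rows the MAF start
#' is an offset on the reverse complement, so the forward interval is
#' `[src_size - start - size, src_size - start)`.
#'
#' @param row one row of an `AlignmentBlock`.
#' @return integer vector `c(start, end)`, 0-based half-open.
#' @export
row_forward_interval <- function(row) {
  if (row$strand == "+") c(row$start, row$start + row$size)
  else c(row$src_size - row$start - row$size, row$src_size - row$start)
}

## Per-row map from gapped columns to forward-strand source offsets.
## Returns an integer matrix (ncol = alignment width, nrow = block rows),
## NA where the row is gapped.  Bijective onto the row's source interval.
block_pos_map <- function(block) {
  w <- nchar(block$text[1])
  out <- matrix(NA_integer_, nrow = nrow(block), ncol = w)
  for (i in seq_len(nrow(block))) {
    ch <- strsplit(block$text[i], "", fixed = TRUE)[[1]]
    ung <- ch != "-"
    idx <- cumsum(ung)
    if (block$strand[i] == "+") {
      pos <- block$start[i] + idx - 1L
    } else {
      fwd_end <- block$src_size[i] - block$start[i]
      pos <- fwd_end - idx
    }
    out[i, ung] <- pos[ung]
  }
  out
}

## character matrix (rows = block rows) of alignment columns
block_char_matrix <- function(block) {
  do.call(rbind, strsplit(block$text, "", fixed = TRUE))
}
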