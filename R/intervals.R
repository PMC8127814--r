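#' Construct a table of genomic intervals
#'
#' All coordinates in this package are 0-based half-open (`[start, end)`),
#' the BED convention. GFF3 input is converted on read.
#'
#' @param seqname character vector of sequence names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand "+" or "-" (recycled).
#' @param name,score optional feature names and numeric scores.
#' @return a data.frame with class `c("intervals", "data.frame")`.
#' @export
intervals <- function(seqname, start, end, strand = "+", name = NA_character_,
                      score = NA_real_) {
  if (length(seqname) == 0L) {
    out <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("intervals", "data.frame")
    return(out)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing integers")
  if (any(start < 0L)) stop("negative interval start")
  if (any(start >= end)) stop("interval start must be < end")
  out <- data.frame(seqname = as.character(seqname), start = start, end = end,
                    strand = rep_len(as.character(strand), length(start)),
                    name = rep_len(as.character(name), length(start)),
                    score = rep_len(as.numeric(score), length(start)),
                    stringsAsFactors = FALSE)
  class(out) <- c("intervals", "data.frame")
  out
}

#' Width of each interval
#' @param x an `intervals` table.
#' @return integer vector of lengths (`end - start`).
#' @export
interval_width <- function(x) x$end - x$start

## Merge overlapping/touching intervals on one sequence; returns matrix cols start,end
merge_spans <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- integer(); oute <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(outs, ms), end = c(oute, me))
}

#' Fraction of an interval covered by a set of hit intervals
#'
#' Computes `|union(hits) ∩ a| / |a|`. Hits on other sequences are
#' ignored; an empty hit set gives 0.
#'
#' @param a a single-row `intervals` table (or list with seqname/start/end).
#' @param hits an `intervals` table.
#' @return numeric fraction in \[0, 1\].
#' @export
coverage_fraction <- function(a, hits) {
  stopifnot(nrow(a) == 1L || (is.list(a) && !is.null(a$start)))
  if (is.data.frame(a)) a <- as.list(a[1, ])
  if (is.null(hits) || nrow(hits) == 0L) return(0)
  h <- hits[hits$seqname == a$seqname, , drop = FALSE]
  if (nrow(h) == 0L) return(0)
  s <- pmax(h$start, a$start); e <- pmin(h$end, a$end)
  keep <- s < e
  if (!any(keep)) return(0)
  m <- merge_spans(s[keep], e[keep])
  sum(m[, "end"] - m[, "start"]) / (a$end - a$start)
}

## which rows of `x` overlap span [s,e) on sequence `seqname`
overlapping_idx <- function(x, seqname, s, e) {
  which(x$seqname == seqname & x$start < e & x$end > s)
}
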