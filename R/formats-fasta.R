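#' Genome set: the sequences of one species plus assembly-gap annotation
#'
#' Sequences are stored uppercase over the alphabet {A,C,G,T,N}. Lower-case
#' (soft-masked) input is uppercased and remembered in a mask track; other
#' IUPAC ambiguity codes are converted to N with a warning. Runs of N of
#' length >= `min_n_run` are recorded as assembly gaps (`n_gaps`) — the
#' operational definition of a sequencing gap used by the gap-free filter.
#'
#' @param species_id short species label (e.g. "hipCom0").
#' @param sequences named character vector of DNA strings.
#' @param min_n_run minimum run of N treated as an assembly gap (default 10).
#' @return an object of class `GenomeSet`.
#' @export
genome_set <- function(species_id, sequences, min_n_run = 10L) {
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence names in genome for ", species_id)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named")
  if (any(nchar(sequences) == 0L)) stop("empty sequence in genome")
  mask <- lapply(sequences, function(s) {
    find_char_runs(s, "[acgtn]")
  })
  up <- toupper(sequences)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    warning("non-ACGTN characters converted to N in ",
            sum(bad), " sequence(s) of ", species_id)
    up[bad] <- gsub("[^ACGTN]", "N", up[bad])
  }
  obj <- list(species_id = species_id, sequences = up,
              n_gaps = lapply(up, function(s) n_run_spans(s, min_n_run)),
              mask = mask, min_n_run = as.integer(min_n_run))
  class(obj) <- "GenomeSet"
  obj
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat("GenomeSet", x$species_id, ":", length(x$sequences), "sequence(s),",
      sum(nchar(x$sequences)), "bp,",
      sum(vapply(x$n_gaps, nrow, 1L)), "N-gap(s)\n")
  invisible(x)
}

## spans (0-based half-open matrix) of regex-matched runs in a string
find_char_runs <- function(s, pattern) {
  m <- gregexpr(paste0("(", pattern, ")+"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(cbind(start = integer(), end = integer()))
  st <- as.integer(m) - 1L
  cbind(start = st, end = st + attr(m, "match.length"))
}

## maximal runs of N with length >= min_run
n_run_spans <- function(s, min_run) {
  r <- find_char_runs(s, "N")
  r[r[, "end"] - r[, "start"] >= min_run, , drop = FALSE]
}

#' Read / write FASTA genomes
#'
#' @param path file path.
#' @param species_id label attached to the resulting `GenomeSet`
#'   (defaults to the file base name).
#' @param min_n_run assembly-gap definition, see [genome_set()].
#' @return `read_fasta` returns a `GenomeSet`; `write_fasta` returns the
#'   path invisibly. Round trips are identical up to line wrapping.
#' @export
read_fasta <- function(path, species_id = NULL, min_n_run = 10L) {
  if (is.null(species_id))
    species_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(ss))) stop("duplicate sequence names in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_set(species_id, seqs, min_n_run = min_n_run)
}

#' @rdname read_fasta
#' @param genome a `GenomeSet`.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$sequences)) {
    s <- genome$sequences[[nm]]
    writeLines(paste0(">", nm), con)
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
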