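## codon prefixes whose third position is fourfold degenerate
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings (ACGTN, case-insensitive).
#' @return reverse-complemented uppercase strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "",
                       fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

## index the reference rows of a block list: for each reference sequence, a
## table of (block id, ref start, ref end) sorted by start, plus cached
## position maps and character matrices, built lazily by callers.
ref_block_index <- function(blocks, ref_species = NULL) {
  if (length(blocks) == 0L) return(list(species = character(), tab = list()))
  if (is.null(ref_species)) ref_species <- blocks[[1]]$species[1]
  tabs <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (b$species[1] != ref_species) next
    iv <- row_forward_interval(b[1, ])
    sq <- b$seqname[1]
    tabs[[sq]] <- rbind(tabs[[sq]],
                        data.frame(block = i, start = iv[1], end = iv[2]))
  }
  tabs <- lapply(tabs, function(t) t[order(t$start), , drop = FALSE])
  list(species = ref_species, tab = tabs)
}

## find (block, column) for a reference position; NA if uncovered
locate_ref_pos <- function(idx, maps, seqname, pos) {
  t <- idx$tab[[seqname]]
  if (is.null(t)) return(c(NA_integer_, NA_integer_))
  k <- findInterval(pos, t$start)
  if (k == 0L || pos >= t$end[k]) return(c(NA_integer_, NA_integer_))
  b <- t$block[k]
  col <- match(pos, maps[[b]][1, ])
  c(b, col)
}

#' Extract fourfold-degenerate (4D) site columns from an alignment
#'
#' Walks the reference-species CDS annotations codon by codon
#' (strand-aware) and collects the alignment column at the third position
#' of every codon whose first two reference bases put it in a 4D codon
#' family (prefixes CT, GT, TC, CC, AC, GC, CG, GG). Columns from
#' minus-strand genes are complemented so all sites are on the coding
#' strand of the reference. Codons that are not fully contained in one
#' alignment block are skipped (count in attribute `"skipped"`).
#'
#' @param blocks list of `AlignmentBlock`s (reference row first).
#' @param ann annotation table from [read_gff3()] with CDS records.
#' @param ref_species reference species id (default: first row of the
#'   first block).
#' @param species species set for the output columns (default: all seen).
#' @return a [site_columns()] object (collapsed, weighted), with
#'   attributes `"skipped"` and `"coords"` (reference coordinates of the
#'   uncollapsed sites).
#' @export
extract_4d_columns <- function(blocks, ann, ref_species = NULL,
                               species = NULL) {
  idx <- ref_block_index(blocks, ref_species)
  maps <- lapply(blocks, block_pos_map)
  mats <- lapply(blocks, block_char_matrix)
  if (is.null(species))
    species <- unique(unlist(lapply(blocks, function(b) b$species)))
  cds <- ann[ann$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS records in annotation")
  cols <- list(); coords <- integer(); skipped <- 0L
  for (tx in unique(cds$parent)) {
    cc <- cds[cds$parent == tx, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    minus <- cc$strand[1] == "-"
    pos <- unlist(lapply(seq_len(nrow(cc)),
                         function(i) cc$start[i]:(cc$end[i] - 1L)))
    if (minus) pos <- rev(pos)          # translation order
    ncod <- length(pos) %/% 3L
    if (ncod == 0L) next
    sq <- cc$seqname[1]
    for (cd in seq_len(ncod)) {
      p3 <- pos[(3L * cd - 2L):(3L * cd)]
      loc <- vapply(p3, function(p) locate_ref_pos(idx, maps, sq, p),
                    integer(2))
      if (anyNA(loc) || length(unique(loc[1, ])) != 1L) {
        skipped <- skipped + 1L
        next
      }
      b <- loc[1, 1]
      refrow <- mats[[b]][1, loc[2, ]]
      bases <- if (minus) unname(COMPLEMENT[refrow]) else refrow
      if (!paste0(bases[1], bases[2]) %in% FOURFOLD_PREFIXES) next
      col <- rep("N", length(species))
      names(col) <- species
      ch <- mats[[b]][, loc[2, 3]]
      if (minus) ch <- unname(COMPLEMENT[ch])
      col[blocks[[b]]$species] <- ch
      cols[[length(cols) + 1L]] <- col
      coords <- c(coords, p3[3])
    }
  }
  if (length(cols) == 0L)
    stop("no 4D sites found; check annotations and alignment")
  m <- do.call(cbind, cols)
  rownames(m) <- species
  out <- site_columns(m, collapse = TRUE)
  attr(out, "skipped") <- skipped
  attr(out, "coords") <- coords
  out
}
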