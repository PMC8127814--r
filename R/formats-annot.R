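#' Read gene annotations (GFF3)
#'
#' Parses gene/mRNA/CDS/exon records into a flat table with 0-based
#' half-open coordinates (GFF3's 1-based inclusive convention is converted
#' on read). Parent linkage is resolved so every record carries the id of
#' its gene. CDS phase consistency is checked per mRNA: successive phases
#' must satisfy `phase[i+1] == (3 - (len[i] - phase[i]) %% 3) %% 3` in
#' translation order.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `type, seqname, start, end, strand,
#'   phase, id, parent, gene_id`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  ph <- if ("phase" %in% names(md)) suppressWarnings(as.integer(as.character(md$phase)))
        else rep(NA_integer_, length(gr))
  ann <- data.frame(
    type = as.character(md$type),
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = ph, id = id, parent = parent,
    stringsAsFactors = FALSE)
  ann <- ann[ann$type %in% c("gene", "mRNA", "CDS", "exon"), , drop = FALSE]
  rownames(ann) <- NULL
  if (any(ann$type == "CDS" & is.na(ann$parent)))
    stop("CDS record without a Parent attribute")
  ann$gene_id <- resolve_gene_ids(ann)
  check_cds_phases(ann)
  ann
}

resolve_gene_ids <- function(ann) {
  by_id <- match(ann$parent, ann$id)
  gid <- ifelse(ann$type == "gene", ann$id, NA_character_)
  for (pass in 1:3) {  # gene <- mRNA <- CDS/exon: at most two hops
    need <- is.na(gid) & !is.na(by_id)
    gid[need] <- gid[by_id[need]]
  }
  gid[is.na(gid)] <- ann$id[is.na(gid)]
  gid
}

check_cds_phases <- function(ann) {
  cds <- ann[ann$type == "CDS" & !is.na(ann$phase), , drop = FALSE]
  if (nrow(cds) == 0L) return(invisible(TRUE))
  for (p in unique(cds$parent)) {
    cc <- cds[cds$parent == p, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    if (cc$strand[1] == "-") cc <- cc[rev(seq_len(nrow(cc))), , drop = FALSE]
    expect <- 0L
    for (i in seq_len(nrow(cc))) {
      if (cc$phase[i] != expect)
        stop("CDS phase inconsistent with exon lengths for mRNA ", p)
      len <- cc$end[i] - cc$start[i]
      expect <- (3L - ((len - expect) %% 3L)) %% 3L
    }
  }
  invisible(TRUE)
}

#' @rdname read_gff3
#' @param ann annotation table as returned by `read_gff3`.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- ifelse(is.na(ann$parent), paste0("ID=", ann$id),
                  paste0("ID=", ann$id, ";Parent=", ann$parent))
  writeLines(paste(ann$seqname, "cneloss", ann$type, ann$start + 1L, ann$end,
                   ".", ann$strand,
                   ifelse(is.na(ann$phase), ".", as.character(ann$phase)),
                   attrs, sep = "\t"), con)
  invisible(path)
}

#' Transcription start sites of annotated genes
#'
#' TSS is the 5' end of the gene interval: `start` on "+", `end - 1` on
#' "-" (0-based).
#'
#' @param ann annotation table from [read_gff3()].
#' @return data.frame `gene_id, seqname, tss, strand`.
#' @export
tss_of <- function(ann) {
  g <- ann[ann$type == "gene", , drop = FALSE]
  data.frame(gene_id = g$gene_id, seqname = g$seqname,
             tss = ifelse(g$strand == "-", g$end - 1L, g$start),
             strand = g$strand, stringsAsFactors = FALSE)
}

#' Read / write BED intervals
#'
#' BED is natively 0-based half-open; no conversion is applied. BED4/BED5
#' columns (name, score) are kept when present.
#'
#' @param path file path.
#' @return an `intervals` table.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("seqname", "start", "end", "name",
                                        "score", "strand")[1:max(3L,
                            length(scan(path, what = "", sep = "\t",
                                        nlines = 1L, quiet = TRUE)))],
                          fill = TRUE)
  intervals(df$seqname, df$start, df$end,
            strand = if ("strand" %in% names(df)) df$strand else "+",
            name = if ("name" %in% names(df)) df$name else NA,
            score = if ("score" %in% names(df)) df$score else NA)
}

#' @rdname read_bed
#' @param x an `intervals` table.
#' @export
write_bed <- function(x, path) {
  nm <- ifelse(is.na(x$name), ".", x$name)
  sc <- ifelse(is.na(x$score), ".", formatC(x$score, format = "g", digits = 6))
  writeLines(paste(x$seqname, x$start, x$end, nm, sc, x$strand, sep = "\t"),
             path)
  invisible(path)
}
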