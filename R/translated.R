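## codon -> amino acid lookup (standard code, * = stop, X = ambiguous)
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a DNA string (standard genetic code)
#' @param dna DNA string; length is truncated to a codon multiple.
#' @return protein string; stops as `*`, ambiguous codons as `X`.
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## six-frame translation with coordinate maps; for each frame:
## strand, offset f (0..2), protein char vector.  aa residue p (1-based)
## occupies, on the strand's own coordinates, nt [f + 3(p-1), f + 3p).
six_frames <- function(seq) {
  L <- nchar(seq)
  rc <- revcomp(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      prot <- translate_dna(substring(s, f + 1L, L))
      out[[length(out) + 1L]] <- list(
        strand = strand, offset = f,
        chars = strsplit(prot, "", fixed = TRUE)[[1]])
    }
  }
  out
}

#' Mine candidate gene loci with a translated (TblastN-style) search
#'
#' Protein queries are matched against the 6-frame translation of the
#' target genome by ungapped seed-and-extend (HSPs never cross a stop
#' codon), HSPs are chained per (query, sequence, strand) across frames,
#' and chains pass two gates: a mapping gate (E-value <= `map_e`,
#' alignment rate >= `map_rate`) and a retention gate (alignment rate >
#' `keep_rate`, identity > `keep_identity`). Retained chain spans are
#' extended `flank` bp up- and downstream and overlapping loci merged;
#' each locus reports its best query.
#'
#' @param protein_queries named character vector of protein sequences.
#' @param target_genome `GenomeSet` or named character vector of DNA.
#' @param map_e,map_rate mapping-stage gates.
#' @param keep_rate,keep_identity retention-stage gates.
#' @param flank bp added on both sides of a retained chain span.
#' @param word_size protein seed length.
#' @return data.frame of loci: `seqname, start, end, strand, best_query,
#'   score, alignment_rate, identity` (0-based half-open, forward
#'   coordinates).
#' @export
mine_candidate_loci <- function(protein_queries, target_genome,
                                map_e = 1e-10, map_rate = 0.5,
                                keep_rate = 0.70, keep_identity = 0.40,
                                flank = 280L, word_size = 4L) {
  seqs <- if (inherits(target_genome, "GenomeSet")) target_genome$sequences
          else target_genome
  ka <- KA_CONST$aa
  cand <- NULL
  for (sq in names(seqs)) {
    L <- nchar(seqs[[sq]])
    frames <- six_frames(seqs[[sq]])
    findex <- lapply(frames, function(fr)
      word_index(fr$chars, word_size, ambig_regex = "[*X]"))
    for (qn in names(protein_queries)) {
      qchars <- strsplit(protein_queries[[qn]], "", fixed = TRUE)[[1]]
      lq <- length(qchars)
      for (strand in c("+", "-")) {
        hs <- NULL
        for (fi in seq_along(frames)) {
          fr <- frames[[fi]]
          if (fr$strand != strand) next
          h <- search_one_strand(qchars, fr$chars, findex[[fi]], word_size,
                                 match = 1, mismatch = -1, xdrop = 12,
                                 min_score = word_size, hard = c("*", "X"),
                                 ambig = "X", ambig_regex = "[*X]")
          if (is.null(h)) next
          # aa -> strand-local nucleotide coords (0-based half-open)
          h$tstart_nt <- fr$offset + 3L * (h$tstart - 1L)
          h$tend_nt <- fr$offset + 3L * h$tend
          h$qstart <- h$qstart - 1L   # 0-based half-open residues
          h$tstart <- h$tstart_nt; h$tend <- h$tend_nt
          hs <- rbind(hs, h)
        }
        if (is.null(hs)) next
        ch <- chain_hsps(hs, lq)
        if (ch$score <= 0) next
        ev <- ka$K * lq * (L / 3) * exp(-ka$lambda * ch$score)
        if (!(ev <= map_e && ch$alignment_rate >= map_rate)) next
        if (!(ch$alignment_rate > keep_rate && ch$identity > keep_identity))
          next
        # strand-local nt span -> forward coordinates
        span <- if (strand == "+") c(ch$tstart, ch$tend)
                else c(L - ch$tend, L - ch$tstart)
        cand <- rbind(cand, data.frame(
          seqname = sq, start = max(0L, span[1] - flank),
          end = min(L, span[2] + flank), strand = strand, best_query = qn,
          score = ch$score, alignment_rate = ch$alignment_rate,
          identity = ch$identity, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(cand))
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      best_query = character(), score = numeric(),
                      alignment_rate = numeric(), identity = numeric()))
  # merge overlapping candidate loci, keeping the best-scoring query
  cand <- cand[order(cand$seqname, cand$start), , drop = FALSE]
  out <- cand[1, , drop = FALSE]
  for (i in seq_len(nrow(cand))[-1]) {
    last <- nrow(out)
    if (cand$seqname[i] == out$seqname[last] &&
        cand$start[i] < out$end[last]) {
      out$end[last] <- max(out$end[last], cand$end[i])
      if (cand$score[i] > out$score[last]) {
        out[last, c("best_query", "score", "alignment_rate", "identity",
                    "strand")] <-
          cand[i, c("best_query", "score", "alignment_rate", "identity",
                    "strand")]
      }
    } else {
      out <- rbind(out, cand[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Scan a ghost locus for evidence of gene loss
#'
#' Locates two flanking anchor genes in a query genome (translated
#' search), takes the interval between them (the ghost locus), and
#' searches every probe (gene CDS fragments, locus CNEs) both inside the
#' interval and genome-wide. The verdict is `"absent"` only when no probe
#' is found anywhere in the genome — ruling out relocation — and the
#' report carries the interval's assembly-gap content so an assembly
#' artifact can be excluded.
#'
#' @param anchor_a,anchor_b named single-element character vectors of
#'   anchor protein sequences.
#' @param genome a `GenomeSet`.
#' @param probes named character vector of DNA probe sequences.
#' @param thresholds rescue gates, see [rescue_search()].
#' @return list report: `anchors` (loci), `interval`, `n_gap_bp`,
#'   `probe_hits` (per probe: inside / anywhere), `verdict` in
#'   {"absent", "present", "present_elsewhere", "locus_broken",
#'   "anchor_not_found"}.
#' @export
ghost_locus_scan <- function(anchor_a, anchor_b, genome, probes,
                             thresholds = list(e = 1e-10, identity = 0.80,
                                               coverage = 0.30)) {
  # flank = 0: anchor boundaries are the raw chain spans, so the
  # inter-anchor interval is not shrunk by gene-model flanks
  loci <- mine_candidate_loci(c(anchor_a, anchor_b), genome, flank = 0L)
  la <- loci[loci$best_query == names(anchor_a), , drop = FALSE]
  lb <- loci[loci$best_query == names(anchor_b), , drop = FALSE]
  if (nrow(la) == 0L || nrow(lb) == 0L)
    return(list(anchors = loci, interval = NULL, n_gap_bp = NA,
                probe_hits = NULL, verdict = "anchor_not_found"))
  la <- la[which.max(la$score), ]; lb <- lb[which.max(lb$score), ]
  if (la$seqname != lb$seqname)
    return(list(anchors = rbind(la, lb), interval = NULL, n_gap_bp = NA,
                probe_hits = NULL, verdict = "locus_broken"))
  s <- min(la$end, lb$end); e <- max(la$start, lb$start)
  if (s >= e) { s <- min(la$start, lb$start); e <- max(la$end, lb$end) }
  sq <- la$seqname
  gaps <- genome$n_gaps[[sq]]
  gap_bp <- if (is.null(gaps) || nrow(gaps) == 0L) 0L else
    sum(pmax(0L, pmin(gaps[, "end"], e) - pmax(gaps[, "start"], s)))
  inside <- substring(genome$sequences[[sq]], s + 1L, e)
  hits <- data.frame(probe = names(probes), inside = FALSE, anywhere = FALSE)
  for (i in seq_along(probes)) {
    hits$inside[i] <- rescue_search(probes[[i]],
                                    stats::setNames(inside, "interval"),
                                    thresholds)$found
    hits$anywhere[i] <- hits$inside[i] ||
      rescue_search(probes[[i]], genome, thresholds)$found
  }
  verdict <- if (!any(hits$anywhere)) "absent"
             else if (any(hits$inside)) "present"
             else "present_elsewhere"
  list(anchors = rbind(la, lb),
       interval = intervals(sq, s, e, name = "ghost_locus"),
       n_gap_bp = gap_bp, probe_hits = hits, verdict = verdict)
}
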