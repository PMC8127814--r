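## Karlin-Altschul calibration constants for the default +1/-1 scoring.
## lambda solves sum_ij pi_i pi_j exp(lambda * s_ij) = 1 at uniform
## residue frequencies (log 3 for 4-letter DNA, log 19 for 20-letter
## protein); K is fixed at 0.5. E-values are a ranking/gating device on
## planted-vs-random separation, not calibrated p-values.
KA_CONST <- list(nt = list(K = 0.5, lambda = log(3)),
                 aa = list(K = 0.5, lambda = log(19)))

## exact-word position index of a sequence (1-based positions)
word_index <- function(chars, word_size, ambig_regex = "[N*X]") {
  n <- length(chars)
  if (n < word_size) return(list())
  acc <- chars[1:(n - word_size + 1L)]
  for (k in 2:word_size)
    acc <- paste0(acc, chars[k:(n - word_size + k)])
  bad <- grepl(ambig_regex, acc)
  split(which(!bad), acc[!bad])
}

## ungapped x-drop extension of a seed; returns c(qs, qe, score, nmatch)
## (1-based inclusive q range; t range follows the fixed diagonal)
extend_seed <- function(q, t, qpos, tpos, word_size, match, mismatch, xdrop,
                        hard = character(0), ambig = "N") {
  lq <- length(q); lt <- length(t)
  base <- sum(ifelse(q[qpos:(qpos + word_size - 1L)] ==
                       t[tpos:(tpos + word_size - 1L)], match, mismatch))
  # right
  best <- 0; cur <- 0; bestoff <- 0L; off <- 0L
  while (qpos + word_size + off <= lq && tpos + word_size + off <= lt) {
    qc <- q[qpos + word_size + off]; tc <- t[tpos + word_size + off]
    if (qc %in% hard || tc %in% hard) break
    cur <- cur + if (qc == tc && !(qc %in% ambig)) match else mismatch
    if (cur > best) { best <- cur; bestoff <- off + 1L }
    if (best - cur > xdrop) break
    off <- off + 1L
  }
  right <- best; re <- bestoff
  # left
  best <- 0; cur <- 0; bestoff <- 0L; off <- 1L
  while (qpos - off >= 1L && tpos - off >= 1L) {
    qc <- q[qpos - off]; tc <- t[tpos - off]
    if (qc %in% hard || tc %in% hard) break
    cur <- cur + if (qc == tc && !(qc %in% ambig)) match else mismatch
    if (cur > best) { best <- cur; bestoff <- off }
    if (best - cur > xdrop) break
    off <- off + 1L
  }
  left <- best; le <- bestoff
  qs <- qpos - le; qe <- qpos + word_size - 1L + re
  seg_q <- q[qs:qe]; seg_t <- t[(tpos - le):(tpos + word_size - 1L + re)]
  nmatch <- sum(seg_q == seg_t & !(seg_q %in% ambig))
  c(qs = qs, qe = qe, score = base + left + right, nmatch = nmatch)
}

## core ungapped search of one query string against one target string
## (single strand); returns HSP data.frame with 1-based inclusive coords
search_one_strand <- function(qchars, tchars, tindex, word_size, match,
                              mismatch, xdrop, min_score, hard = character(0),
                              ambig = "N", ambig_regex = "[N*X]") {
  lq <- length(qchars)
  if (lq < word_size) return(NULL)
  acc <- qchars[1:(lq - word_size + 1L)]
  for (k in 2:word_size)
    acc <- paste0(acc, qchars[k:(lq - word_size + k)])
  hsps <- NULL
  covered <- list()  # per diagonal: matrix of covered q ranges
  # one hashed lookup of all query words (named-list access is linear)
  hit <- match(acc, names(tindex))
  for (qp in which(!is.na(hit))) {
    if (grepl(ambig_regex, acc[qp])) next
    tp <- tindex[[hit[qp]]]
    for (t0 in tp) {
      dg <- as.character(t0 - qp)
      cv <- covered[[dg]]
      if (!is.null(cv) && any(cv[, 1] <= qp & cv[, 2] >= qp + word_size - 1L))
        next
      ex <- extend_seed(qchars, tchars, qp, t0, word_size, match, mismatch,
                        xdrop, hard, ambig)
      covered[[dg]] <- rbind(cv, c(ex["qs"], ex["qe"]))
      if (ex["score"] < min_score) next
      len <- ex["qe"] - ex["qs"] + 1L
      hsps <- rbind(hsps, data.frame(
        qstart = unname(ex["qs"]), qend = unname(ex["qe"]),
        tstart = t0 - (qp - ex[["qs"]]),
        tend = t0 + word_size - 1L + (ex[["qe"]] - (qp + word_size - 1L)),
        score = unname(ex["score"]),
        identity = unname(ex["nmatch"]) / len))
    }
  }
  if (!is.null(hsps)) hsps <- unique(hsps)
  hsps
}

#' Seed-and-extend ungapped local search (BLASTN-style)
#'
#' Finds maximal-scoring ungapped extensions of exact word seeds between a
#' DNA query and target, on both strands. E-values use
#' `K * m * n * exp(-lambda * S)` with the calibration constants for the
#' +1/-1 scoring documented in `KA_CONST`.
#'
#' @param query,target DNA strings (uppercase ACGTN).
#' @param word_size exact seed length.
#' @param match,mismatch scores (N never matches).
#' @param xdrop extension drop-off.
#' @param min_score minimum HSP score reported (default: seed score).
#' @param target_index optional precomputed [word_index()] of the target
#'   (reuse across many queries).
#' @return data.frame of HSPs: 0-based half-open `qstart/qend` (on the
#'   forward query), `tstart/tend` (forward target), `strand`, `score`,
#'   `identity`, `evalue`. Empty (with a warning) if the query is shorter
#'   than `word_size`.
#' @export
seed_and_extend <- function(query, target, word_size = 11L, match = 1,
                            mismatch = -1, xdrop = 10, min_score = NULL,
                            target_index = NULL) {
  if (is.null(min_score)) min_score <- word_size * match
  lq <- nchar(query); lt <- nchar(target)
  empty <- data.frame(qstart = integer(), qend = integer(),
                      tstart = integer(), tend = integer(),
                      strand = character(), score = numeric(),
                      identity = numeric(), evalue = numeric())
  if (lq < word_size) {
    warning("query shorter than word size")
    return(empty)
  }
  tchars <- strsplit(target, "", fixed = TRUE)[[1]]
  if (is.null(target_index)) target_index <- word_index(tchars, word_size)
  out <- NULL
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    qchars <- strsplit(qs, "", fixed = TRUE)[[1]]
    h <- search_one_strand(qchars, tchars, target_index, word_size, match,
                           mismatch, xdrop, min_score)
    if (is.null(h)) next
    if (strand == "-") {
      tmp <- h$qstart
      h$qstart <- lq - h$qend + 1L
      h$qend <- lq - tmp + 1L
    }
    h$strand <- strand
    out <- rbind(out, h)
  }
  if (is.null(out)) return(empty)
  # convert to 0-based half-open
  out$qstart <- out$qstart - 1L
  out$tstart <- out$tstart - 1L
  ka <- KA_CONST$nt
  out$evalue <- ka$K * lq * lt * exp(-ka$lambda * out$score)
  out[order(-out$score), , drop = FALSE]
}

#' Chain collinear HSPs (Solar-style concatenation)
#'
#' Sparse dynamic programming for the maximum-total-score chain of HSPs
#' with strictly increasing query and target starts and inter-HSP gaps at
#' most `max_gap`; overlap between successive HSPs is charged to the
#' lower-scoring one at its per-base score density. The chain's
#' `alignment_rate` is the fraction of the query covered by its HSPs and
#' its identity the length-weighted mean HSP identity.
#'
#' @param hsps HSP data.frame from one (query, target, strand) triple.
#' @param query_length full query length (for the alignment rate).
#' @param max_gap maximum gap between chained HSPs (query or target).
#' @return list `(hsps, score, alignment_rate, identity, tstart, tend)`;
#'   empty input gives score 0 and no members.
#' @export
chain_hsps <- function(hsps, query_length, max_gap = 5000) {
  if (is.null(hsps) || nrow(hsps) == 0L)
    return(list(hsps = NULL, score = 0, alignment_rate = 0, identity = 0,
                tstart = NA_integer_, tend = NA_integer_))
  h <- hsps[order(hsps$qstart, hsps$tstart), , drop = FALSE]
  n <- nrow(h)
  dens <- h$score / (h$qend - h$qstart)
  dp <- h$score
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (h$qstart[i] <= h$qstart[j] || h$tstart[i] <= h$tstart[j]) next
      if (h$qstart[i] - h$qend[j] > max_gap) next
      if (h$tstart[i] - h$tend[j] > max_gap) next
      ov <- max(0L, h$qend[j] - h$qstart[i], h$tend[j] - h$tstart[i])
      pen <- ov * min(dens[i], dens[j])
      cand <- dp[j] + h$score[i] - pen
      if (cand > dp[i]) { dp[i] <- cand; prev[i] <- j }
    }
  }
  best <- which.max(dp)
  chain <- integer()
  k <- best
  while (k != 0L) { chain <- c(k, chain); k <- prev[k] }
  ch <- h[chain, , drop = FALSE]
  m <- merge_spans(ch$qstart, ch$qend)
  covered <- sum(m[, "end"] - m[, "start"])
  lens <- ch$qend - ch$qstart
  list(hsps = ch, score = dp[best],
       alignment_rate = covered / query_length,
       identity = sum(ch$identity * lens) / sum(lens),
       tstart = min(ch$tstart), tend = max(ch$tend))
}

#' Homology rescue search for a missing CNE
#'
#' Searches a CNE sequence against a whole genome and reports it found
#' when some collinear HSP chain passes all three gates: E-value below
#' `e`, chain identity at least `identity`, and query coverage at least
#' `coverage`. This recovers CNEs absent from the projection alignment
#' because of rearrangement or assignment to the duplicate paralogon.
#'
#' @param cne_seq CNE DNA sequence (reference genome).
#' @param target_genome a `GenomeSet`, or named character vector of DNA
#'   strings.
#' @param thresholds list with `e`, `identity`, `coverage`.
#' @param word_size seed length.
#' @param index optional named list of precomputed [word_index()]es per
#'   target sequence.
#' @return list `(found, chain, seqname, strand, evalue)`.
#' @export
rescue_search <- function(cne_seq, target_genome,
                          thresholds = list(e = 1e-10, identity = 0.80,
                                            coverage = 0.30),
                          word_size = 11L, index = NULL) {
  seqs <- if (inherits(target_genome, "GenomeSet")) target_genome$sequences
          else target_genome
  lq <- nchar(cne_seq)
  ka <- KA_CONST$nt
  best <- list(found = FALSE, chain = NULL, seqname = NA_character_,
               strand = NA_character_, evalue = Inf)
  for (sq in names(seqs)) {
    hs <- seed_and_extend(cne_seq, seqs[[sq]], word_size = word_size,
                          target_index = index[[sq]])
    if (nrow(hs) == 0L) next
    for (st in unique(hs$strand)) {
      ch <- chain_hsps(hs[hs$strand == st, , drop = FALSE], lq)
      ev <- ka$K * lq * nchar(seqs[[sq]]) * exp(-ka$lambda * ch$score)
      ok <- ev < thresholds$e && ch$identity >= thresholds$identity &&
        ch$alignment_rate >= thresholds$coverage
      if ((ok && !best$found) || (ok == best$found && ev < best$evalue)) {
        best <- list(found = ok, chain = ch, seqname = sq, strand = st,
                     evalue = ev)
      }
    }
  }
  best
}
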