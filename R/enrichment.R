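#' Assign CNEs to the gene with the nearest TSS within 1 Mb
#'
#' The CNE's midpoint is the anchor point; it maps to the gene whose
#' transcription start site is nearest on the same sequence and within
#' `max_dist` bp, else the CNE stays unassigned. Exact distance ties are
#' broken deterministically toward the smaller TSS coordinate; all tied
#' genes are recorded in the `"multi"` attribute.
#'
#' @param cnes `intervals` table.
#' @param tss TSS table from [tss_of()].
#' @param max_dist maximum assignment distance in bp (default 1e6).
#' @return data.frame `cne, gene_id, distance, assigned` (distance is
#'   signed: midpoint minus TSS).
#' @export
assign_to_nearest_tss <- function(cnes, tss, max_dist = 1e6) {
  out <- data.frame(cne = cnes$name, gene_id = NA_character_,
                    distance = NA_real_, assigned = FALSE,
                    stringsAsFactors = FALSE)
  multi <- NULL
  for (i in seq_len(nrow(cnes))) {
    mid <- floor((cnes$start[i] + cnes$end[i]) / 2)
    cand <- tss[tss$seqname == cnes$seqname[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- mid - cand$tss
    ad <- abs(d)
    if (min(ad) > max_dist) next
    hit <- which(ad == min(ad))
    if (length(hit) > 1L) {
      multi <- rbind(multi, data.frame(cne = cnes$name[i],
                                       gene_id = cand$gene_id[hit],
                                       stringsAsFactors = FALSE))
      hit <- hit[which.min(cand$tss[hit])]
    }
    out$gene_id[i] <- cand$gene_id[hit]
    out$distance[i] <- d[hit]
    out$assigned[i] <- TRUE
  }
  attr(out, "multi") <- multi
  out
}

#' Hypergeometric term enrichment with Benjamini-Hochberg FDR
#'
#' For each term: k = genes in the sample annotated with the term, K =
#' term genes in the universe, n = sample size, N = universe size;
#' upper-tail hypergeometric p = P(X >= k), then BH q-values. The
#' significant set is q < `alpha`.
#'
#' @param sample_genes character vector (subset of `universe`).
#' @param term_map data.frame with columns `gene_id`, `term_id`.
#' @param universe character vector of all eligible genes.
#' @param alpha FDR threshold stored in the `"alpha"` attribute.
#' @return data.frame `term, k, K, n, N, p, q, significant`, sorted by q
#'   then p.
#' @export
hypergeometric_enrichment <- function(sample_genes, term_map, universe,
                                      alpha = 0.05) {
  sample_genes <- unique(sample_genes)
  universe <- unique(universe)
  if (length(sample_genes) == 0L) stop("empty sample gene set")
  if (!all(sample_genes %in% universe))
    stop("sample genes must be a subset of the universe")
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- unique(tm$term_id)
  N <- length(universe); n <- length(sample_genes)
  res <- do.call(rbind, lapply(terms, function(tt) {
    tg <- unique(tm$gene_id[tm$term_id == tt])
    K <- length(tg)
    k <- length(intersect(tg, sample_genes))
    data.frame(term = tt, k = k, K = K, n = n, N = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  res
}

#' Genes ranked by number of adjacent lost CNEs
#'
#' The descriptive companion to the enrichment test: counts lost CNEs per
#' assigned gene and returns the top of the ranking.
#'
#' @param assignments output of [assign_to_nearest_tss()] restricted to
#'   lost CNEs.
#' @param top how many genes to return (default 20).
#' @return data.frame `gene_id, n_lost` sorted decreasingly.
#' @export
gene_loss_counts <- function(assignments, top = 20L) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(gene_id = character(), n_lost = integer()))
  tab <- sort(table(a$gene_id), decreasing = TRUE)
  utils::head(data.frame(gene_id = names(tab), n_lost = as.integer(tab),
                         stringsAsFactors = FALSE), top)
}
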