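## Per-species projection of an alignment onto reference coordinates.
## For one target species, three parallel vectors sorted by reference
## position: `refpos` (reference positions where the species row is
## aligned, i.e. not "-"), `sppos` (the species' own forward coordinate
## there) and `base_ok` (TRUE when the aligned base is a real base, not
## N).  Aligning to N carries no evidence of presence, so coverage counts
## only `base_ok` sites, while anchoring (for gap projection) uses all
## aligned sites.
species_projection <- function(blocks, species, ref_species = NULL) {
  if (is.null(ref_species)) ref_species <- blocks[[1]]$species[1]
  refpos <- list(); sppos <- list(); ok <- list(); seqn <- list()
  spseq <- list()
  for (b in blocks) {
    if (b$species[1] != ref_species) next
    r <- match(species, b$species)
    if (is.na(r)) next
    pm <- block_pos_map(b)
    cm <- block_char_matrix(b)
    sel <- !is.na(pm[1, ]) & !is.na(pm[r, ])
    if (!any(sel)) next
    refpos[[length(refpos) + 1L]] <- pm[1, sel]
    sppos[[length(sppos) + 1L]] <- pm[r, sel]
    ok[[length(ok) + 1L]] <- cm[r, sel] %in% BASES
    seqn[[length(seqn) + 1L]] <- rep(b$seqname[1], sum(sel))
    spseq[[length(spseq) + 1L]] <- rep(b$seqname[r], sum(sel))
  }
  if (length(refpos) == 0L) return(list(by = list()))
  refpos <- unlist(refpos); seqn <- unlist(seqn)
  sppos <- unlist(sppos); ok <- unlist(ok); spseq <- unlist(spseq)
  by <- list()
  for (sq in unique(seqn)) {
    sel <- which(seqn == sq)
    o <- sel[order(refpos[sel])]
    by[[sq]] <- list(refpos = refpos[o], sppos = sppos[o],
                     base_ok = ok[o], sp_seq = spseq[o],
                     pref = cumsum(ok[o]))   # prefix sums of real bases
  }
  list(by = by)
}

## coverage of reference span [s,e) on ref sequence sq by real bases of
## the projected species; O(log n) via prefix sums
projection_coverage <- function(proj, sq, s, e) {
  b <- proj$by[[sq]]
  if (is.null(b)) return(0)
  i1 <- findInterval(s - 1L, b$refpos) + 1L
  i2 <- findInterval(e - 1L, b$refpos)
  if (i2 < i1) return(0)
  (b$pref[i2] - if (i1 > 1L) b$pref[i1 - 1L] else 0L) / (e - s)
}

#' Alignment-based presence of a CNE in one species
#'
#' Coverage is the fraction of the CNE's reference bases aligned to real
#' (non-gap, non-N) bases of the species across all blocks; the element
#' is present when coverage is at least `threshold` (boundary inclusive).
#'
#' @param cne single-row `intervals` table (reference coordinates).
#' @param blocks list of `AlignmentBlock`s.
#' @param species target species id.
#' @param threshold presence threshold (default 0.30).
#' @return list `(coverage, present)`.
#' @export
alignment_presence <- function(cne, blocks, species, threshold = 0.30) {
  proj <- species_projection(blocks, species)
  cov <- projection_coverage(proj, cne$seqname[1], cne$start[1], cne$end[1])
  list(coverage = cov, present = cov >= threshold)
}

#' Classify per-species presence of every CNE
#'
#' Two-stage rule per (CNE, species) cell: `present_by_alignment` when
#' projection coverage >= `threshold`; otherwise `present_by_rescue` when
#' the whole-genome homology search passes its gates (catching elements
#' displaced by rearrangement or assigned to the duplicate paralogon);
#' otherwise `missing` — unless the CNE's projected locus (the target
#' span between its nearest flanking aligned anchors) overlaps an
#' assembly N-gap, or the CNE has no flanking anchors at all, in which
#' case the cell is `gap_uncertain` and never counted as a loss.
#'
#' @param cnes `intervals` table of CNEs (named rows).
#' @param blocks alignment blocks.
#' @param genomes named list of `GenomeSet`s including the reference.
#' @param ref reference species id.
#' @param threshold alignment-coverage presence threshold.
#' @param rescue_thresholds gates for [rescue_search()].
#' @return character matrix (CNE x species) of states with attribute
#'   `"coverage"` (numeric matrix).
#' @export
classify_presence <- function(cnes, blocks, genomes, ref = NULL,
                              threshold = 0.30,
                              rescue_thresholds = list(e = 1e-10,
                                                       identity = 0.80,
                                                       coverage = 0.30)) {
  if (is.null(ref)) ref <- blocks[[1]]$species[1]
  species <- setdiff(names(genomes), ref)
  refg <- genomes[[ref]]
  states <- matrix("missing", nrow = nrow(cnes), ncol = length(species),
                   dimnames = list(cnes$name, species))
  covm <- matrix(0, nrow = nrow(cnes), ncol = length(species),
                 dimnames = list(cnes$name, species))
  for (sp in species) {
    proj <- species_projection(blocks, sp)
    widx <- lapply(genomes[[sp]]$sequences, function(s)
      word_index(strsplit(s, "", fixed = TRUE)[[1]], 11L))
    gaps <- genomes[[sp]]$n_gaps
    for (i in seq_len(nrow(cnes))) {
      sq <- cnes$seqname[i]; s <- cnes$start[i]; e <- cnes$end[i]
      cov <- projection_coverage(proj, sq, s, e)
      covm[i, sp] <- cov
      if (cov >= threshold) { states[i, sp] <- "present_by_alignment"; next }
      cseq <- substring(refg$sequences[[sq]], s + 1L, e)
      rs <- rescue_search(cseq, genomes[[sp]], rescue_thresholds,
                          index = widx)
      if (rs$found) { states[i, sp] <- "present_by_rescue"; next }
      states[i, sp] <- if (locus_gap_uncertain(proj, gaps, sq, s, e))
        "gap_uncertain" else "missing"
    }
  }
  attr(states, "coverage") <- covm
  states
}

## does the projected target locus of ref span [s,e) overlap an N-gap?
## TRUE also when the span has no flanking anchors (conservative).
locus_gap_uncertain <- function(proj, gaps, sq, s, e) {
  b <- proj$by[[sq]]
  if (is.null(b)) return(TRUE)
  left <- which(b$refpos < s)
  right <- which(b$refpos >= e)
  if (length(left) == 0L || length(right) == 0L) return(TRUE)
  a1 <- b$sppos[left[length(left)]]
  a2 <- b$sppos[right[1]]
  tsq <- b$sp_seq[left[length(left)]]
  if (tsq != b$sp_seq[right[1]]) return(TRUE)
  span <- sort(c(a1, a2))
  g <- gaps[[tsq]]
  if (is.null(g) || nrow(g) == 0L) return(FALSE)
  any(g[, "start"] < span[2] & g[, "end"] > span[1])
}

#' Gap-free syntenic intervals between the reference and one species
#'
#' Consecutive alignment blocks on the same (reference, target) sequence
#' pair and strand, with both coordinates advancing monotonically and
#' inter-anchor distance at most `max_anchor_gap`, are merged into
#' syntenic runs. A run is `gap_free` when no target N-gap intersects its
#' target span. With `split_at_gaps`, runs containing N-gaps are
#' subdivided at the gaps and the clean sub-spans re-emitted as gap-free
#' intervals, so an element sitting away from any gap can still enter
#' the high-confidence set.
#'
#' @param blocks alignment blocks.
#' @param genome the target species' `GenomeSet`.
#' @param species target species id.
#' @param max_anchor_gap maximum distance (bp, both genomes) bridged
#'   between consecutive anchors.
#' @param split_at_gaps subdivide gapped runs (default TRUE).
#' @return data.frame `ref_seqname, ref_start, ref_end, target_seqname,
#'   target_start, target_end, strand, gap_free, n_anchors`.
#' @export
gap_free_syntenic_intervals <- function(blocks, genome, species,
                                        max_anchor_gap = 100000L,
                                        split_at_gaps = TRUE) {
  ref <- blocks[[1]]$species[1]
  anchors <- NULL
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (b$species[1] != ref) next
    r <- match(species, b$species)
    if (is.na(r) || b$size[r] == 0L) next
    ri <- row_forward_interval(b[1, ])
    ti <- row_forward_interval(b[r, ])
    anchors <- rbind(anchors, data.frame(
      block = bi, ref_seq = b$seqname[1], rs = ri[1], re = ri[2],
      target_seq = b$seqname[r], ts = ti[1], te = ti[2],
      strand = b$strand[r], stringsAsFactors = FALSE))
  }
  if (is.null(anchors)) return(empty_synteny())
  anchors <- anchors[order(anchors$ref_seq, anchors$rs), , drop = FALSE]
  runs <- list()
  cur <- anchors[1, , drop = FALSE]
  for (i in seq_len(nrow(anchors))[-1]) {
    a <- anchors[i, ]
    last <- cur[nrow(cur), ]
    compat <- a$ref_seq == last$ref_seq && a$target_seq == last$target_seq &&
      a$strand == last$strand && a$rs >= last$re - 0L &&
      a$rs - last$re <= max_anchor_gap &&
      (if (a$strand == "+") a$ts >= last$te && a$ts - last$te <= max_anchor_gap
       else a$te <= last$ts && last$ts - a$te <= max_anchor_gap)
    if (compat) cur <- rbind(cur, a)
    else { runs[[length(runs) + 1L]] <- cur; cur <- a }
  }
  runs[[length(runs) + 1L]] <- cur

  proj <- species_projection(blocks, species)
  out <- NULL
  for (run in runs) {
    rs <- min(run$rs); re <- max(run$re)
    ts <- min(run$ts); te <- max(run$te)
    tsq <- run$target_seq[1]
    g <- genome$n_gaps[[tsq]]
    ov <- if (is.null(g) || nrow(g) == 0L) g[0, , drop = FALSE] else
      g[g[, "start"] < te & g[, "end"] > ts, , drop = FALSE]
    gap_free <- nrow(ov) == 0L
    out <- rbind(out, data.frame(
      ref_seqname = run$ref_seq[1], ref_start = rs, ref_end = re,
      target_seqname = tsq, target_start = ts, target_end = te,
      strand = run$strand[1], gap_free = gap_free, n_anchors = nrow(run),
      stringsAsFactors = FALSE))
    if (!gap_free && split_at_gaps) {
      pb <- proj$by[[run$ref_seq[1]]]
      sel <- if (is.null(pb)) logical(0) else pb$refpos >= rs & pb$refpos < re
      rp <- pb$refpos[sel]; tp <- pb$sppos[sel]
      if (length(rp) < 2L) next
      # a position is bad when its own target base sits in an N-gap; a
      # boundary is cut when the target jump between consecutive aligned
      # positions crosses an N-gap (the gap may lie in unaligned target
      # sequence between two anchors)
      ingap <- rep(FALSE, length(tp))
      for (k in seq_len(nrow(ov)))
        ingap <- ingap | (tp >= ov[k, "start"] & tp < ov[k, "end"])
      lo <- pmin(tp[-length(tp)], tp[-1])
      hi <- pmax(tp[-length(tp)], tp[-1]) + 1L
      cross <- rep(FALSE, length(lo))
      for (k in seq_len(nrow(ov)))
        cross <- cross | (ov[k, "start"] < hi & ov[k, "end"] > lo)
      grp <- cumsum(c(0L, as.integer(cross | diff(ingap) != 0L)))
      for (pc in split(seq_along(rp), grp)) {
        if (ingap[pc[1]] || length(pc) < 2L) next
        out <- rbind(out, data.frame(
          ref_seqname = run$ref_seq[1], ref_start = rp[pc[1]],
          ref_end = rp[pc[length(pc)]] + 1L, target_seqname = tsq,
          target_start = min(tp[pc]), target_end = max(tp[pc]) + 1L,
          strand = run$strand[1], gap_free = TRUE, n_anchors = nrow(run),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

empty_synteny <- function() {
  data.frame(ref_seqname = character(), ref_start = integer(),
             ref_end = integer(), target_seqname = character(),
             target_start = integer(), target_end = integer(),
             strand = character(), gap_free = logical(),
             n_anchors = integer(), stringsAsFactors = FALSE)
}

#' Call CNEs uniquely lost in single lineages
#'
#' A candidate loss in species S is a CNE whose cell is `missing` for S,
#' `missing` for no other species (uniqueness), and present in at least
#' `min_witnesses` other species. The call is upgraded to
#' `high_confidence` when the CNE lies entirely inside a gap-free
#' syntenic interval for S, so its absence cannot be an assembly
#' artifact.
#'
#' @param states presence matrix from [classify_presence()].
#' @param cnes `intervals` table matching the matrix rows.
#' @param synteny named list (per species) of interval tables from
#'   [gap_free_syntenic_intervals()].
#' @param min_witnesses minimum present species among the others.
#' @return data.frame `cne, species, tier` with tier in
#'   {"candidate", "high_confidence"}.
#' @export
call_unique_losses <- function(states, cnes, synteny, min_witnesses = 1L) {
  present <- states == "present_by_alignment" | states == "present_by_rescue"
  missing <- states == "missing"
  out <- NULL
  for (i in seq_len(nrow(states))) {
    if (sum(missing[i, ]) != 1L) next
    sp <- colnames(states)[missing[i, ]]
    if (sum(present[i, colnames(states) != sp]) < min_witnesses) next
    k <- match(rownames(states)[i], cnes$name)
    tier <- "candidate"
    sy <- synteny[[sp]]
    if (!is.null(sy)) {
      gf <- sy[sy$gap_free, , drop = FALSE]
      inside <- any(gf$ref_seqname == cnes$seqname[k] &
                      gf$ref_start <= cnes$start[k] &
                      gf$ref_end >= cnes$end[k])
      if (inside) tier <- "high_confidence"
    }
    out <- rbind(out, data.frame(cne = rownames(states)[i], species = sp,
                                 tier = tier, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(cne = character(), species = character(),
                      tier = character(), stringsAsFactors = FALSE)
  out
}
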