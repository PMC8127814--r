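STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' The stated world for all synthetic fixtures: a 6-taxon teleost-like
#' phylogeny (total length ~1.2 substitutions/site), a GTR model with
#' transition bias, conserved elements whose branch lengths are scaled by
#' `rho_conserved`, lineage-specific deletions, assembly N-gaps planted
#' over elements, and single-exon genes supplying 4D sites and TSSs.
#' Element lengths follow a truncated geometric with mean 168 bp (the
#' typical observed CNE size in teleost screens).
#'
#' @param tree `ape::phylo`; default is the packaged 6-taxon tree.
#' @param model a [gtr_model()].
#' @param rho_conserved branch scaling inside conserved elements.
#' @param n_elements number of planted elements.
#' @param element_length list(mean, min, max) in bp.
#' @param background_length total reference length in bp.
#' @param loss_plan named integer vector: species -> number of elements
#'   deleted in that species.
#' @param gap_plan named integer vector: species -> number of elements
#'   replaced by assembly N-runs in that species.
#' @param gene_plan list(n, cds_length): planted single-exon genes.
#' @param block_length alignment block size (columns) for MAF output.
#' @param ref reference species (never deleted or gapped).
#' @param seqname reference sequence name.
#' @param min_n_run assembly-gap definition.
#' @param seed RNG seed; same config + seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(tree = default_tree(),
                       model = gtr_model(c(0.31, 0.19, 0.19, 0.31),
                                         c(1, 4, 1, 1, 4, 1)),
                       rho_conserved = 0.3,
                       n_elements = 500L,
                       element_length = list(mean = 168, min = 50, max = 500),
                       background_length = 300000L,
                       loss_plan = c(hipCom0 = 50L),
                       gap_plan = c(hipCom0 = 25L),
                       gene_plan = list(n = 30L, cds_length = 300L),
                       block_length = 2000L,
                       ref = "Zv9", seqname = "chr1",
                       min_n_run = 10L, seed = 42L) {
  cfg <- list(tree = tree, model = model, rho_conserved = rho_conserved,
              n_elements = as.integer(n_elements),
              element_length = element_length,
              background_length = as.integer(background_length),
              loss_plan = loss_plan, gap_plan = gap_plan,
              gene_plan = gene_plan, block_length = as.integer(block_length),
              ref = ref, seqname = seqname,
              min_n_run = as.integer(min_n_run), seed = as.integer(seed))
  stopifnot(rho_conserved > 0, rho_conserved <= 1,
            all(c(names(loss_plan), names(gap_plan)) %in% tree$tip.label),
            !ref %in% c(names(loss_plan), names(gap_plan)),
            sum(loss_plan) + sum(gap_plan) <= n_elements,
            gene_plan$cds_length %% 3 == 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Build a simulation config from a JSON file
#'
#' Keys mirror the [sim_config()] arguments; `tree` may be a newick
#' string or a file path, `model` a list with `pi` and `rates`. Missing
#' keys keep their defaults.
#'
#' @param path JSON config file.
#' @param seed optional seed overriding the file's value.
#' @return a `sim_config`.
#' @export
sim_config_from_json <- function(path, seed = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(cfg$tree)) {
    args$tree <- if (file.exists(cfg$tree)) ape::read.tree(cfg$tree)
                 else ape::read.tree(text = cfg$tree)
  }
  if (!is.null(cfg$model))
    args$model <- gtr_model(unlist(cfg$model$pi), unlist(cfg$model$rates))
  for (k in c("rho_conserved", "n_elements", "background_length",
              "block_length", "ref", "seqname", "min_n_run", "seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  for (k in c("loss_plan", "gap_plan"))
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  for (k in c("element_length", "gene_plan"))
    if (!is.null(cfg[[k]])) args[[k]] <- as.list(cfg[[k]])
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(sim_config, args)
}

#' The packaged 6-taxon tree
#' @return `ape::phylo` with branch lengths (~1.2 subst/site total).
#' @export
default_tree <- function() {
  path <- system.file("extdata", "tree_6taxa.nwk", package = "cneloss")
  if (path == "") path <- file.path("inst", "extdata", "tree_6taxa.nwk")
  ape::read.tree(path)
}

## draw element lengths: min + geometric, truncated at max
draw_element_lengths <- function(n, el) {
  p <- 1 / (el$mean - el$min + 1)
  out <- integer(0)
  while (length(out) < n) {
    x <- el$min + stats::rgeom(n, p)
    out <- c(out, x[x <= el$max])
  }
  out[seq_len(n)]
}

## place n intervals of given lengths into [0, L) avoiding `occupied`
## (sorted two-column matrix) with `spacing` bp of clearance
place_intervals <- function(lengths, L, occupied = NULL, spacing = 10L,
                            max_tries = 10000L) {
  occ_s <- if (is.null(occupied)) integer() else occupied[, 1]
  occ_e <- if (is.null(occupied)) integer() else occupied[, 2]
  starts <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - len, 1L) - 1L
      e <- s + len
      if (!any(occ_s < e + spacing & occ_e > s - spacing)) { ok <- TRUE; break }
    }
    if (!ok) stop("element placement overflow: background too small for plan")
    starts[i] <- s
    occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
  }
  cbind(start = starts, end = starts + lengths)
}

## random ORF of `len` bp (ATG + non-stop codons + stop), as a string
make_orf <- function(len) {
  ncod <- len %/% 3L - 2L
  codons <- character(0)
  sense <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste,
                         collapse = ""), STOP_CODONS)
  codons <- sample(sense, ncod, replace = TRUE)
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Plant single-exon genes for a simulation
#'
#' Generates `gene_plan$n` random open reading frames (ATG start, no
#' internal stop, stop codon, length divisible by 3), places them on
#' random strands at non-overlapping positions, and returns the
#' annotation table (gene/mRNA/exon/CDS records) plus the genomic-strand
#' sequences to splice into the reference.
#'
#' @param config a [sim_config()].
#' @param occupied optional matrix of already-occupied spans.
#' @return list with `ann` (annotation table), `where` (interval matrix),
#'   `genomic_seq` (character vector, genomic strand).
#' @export
plant_genes <- function(config, occupied = NULL) {
  n <- config$gene_plan$n
  if (n == 0L)
    return(list(ann = empty_annotation(), where = cbind(start = integer(),
                end = integer()), genomic_seq = character()))
  len <- rep(config$gene_plan$cds_length, n)
  where <- place_intervals(len, config$background_length, occupied)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  orfs <- vapply(seq_len(n), function(i) make_orf(len[i]), "")
  genomic <- ifelse(strand == "+", orfs, revcomp(orfs))
  ids <- sprintf("gene%03d", seq_len(n))
  ann <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(type = c("gene", "mRNA", "exon", "CDS"),
               seqname = config$seqname,
               start = unname(where[i, "start"]), end = unname(where[i, "end"]),
               strand = strand[i],
               phase = c(NA, NA, NA, 0L),
               id = paste0(ids[i], c("", ".t1", ".e1", ".c1")),
               parent = c(NA, ids[i], paste0(ids[i], ".t1"),
                          paste0(ids[i], ".t1")),
               gene_id = ids[i], stringsAsFactors = FALSE)
  }))
  list(ann = ann, where = where, genomic_seq = genomic)
}

empty_annotation <- function() {
  data.frame(type = character(), seqname = character(), start = integer(),
             end = integer(), strand = character(), phase = integer(),
             id = character(), parent = character(), gene_id = character(),
             stringsAsFactors = FALSE)
}

## outward edge list (from, to, length) of a tree re-rooted at a tip.
## Under a reversible model, simulating outward from any leaf is
## distributionally identical to simulating from the root.
edges_from_tip <- function(tree, tip_label) {
  m <- rbind(tree$edge, tree$edge[, 2:1])
  len <- c(tree$edge.length, tree$edge.length)
  start <- match(tip_label, tree$tip.label)
  if (is.na(start)) stop("reference tip not in tree: ", tip_label)
  visited <- start
  queue <- start
  out <- NULL
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    k <- which(m[, 1] == u & !(m[, 2] %in% visited))
    for (j in k) {
      v <- m[j, 2]
      out <- rbind(out, c(u, v, len[j]))
      visited <- c(visited, v)
      queue <- c(queue, v)
    }
  }
  out
}

#' Evolve a synthetic alignment with planted truth
#'
#' Draws the reference sequence (equilibrium background, planted genes),
#' evolves every site independently outward along the tree under
#' `P(t) = exp(Qt)` — with `t` scaled by `rho_conserved` inside planted
#' elements — then applies the loss plan (element columns deleted from
#' the target species' row and genome) and the gap plan (element bases
#' replaced by N in the target species, alignment row retained). The true
#' alignment is emitted as blocks; no aligner is involved, so the truth
#' table is exact.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (list of `GenomeSet`), `blocks` (MAF-style
#'   alignment blocks), `elements` (truth `intervals`), `status` (long
#'   data.frame element x species status), `ann` (gene annotations),
#'   `config`.
#' @export
evolve_alignment <- function(config) {
  set.seed(config$seed)
  L <- config$background_length
  genes <- plant_genes(config)
  el_len <- draw_element_lengths(config$n_elements, config$element_length)
  el <- place_intervals(el_len, L, occupied = genes$where)
  el <- el[order(el[, "start"]), , drop = FALSE]
  el_names <- sprintf("cne%04d", seq_len(config$n_elements))

  tips <- config$tree$tip.label
  others <- setdiff(tips, config$ref)

  # reference sequence: background from pi, genes spliced in
  refseq <- sample.int(4L, L, replace = TRUE, prob = config$model$pi)
  for (i in seq_len(nrow(genes$where))) {
    span <- (genes$where[i, "start"] + 1L):genes$where[i, "end"]
    refseq[span] <- match(strsplit(genes$genomic_seq[i], "")[[1]], BASES)
  }

  # per-site branch scaling: rho inside elements, 1 elsewhere; coding
  # sequence is constrained at codon positions 1-2 (rho) while third
  # positions evolve neutrally, so extracted 4D sites stay neutral
  mult <- rep(1, L)
  for (i in seq_len(nrow(el))) mult[(el[i, "start"] + 1L):el[i, "end"]] <-
    config$rho_conserved
  g <- genes$ann[genes$ann$type == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    p <- g$start[i]:(g$end[i] - 1L)
    third <- if (g$strand[i] == "+") (p - g$start[i]) %% 3L == 2L
             else (g$end[i] - 1L - p) %% 3L == 2L
    mult[p[!third] + 1L] <- config$rho_conserved
  }

  edges <- edges_from_tip(config$tree, config$ref)
  nn <- length(tips) + config$tree$Nnode
  states <- matrix(NA_integer_, nrow = nn, ncol = L)
  states[match(config$ref, tips), ] <- refseq
  cons <- mult < 1
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]; t <- edges[k, 3]
    Pn <- transition_matrix(config$model, t)
    Pc <- transition_matrix(config$model, t * config$rho_conserved)
    ps <- states[u, ]
    cs <- integer(L)
    for (b in 1:4) {
      for (cc in c(FALSE, TRUE)) {
        idx <- which(ps == b & cons == cc)
        if (length(idx))
          cs[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                prob = if (cc) Pc[b, ] else Pn[b, ])
      }
    }
    states[v, ] <- cs
  }

  aln <- matrix(BASES[states[seq_along(tips), , drop = FALSE]],
                nrow = length(tips), dimnames = list(tips, NULL))

  # loss / gap plans over disjoint element subsets
  status <- matrix("present", nrow = config$n_elements, ncol = length(others),
                   dimnames = list(el_names, others))
  pool <- seq_len(config$n_elements)
  pick <- function(n) { s <- sample(pool, n); pool <<- setdiff(pool, s); s }
  for (sp in names(config$loss_plan)) {
    for (e in pick(config$loss_plan[[sp]])) {
      aln[sp, (el[e, "start"] + 1L):el[e, "end"]] <- "-"
      status[e, sp] <- "deleted"
    }
  }
  for (sp in names(config$gap_plan)) {
    for (e in pick(config$gap_plan[[sp]])) {
      aln[sp, (el[e, "start"] + 1L):el[e, "end"]] <- "N"
      status[e, sp] <- "gap_obscured"
    }
  }

  genomes <- lapply(tips, function(sp) {
    s <- paste(aln[sp, aln[sp, ] != "-"], collapse = "")
    g <- stats::setNames(s, config$seqname)
    genome_set(sp, g, min_n_run = config$min_n_run)
  })
  names(genomes) <- tips

  blocks <- chop_alignment(aln, config)
  long <- data.frame(
    element = rep(el_names, times = length(others)),
    species = rep(others, each = config$n_elements),
    status = as.vector(status), stringsAsFactors = FALSE)
  list(genomes = genomes, blocks = blocks,
       elements = intervals(config$seqname, el[, "start"], el[, "end"],
                            name = el_names, score = config$rho_conserved),
       status = long, ann = genes$ann, config = config)
}

## cut the full alignment matrix into MAF-style blocks; rows whose block
## slice is entirely gapped are dropped (missing species row)
chop_alignment <- function(aln, config) {
  tips <- rownames(aln)
  order_sp <- c(config$ref, setdiff(tips, config$ref))
  L <- ncol(aln)
  srclen <- vapply(order_sp, function(sp) sum(aln[sp, ] != "-"), 1L)
  offset <- stats::setNames(rep(0L, length(order_sp)), order_sp)
  starts <- seq(1L, L, by = config$block_length)
  blocks <- vector("list", length(starts))
  for (bi in seq_along(starts)) {
    cols <- starts[bi]:min(starts[bi] + config$block_length - 1L, L)
    rows <- list()
    for (sp in order_sp) {
      txt <- paste(aln[sp, cols], collapse = "")
      size <- sum(aln[sp, cols] != "-")
      if (size == 0L && sp != config$ref) { next }
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, seqname = config$seqname, start = offset[[sp]],
        size = size, strand = "+", src_size = srclen[[sp]], text = txt,
        stringsAsFactors = FALSE)
    }
    for (sp in order_sp) offset[[sp]] <- offset[[sp]] +
      sum(aln[sp, cols] != "-")
    b <- do.call(rbind, rows)
    class(b) <- c("AlignmentBlock", "data.frame")
    blocks[[bi]] <- b
  }
  blocks
}

#' Write all simulation outputs to a fixture directory
#'
#' Emits one FASTA per species, the alignment as MAF, gene annotations as
#' GFF3, the planted-element truth as BED, and the per-(element, species)
#' status table as TSV. Re-running the same config reproduces identical
#' files byte for byte.
#'
#' @param sim output of [evolve_alignment()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
emit_fixtures <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory ", dir)
  paths <- c()
  for (sp in names(sim$genomes)) {
    p <- file.path(dir, paste0(sp, ".fa"))
    write_fasta(sim$genomes[[sp]], p)
    paths[paste0("fasta_", sp)] <- p
  }
  write_maf(sim$blocks, paths["maf"] <- file.path(dir, "alignment.maf"))
  write_gff3(sim$ann, paths["gff3"] <- file.path(dir, "genes.gff3"))
  write_bed(sim$elements, paths["truth_bed"] <-
              file.path(dir, "truth_elements.bed"))
  p <- file.path(dir, "truth_status.tsv")
  utils::write.table(sim$status, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth_status"] <- p
  invisible(paths)
}
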