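test_that("fixture emission is seed-deterministic and complete", {
  cfg <- sim_config(n_elements = 20L, background_length = 15000L,
                    loss_plan = c(hipCom0 = 4L), gap_plan = c(gasAcu1 = 3L),
                    gene_plan = list(n = 3L, cds_length = 300L), seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_fixtures(evolve_alignment(cfg), d1)
  p2 <- emit_fixtures(evolve_alignment(cfg), d2)
  expect_setequal(basename(unname(p1)),
                  c(paste0(cfg$tree$tip.label, ".fa"), "alignment.maf",
                    "genes.gff3", "truth_elements.bed", "truth_status.tsv"))
  for (k in names(p1))
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])))

  # bookkeeping: the loss plan count appears verbatim in the truth table
  st <- read.delim(p1[["truth_status"]])
  expect_equal(sum(st$status == "deleted" & st$species == "hipCom0"), 4L)
  expect_equal(sum(st$status == "gap_obscured" & st$species == "gasAcu1"), 3L)
  expect_equal(sum(st$status == "deleted" & st$species != "hipCom0"), 0L)

  # everything re-parses cleanly through the readers
  expect_no_warning({
    blocks <- read_maf(p1[["maf"]])
    ann <- read_gff3(p1[["gff3"]])
    bed <- read_bed(p1[["truth_bed"]])
    genomes <- lapply(cfg$tree$tip.label, function(sp)
      read_fasta(p1[[paste0("fasta_", sp)]], species_id = sp))
  })
  expect_equal(nrow(bed), 20L)
  expect_length(blocks, ceiling(15000 / cfg$block_length))
})

test_that("deletions and assembly gaps are planted as specified", {
  sim <- small_sim()
  tm <- truth_matrix(sim)
  blocks <- sim$blocks
  # deleted elements have zero aligned bases in the target species
  for (e in rownames(tm)[tm[, "hipCom0"] == "deleted"]) {
    i <- match(e, sim$elements$name)
    ap <- alignment_presence(sim$elements[i, ], blocks, "hipCom0")
    expect_equal(ap$coverage, 0)
  }
  # gap-obscured elements are N in the FASTA but their MAF rows exist
  gs <- sim$genomes$hipCom0
  proj <- cneloss:::species_projection(blocks, "hipCom0")$by$chr1
  for (e in rownames(tm)[tm[, "hipCom0"] == "gap_obscured"]) {
    i <- match(e, sim$elements$name)
    s <- sim$elements$start[i]; en <- sim$elements$end[i]
    aligned <- sum(proj$refpos >= s & proj$refpos < en)
    expect_equal(aligned, en - s)        # row exists across the element
    spn <- proj$sppos[proj$refpos >= s & proj$refpos < en]
    piece <- substring(gs$sequences[["chr1"]], min(spn) + 1, max(spn) + 1)
    expect_match(piece, "^N+$")
    # and the run is annotated as an assembly gap
    expect_true(any(gs$n_gaps$chr1[, "start"] <= min(spn) &
                      gs$n_gaps$chr1[, "end"] >= max(spn) + 1))
  }
})

test_that("conserved elements show elevated identity; rho = 1 does not", {
  cfg <- sim_config(n_elements = 40L, background_length = 30000L,
                    rho_conserved = 0.3, loss_plan = NULL, gap_plan = NULL,
                    gene_plan = list(n = 0L, cds_length = 300L), seed = 9L)
  sim <- evolve_alignment(cfg)
  idm <- function(sim) {
    a <- do.call(rbind, strsplit(vapply(sim$blocks, function(b)
      b$text[match("oryLat2", b$species)], ""), ""))
    r <- do.call(rbind, strsplit(vapply(sim$blocks, function(b)
      b$text[1], ""), ""))
    match_col <- as.vector(t(a)) == as.vector(t(r))
    inel <- rep(FALSE, cfg$background_length)
    for (i in seq_len(nrow(sim$elements)))
      inel[(sim$elements$start[i] + 1):sim$elements$end[i]] <- TRUE
    list(inside = mean(match_col[inel]), outside = mean(match_col[!inel]))
  }
  m <- idm(sim)
  # one-sided two-proportion comparison: inside must clearly exceed outside
  expect_gt(m$inside, m$outside + 0.05)

  cfg1 <- sim_config(n_elements = 40L, background_length = 30000L,
                     rho_conserved = 1.0, loss_plan = NULL, gap_plan = NULL,
                     gene_plan = list(n = 0L, cds_length = 300L), seed = 10L)
  sim1 <- evolve_alignment(cfg1)
  m1 <- idm(sim1)
  n_in <- sum(interval_width(sim1$elements))
  n_out <- cfg1$background_length - n_in
  phat <- (m1$inside * n_in + m1$outside * n_out) / (n_in + n_out)
  z <- (m1$inside - m1$outside) /
    sqrt(phat * (1 - phat) * (1 / n_in + 1 / n_out))
  expect_lt(abs(z), 3)   # rho = 1: no conservation signal
})

test_that("planted genes are valid ORFs with 4D sites on both strands", {
  set.seed(15)
  cfg <- sim_config(n_elements = 5L, background_length = 20000L,
                    loss_plan = NULL, gap_plan = NULL,
                    gene_plan = list(n = 8L, cds_length = 300L), seed = 15L)
  g <- plant_genes(cfg)
  expect_equal(nrow(g$ann), 8L * 4L)
  cds <- g$ann[g$ann$type == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    orf <- if (cds$strand[i] == "+") g$genomic_seq[i]
           else revcomp(g$genomic_seq[i])
    prot <- translate_dna(orf)
    expect_match(prot, "^M")                      # start codon
    expect_match(prot, "\\*$")                    # terminal stop
    expect_false(grepl("\\*.", prot))             # no internal stop
    # at least one 4D codon family member
    codons <- substring(orf, seq(1, nchar(orf) - 2, 3),
                        seq(3, nchar(orf), 3))
    expect_gte(sum(substr(codons, 1, 2) %in%
                     c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")), 1)
  }
  # zero genes: empty annotation
  cfg0 <- sim_config(gene_plan = list(n = 0L, cds_length = 300L),
                     n_elements = 5L, background_length = 5000L,
                     loss_plan = NULL, gap_plan = NULL, seed = 1L)
  expect_equal(nrow(plant_genes(cfg0)$ann), 0L)
})

test_that("placement overflow raises an error", {
  expect_error(
    evolve_alignment(sim_config(n_elements = 200L,
                                background_length = 5000L,
                                loss_plan = NULL, gap_plan = NULL,
                                gene_plan = list(n = 0L, cds_length = 300L),
                                seed = 2L)),
    "overflow")
})
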