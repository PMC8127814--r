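## hand-built two-species block: 100 reference bases, an aligned stretch
## of `n_aligned` real bases in the target, the rest gapped
presence_block <- function(n_aligned, target_char = "A") {
  ref <- paste(rep("A", 100), collapse = "")
  tgt <- paste(c(rep(target_char, n_aligned), rep("-", 100 - n_aligned)),
               collapse = "")
  b <- data.frame(species = c("zv", "q"), seqname = c("chr1", "s1"),
                  start = 0L, size = c(100L, n_aligned), strand = "+",
                  src_size = c(100L, max(n_aligned, 1L)),
                  text = c(ref, tgt), stringsAsFactors = FALSE)
  class(b) <- c("AlignmentBlock", "data.frame")
  list(b)
}

test_that("the 30% presence rule is boundary-inclusive", {
  cne <- intervals("chr1", 0L, 100L, name = "c1")
  expect_true(alignment_presence(cne, presence_block(30), "q")$present)
  r29 <- alignment_presence(cne, presence_block(29), "q")
  expect_false(r29$present)
  expect_equal(r29$coverage, 0.29)
  # aligning to N carries no evidence of presence
  expect_false(alignment_presence(cne, presence_block(35, "N"), "q")$present)
  # species absent from all blocks: coverage 0
  expect_equal(alignment_presence(cne, presence_block(30), "other")$coverage,
               0)
})

test_that("presence classification matches the planted truth", {
  sim <- small_sim()
  tm <- truth_matrix(sim)
  states <- classify_presence(sim$elements, sim$blocks, sim$genomes,
                              ref = "Zv9")
  # no false missing among undeleted, ungapped cells
  expect_equal(sum(states[tm == "present"] == "missing"), 0L)
  # deleted cells are recalled as missing
  expect_gte(mean(states[tm == "deleted"] == "missing"), 0.95)
  # gap-obscured cells are gap_uncertain, never missing
  expect_true(all(states[tm == "gap_obscured"] == "gap_uncertain"))
  expect_equal(sum(states[tm == "gap_obscured"] == "missing"), 0L)
  # state machine is total: exactly one state per cell, coverage recorded
  expect_true(all(states %in% c("present_by_alignment", "present_by_rescue",
                                "missing", "gap_uncertain")))
  expect_equal(dim(attr(states, "coverage")), dim(states))

  # raising the threshold never converts missing to present
  strict <- classify_presence(sim$elements, sim$blocks, sim$genomes,
                              ref = "Zv9", threshold = 0.6)
  was_missing <- states == "missing"
  expect_false(any(strict[was_missing] %in%
                     c("present_by_alignment", "present_by_rescue")))
})

test_that("syntenic intervals merge collinear blocks and respect N-gaps", {
  mkblk <- function(rs, ts, n, reftxt = NULL, tgttxt = NULL) {
    b <- data.frame(species = c("zv", "q"), seqname = c("chr1", "s1"),
                    start = c(rs, ts), size = n, strand = "+",
                    src_size = 10000L,
                    text = c(if (is.null(reftxt)) strrep("A", n) else reftxt,
                             if (is.null(tgttxt)) strrep("A", n) else tgttxt),
                    stringsAsFactors = FALSE)
    class(b) <- c("AlignmentBlock", "data.frame")
    b
  }
  blocks <- list(mkblk(0L, 0L, 50L), mkblk(50L, 50L, 50L))
  clean <- genome_set("q", c(s1 = rand_dna(10000)))
  sy <- gap_free_syntenic_intervals(blocks, clean, "q")
  expect_equal(nrow(sy), 1L)
  expect_true(sy$gap_free)
  expect_equal(sy$ref_start, 0L); expect_equal(sy$ref_end, 100L)

  # a 50 bp N-run inside the target span: not gap-free
  gseq <- paste0(strrep("A", 100), strrep("N", 50), rand_dna(9850))
  gappy <- genome_set("q", c(s1 = gseq))
  blocks2 <- list(mkblk(0L, 0L, 50L), mkblk(50L, 200L, 50L))
  sy2 <- gap_free_syntenic_intervals(blocks2, gappy, "q",
                                     split_at_gaps = FALSE)
  expect_equal(nrow(sy2), 1L)
  expect_false(sy2$gap_free)
  # with splitting, the clean sub-spans come back gap-free
  sy3 <- gap_free_syntenic_intervals(blocks2, gappy, "q")
  expect_true(any(sy3$gap_free))
  expect_true(all(sy3$ref_end[sy3$gap_free] <= 50L |
                    sy3$ref_start[sy3$gap_free] >= 50L))
})

test_that("syntenic intervals tile the undeleted reference span", {
  sim <- small_sim()
  sy <- gap_free_syntenic_intervals(sim$blocks, sim$genomes$oreNil2,
                                    "oreNil2")
  covered <- sum(sy$ref_end[sy$gap_free] - sy$ref_start[sy$gap_free])
  expect_gte(covered / sim$config$background_length, 0.9)
})

test_that("unique-loss calling requires uniqueness, witnesses and synteny", {
  cnes <- intervals("chr1", c(0L, 100L, 200L), c(50L, 150L, 250L),
                    name = c("c1", "c2", "c3"))
  sp <- c("s1", "s2", "s3")
  st <- matrix("present_by_alignment", 3, 3,
               dimnames = list(cnes$name, sp))
  st["c1", "s1"] <- "missing"                       # unique loss in s1
  st["c2", c("s1", "s2")] <- "missing"              # lost twice: no call
  st["c3", "s1"] <- "gap_uncertain"                 # uncertain: no call
  sy <- list(s1 = data.frame(ref_seqname = "chr1", ref_start = 0L,
                             ref_end = 60L, target_seqname = "t",
                             target_start = 0L, target_end = 60L,
                             strand = "+", gap_free = TRUE, n_anchors = 2L))
  calls <- call_unique_losses(st, cnes, sy)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$cne, "c1")
  expect_equal(calls$tier, "high_confidence")

  # outside any gap-free interval: candidate only
  sy2 <- list(s1 = sy$s1[0, ])
  expect_equal(call_unique_losses(st, cnes, sy2)$tier, "candidate")
  # no witness among the others: no call at all
  st2 <- st
  st2["c1", c("s2", "s3")] <- "gap_uncertain"
  expect_equal(nrow(call_unique_losses(st2, cnes, sy)), 0L)
})

test_that("ghost-locus scanning distinguishes absent, present, relocated", {
  set.seed(41)
  pa <- rand_protein(150); pb <- rand_protein(150)
  mid <- rand_dna(600)
  probes <- c(p1 = substr(mid, 1, 200), p2 = substr(mid, 201, 400))
  build <- function(middle, extra = "") {
    genome_set("q", c(chr1 = paste0(rand_dna(3000), back_translate(pa),
                                    rand_dna(1200), middle, rand_dna(1200),
                                    back_translate(pb), rand_dna(3000),
                                    extra)))
  }
  r_del <- ghost_locus_scan(c(A = pa), c(B = pb), build(""), probes)
  expect_equal(r_del$verdict, "absent")
  truth_len <- 2400
  expect_lt(abs(interval_width(r_del$interval) - truth_len) / truth_len, 0.1)
  expect_equal(r_del$n_gap_bp, 0L)

  r_int <- ghost_locus_scan(c(A = pa), c(B = pb), build(mid), probes)
  expect_equal(r_int$verdict, "present")
  expect_true(all(r_int$probe_hits$inside))

  r_tr <- ghost_locus_scan(c(A = pa), c(B = pb),
                           build("", extra = paste0(mid, rand_dna(500))),
                           probes)
  expect_equal(r_tr$verdict, "present_elsewhere")

  # anchors on different sequences: locus broken, no verdict
  g2 <- genome_set("q", c(c1 = paste0(rand_dna(2000), back_translate(pa),
                                      rand_dna(2000)),
                          c2 = paste0(rand_dna(2000), back_translate(pb),
                                      rand_dna(2000))))
  expect_equal(ghost_locus_scan(c(A = pa), c(B = pb), g2, probes)$verdict,
               "locus_broken")
})
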