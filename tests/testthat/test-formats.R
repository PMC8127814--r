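test_that("FASTA round-trips and computes N-gap annotation", {
  d <- withr::local_tempdir()
  set.seed(101)
  seqs <- c(chr1 = rand_dna(500), chr2 = rand_dna(211), chr3 = rand_dna(77))
  g <- genome_set("spX", seqs)
  p <- file.path(d, "g.fa")
  write_fasta(g, p, width = 60)
  g2 <- read_fasta(p, species_id = "spX")
  expect_identical(g2$sequences, g$sequences)
  expect_identical(g2$n_gaps, g$n_gaps)

  g3 <- genome_set("s", c(s1 = "ACNNNNNNNNNNGT"), min_n_run = 10L)
  expect_equal(unname(g3$n_gaps$s1), cbind(start = 2L, end = 12L),
               ignore_attr = TRUE)
  g4 <- genome_set("s", c(s1 = "ACNNNNNNNNNGT"), min_n_run = 10L)
  expect_equal(nrow(g4$n_gaps$s1), 0L)  # run of 9 is below threshold

  expect_error(genome_set("s", c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(genome_set("s", c(a = "")), "empty")
})

test_that("soft-masked and ambiguous letters are normalized with a mask track", {
  expect_warning(g <- genome_set("s", c(a = "acgtRYacgt")), "non-ACGTN")
  expect_identical(unname(g$sequences["a"]), "ACGTNNACGT")
  expect_equal(g$mask$a[, "start"], c(0L, 6L), ignore_attr = TRUE)
})

test_that("MAF parses, normalizes strand intervals and round-trips", {
  d <- withr::local_tempdir()
  p <- file.path(d, "a.maf")
  writeLines(c("##maf version=1", "", "a score=0",
               "s zv.chr1 10 5 + 100 AC-GTT",
               "s sp.s1 0 6 + 50 ACAGTT"), p)
  b <- read_maf(p)
  expect_length(b, 1L)
  expect_equal(b[[1]]$size, c(5L, 6L))
  expect_equal(b[[1]]$species, c("zv", "sp"))

  # minus-strand MAF convention on a 10 bp toy source, verified by
  # reverse complement: rc slice at rc-offset 2, size 3 must equal the
  # forward interval [10-2-3, 10-2) = [5, 8)
  src <- "ACGTACGTAC"
  rc <- revcomp(src)
  txt <- substring(rc, 3, 5)
  row <- data.frame(species = "q", seqname = "s", start = 2L, size = 3L,
                    strand = "-", src_size = 10L, text = txt)
  iv <- row_forward_interval(row)
  expect_equal(iv, c(5L, 8L))
  expect_identical(revcomp(substring(src, iv[1] + 1L, iv[2])), txt)

  p2 <- file.path(d, "b.maf")
  write_maf(b, p2)
  expect_identical(read_maf(p2), b)

  p3 <- file.path(d, "empty.maf")
  writeLines("##maf version=1", p3)
  expect_length(read_maf(p3), 0L)

  p4 <- file.path(d, "bad.maf")
  writeLines(c("a", "s zv.chr1 10 5 + 100 AC-GTT", "s sp.s1 0 6 + 50 ACA"),
             p4)
  expect_error(read_maf(p4), "block 1")
})

test_that("alignment-column to source-offset maps are bijections", {
  set.seed(42)
  for (rep in 1:20) {
    w <- sample(20:60, 1)
    mk_row <- function(sp, strand) {
      ch <- sample(c(BASES4, "-"), w, replace = TRUE, prob = c(rep(.2, 4), .2))
      size <- sum(ch != "-")
      if (size == 0L) ch[1] <- "A"
      size <- sum(ch != "-")
      data.frame(species = sp, seqname = "s", start = sample(0:50, 1),
                 size = size, strand = strand, src_size = 1000L,
                 text = paste(ch, collapse = ""))
    }
    b <- rbind(mk_row("ref", "+"), mk_row("q", sample(c("+", "-"), 1)))
    pm <- block_pos_map(b)
    for (i in 1:2) {
      pos <- pm[i, !is.na(pm[i, ])]
      iv <- row_forward_interval(b[i, ])
      expect_equal(sort(pos), seq(iv[1], iv[2] - 1L))  # bijective onto range
    }
  }
})

test_that("GFF3 conversion, TSS and phase checks work", {
  d <- withr::local_tempdir()
  ann <- data.frame(
    type = c("gene", "mRNA", "CDS", "gene"),
    seqname = "chr1",
    start = c(100L, 100L, 100L, 300L), end = c(200L, 200L, 199L, 400L),
    strand = c("+", "+", "+", "-"),
    phase = c(NA, NA, 0L, NA),
    id = c("g1", "g1.t1", "g1.c1", "g2"),
    parent = c(NA, "g1", "g1.t1", NA),
    gene_id = c("g1", "g1", "g1", "g2"), stringsAsFactors = FALSE)
  p <- file.path(d, "a.gff3")
  write_gff3(ann, p)
  a2 <- read_gff3(p)
  expect_equal(a2$start[a2$id == "g1"], 100L)  # GFF 101..200 -> [100,200)
  expect_equal(a2$end[a2$id == "g1"], 200L)
  tss <- tss_of(a2)
  expect_equal(tss$tss[tss$gene_id == "g1"], 100L)
  expect_equal(tss$tss[tss$gene_id == "g2"], 399L)  # minus strand: end - 1
  expect_equal(a2$gene_id[a2$type == "CDS"], "g1")

  # inconsistent CDS phases: second exon phase must follow from first
  bad <- data.frame(
    type = c("mRNA", "CDS", "CDS"), seqname = "chr1",
    start = c(0L, 0L, 50L), end = c(100L, 10L, 60L), strand = "+",
    phase = c(NA, 0L, 0L),   # correct phase after 10 bp would be 2
    id = c("m1", "c1", "c2"), parent = c(NA, "m1", "m1"),
    gene_id = "m1", stringsAsFactors = FALSE)
  pb <- file.path(d, "bad.gff3")
  write_gff3(bad, pb)
  expect_error(read_gff3(pb), "phase")
})

test_that("BED round-trips and rejects bad intervals", {
  d <- withr::local_tempdir()
  x <- intervals(c("chr1", "chr2"), c(5L, 0L), c(15L, 7L),
                 name = c("cne1", "cne2"), score = c(320, 1.5))
  p <- file.path(d, "x.bed")
  write_bed(x, p)
  y <- read_bed(p)
  expect_equal(y$start, x$start)
  expect_equal(y$name, x$name)
  expect_equal(y$score, x$score)
  expect_error(intervals("chr1", -1L, 5L), "negative")
  expect_error(intervals("chr1", 9L, 9L), "start must be <")
})

test_that("coverage_fraction takes the union of hits and is monotone", {
  a <- intervals("c", 0L, 10L)
  expect_equal(coverage_fraction(a, intervals("c", 5L, 15L)), 0.5)
  expect_equal(coverage_fraction(a, intervals(c("c", "c"), c(0L, 2L),
                                              c(4L, 6L))), 0.6)
  expect_equal(coverage_fraction(a, intervals(character(), integer(),
                                              integer())), 0)
  expect_equal(coverage_fraction(a, intervals("other", 0L, 10L)), 0)
  set.seed(7)
  for (rep in 1:10) {
    s <- sample(0:40, 6); e <- s + sample(1:10, 6, replace = TRUE)
    hits <- intervals("c", s, e)
    a2 <- intervals("c", 0L, 40L)
    c1 <- coverage_fraction(a2, hits[1:3, ])
    c2 <- coverage_fraction(a2, hits)      # superset of hits
    expect_gte(c2, c1)
    expect_true(c2 >= 0 && c2 <= 1)
  }
})
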