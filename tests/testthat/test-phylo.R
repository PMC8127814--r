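test_that("GTR rate matrices satisfy the reversible-model identities", {
  set.seed(21)
  for (rep in 1:10) {
    m <- rand_gtr()
    expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(-m$pi * diag(m$Q)), 1, tolerance = 1e-12)
    # detailed balance pi_i Q_ij = pi_j Q_ji
    F <- diag(m$pi) %*% m$Q
    expect_equal(F, t(F), tolerance = 1e-12, ignore_attr = TRUE)
    # exp(Q*0) = I and Chapman-Kolmogorov
    expect_equal(transition_matrix(m, 0), diag(4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    s <- runif(1, 0, 1); t <- runif(1, 0, 1)
    expect_equal(transition_matrix(m, s) %*% transition_matrix(m, t),
                 transition_matrix(m, s + t), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rowSums(transition_matrix(m, t)), rep(1, 4),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pruning likelihood matches closed forms and enumeration", {
  # single observed leaf (partner all-missing): log pi_base
  m <- rand_gtr()
  t2 <- ape::read.tree(text = "(A:0.0,B:0.5);")
  col <- matrix(c("A", "N"), 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(column_log_likelihood(t2, m, col), log(unname(m$pi["A"])),
               tolerance = 1e-12)

  # JC69 two-leaf closed form
  jc <- gtr_model(rep(0.25, 4), rep(1, 6))
  for (tt in c(0.01, 0.1, 0.5, 1, 2)) {
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", tt / 3, 2 * tt / 3))
    same <- matrix(c("G", "G"), 2, 1, dimnames = list(c("A", "B"), NULL))
    diff <- matrix(c("G", "T"), 2, 1, dimnames = list(c("A", "B"), NULL))
    expect_equal(exp(column_log_likelihood(tr, jc, same)),
                 0.25 * (0.25 + 0.75 * exp(-4 * tt / 3)), tolerance = 1e-10)
    expect_equal(exp(column_log_likelihood(tr, jc, diff)),
                 0.25 * (0.25 - 0.25 * exp(-4 * tt / 3)), tolerance = 1e-10)
  }

  # 4-leaf enumeration oracle, including missing data
  set.seed(77)
  for (rep in 1:25) {
    m <- rand_gtr()
    tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.8))
    tr$tip.label <- c("A", "B", "C", "D")
    states <- sample(c("A", "C", "G", "T", "N"), 4, replace = TRUE,
                     prob = c(rep(0.22, 4), 0.12))
    col <- matrix(states, 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
    expect_equal(column_log_likelihood(tr, m, col),
                 brute_column_loglik(tr, m,
                                     setNames(states, c("A", "B", "C", "D"))),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  set.seed(31)
  m <- rand_gtr()
  tr <- default_tree()
  cols <- simulate_columns(tr, m, 200)
  sc <- site_columns(cols, collapse = TRUE)
  ll1 <- total_log_likelihood(tr, m, sc)
  rerooted <- ape::root(tr, outgroup = "oryLat2", resolve.root = TRUE)
  ll2 <- total_log_likelihood(rerooted, m, sc)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("leaf in columns absent from tree errors", {
  m <- rand_gtr()
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  col <- matrix("A", 1, 1, dimnames = list("Z", NULL))
  expect_error(column_log_likelihood(tr, m, col), "absent from tree")
})

test_that("4D extraction follows codons strand-aware", {
  # single-exon plus-strand gene: GCA (Ala, 4D) ATG (Met, not 4D) CCT (Pro)
  ref <- "AAGCAATGCCTTAA"  # gene CDS at [2, 14)
  sp2 <- "AAGCGATGCCATAA"
  blk <- data.frame(species = c("zv", "q"), seqname = c("chr1", "s1"),
                    start = 0L, size = 14L, strand = "+", src_size = 14L,
                    text = c(ref, sp2), stringsAsFactors = FALSE)
  class(blk) <- c("AlignmentBlock", "data.frame")
  ann <- data.frame(type = c("mRNA", "CDS"), seqname = "chr1",
                    start = 2L, end = 14L, strand = "+",
                    phase = c(NA, 0L), id = c("m1", "c1"),
                    parent = c(NA, "m1"), gene_id = "g1",
                    stringsAsFactors = FALSE)
  cols <- extract_4d_columns(list(blk), ann)
  # third positions of GCA and CCT are 4D; ATG's is not
  expect_equal(sort(attr(cols, "coords")), c(4L, 10L))
  expect_equal(sum(cols$weights), 2)

  # minus-strand gene on the same alignment: manual codon walk oracle
  set.seed(13)
  orf <- paste0("ATG", back_translate(rand_protein(10)), "TAA")
  gseq <- revcomp(orf)                     # genomic strand
  pad <- rand_dna(6)
  refm <- paste0(pad, gseq, rand_dna(4))
  blk2 <- data.frame(species = c("zv", "q"), seqname = c("chr1", "s1"),
                     start = 0L, size = nchar(refm), strand = "+",
                     src_size = nchar(refm),
                     text = c(refm, rand_dna(nchar(refm))),
                     stringsAsFactors = FALSE)
  class(blk2) <- c("AlignmentBlock", "data.frame")
  ann2 <- data.frame(type = c("mRNA", "CDS"), seqname = "chr1",
                     start = 6L, end = 6L + nchar(orf), strand = "-",
                     phase = c(NA, 0L), id = c("m1", "c1"),
                     parent = c(NA, "m1"), gene_id = "g1",
                     stringsAsFactors = FALSE)
  cols2 <- extract_4d_columns(list(blk2), ann2)
  # oracle: walk codons of the ORF (coding strand), pick 4D third
  # positions, map to genome coordinates on the minus strand
  fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  exp_coords <- integer()
  cend <- 6L + nchar(orf)
  for (cd in seq_len(nchar(orf) / 3)) {
    codon <- substring(orf, 3 * cd - 2, 3 * cd)
    if (substr(codon, 1, 2) %in% fourfold)
      exp_coords <- c(exp_coords, cend - 3L * cd)  # genome coord of 3rd pos
  }
  expect_equal(sort(attr(cols2, "coords")), sort(exp_coords))
})

test_that("neutral-model fitting behaves like a maximum-likelihood estimator", {
  tr <- default_tree()
  # all columns identical: every branch at the lower bound
  same <- matrix("A", 6, 30, dimnames = list(tr$tip.label, NULL))
  sc <- site_columns(same, collapse = TRUE)
  expect_error(fit_neutral_model(sc, tr), "no variable")
  same[1, 1] <- "C"  # one substitution makes it fittable
  fit0 <- fit_neutral_model(site_columns(same, collapse = TRUE), tr)
  expect_true(mean(fit0$tree$edge.length <= 1e-6) >= 0.5)

  # fitted log-likelihood >= likelihood at the generating parameters
  set.seed(99)
  m <- gtr_model(c(0.31, 0.19, 0.19, 0.31), c(1, 4, 1, 1, 4, 1))
  cols <- simulate_columns(tr, m, 3000)
  sc <- site_columns(cols, collapse = TRUE)
  fit <- fit_neutral_model(sc, tr)
  expect_gte(fit$loglik, total_log_likelihood(tr, m, sc))
  expect_gte(fit$loglik, fit$init_loglik)
})

test_that("outgroup distances equal path sums", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,O:0.3);")
  d <- distance_to_outgroup(tr, "O")
  expect_equal(unname(d["A"]), 0.45)
  expect_equal(unname(d["B"]), 0.55)
  cm <- attr(d, "cophenetic")
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), rep(0, 3), ignore_attr = TRUE)
  expect_error(distance_to_outgroup(tr, "Z"), "unknown leaf")

  set.seed(5)
  tr8 <- ape::rtree(8)
  d8 <- distance_to_outgroup(tr8, tr8$tip.label[1])
  for (lf in names(d8))
    expect_equal(unname(d8[lf]),
                 brute_leaf_distance(tr8, tr8$tip.label[1], lf),
                 tolerance = 1e-12)
})

test_that("relative rate test counts and tests lineage-specific changes", {
  # equal counts: chi-square 0, p = 1
  o <- strsplit(paste(rep("A", 40), collapse = ""), "")[[1]]
  a <- o; a[1:10] <- "C"
  b <- o; b[11:20] <- "G"
  r <- relative_rate_test(a, b, o)
  expect_equal(r$m1, 10); expect_equal(r$m2, 10)
  expect_equal(r$chisq, 0); expect_equal(r$p_value, 1)

  # 15 vs 5
  a2 <- o; a2[1:15] <- "C"
  b2 <- o; b2[16:20] <- "G"
  r2 <- relative_rate_test(a2, b2, o)
  expect_equal(r2$chisq, 5)
  expect_equal(r2$p_value, 0.02535, tolerance = 1e-3)

  # 60 bp toy: counts match an independent column scan, N/- excluded
  set.seed(61)
  sq <- function() sample(c(BASES4, "N", "-"), 60, replace = TRUE,
                          prob = c(rep(.22, 4), .06, .06))
  a3 <- sq(); b3 <- sq(); o3 <- sq()
  ok <- a3 %in% BASES4 & b3 %in% BASES4 & o3 %in% BASES4
  m1 <- sum(ok & a3 != o3 & b3 == o3)
  m2 <- sum(ok & b3 != o3 & a3 == o3)
  r3 <- relative_rate_test(a3, b3, o3)
  expect_equal(r3$m1, m1)
  expect_equal(r3$m2, m2)
  expect_equal(r3$n_excluded, sum(!ok))
  expect_error(relative_rate_test(a3[1:10], b3, o3), "equal length")
})
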