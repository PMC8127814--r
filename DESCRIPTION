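Package: cneloss
Title: Detection of Lineage-Specific Conserved Noncoding Element Loss
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-genomics machinery for detecting lineage-specific
    loss of conserved noncoding elements (CNEs) from reference-anchored
    multiple alignments. Fits a neutral general time-reversible (GTR)
    substitution model from fourfold-degenerate sites by Felsenstein
    pruning, segments alignments into conserved elements with a two-state
    phylogenetic hidden Markov model (including rho estimation for the
    conserved model), classifies per-species element presence with a
    coverage rule plus a seed-and-extend homology rescue search, filters
    loss calls to gap-free syntenic intervals so assembly gaps cannot
    masquerade as losses, tests lineage rate differences, scans ghost loci
    for gene loss, and performs nearest-TSS hypergeometric enrichment with
    FDR control. Ships a seed-deterministic simulator that evolves genomes
    along a phylogeny with planted conserved elements, deletions, assembly
    gaps and genes, so the whole pipeline is testable against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
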