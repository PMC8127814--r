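---
title: "Detecting lineage-specific CNE loss: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific CNE loss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cneloss)
```

## The problem

Conserved noncoding elements (CNEs) are genomic intervals that evolve far
more slowly than the neutral expectation yet overlap no coding exon; most
act as cis-regulatory elements. When a CNE that is conserved across a
clade is missing from exactly one lineage, that loss is a candidate
driver of lineage-specific morphology — but "missing from an alignment"
can also mean a genome rearrangement, assignment of the element to the
other member of a duplicated paralogon, or simply an assembly gap.
`cneloss` implements the full decision chain that separates genuine loss
from these artifacts, plus the machinery needed before it: a neutral
substitution model fitted from fourfold-degenerate (4D) sites, a
two-state phylogenetic HMM that segments a reference-anchored multiple
alignment into conserved elements, and downstream rate tests, ghost-locus
scans and enrichment statistics.

Because the genome-scale inputs behind published counts are
multi-gigabyte downloads, the package carries a first-class simulator
that generates genomes, true alignments, annotations and a truth table
with the statistical structure the analysis assumes. Every pipeline
stage is therefore testable against planted truth.

## Substitution model and likelihoods

The neutral model is a general time-reversible (GTR) model: equilibrium
frequencies $\pi$ and six exchangeabilities $s_{ij}$ give
$Q_{ij} = s_{ij}\pi_j$ ($i \ne j$), diagonal set so rows sum to zero,
and $Q$ scaled so $-\sum_i \pi_i Q_{ii} = 1$; branch lengths are then in
expected substitutions per site. $P(t) = e^{Qt}$ is computed by
eigendecomposition of the symmetrized matrix
$D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}(\pi)$), which guarantees a
valid stochastic matrix for any $t \ge 0$.

Column likelihoods use Felsenstein pruning, vectorized across columns
with per-column rescaling; `N` and `-` are missing data (partial
likelihoods of 1). Identical columns are collapsed into weighted
patterns before any optimization, which is what makes 50 kb fits cheap:
a 6-taxon alignment has at most $4^6$ complete patterns.

### Fitting

`fit_neutral_model()` sets $\pi$ to the weighted empirical base
frequencies, then alternates Brent line searches on each branch length
(bounds $[10^{-6}, 10]$; the lower bound is checked explicitly so
saturated data land exactly on it) with a bounded quasi-Newton step on
the log exchangeabilities (GT fixed at 1), until the log-likelihood
improves by less than `tol` ($10^{-6}$) in a sweep. With a two-child
root only the *sum* of the two root-adjacent branch lengths is
identifiable under a reversible model; the implementation pins one of
them near zero so its sibling carries the sum, and the acceptance test
evaluates recovery on that sum. Branch lengths of all other edges are
recovered within ±15% from 50 kb of simulated 4D-like columns.

4D sites are extracted from the reference species' CDS annotations only:
a third codon position qualifies when the first two reference bases put
the codon in a 4D family (prefixes CT, GT, TC, CC, AC, GC, CG, GG).
Columns from minus-strand genes are complemented onto the coding strand.
Codons not fully contained in one alignment block are skipped and
counted.

## The conservation HMM

Two states — neutral and conserved — emit alignment columns with
phylogenetic likelihoods; the conserved state uses the neutral tree with
every branch multiplied by $\rho < 1$. The two user-facing knobs are the
target coverage $\gamma$ (default 0.3) and the expected element length
$\omega$ (default 45 bp), the values standard for teleost whole-genome
screens. They map to transition rates $\mu = 1/\omega$
(conserved→neutral) and $\nu = \mu\gamma/(1-\gamma)$, which makes
$\gamma$ the *exact* stationary conserved occupancy and $\omega$ the
exact mean conserved run length; the chain is initialized at this
stationary distribution.

$\rho$ is estimated per reference chromosome by maximizing the total HMM
log-likelihood with Brent search on $(0.01, 1]$ (golden-section with a
parabolic accelerator; the optimum is the same), and per-chromosome
estimates are averaged arithmetically into one conserved model (a
length-weighted mean is available by flag). Estimates within 0.02 of a
search bound set a boundary flag and warn — fully neutral data, for
example, drives $\hat\rho$ to the upper bound.

Segmentation uses the Viterbi path rather than posterior thresholding:
it is deterministic and checkable against exhaustive path enumeration,
and ties are broken toward the neutral state so ambiguous columns never
extend an element. Element scores are summed per-column log-odds
(conserved minus neutral). Columns where the reference row is gapped
carry no reference coordinate; a conserved run is bridged across at most
10 such columns, otherwise split. Elements shorter than 15 reference bp
are dropped as a noise floor. Both choices are configurable; the
upstream literature is silent on them.

A CNE is a called element with zero overlap to any annotated CDS or exon
and presence in at least one non-reference species.

## Presence, rescue, and the gap-free filter

Per (CNE, species) cell the classification is a two-stage rule:

1. **Alignment coverage.** The fraction of the CNE's reference bases
   aligned to real (non-gap, non-N) bases of the species; at least 30%
   (boundary inclusive) means `present_by_alignment`. Counting a base
   aligned to `N` as evidence of presence would make assembly gaps
   self-certifying, so N-aligned bases are excluded.
2. **Homology rescue.** Otherwise the CNE sequence is searched against
   the whole target genome; a collinear chain with E-value $< 10^{-10}$,
   identity ≥ 80% and query coverage ≥ 30% means `present_by_rescue`.
   This recovers elements displaced by rearrangement or sitting on the
   duplicate paralogon.

A cell that fails both is `missing` — unless the CNE's projected locus
(the target span between its nearest flanking aligned anchors) overlaps
an assembly N-gap, or the CNE has no flanking anchors at all, in which
case it is `gap_uncertain` and never counted as a loss.

A *unique loss* in species S is a CNE missing in S, missing in no other
species, and present in at least one other non-reference species (the
witness count is configurable). The call is *high-confidence* when the
CNE additionally lies inside a gap-free syntenic interval for S:
consecutive collinear alignment blocks are merged into syntenic runs
(same sequence pair and strand, monotone advance, anchor spacing ≤ 100
kb), and a run is gap-free when no target N-run intersects its target
span. Runs containing N-gaps are subdivided at the gaps — including
gaps lying in unaligned sequence between anchors — and the clean
sub-spans re-emitted, so elements away from any gap still reach the
high-confidence set. The construction of these intervals is not
specified in the upstream literature; this block-merging definition is
our declared, parameterized interpretation.

## Homology search

The search engine is a self-contained seed-and-extend: exact word seeds
(11 nt, or 4 aa for the translated search) extended ungapped under
+1/−1 scoring with an x-drop, gaps handled at the chaining level —
the division of labour used by chaining-based pipelines. Chaining is
sparse dynamic programming for the maximum-score collinear set, with
overlap charged to the lower-scoring HSP at its per-base score density;
"alignment rate" is chain coverage of the query. E-values use
$K m n e^{-\lambda S}$ with $\lambda = \ln 3$ (DNA) or $\ln 19$
(protein) — the exact solutions for ±1 scoring at uniform frequencies —
and $K$ fixed at 0.5. These E-values rank and gate; no acceptance
property depends on their absolute scale, only on planted-versus-random
separation.

The translated miner applies the two-stage gates used for gene-family
mining (mapping: E ≤ 1e−10, rate ≥ 0.5; retention: rate > 70%,
identity > 40%), extends retained spans by 280 bp and merges overlaps.
Where the two gate sets apply was not spelled out upstream; the
two-stage reading is implemented and both sets are parameters.
`ghost_locus_scan()` reuses the miner with zero flank so the
inter-anchor interval is not shrunk by gene-model padding, and its
verdict is `absent` only when no probe is found anywhere in the genome.

## Enrichment

Lost CNEs are assigned to the gene with the nearest transcription start
site within 1 Mb (midpoint anchor; exact ties break to the smaller
coordinate and are recorded in a sidecar). Enrichment is an upper-tail
hypergeometric test per term with Benjamini–Hochberg FDR control; the
default universe is the genes with at least one CNE assigned — whether
the original analyses used all genes or CNE-adjacent genes is unstated,
so the universe is switchable. Note that hypergeometric p-values are
discrete and therefore conservative in small universes; the calibration
test asserts approximate uniformity of permutation p-values at a scale
(2,000 genes) where discreteness is negligible, which is a property of
the test statistic, not of any particular data set.

## The synthetic world

`sim_config()` fixes the stated world: the 6-taxon topology
`(Zv9,(hipCom0,((fr3,gasAcu1),(oryLat2,oreNil2))))` with branch lengths
totalling ~1.2 substitutions/site; a GTR model with transition bias
(π = 0.31/0.19/0.19/0.31, AG = CT = 4); ρ = 0.3 in conserved elements;
500 elements with truncated-geometric lengths of mean 168 bp (the
typical observed CNE size in teleost screens) on a 300 kb background
(≈ 28% element coverage, matching γ = 0.3); 50 elements deleted and 25
replaced by assembly N-runs in the seahorse lineage (both plans hit the
same lineage deliberately — gaps faking losses is precisely the failure
mode the gap-free filter exists for); and 30 single-exon 300-bp genes.

Sites evolve independently under $P(t) = e^{Qt}$; because the model is
reversible, the simulator roots the tree at the reference tip, which
lets planted ORFs appear verbatim in the emitted reference genome.
Coding sequence is constrained at codon positions 1–2 (scaled by ρ)
while third positions evolve neutrally — so exon sensitivity checks have
signal to find and extracted 4D sites remain a valid neutral proxy.
Deletions remove element columns from the target row and genome; gap
plans replace the element's bases by N in both the genome and the
alignment row (the assembly, and any alignment of it, shows N there).

What the simulator does **not** emulate: indels and alignment error (the
emitted alignment is the true one; no aligner runs), rearrangements,
transposable elements, rate variation across sites beyond the
element/background dichotomy, and base-composition heterogeneity along
the genome. A green end-to-end test therefore establishes that the
decision rules are implemented correctly and are robust to the planted
artifact modes — not that the pipeline is robust to alignment error.

## Numerical choices

* Branch-length bounds $[10^{-6}, 10]$, coordinate-ascent convergence at
  $\Delta\ell < 10^{-6}$, Brent tolerance $10^{-5}$.
* $\rho$ search bounds $(0.01, 1]$, tolerance $10^{-4}$, boundary
  margin 0.02.
* Forward–backward uses scaled linear-space recursions; forward and
  backward totals agree to $10^{-9}$ and are tested against exhaustive
  enumeration for $L \le 8$.
* Assembly gaps are maximal N-runs of length ≥ 10 (`min_n_run`); the
  operational definition of a sequencing gap is not stated upstream.
* Soft-masked input is uppercased with a retained mask track; other
  IUPAC codes become N with a warning.
* All internal coordinates are 0-based half-open; GFF3 converts on
  read/write, MAF minus-strand rows normalize through
  `row_forward_interval()`.
* Pipeline stage seeds derive from the config seed by a fixed affine
  hash below $2^{31}$.

## Known limitations

Ungapped HSPs understate identity across true indels, so rescue of CNEs
with large internal insertions is conservative. The HMM treats columns
with missing species via missing-data partials rather than dropping
them; with many absent rows the conserved/neutral contrast weakens and
calls become prior-driven. Syntenic intervals come from the same
projection alignment used for presence, not from an independent
chain/net, so a CNE absent because the whole region failed to align is
`gap_uncertain` rather than `missing` — conservative by design. The
enrichment stage ships a placeholder two-term map when no annotation is
supplied; real analyses must provide gene–term tables.
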