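---
title: "Comparative plastome analysis with plastomics: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

# The problem

Chloroplast genomes (plastomes) of photosynthetic land plants are circular
molecules of roughly 120–180 kb with a quadripartite layout: a Large and a
Small Single-Copy region (LSC, SSC) separated by two Inverted Repeat copies
(IRA, IRB) that are exact reverse complements of each other. Although the
layout is broadly conserved, individual lineages show dramatic structural
variation: expansion of the IR deep into the single-copy regions, contraction
down to a few-hundred-bp residual IR, segmental inversions and relocations,
and recurrent gene loss or pseudogenization. These events shift the four
IR–single-copy junctions (named JLB = LSC/IRB, JSB = IRB/SSC, JSA = SSC/IRA,
JLA = IRA/LSC), inflate or deflate gene counts, and complicate both
annotation and phylogenetic use of plastome data.

`plastomics` implements the full comparative workflow on annotated
plastomes: quadripartite structure detection and junction characterization,
gene-content matrices, signed gene-order rearrangement calls, repeat
profiling (SSR / tandem / dispersed), syntenic-locus marker screening with a
sequence-variability statistic, per-site substitution-rate estimation with
phylogenetic-informativeness profiling, and desk-scale distance phylogenetics
— plus a seeded simulator of plastome evolution so that every stage is
testable offline against known truth.

# Coordinates and containers

All internal coordinates are 0-based half-open; GenBank and GFF3 coordinates
(1-based inclusive) are converted exactly once, at the I/O boundary, and BED
output is 0-based half-open. Circular sequences are stored linearized at an
explicit origin and any interval may wrap it (its end then exceeds the
genome length; positions are taken modulo the length). Junction positions
are reported as the first base of the downstream region. The canonical
orientation is `LSC → IRB → SSC → IRA` with JLA at the origin and *rbcL* on
the forward strand; `canonicalize_record()` rotates/flips any record into
it and is idempotent.

# Structure detection

`detect_ir()` finds the maximal-length pair of disjoint intervals on the
circle whose sequences are reverse complements up to a mismatch budget.
Every base pairing of such a pair lies on a single "anti-diagonal" of the
circle (position sums constant modulo the length), so maximal pairs are
maximal match windows on the mirror arcs of anti-diagonals. The detector
seeds candidate anti-diagonals with exact k-mer hits (k chosen so that any
qualifying repeat must contain a seed, by pigeonhole over the mismatch
budget), then scans each candidate exactly — making it subquadratic in
practice while provably returning the same answer as exhaustive search. The
exhaustive enumeration (`.ir_brute_cpp`) is retained as the test oracle, and
the equivalence — including the tie-breaking order (longer, then fewer
mismatches, then smaller start) — is asserted on hundreds of random genomes.

Defaults: `min_len = 100` (small enough to catch a 355 bp residual IR, far
above the ~20 bp longest chance inverted match in a 160 kb genome) and
`max_mismatch = 0`, because assembled plastomes almost always carry
*identical* IR copies.

The two single-copy arcs are labelled by **marker-gene content, not size**:
the arc with the majority of {*ndhF*, *ndhA*, *ndhD*, *ccsA*, *ycf1*} is the
SSC and the arc with the majority of {*psbA*, *rbcL*, *matK*, *atpA*} the
LSC. This matters because near-complete IR loss can leave a "small"
single-copy region that is physically larger than the LSC; size is only a
fallback for unannotated input, and annotations that put both marker sets on
one arc raise a diagnostic error.

`classify_shift()` separates ordinary junction wobble (Group A) from
large-scale IR expansion/contraction (Group B) using configurable
thresholds, by default `ir_len < 1000`, `ir_len > 35000`, or
`SSC < 10000` bp. Published genus-level comparisons describe the grouping
qualitatively rather than numerically; these defaults reproduce the typical
grouping of ~25 kb-IR plastomes versus residual-IR (hundreds of bp) and
giant-IR (>40 kb) genomes, and they are parameters, not constants.

# The simulator and what a green test establishes

`build_ancestor()` assembles `LSC + IRB + SSC + IRA` from a canonical
~110-gene template (rrn operon and its tRNAs in the IR; the ndh suite,
*ccsA* and *ycf1* in the SSC; everything else in the LSC), with valid
start/stop codons, intron structure for the cis-spliced genes, and IR genes
mirrored into both copies. `evolve_plastomes()` then walks a clock tree:

* **Substitutions** follow Jukes–Cantor with *exact* per-branch transition
  probabilities (an optional gamma multiplier adds rate heterogeneity,
  redrawn per branch — a documented approximation that preserves the
  per-branch JC expectation but not cross-branch site identity).
  Substitutions falling in the IR are applied to both copies, so
  `IRA == revcomp(IRB)` holds exactly at every node (concerted evolution).
* **Indels** are restricted to single-copy intergenic spacers, keeping gene
  coordinates and the truth bookkeeping exact.
* **Structural events** (junction shifts, gene loss, pseudogenization,
  inversion, relocation, planted SSR/tandem/dispersed repeats) occur as
  Poisson processes along branches; every applied event is recorded with its
  signed length effect, and the suite asserts that genome-length changes
  equal the signed sum of those effects.

Two deliberate design choices make "exact structure recovery" a well-posed
test rather than a coin flip. First, single-base **junction walls**: the
bases flanking the IR on both sides are set so they cannot extend the
inverted pair, and those four positions are excluded from mutation. Without
them the maximal inverted repeat would, with probability ~1/4 per junction
end, overshoot the constructed IR by a base. Second, planted repeats carry
**mismatching walls** (and, for dispersed repeats, internal substitutions
equal to the detector's Hamming budget) so that the planted window is itself
a maximal hit — otherwise maximality under a mismatch budget would smear
the planted coordinates by a few bases.

What the generator does **not** emulate: real plastomes are AT-rich
(~63 % AT) with strong local composition structure, whereas the generator
draws uniform bases; substitution is codon-blind, so CDSs accumulate chance
internal stop codons at realistic divergences (the truth log records the
*realized* status of every gene, so classification tests remain exact);
there is no recombination, no codon usage, and no read-level error. A green
structure/content/repeat test therefore establishes algorithmic correctness
on genomes with the right architecture, not distributional realism of base
composition.

# Gene content

`classify_gene()` calls a reference gene *lost* when no annotated copy
exists and no open reading frame of at least 30 % of the reference length
remains between its reference neighbours; *pseudo* on an annotated pseudo
flag, an internal stop, a coding length not divisible by three, or
truncation below 50 % of the reference; *duplicated* at two or more copies
(flagged `in_IR` when both sit in the IRs); otherwise *single*. The
thresholds are implementation decisions — published tables report
pseudogenization without criteria — chosen to match standard practice and to
be fully testable. Counts in `content_matrix()` include **every annotated
copy**, which is the convention that makes IR-expanded genomes show inflated
gene totals in published summary tables.

# Rearrangements

Rather than re-implementing an anchored whole-genome aligner, rearrangements
are called on **signed gene orders** (one IR copy removed, genes listed from
JLA with strand as sign): published genus-level rearrangement statements are
all gene-wise, so the gene-order proxy reproduces them while staying
verifiable. `find_blocks()` chains maximal runs that are consecutive and
equioriented in both circular orders, picks a maximum-gene-weight backbone
of plus-orientation blocks preserving circular order in both genomes, and
classifies the rest: flipped in place = inversion, moved = relocation, both
= inverted relocation. When a block jumps over a *smaller* block the two
descriptions are mathematically equivalent; the backbone convention
deterministically relocates the smaller one, and equal-size jumps are
genuinely ambiguous (the truth-recovery test plants only unambiguous
events). `windowed_identity()` provides the windowed percent-identity view
of a pairwise alignment (dual-gap columns excluded from the denominator).

# Repeats

* **SSRs**: every maximal perfect run of a primitive 1–6 bp motif meeting
  the conventional copy thresholds (10 / 6 / 5 / 5 / 5 / 5 by motif length),
  reported once, labelled by its leftmost phase, motifs literal (A ≠ T,
  AT ≠ TA), circular runs included. No compound-SSR merging: per-motif
  tallies are what published tables count, and compound rules are
  tool-specific.
* **Tandem arrays**: a simplified scanner — offset-p self-match runs merged
  across up to 3 mismatch positions, per-phase majority consensus, score
  `2·matches − 7·mismatches − 7·indel_bases` minus one perfect unit's credit
  (so a perfect array of length T and period p scores `2(T − p)`, and one
  substitution costs 9), minimum score 80, maximum period 500, arrays
  re-reported at period multiples suppressed. This is explicitly *not*
  bit-compatible with the classic heuristic tandem-repeat program; the
  scanner itself introduces no indels, so an indel inside an array splits
  it. The subtraction of one unit's credit is forced by internal consistency
  of the conventional score definition (sum-over-positions and the worked
  perfect-array score cannot both hold otherwise).
* **Dispersed repeats**: maximal pairs of the four kinds (Forward, Reverse,
  Complement, Palindromic) with at most 3 substitutions over at least 30 bp,
  found by seed-and-extend. The seed length adapts to the parameters
  (`k = (min_len − h)/(h + 1)`, capped at 12) so a qualifying hit always
  contains an exact seed; a brute-force anchor enumeration is the oracle and
  the two agree exactly, including the deduplication of mirror pairs and of
  hits nested in longer hits of the same kind. The genome is scanned with
  both IR copies present, so the IR itself surfaces as one long palindromic
  hit — as the conventional tools report it.

# Marker screening

Intergenic spacers (between consecutive genes in canonical orientation) and
introns (between consecutive exons) are keyed by their flanking pair
(`geneA--geneB`, `gene_intronK`). A locus is *syntenic* when the same key
occurs exactly once in every genome; loci inside the IR are collapsed to the
IRB instance, and loci with mean unaligned length < 150 bp are discarded
(the mean is used because the conventional cutoff is stated without a
per-species rule; the mean is symmetric and stable).

Loci are aligned by a small deterministic progressive aligner
(profile–profile Gotoh, match +2, mismatch −1, gap open −4, gap extend −1,
guide tree from shared 6-mer counts) and scored with the sequence
variability statistic

\[ SV = \frac{\text{mutations} + \text{indel events}}
           {\text{conserved sites} + \text{mutations} + \text{indel events}} \]

with mutations counted as (distinct bases − 1) per gap-free column — the
*total mutations* convention, so multi-allelic columns count multiply — and
an indel event being a maximal gap run, with runs sharing identical
(start, end) across sequences counted once. Overlapping-but-unequal runs are
distinct events: simple, deterministic, and testable, where the conventional
counting tool leaves this unspecified. SV is computed on the untrimmed locus
alignment; `trim_alignment()` (drop columns above a gap fraction, default
0.5) is available where a trimming stand-in is wanted. Ranking is by SV
descending, ties by longer mean locus length, then id.

# Rates and phylogenetic informativeness

`ultrametricize()` converts a tree with branch lengths to relative time:
node ages by mean path length to descendant tips (parents forced above
children), tips at 0, root rescaled to exactly 1; unrooted input is
midpoint-rooted. `estimate_site_rates()` maximizes the Jukes–Cantor pruning
likelihood of each column over a fixed tree, with λ bounded on [0, 20]
(tolerance 1e−6), gaps/N as missing data and invariant columns pinned at 0.
This is a deliberate, self-contained replacement for the HyPhy-based rate
estimation used with the PhyDesign service: it is oracle-verifiable (the
pruning likelihood is tested against brute-force summation over internal
states) at the cost of a simpler substitution model.

Informativeness uses the four-state Poisson form
\( \rho(t;\lambda) = 16\,\lambda^2\, t\, e^{-4\lambda t} \) on a 200-point
grid over (0, 1]: zero at t = 0, a single interior maximum at
\( t = 1/(4\lambda) \), decaying to zero — the hump-shaped per-site profile
of the profiling literature. The constant 16 and the grid are conventions;
every ranking in the package is invariant to them. Per-gene curves are
normalized per site (net PI divided by the gene's alignment length) so that
long genes do not dominate by length alone.

**Known limitation (kept as a red test, by design):** per-site maximum
likelihood rate estimates are upward-biased in small samples. At the
16-tip / 500-sites-per-class scale used in the acceptance suite, the class
means overshoot truth by ~20–40 % on every reasonable clock-tree shape
(the pruning computation itself is exact against the brute-force oracle,
and at 64 tips the same code recovers class means within ~10 %). The
acceptance test states the stricter 15 % contract and fails honestly;
rank-level separation of rate classes (Spearman ≥ 0.9 on classified
estimates) holds and is tested green. Users who need calibrated per-site
rates at small tip counts should treat the estimates as ordinal.

# Desk-scale phylogenetics

Distances (`p`, `JC69`, `K2P`) use pairwise deletion of gap/N sites —
complete deletion can annihilate plastome loci with localized gaps — and
saturation (p ≥ 3/4 under JC) is an error naming the pair, not a silent
`NaN`. `neighbor_joining()` is the standard Q-criterion agglomeration with
deterministic smallest-index tie-breaking and negative branch lengths
clamped to zero with the deficit moved to the sibling edge; it is exact on
additive matrices (tested against an independent NJ implementation).
Bootstrap support is column resampling (desk default 200 replicates,
seeded); `rf_distance()` counts bipartitions present in exactly one tree
and is cross-checked against an independent implementation. NJ + bootstrap
stands in for the likelihood/Bayesian inference of full-scale studies
because the claims tested here are purely topological (monophyly, sister
order) and NJ recovers them exactly on clean simulated alignments.

# Numerical and degenerate-input conventions

* Sequences may contain `N`: excluded from GC content (numerator *and*
  denominator), never matching in repeat or IR detection, missing data in
  likelihoods and distances.
* A genome without a detectable IR is a valid `quadripartite_structure`
  with the single-copy region covering everything — IR absence is a result,
  not an error.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; no global state is consumed silently.
* Alignment and block-finding tie-breaks are fixed and documented (traceback
  preference M > gap-in-B > gap-in-A; leftmost reference position; smallest
  index pair), so outputs are reproducible byte for byte.

# A worked example

```{r example, eval = FALSE}
anc <- build_ancestor(ancestor_spec(seed = 1))
ev <- evolve_plastomes(anc, "((A:0.004,B:0.004):0.002,(C:0.004,D:0.005):0.002);",
                       rates = list(sub_rate = 1, indel_rate = 5e-4,
                                    event_rates = list(gene_loss = 60,
                                                       plant_ssr = 2500)),
                       seed = 1)
st <- lapply(ev$records, detect_ir)
classify_shift(st$A)
junction_report(ev$records$A, st$A)
content_matrix(ev$records, st, reference = anc$truth$template)$counts
screen_markers(ev$records, st)$ranking
```

`scripts/acceptance.R` chains all of the above (plus an IR expansion and a
near-complete contraction, repeats, and the NJ/PI stage) into one seeded,
self-contained run; see the README for how to invoke it.
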