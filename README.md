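# plastomics

Comparative analysis of chloroplast genomes (plastomes) in R: quadripartite
structure and IR-junction analysis, gene content, rearrangements, repeats,
marker screening by sequence variability, phylogenetic-informativeness
profiling, and desk-scale phylogenetics — with a seeded plastome-evolution
simulator so the whole pipeline is testable offline.

## Who it is for

Researchers comparing annotated plastomes within a genus or family — the
setting where IR expansion/contraction, gene loss/pseudogenization and
segmental rearrangements are the story, and where candidate loci must be
screened for phylogenetic work. Input is one annotated genome per species
(GenBank flat file, or FASTA + GFF3); every analysis stage is an ordinary R
function returning data frames and plain S3 objects.

## What it computes

* **Quadripartite structure.** The plastome is LSC + IRB + SSC + IRA with
  IRA the reverse complement of IRB. `detect_ir()` finds the maximal
  inverted-repeat pair on the circle (k-mer-seeded, provably identical to
  exhaustive search), labels the single-copy arcs by marker-gene content
  (the ndh suite and *ycf1* mark the SSC — content beats size, which matters
  when a residual IR leaves an "SSC" larger than the LSC), and reports the
  four junctions JLB, JSB, JSA, JLA with the genes spanning or flanking
  them. `classify_shift()` calls large-scale IR expansion/contraction
  (Group B: `ir < 1` kb, `ir > 35` kb, or `SSC < 10` kb by default).
* **Gene content.** Per-genome status of every reference gene —
  single / IR-duplicated / pseudo (internal stop, frameshift, truncation,
  annotated flag) / lost — and summary counts in which every annotated copy
  is counted (so IR expansion visibly inflates totals).
* **Rearrangements.** Signed gene orders (one IR copy removed) chained into
  collinear blocks; inversions, relocations and inverted relocations called
  per block, with region labels. Windowed percent identity for pairwise
  alignments.
* **Repeats.** SSRs (maximal perfect runs, thresholds 10/6/5/5/5/5 by motif
  length, literal motifs, circular runs), a simplified tandem-array scanner
  (score `2·match − 7·mismatch − 7·indel` minus one unit's credit, min
  score 80, max period 500), and maximal dispersed repeats of the four kinds
  (Forward / Reverse / Complement / Palindromic, ≥ 30 bp, ≤ 3 mismatches),
  seed-and-extend with a brute-force oracle in the test suite.
* **Marker screening.** Syntenic intergenic/intron loci (same flanking genes
  in every genome, ≥ 150 bp mean length), progressive alignment, and

  ```
  SV = (mutations + indel events) / (conserved + mutations + indel events)
  ```

  ranking the most variable candidate loci.
* **Informativeness.** Per-site Jukes–Cantor rate ML on a fixed ultrametric
  tree (tips at time 0, root at 1), and per-site phylogenetic
  informativeness `rho(t) = 16 λ² t e^(−4λt)` — peaking at `t = 1/(4λ)` —
  summed per gene and normalized by gene length, with top-k gene ranking.
* **Phylogenetics (desk scale).** p/JC69/K2P distances with pairwise
  deletion, neighbor joining with deterministic tie-breaking, column
  bootstrap, alignment concatenation with a partition table, and
  Robinson–Foulds comparison.
* **Simulator.** `build_ancestor()` + `evolve_plastomes()` generate
  annotated quadripartite genomes along a clock tree with exact JC
  substitutions (concerted in the IR), spacer-only indels, junction shifts,
  gene loss, pseudogenization, inversions/relocations and planted repeats —
  all recorded in a ground-truth log that the analysis stages are tested
  against.

## Worked example

The one-command pipeline (also what the acceptance script runs):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates a four-species clade from a ~158 kb ancestor, adds one genome with
a 9 kb IR expansion and one with a near-complete IR contraction, and runs
every stage. Output (abridged, seed 1):

```
-- quadripartite structure --
spA             159172 bp  LSC  88086  SSC  18086  IR  26500  GC 50.4  group A
spB             158762 bp  LSC  87670  SSC  18092  IR  26500  GC 50.4  group A
...
spE_expanded    167155 bp  LSC  86988  SSC   9167  IR  35500  GC 50.3  group B
spF_reduced     132876 bp  LSC  87891  SSC  44275  IR    355  GC 50.5  group B

-- junction report (spA) --
 junction position           gene spans_junction
      JLB    88086    rpl22--rpl2          FALSE
      JSB   114586 trnN-GUU--ndhF          FALSE
      JSA   132672 ycf1--trnN-GUU          FALSE
      JLA        0 rpl2--trnH-GUG          FALSE

-- gene content --
      species n_genes n_cds n_trna n_rrna n_loss_pseudo
          spA     127    82     37      8            15
 spE_expanded     136    90     38      8            18
  spF_reduced     112    78     30      4            12
```

Reading it: the two structurally deviant genomes are flagged Group B — the
expanded one because its IR exceeds 35 kb (its SSC shrank below 10 kb and
its gene total is inflated by the extra duplicated copies), the reduced one
because only a 355 bp IR remains, so the marker-gene rule labels its
*larger* single-copy arc as the SSC and its rRNA/tRNA counts drop to a
single copy. The junction report shows the classic gene neighborhoods
(*rpl22*/*rps19*–*rpl2* at JLB, *ndhF* at JSB, *ycf1* at JSA,
*rpl2*–*trnH* at JLA). The run continues with repeat tallies, the top-10
most variable syntenic loci, an NJ tree with 100 % bootstrap on the single
deep split, and the per-site-informativeness gene ranking, then writes the
acceptance JSON.

## The acceptance script

`scripts/acceptance.R --seed <int> --out <path>` re-runs the entire pipeline
from scratch — simulation, structure, content, rearrangements, repeats,
marker screen, tree and informativeness — under the given seed and writes
the acceptance-target JSON to `--out`. It reads nothing outside the
repository and needs no network.

The test suite (`tests/testthat/`) contains per-module unit and property
tests plus `test-acceptance.R`, whose blocks assert the oracle-equivalence
and recovery criteria (IR detection vs exhaustive search, structure
round-trips against simulator truth, repeat detectors vs brute force,
SV arithmetic and rate/informativeness behavior, NJ/RF exactness, 4-clade
recovery with bootstrap support). One acceptance assertion — per-site rate
class means within 15 % at 16 tips — fails by design: per-site ML rates are
intrinsically upward-biased at that sample size (the likelihood itself is
verified against a brute-force oracle); see the methods vignette.
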