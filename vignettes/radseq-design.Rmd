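---
title: "Designing organelle-depleted RAD-seq experiments with radopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing organelle-depleted RAD-seq experiments with radopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radopt)
library(dplyr)
```

## The problem radopt models

Reduced-representation sequencing selects, by restriction digestion and
size selection, a few thousand genomic fragments to be sequenced deeply
in every individual of a population. In plants the DNA extracted from
leaf tissue is not just nuclear: a cell carries on the order of a
thousand chloroplast genomes and several hundred rRNA gene repeats per
haploid genome. A fragment originating from these regions is therefore
amplified and sequenced hundreds to thousands of times more often than a
single-copy genomic fragment. Even a few dozen organellar fragments in
the selection can claim the majority of the reads.

radopt implements the design response: after the first digestion defines
the selected fragment set, a *second* digestion with additional enzymes
is chosen so that every chloroplast- and rRNA-derived fragment is cut —
and thereby excluded from adapter-mediated amplification — while as many
genomic fragments as possible remain intact.

## In-silico digestion conventions

All coordinates are 0-based and half-open; cut positions are top-strand
coordinates ("the position before which the strand is cut"), so a
`G^AATTC` site starting at position *s* cuts at *s + 1*. Fragment
lengths are measured cut-to-cut on the top strand, ignoring overhang
stagger — the standard convention for in-silico digestion, since the
double-stranded fragment is defined up to the few staggered bases of its
overhangs. Degenerate recognition symbols follow the IUPAC code; an
ambiguous base (`N`) in the *genome* never supports a match, which
avoids phantom fragments in gappy assemblies. Non-palindromic sites are
scanned on both strands and the reverse-strand cut is mapped to
top-strand coordinates. Enzymes cutting outside their recognition site
(type IIS/IIB) are rejected at catalog parse time: the method depends on
the cut being regenerated at fragment ends, which only within-site
cutters guarantee.

Complete digestion is assumed: fragments between consecutive cuts tile
each sequence exactly (a property the test suite asserts, along with
equality to a naive string-splitting oracle). Fragments bounded by a
sequence end are produced but excluded from design statistics by
default — they are not ligatable on both ends. The size-selection window
(default 224–424 bp) is inclusive on both bounds. A fragment counts as
rRNA-derived if it overlaps an annotated rRNA interval by at least 1 bp;
the overlap fraction is deliberately not thresholded, since any overlap
places the fragment inside a high-copy repeat.

## First-round ranking

`first_round_search()` evaluates every combination of 2–3 candidate
enzymes and ranks them: combinations recovering at least the required
number of selected fragments first, then ascending organellar fragment
count, then descending count of known polymorphic positions covered
(when a position list is supplied), then descending selected fragments,
with alphabetical enzyme labels as the final deterministic tie-break.
The candidate default (EcoRI, HindIII, MspI, MseI) mixes 6-bp rare
cutters, which carry the barcoded adapter, with 4-bp frequent cutters
carrying the universal adapter; `filter_by_end_composition()` can
restrict counting to fragments with the ddRAD-compatible one-rare-end or
mixed-end configurations.

## Second-round search

`second_round_search()` treats organellar removal as a covering problem.
A fragment is "cut" when an enzyme of the subset has at least one cut
site strictly inside the fragment interval (a site straddling a fragment
boundary cannot exist after the first digestion). Three design choices
make catalog-scale search exact and fast:

* **Incidence precomputation.** Each (enzyme, fragment) pair is scanned
  once into a boolean incidence matrix; evaluating a subset is then a
  column-wise union, so enumerating all single, pair and triple subsets
  of a ~270-enzyme catalog costs set operations, not sequence scans.
* **Pruning.** Enzymes that cut no organellar fragment are dropped
  before enumeration: adding one to any subset leaves organellar
  coverage unchanged and can only destroy genomic fragments, so no
  optimal subset contains one (asserted against unpruned brute force in
  the tests).
* **Ranking.** Complete covers rank first, by descending intact genomic
  fragments, then fewer enzymes, then label. Among *incomplete* covers,
  organellar coverage dominates intactness — otherwise a subset cutting
  nothing would trivially "win" on intactness. This ordering is what
  makes the pruned search provably equal to unpruned brute force in both
  regimes.

Subset size is capped at 3 by default: optimized designs in practice use
at most three second-round enzymes, and each additional enzyme adds
cost, star-activity risk and genomic collateral damage.

## The read-dilution model

Reads are modelled as drawn from selected fragments in proportion to
per-cell copy number: genomic fragments occur `ploidy` times per cell,
rRNA fragments `ploidy × rRNA copies per haploid genome` times, and
chloroplast fragments `copies per cell` times, independent of nuclear
ploidy. Defaults are 700 rRNA copies per haploid genome (the measured
value in Arabidopsis leaf tissue) and 1,200 chloroplast genomes per cell
(the midpoint of the reported 1,000–1,500 range; this midpoint also
keeps the per-cell copy totals in whole numbers). Raw
fractions are always retained; report percentages are rounded half away
from zero to one decimal, so a fraction of 0.33760 prints as 33.8 %.
The model predicts the characteristic ploidy effect: because chloroplast
copies are per-cell, the genomic read share *rises* with ploidy
(43.6 % diploid to 58.4 % tetraploid for the same design), a monotone
property the tests assert.

`simulate_read_pool()` draws read pairs under exactly this weighting, so
the law-of-large-numbers agreement between simulated class fractions and
`predict_read_proportions()` is a genuine dual-route check: closed-form
arithmetic versus multinomial sampling.

## Demultiplexing and pool balance

Inline 5-bp barcodes sit at the start of read 1 (the barcoded adapter
ligates at the rare-cutter site, so the enzyme's regenerated overhang
immediately follows the barcode and can optionally be required as an
anchor). The default mismatch tolerance is 0; tolerance 1 is allowed
only when the barcode set's pairwise Hamming distances (≥ 2·tolerance+1)
make assignment unambiguous, which is validated up front.
`default_barcode_table()` builds a distance-3 code greedily in a fixed
enumeration order, so it is reproducible without randomness.

`read_balance_report()` reports the coefficient of variation of
per-sample counts (sample standard deviation over mean) and a two-sided
one-sample t-test against the expected per-sample mean. When all pool
samples are included, the counts average to that mean by construction
and the statistic is 0 — the test is informative per-lane or on sample
subsets; this caveat is kept because pool-evenness t-tests are the
conventional report for pooled RAD libraries.

## Variant filtering and segregation validation

`filter_variants()` first masks individual calls failing the per-sample
thresholds (depth < 10 reads or genotype quality < 20), then rejects
sites by the first failed criterion in a fixed order: missing parental
genotype, fewer than 7 genotyped offspring, offspring alleles absent
from both parents, more than two alleles. The order is a package
decision (no canonical order exists) chosen so rejection tallies are
deterministic and the cheap checks run first; tightening any threshold
can only shrink the passing set, a monotonicity property under test.

Genotypes are reduced to allele-presence classes relative to the
parents: `homP1`/`homP2` when only one parent's allele is observed,
`het` otherwise. In autotetraploids this is deliberately dosage-free —
sequencing reads identify constituent alleles, not allelic dosage, and
no dosage calling is attempted.

Expected class frequencies:

* diploid F2: 1/4, 1/2, 1/4; homozygous × heterozygous F1: 1/2, 1/2, 0.
* tetraploid F2 (duplex × duplex, AAaa × AAaa): a duplex parent's gamete
  is homozygous (AA or aa) with frequency `g = (1 + 2α)/6`, where α is
  the coefficient of double reduction — with probability `1 − α` the
  gamete is one of the six equally likely chromosome pairings (AA with
  probability 1/6), and with probability α it carries two copies of one
  of the four alleles (homozygous with probability 1/2). Offspring show
  a single parental allele only when both gametes are the matching
  homozygote, giving `hom = g²` per class and `het = 1 − 2g²` — 1/36,
  34/36, 1/36 at α = 0. This derivation is verified against a
  brute-force gamete-enumeration oracle in the tests. User-supplied
  expected frequencies are accepted for non-standard configurations.
* tetraploid F1 (simplex × nulliplex): 0, (2 − α)/4, (2 + α)/4.

α is capped at 1/6, its theoretical maximum under complete equational
separation. Homozygote classes increase strictly with α, which is why
`homozygote_centromere_correlation()` — Pearson correlation between a
marker's homozygote frequency and its distance to the nearest
centromere — serves as a genome-wide signature of double reduction.

`chisq_gof()` computes Pearson's X² = Σ(Oᵢ−Eᵢ)²/Eᵢ with 2 degrees of
freedom for three positive classes. A class with zero expected frequency
is dropped (df = 1) when unobserved; if it is observed, the marker is
flagged inconsistent with the model rather than tested, since the
statistic is undefined there. `segregation_scan()` applies the Sidak
threshold `1 − (1 − α_fam)^(1/m)` with *m* equal to the number of
testable markers; the family-wise error calibration of the whole scan is
checked by simulation (100 replicate null scans of 1,000 markers × 200
offspring) in the acceptance tests.

## What the simulator does and does not emulate

`simulate_genome()` builds chromosomes as site-free background
(i.i.d. bases at a configurable GC content, default 0.36 as typical of a
small plant nuclear genome) interleaved with *planted* fragments bounded
by concrete enzyme sites. Interiors and background are rejection-sampled
(in chunks, with junction-spanning windows checked, keeping generation
linear in genome length) to contain no site of the digestion enzymes,
and every planted block is verified with the production scanner before
acceptance. Organellar fragments additionally carry exactly one
second-round cut site, genomic fragments none — so complete digestion
plus size selection recovers exactly the planted fragments, and the
truth-optimal second round is known by construction. Default scale
follows the emulated study design: five 1-Mb chromosomes, a 150-kb
chloroplast with 40 planted fragments, a four-unit 10-kb rRNA array,
12-sample pools with 5-bp barcodes, and populations of 2 parents plus 10
offspring; tests and examples pass smaller explicit configurations
(tens of kb, 10–60 fragments) to keep the suite fast.

The simulator intentionally omits: partial digestion, methylation
blocking, PCR and GC bias, indel errors and quality-score structure,
reference bias, and linkage between markers (population genotypes are
drawn i.i.d. per marker). Passing tests therefore demonstrate
correctness of the combinatorics, the dilution arithmetic and the
statistical machinery under the stated model — not robustness to
library-chemistry artefacts in real data, for which the QC functions
(`fragment_length_distribution()`, `depth_summary()`,
`classify_mapped_reads()`) exist.

## Numerical and degenerate-input choices

* Proportions sum to 1 within 1e−12; chi-square agreement with the
  generic `stats::chisq.test()` route is asserted to 1e−10.
* Ties in every ranking are broken by alphabetical enzyme labels, so all
  searches are deterministic.
* Degenerate inputs have explicit contracts: an empty sequence digests
  to no cut sites; zero organellar fragments make the empty enzyme set
  the second-round optimum; a quality filter that removes every read
  pair yields an explicit empty result with a warning rather than NaN
  proportions; an all-even pool reports CV = 0 with an exact-fit t-test
  rather than a 0/0 statistic; constant homozygote frequencies make the
  centromere correlation undefined (NA with a warning), not 0.
* All randomness flows through R's RNG: a fixed seed makes every
  generator byte-reproducible.

## Known limitations

The bundled enzyme catalog is a reconstruction of the commercial type
IIP repertoire; combinatorial search results on real genomes depend on
catalog content, and users with a definitive catalog should supply it
via `read_enzyme_catalog()`. Fragment-level depth (pair outer spans) is
the default coverage currency; per-mate base-level coverage differs near
fragment ends. Genome bins approximate genetic-map intervals by equal
physical size; no genetic map is consumed. Tetraploid dosage estimation
is out of scope.
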