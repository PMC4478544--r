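---
title: "Validating tandem gene array assemblies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating tandem gene array assemblies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemcheck)
```

`tandemcheck` audits assemblies of tandemly duplicated gene arrays with
three independent evidence classes — k-mer subtraction, read-depth tracks
and depth-calibrated copy-number calls — and classifies candidate gene
variants as genuine, missing, or PCR recombination artifacts.  This
vignette documents the models behind each component, the parameters that
matter, and what the simulation does and does not establish about real
data.

## The simulated system

The generator emulates a Y-chromosome gene array born of a single
transposition: a ~3.4-kb autosomal source locus — a complete gene with a
small intron, nested between two exon fragments of one flanking gene and a
UTR fragment of another — copied onto a haploid chromosome and tandemly
amplified.  `make_source_locus()` builds that locus with a contiguous,
stop-free open reading frame (860-bp gene: 30 + 62-bp intron + 30 bp of
untranslated leader, a 648-bp CDS, 90-bp trailer).  The intron is placed
in the 5' untranslated region so the CDS stays contiguous and a pseudogene
can be made by a single in-frame substitution to a stop codon; real
pseudogenes in such arrays carry premature stops and indels in unspecified
numbers, and one stop is the minimal disruption.

`make_variant_set()` derives `n` gene variants by independent per-site
substitution (default rate 0.005 per site, i.e. ~99% pairwise identity —
matching the observation that distinct copies in such arrays can be 99.5%
identical).  `build_tandem_array()` then lays the copies out left to right
on one strand, every copy embedded in its full source-locus context,
separated by spacers filled with segments from a bundled **synthetic**
retroelement library.

Two design choices deserve justification:

* **TE fraction is targeted over the array span, not over spacer bases.**
  The empirical figure this emulates — repeats occupying ~48% of the
  region — is a fraction of the whole array span.  With a full 3.4-kb
  context per copy, 18 copies occupy ~61 kb; no allocation of TE content
  *within spacers* could reach 48% of the span unless the spacers
  themselves carry most of the budget.  The builder therefore draws spacer
  lengths (default mean 3.8 kb, sd 0.8 kb) and budgets TE segments across
  them so the realized span fraction lands on the target (tolerance ±3
  points, typically much closer).
* **The diploid contig carries the intact source locus.**  Male-derived
  sequencing covers autosomes at twice the sex-chromosome depth; the
  fixture encodes exactly this two-contig ploidy contrast (default 45x per
  haploid copy, hence ~90x on the autosomal contig), which is the
  calibration every depth audit relies on.

### Reads

`short_read_config()` gives fixed-length 100-bp reads with a
substitution-dominated error profile (default 0.1%), the regime of
high-accuracy short-read sequencing.  `long_read_config()` gives
log-normal lengths (mean 8 kb — comfortably above the 3.4-kb duplication
unit, which is the whole point of long reads here: a read spanning a copy
plus flanking sequence anchors identical copies apart) and an
indel-dominated error profile (defaults 1% substitution, 6% insertion, 5%
deletion; ~12% total, raw-long-read-like).  These error defaults are the
package's own choices; the emulated study does not parameterize error
profiles.  Read templates are drawn uniformly with overhang at contig ends
(clipped back to the contig), so expected depth is uniform from the first
base to the last — otherwise contig ends would show artifactual coverage
dips that the audits would flag on perfectly clean assemblies.

Every read records its provenance (contig, template interval, strand),
which gives the tests a mapper-independent oracle pileup.

### PCR clones

`simulate_pcr_clones()` models PCR as a binary replication tree: each
cycle, every molecule yields one copy; the copy acquires point errors
(default 5 × 10⁻⁵ per base per replication) and, with probability 0.02,
switches template at a uniform breakpoint — a single-crossover chimera.
Both rates are placeholders exposed in `pcr_sim_config()`; no published
value exists for the polymerase in question.  The implementation never
materializes the 2³⁰-molecule pool: sampled clones are traced *backwards*
through the tree to their replication events, and events shared by several
clones are memoized, so early-cycle "jackpot" mutations reach high clone
frequencies exactly as the branching process dictates.  The
accepted-variant table then applies the classic guard — keep only
sequences seen at least twice among (default) 115 clones — and records
each accepted sequence's true provenance.  The simulation shows this guard
is insufficient: across seeds, recombination artifacts regularly clear the
seen-twice bar.

## The audits

**k-mer subtraction** (`build_read_kmer_set()`, `audit_assembly()`).  Both
the assembly and the reads are decomposed into canonical k-mers (k = 15 by
default; the emulated workflow does not state k, and 15 saturates at ~45x
coverage on fixtures of this size while keeping random collisions
negligible at 4¹⁵ ≈ 10⁹).  Tiled mode (non-overlapping windows) is the
default report so a point error yields exactly one "unmatched k-mer";
sliding mode reports every affected offset (up to k per substitution).
The audit is presence/absence only — no k-mer counting — and requires
high-coverage reads: at low depth, read errors can leave true k-mers
unobserved.  An optional single-copy filter skips windows whose k-mer
recurs in the assembly.

**Depth audits** (`map_reads()`, `compute_depth()`,
`find_zero_coverage()`, `find_consistent_mismatches()`).  The bundled
aligner is exact-seed (13-mers, stride 4) plus banded edit-distance
extension; a read is placed at its minimal-mismatch locus, with ties
resolved randomly (seeded) or fractionally (`all_best`).  This is not a
general-purpose mapper — it is adequate for the simulated error regimes
and keeps the pipeline dependency-free.  Zero-coverage regions are maximal
runs of zero depth including contig ends; consistent-mismatch sites
require depth ≥ 10 and a single non-reference base at ≥ 80% support,
thresholds far above what 1% random sequencing error can reach at 45x
(binomial tail ≪ 10⁻¹⁰ per site).

**Copy number** (`estimate_copy_number()`).  Long reads are searched for
panel-gene instances (the panel should contain every candidate gene *and*
the autosomal source gene, so autosomal reads have a panel home); each
instance is assigned to the best-matching variant(s), ties splitting
weight evenly, and per-variant mean depth is read against the diploid
calibration `D`:

```
copy_number = round(2 * mean_depth / D)    # half away from zero
artifact    = mean_depth < tau * D / 2     # tau = 0.1
```

Fragments covering less than half a variant (`min_instance_cov = 0.5`) are
discarded even when clipped at a read end: sub-half overlaps rarely span
an informative site, cannot distinguish near-identical paralogs, and in
testing leaked ~10% of a haploid unit of depth onto absent panel entries.
With the filter, genuine variants keep ≥ 93% of their expected depth
(copy-number rounding is unaffected) and absent variants sit essentially
at zero, so any `tau ≤ 0.5` separates the artifact band from the haploid
band; 0.1 is deliberately conservative.  Short reads are refused for panel
calls — at 100 bp they cannot be unambiguously assigned among 99.5%
identical paralogs.

**Chimera detection** (`align_variants()`, `explain_recombinant()`).
Candidates and validated parents are aligned (positionally for equal
lengths; anchor-based global alignment with merged insertion columns
otherwise; gaps are a fifth character state).  For every ordered parent
pair the candidate's alleles are read along the pair's informative sites;
the explanation minimizing `(novel alleles, switches)` wins.  The verdict
`recombinant_artifact` demands a perfect single-crossover mosaic: zero
novel alleles, exactly one 5'→3' switch, at least one supporting site per
parent.  Multi-switch mosaics are reported `unexplained`, not artifacts —
the mechanism modeled is one template switch.  Ambiguous parent pairs are
all recorded, with the lexicographically smallest pair as primary.
`detect_complementary_pairs()` finds reciprocal products (A,B)/(B,A) with
overlapping crossover intervals — the signature of both strands of one
switching event surviving to the clone library.

## Numerical and coordinate conventions

Coordinates are 1-based inclusive everywhere in R objects and TSV
reports, converted to 0-based half-open only when writing BED.  Copy
number rounds half away from zero, with the artifact threshold arbitrating
first.  Region spans round to the nearest kb, half up, with exact bp
retained.  k-mer sets store canonical 2-bit codes exactly in doubles
(k ≤ 26).  Every stochastic function takes an explicit seed;
`run_pipeline()` derives stage seeds from one global seed and reruns
byte-identically.

## Problem sizes

The test suite and the acceptance script run the reference scenario at
full fixture scale (an ~130-kb array contig, 18 copies, ~76,000 short
reads, ~1,000 long reads) and exercise parameter-recovery loops (20 seeds
for copy-number {1,2,3}) on a compact 7-copy fixture; these sizes were
chosen so the complete validation chain demonstrates the same
depth-calibration regime as the emulated study while remaining a
desk-scale computation.

## What passing tests do and do not show

The generator reproduces the *structure* the audits assume — near-identical
same-orientation copies, ploidy-contrasted depth, indel-dominated long-read
error, TE-laden spacers — but not real sequence content: no real TE
families, no sequence-dependent error hotspots (homopolymer slippage is
not modeled, and the audits' behavior on homopolymer indels is
correspondingly untested), no base-quality information, no diploid
heterozygosity (the emulated strain is inbred), and no PCR primer or GC
bias.  Copy-number accuracy on real data further depends on the mapper
and on reference completeness; the bundled aligner deliberately trades
generality for reproducibility.  The chimera detector assumes recent
paralogs (≥ 90% identity) and exactly one crossover; gene-conversion
mosaics and multi-switch artifacts fall outside its artifact definition by
design.
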