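---
title: "Quantifying tissue-specific cfDNA by methylation haplotypes of a bisulfite amplicon"
author: "ampliMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue-specific cfDNA by methylation haplotypes of a bisulfite amplicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliMeth)
```

## The measurement problem

Dying cells release short DNA fragments into the blood (cell-free DNA,
cfDNA).  Every tissue carries a characteristic DNA methylation pattern,
so the tissue of origin of a cfDNA molecule can be read from the
methylation states it carries.  This package implements the analysis for
a targeted assay built on one such marker: a CpG island near the FAM101A
locus whose six CpGs are unmethylated in cardiomyocytes and methylated
in leukocytes and other non-cardiac tissues.  Serum cfDNA is bisulfite
converted, the marker region is PCR amplified, and the amplicon is
sequenced deeply (tens of thousands of read pairs per sample).  After
bisulfite treatment an unmethylated cytosine reads as T while a
methylated cytosine is protected and still reads as C, so each sequenced
molecule exposes the joint methylation state of all six CpGs — its
*methylation haplotype*.

The assay's readout is deliberately strict: a molecule counts as
cardiomyocyte-derived only when **all six CpGs read unmethylated**.
Requiring the full haplotype, rather than averaging per-CpG methylation,
suppresses background from stochastic methylation loss at individual
CpGs in non-cardiac DNA, which is what makes fractions on the order of
$10^{-3}$ measurable at all.

## The statistical model

For a sample, let $N$ be the number of evaluable sequenced molecules and
$k$ the number whose six CpGs all read unmethylated.  The primary
statistic is the fully-unmethylated fraction

$$ f = k / N, $$

with an exact Clopper–Pearson binomial confidence interval.  Molecules
with any ambiguous CpG (read N, an unexpected base, or an uncovered
position) are excluded from both $k$ and $N$.  Because two printed
conventions exist for this quantity, the odds-style ratio $k/(N-k)$ is
emitted as a secondary column; with $f \approx 0.02$ the two differ by
about 2%, and we treat $k/N$ as primary because it is a proper fraction
with exact binomial inference.  Whether the denominator should include
unevaluable reads is genuinely ambiguous in the assay's description; we
exclude them, since an unevaluable molecule carries no haplotype
information.

Three derived quantities build on $f$:

* **Genome equivalents.** When the sample's total cfDNA mass $m$ (pg) is
  known, marker-positive DNA is expressed as $f \cdot m / 3.3$ haploid
  genome copies (3.3 pg per haploid genome).
* **Limit of detection.** The assay shows a detection floor set by
  background chemistry, not by sampling.  We define the LoD as the
  one-sided exact binomial upper bound, at tail probability
  $\alpha = 0.05$, on the pooled fraction of negative-control samples
  (methylated buffy-coat DNA); for controls with $k = 0$ this is the
  closed form $1 - \alpha^{1/N}$.  A sample is "detected" when its $f$
  strictly exceeds the bound.  The derivation behind the published
  assay's detection floor is not stated anywhere we could follow, so
  this reproducible, assumption-light definition is the package's own
  choice.
* **Spike-in calibration.** For a dilution series of cardiomyocyte DNA
  into buffy-coat DNA the package reports mean and SD of $f$ per level
  and the lowest level whose replicates all exceed the LoD.

## Pipeline stages and their parameters

**Assay definition.**  An assay is the unconverted top-strand amplicon
insert, the 0-based offsets of its CpG cytosines, and the
primer/adapter sequences.  All internal coordinates are 0-based
half-open; the 1-based locus label (`chr12:124,207,916-124,208,005`) is
display-only.  The packaged default assay carries the published
locus-specific primers and adapter overhangs verbatim, but its 90 bp
insert sequence is a **synthetic stand-in** — the genomic insert was
never published with the assay — constructed so that the
bisulfite-converted primer footprints match the published primers
exactly, with six CpGs at realistic spacing and six non-CpG cytosines
for conversion-rate estimation.  Users analysing real data substitute
the genomic sequence through the YAML assay format.

**Converted reference.**  Every non-CpG cytosine is converted to T in
silico; CpG cytosines are *bivalent*, matching read C or T at zero
penalty, so alignment is methylation-unbiased.  Only the bisulfite top
strand is modeled: the amplicon's primer pair fixes read orientation, so
a bottom-strand (G→A) alignment path would never be used.  This is a
documented limitation for reuse with other assay designs.

**Pair merging.**  With 2×150 bp reads over a ≤200 bp amplicon the mates
overlap; merging reconstructs each molecule once.  Every candidate
insert length from `max(len1, len2)` to `len1 + len2 - minOverlap`
(default `minOverlap` 10 bp) is scored and the orientation maximizing
matches − mismatches wins, ties broken towards the shortest insert.
Overlap disagreements become N — qualities are synthetic in simulation,
so a quality-weighted consensus would be fiction; N conservatively
renders an affected CpG unevaluable.  Insert lengths shorter than a
read (adapter read-through) are not modeled.

**Alignment.**  An exhaustive ungapped scan over all offsets of the
(<200 bp) reference is exact and trivially verifiable, which is why we
use it instead of re-implementing a seed-and-extend aligner whose
behavior could not be reproduced from its description.  A read T over a
reference C at any conversion-eligible position is not a mismatch; read
N is neutral; ties break to the smallest offset.  Reads longer than the
reference are flagged unaligned rather than raising an error.

**Filters.**  Following the assay's description, molecules must be
properly merged ("proper pair"), aligned, and have the correct insert
size.  "Correct" is not quantified in the assay's description; the
default window is the amplicon insert length ± 5 bp, since amplicon
sequencing has a fixed expected insert.  A mismatch-rate cap (default
0.1 of the merged length) removes garbage reads while tolerating the
default per-base error rate of 0.001.  The QC tally partitions the
input exactly — every molecule is counted once, under its first failing
reason or as kept.

**Haplotype calling.**  Per molecule and CpG: C → methylated (M),
T → unmethylated (U), anything else → ambiguous (A).  The label is
`FULLY_UNMETHYLATED` iff all CpGs are U, `UNEVALUABLE` iff any is A,
otherwise `OTHER`.  A zero-CpG assay degenerates to every molecule
vacuously fully unmethylated; the constructor permits it because the
configuration format should not forbid degenerate assays that are
useful in testing.  Non-CpG reference cytosines are tallied as
converted (T) versus unconverted (C); the pooled ratio estimates the
bisulfite conversion efficiency with an exact interval.  An optional
filter (off by default, because the original analysis describes no such
step) can drop molecules whose non-CpG cytosines suggest failed
conversion.

## What the simulator emulates

The synthetic-data module generates the study conditions the analysis
assumes, with explicit seeds and truth tables:

* **Tissue haplotype profiles.**  Frequency tables over six-CpG state
  strings.  Packaged profiles: cardiomyocyte 0.78 fully unmethylated,
  heart ventricle 0.20 (the tissue contains non-cardiomyocyte cells),
  buffy coat and other non-cardiac tissue 0.001 (below the assay's
  0.002 specificity bound), universal methylated control 0.  The
  remainder of each two-haplotype profile is fully methylated; arbitrary
  haplotype tables (partially methylated molecules) are supported but
  not packaged, matching what was measured for the real tissues.
* **Chemistry.**  Unmethylated C reads T with probability 0.99 (the
  measured conversion rate); methylated C reads T with probability
  0.005 and the sequencer substitutes bases at 0.001/base.  The latter
  two are not published; they were chosen once so that fully methylated
  DNA yields a fully-unmethylated background
  ($\approx 0.005^6 \sim 10^{-14}$ plus error leakage) comfortably
  below the assay's 0.2% specificity bound, and are explicit knobs.
* **Fragmentation.**  Serum cfDNA fragment lengths follow a discretized
  log-normal with mode 150 bp truncated at 200 bp (the published mode
  and maximum; the shape between them is the package's choice of the
  standard cfDNA form), dispersion 0.12 on the log scale.  A fragment is
  amplifiable iff it spans both primer footprints; amplicon PCR is
  modeled as uniform resampling of amplifiable fragments without
  duplicate structure — the assay has no UMIs, and the original
  analysis counts reads.  Because the truth table still records a
  template identifier (finite template pools can be simulated), either
  counting convention — read pairs or unique molecules — can be
  tested; the package's own counts are per read pair.
* **Reads.**  R1 is the converted top strand 5'→3', R2 the reverse
  complement from the other end, both capped at the insert length (no
  adapter read-through), constant Q37 qualities since no downstream
  step uses qualities.  Identical seeds give byte-identical FASTQ, and
  the random-number stream layout is independent of the chemistry
  parameters, so chemistry sweeps are pathwise coupled — the
  monotonicity property test (background counts never decrease as
  inappropriate conversion rises) holds deterministically, not just in
  distribution.
* **Cohort.**  Ten patients × three timepoints (pre, post, recovery),
  depth uniform on 35,000–74,000 read pairs.  True shedding fractions
  are drawn from log-normal patient baselines (median 0.019, log-sd
  0.35) with log-normal timepoint variation (log-sd 0.25), emulating
  per-timepoint medians around 0.018–0.020; the realized cohort
  median's documented design band is [0.012, 0.030].

The simulator does **not** model indels, index hopping, strand-specific
PCR bias, polymerase errors during PCR (which would correlate within
duplicate families), quality-score structure, or contamination between
samples.  Passing tests therefore demonstrate that the pipeline's
inference is correct *for the generative model stated above* — they
cannot certify behavior on real sequencer artifacts, and the alignment
stage in particular is exercised only with substitution-type noise.

## Expected readout under the chemistry

A point worth making explicit: for a tissue whose fully-unmethylated
haplotype frequency is $u$, the assay's expected readout is **not** $u$
but approximately

$$ E[f] \approx u \cdot e^6 $$

with $e = 0.99$ the conversion efficiency, because a single failed
conversion at any of the six CpGs reclassifies the molecule as
methylated under the all-or-nothing rule ($0.99^6 \approx 0.94$).
Sequencing-error terms cancel to first order: an error at a CpG almost
always produces an A/G (ambiguous) call, which removes the molecule
from numerator and denominator alike.  `expectedUnmethFraction()`
computes this expectation exactly from a profile and chemistry model,
independent of the read-level code, and is the oracle against which the
simulation-based tests check pipeline recovery.  Consequently the
packaged cardiomyocyte profile ($u = 0.78$) reads out at ≈ 73.4% and
the ventricle profile ($u = 0.20$) at ≈ 18.8%; the published
characterization measured 78% and 20% *through the same chemistry*, so
those figures and a simulation truth of $u = 0.78$ jointly overstate
the chain by one conversion factor.  We keep the profiles at their
measured values rather than inverting the attenuation, and report the
readouts the model actually produces.

## Numerical choices and degenerate inputs

* Exact binomial machinery is `stats::qbeta` throughout
  (`qbeta(1-α, k+1, N-k)` upper bounds, two-sided Clopper–Pearson
  intervals); the $k=0$ LoD agrees with the closed form
  $1-\alpha^{1/N}$ to $10^{-12}$, which the test suite asserts.
* Tie-breaks are deterministic everywhere: smallest offset in
  alignment, shortest insert in merging, so reruns are bit-identical.
* Degenerate inputs fail loudly with typed conditions — configuration
  errors (`ampliMeth_config_error`) versus data errors
  (`ampliMeth_data_error`), mapped to exit codes 2 and 3 by the CLI
  wrapper — e.g. a sample with zero evaluable molecules, a dilution
  series without a 0 level, an insert window with min > max, a
  fragment model whose maximum is shorter than the insert.
* A patient missing a timepoint is included as an explicit gap with a
  warning, not dropped silently.

## Problem sizes used by the test and acceptance suites

The characterization experiments run at the study's depth of 50,000
read pairs per sample (background specificity, methylated control,
conversion rate, tissue recovery, and a 5-level × 3-replicate spike-in
series); unit and property tests use 200–20,000 read pairs, 1,000
random reads for the alignment oracle, all $3^6$ state vectors for the
classification oracle, and 100,000 draws for fragment-length checks.
These sizes keep the full suite within a few minutes on one core while
leaving every binomial tolerance (3 exact SDs) well-powered.

## Known limitations

* Single amplicon, top strand only; no multi-marker panels.
* Ungapped alignment: an indel-bearing read is scored as mismatches and
  usually filtered, not realigned.
* The synthetic default insert is a stand-in; coordinates and counts
  are faithful to the assay's geometry but the base composition outside
  primers and CpGs is invented.
* PCR duplicate variance is ignored when the template pool is infinite
  (the default); fractions are unbiased but their binomial intervals
  are slightly anti-conservative if real libraries have low template
  complexity.
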