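---
title: "GC-stratified annotation assessment: models, parameters and design"
author: "gcstratify authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GC-stratified annotation assessment: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcstratify)
```

## The problem

In most plants the GC content of coding sequences is narrow and unimodal,
but in the grasses it is broad and bimodal: there are effectively two
classes of genes, one centred near 47--49% GC and one near 67--68%.  Ab
initio gene predictors are trained on a sample of high-quality gene
models; when that sample is drawn without regard to GC, the resulting
model is an average over two heterogeneous classes and predicts poorly at
both tails.  Because grass genomes lack isochores -- gene GC is
essentially uncorrelated with the GC of the flanking genomic sequence --
stratifying by *regional* GC does not help; the productive split is by
the GC of the genes themselves.

`gcstratify` implements the quantitative scaffolding of a GC-stratified
annotation protocol: profiling the gene GC distribution and finding its
two modes, partitioning transcript-derived training models by those
modes, scoring gene models against evidence with the annotation edit
distance (AED), merging predictions from several predictor sources,
filtering gene lists by evidence/domain support and removing
transposable-element (TE) predictions, and summarising codon usage and
expression support.  Training and running the predictors themselves
(SNAP, AUGUSTUS, MAKER) is out of scope: the package prepares their
inputs and evaluates their outputs.

## GC profiling and cutoff detection

Per-transcript CDS GC is `100 * (G + C) / (A + C + G + T)`; ambiguous
`N` bases are excluded from the denominator, and all-`N` records are
flagged rather than silently dropped.  GC values are binned by
`floor()` into integer-percent bins 0..100 (a GC of exactly 100 falls in
bin 100), and the histogram is smoothed with a truncated centred moving
average of width `smooth_window` (odd, default 7): each bin's smoothed
value is the mean of the raw counts over the window intersected with
\[0, 100\].  Windows are truncated at the edges, not padded, so a bin
near an edge averages fewer values; total mass is conserved exactly for
mass away from the edges and to within `smooth_window/101` relatively
otherwise (edge bins divide by smaller windows, so edge counts can
contribute slightly more or less than unit mass).

A bin is a **peak** when the `(peak_window - 1)/2` bins on each side all
exist and all have *strictly* lower smoothed counts (`peak_window` odd,
default 5).  Three consequences of this rule are deliberate:

* edge bins without a full window on both sides are never peaks;
* plateaus and exact ties never produce peaks (strict inequality), so a
  flat-topped mode can fail to yield a peak;
* "lower" refers to the smoothed *frequency* in the neighbouring bins,
  not to the GC coordinate -- the only reading under which the rule
  defines a mode of the distribution.

`determine_cutoffs()` keeps the two peaks with the highest smoothed
counts (ties broken toward the bin farther from 50, preferring the more
extreme, more class-typical mode) and orders them into a low and a high
set point.  With fewer than two peaks it stops with an error inviting
manual cutoffs, since a unimodal distribution has no defensible split.

The strict-tie rule has a measurable statistical cost.  Near a flat
mode, two adjacent smoothed values are equal exactly when two raw counts
a window apart are equal, and for Poisson-scale counts of order 50--100
that happens in a few percent of simulated genomes; the high-GC mode is
then suppressed and no cutoff pair is reported for that replicate.  This
is intrinsic to the published rule, and the package reports it as the
documented error rather than papering over it.  At the simulator's
default conditions (below), both modes are recovered to within ±2 bins
in roughly 95% of replicates.

## Training sets

Models are first filtered to AED ≤ 0.2 (boundary inclusive), the
conventional quality bar for transcript-derived training models;
filtering precedes partitioning (a flag disables the filter).  The
partition keeps models with GC at or below the low peak in the low-GC
set and at or above the high peak in the high-GC set -- the peak bins
hold the densest, most class-typical members, so both boundaries are
inclusive -- and leaves the middle to neither.  Randomised control
subsets are drawn without replacement with an explicitly named PRNG
(Mersenne-Twister, rejection sampling) seeded at `base_seed + 0,1,2`, so
the three draws are independent, may overlap, and reproduce exactly
across platforms.  Their default size `k = min(|low|, |high|)` matches
the stratified sets, making the random control comparable.

## Annotation edit distance

For a model footprint and an evidence alignment on the same sequence,
with `o` overlapping bases, sensitivity `sn = o/|evidence|`, specificity
`sp = o/|footprint|`, and `AED = 1 - (sn + sp)/2`: 0 is perfect
concordance, 1 is no support.  Transcript evidence is compared against
the exon footprint (CDS when exons are absent), protein evidence against
the CDS footprint.  If either strand is unknown the pair is compared; if
both are known and differ, the evidence lends no support.  A model's
AED is the minimum over its evidence alignments, and an unsupported
model scores exactly 1.  `AED < 0.5` (strict) defines the
"well-supported" fraction used as a genome-wide quality summary.  Mean
transcript length is reported on spliced coordinates (summed exon
lengths), the reading consistent with transcript-level statistics.

## Merging, novelty, improvement

Loci are single-linkage clusters of model spans overlapping by at least
1 bp, strand-aware by default because loci on opposite strands are
biologically distinct.  Per locus the minimum-AED member wins; ties go
to the longer spliced length, then to the earlier source in the declared
source order, then to the lexicographically smaller id, so merging is
deterministic.  Novelty is zero-overlap (strand-agnostic, 1 bp minimum,
both configurable) of a query span against every reference set, the
span-intersection convention of interval tools.  A standard model counts
as *improved* when the merged annotation's choice at an overlapping
locus comes from a non-standard source with a strictly lower AED.

## Quality and TE filtering

The "standard" gene list keeps models with evidence support
(operationalised as AED < 1) or a Pfam hit with full-sequence e-value
≤ 1e-10.  TE filtering removes models by four accumulated (not
short-circuited) rules: Gypsy domain hit ≤ 1e-5, transposase homology
≤ 1e-10, TE-listed Pfam domain ≤ 1e-10, or membership in any
reference-TE refmap entry.  Full-sequence e-values are used throughout
(rather than per-domain values), and any refmap class code counts as
overlap unless a whitelist is given -- both choices are configurable
because upstream conventions vary.

## Codon usage

GC3s is the G+C fraction at third positions of codons whose amino acid
has at least two synonymous codons (Met, Trp and stops excluded).  The
effective number of codons follows Wright's estimator: per amino acid
with `n ≥ 2` observations, codon homozygosity
`F = (n·Σp² − 1)/(n − 1)`; class means over the 2-, 3-, 4- and 6-fold
degeneracy classes; `Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`, capped at
61.  Sparse-data conventions: amino acids with `n < 2` are excluded from
their class; `F = 0` members are dropped and the class mean recomputed;
a missing 3-fold class (no Ile) is imputed as `(F̄₂ + F̄₄)/2`; any other
empty class renders Nc undefined.  All applied fallbacks are recorded on
the result.  The no-selection null curve is
`Nc(s) = 2 + s + 29/(s² + (1 − s)²)`, with maximum 60.5 at `s = 0.5`
and endpoints 31 and 32.  Only the standard genetic code is supported;
internal stop codons are excluded with a warning.

## Expression

TPM is the standard length-normalised relative abundance
(`10⁶·rateᵢ/Σrate`, columns summing to one million); effective lengths
are plain transcript lengths (no fragment-length correction).  The
translatome enrichment index is the ratio of TRAP-seq TPM to mRNA-seq
TPM; a zero mRNA TPM makes it undefined (`NA`), reported distinctly from
a TEI of 0.  Heatmap display uses row scaling to a sum of one, leaving
all-zero rows untouched with a warning.  "Expressed" for support
fractions means at least one count in at least one sample, with the
threshold exposed as a flag.

## The synthetic genome

The simulator generates the statistical structure the methods assume,
so every module is testable without external data.  Defaults (chosen
once, as study conditions):

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | enough for stable integer-bin histograms |
| mixture | 60% at N(47, 3), 40% at N(68, 3) | two GC classes, low mode major, modes at the grass values |
| CDS length | N(900, 300) bp, min 300, ×3 | typical transcript-derived CDS scale |
| chromosomes | 5 | exercises multi-sequence code paths |
| intergenic | lognormal ≈ 1000 + 300 bp at 43% GC | spacer GC independent of gene GC (no isochores) |
| evidence | ends extended by e = 50 bp, 10% dropout | induces `AED = 1 − (1 + L/(L+2e))/2` exactly |
| TE fraction | 0.1 | a visible but minority TE load |
| sources | 6 at 80% presence | up to six predictions per locus |
| counts | NB, mean depth 1000, size 100 | mildly overdispersed counts |

CDS sequences are generated codon-wise: first/second positions at a
clamped GC, third positions tuned so the overall GC hits the target,
stop codons repaired, then a correction pass flips third-position bases
(never creating stops) until the GC count matches `round(g·L)` — GC is
concentrated at synonymous sites, as in real high-GC grass genes, and
realized GC lands within a fraction of a percent of target.  Every
simulator is a pure function of its configuration: the same seed gives
byte-identical output, and all seeded work restores the caller's RNG
state.

What the simulator does *not* emulate — multi-exon structure beyond the
single-exon default, realistic repeat landscapes, splice-variant
evidence, alignment noise other than symmetric end-extension, sequencing
reads — bounds what passing tests show: they validate the statistics and
the bookkeeping, not robustness to every artefact of real alignments.

## Numerical and degenerate-input choices

Coordinates are 1-based inclusive everywhere (GFF3 native); half-open
conversion happens only inside interval arithmetic.  Unknown strand is
kept as `*`, never coerced.  Duplicate transcript ids are errors, not
silent renames.  The GFF3 writer emits a canonical dialect (fixed
nesting, `ID`/`Parent` plus `_AED` on mRNA lines, deterministic
ordering, UNIX newlines) such that write→read→write is a byte-identical
fixpoint; AED values are serialised with `as.character`, which
round-trips doubles at 15 significant digits.  Empty inputs yield
defined results (`NA` with a warning) where a statistic is undefined:
AED₀.₅ of nothing, mean length of nothing, GC of an all-N sequence,
TEI over zero mRNA.

Problem sizes in the test-suite checks are the smallest at which each
property is statistically meaningful: 1000 random histograms/interval
configurations for the oracle equivalences, 20 replicate genomes of
2000 genes for cutoff recovery, 500 loci for merge correctness, 500
genes for the filter chain, 200 genes × 3 tissues for TEI recovery.

## Known limitations

* The peak rule's strict-tie behaviour makes cutoff detection fail on a
  few percent of perfectly bimodal replicates (see above); rerunning
  with a different smoothing window or supplying manual cutoffs is the
  documented remedy, as in the original protocol.
* AED here is nucleotide-level only; splice-aware variants and
  pooled-evidence scoring are not implemented.
* Nc conventions for sparse data follow one published line of practice;
  other tools differ in their treatment of rare amino acids, so Nc
  values are comparable within this package, not necessarily across
  tools.
* TPM uses plain transcript lengths; no fragment-length model.
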