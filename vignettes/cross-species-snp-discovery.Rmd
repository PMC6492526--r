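---
title: "Cross-species SNP discovery: methods and design decisions"
author: "xenoSNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species SNP discovery: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoSNP)
```

## Scope and model

xenoSNP analyses genotypes obtained by running samples of a *target* species
on a SNP array designed for a related *source* species. The biological signal
is weak and the noise structured: most probes fail to hybridise cleanly, many
that do sit on sites monomorphic in the target, and a called genotype may be
an artifact of a distorted cluster. The package therefore treats discovery as
two independent lines of evidence that must both hold:

- **statistical**: the SNP's genotype calls are of high quality across
  samples, and the site is polymorphic in the sample;
- **sequence-level**: the probe's flanking sequence anchors the SNP to
  exactly one location in each of two independent target assemblies.

The unit of data is a `SnpCallSet` (a `SummarizedExperiment` with assays
`allele1`, `allele2`, `score`), carrying one per-genotype quality score in
[0, 1] per call and the per-SNP manifest (allele pair, probe flanks, GenTrain
score) in `rowData`. Scores and GenTrain values are *inputs*: the package
does not recompute them from raw intensities, which is the genotyping
software's job.

## Quality metrics

Under a no-call threshold $t$, a genotype is a call iff its score
$s \ge t$ and it is not a vendor-level no-call (the `-/-` entries the
genotyping software itself refuses to call; both kinds count as no-calls in
every denominator). The comparison is $\ge$: a score exactly at the
threshold is a call, consistent with the convention that scores *less than*
the cutoff are not assigned.

Per SNP the package computes:

- call frequency $= n_\mathrm{called} / (n_\mathrm{called} +
  n_\mathrm{nocall})$, exact as a count ratio;
- GC10/GC50, the 10th and 50th percentiles of scores over called genotypes
  only, and $\mathrm{avgGC} = (\mathrm{GC10} + \mathrm{GC50})/2$;
- genotype counts, $\mathrm{MAF} = \min(c_A, c_B)/(2 n_\mathrm{called})$
  with $c_A = 2 n_{AA} + n_{AB}$;
- a Hardy–Weinberg 1-df chi-square without continuity correction, testing
  observed counts against $(p^2, 2pq, q^2) \cdot n$ at the sample allele
  frequencies, with $\alpha = 0.05$; monomorphic SNPs are *not applicable*,
  never "failed".

**Percentile rule.** The genotyping software's interpolation convention is
not documented, so the package fixes one explicitly: linear interpolation
between closest order statistics at rank $p(n-1)$ (the "type 7" convention,
R's default). The test-suite oracle implements the same declared rule
independently; any other convention would shift avgGC by at most the spacing
of adjacent order statistics and would not change the architecture.

**MAF timing.** Whether published MAF values were computed before or after
threshold-induced no-calls is unknowable from the outside; this package
computes MAF over called genotypes *under the active method's threshold*,
which keeps every metric conditioned on the same denominator.

## Filter methods and the cascade

`methodConfig("I")` … `"VII"` encode the crossed design: no-call threshold
0.05/0.15/0.25 × call frequency (≥ 0.9 or = 1), with avgGC ≥ 0.7 everywhere
except method VII (stage disabled) and GenTrain ≥ 0.25 throughout. Retained
sets are reported at MAF ≥ 0.01 and ≥ 0.05 (both inclusive).

Design decisions:

- **Stage order** is call frequency → avgGC → GenTrain → MAF. The stages are
  conjunctive filters, so the final set is order-independent; the order only
  shapes the intermediate counts, and this order matches how such results
  are conventionally tabulated.
- **"= 1" is an integer condition**: zero no-calls, never a floating-point
  equality on the frequency.
- **Threshold guarding**: `applyMethod()` refuses metrics computed at a
  different no-call threshold than the method's own — a cheap guard against
  a subtle class of bugs, since all seven methods share one call set but not
  one metrics table.
- A SNP with undefined avgGC (nothing called) or undefined MAF fails the
  corresponding stage rather than erroring the batch.

## Flank queries and exact search

Array probes read the target DNA immediately 3′-adjacent to the variant;
mismatches closest to the variant are the most destabilising. Validation
therefore asks for *perfect* identity over the first 20 or 25 bases on each
side of the variant. For each length $L \in \{21, 26\}$ and allele $X$:

- upstream query: last $L-1$ nt of the 5′ flank, then $X$;
- downstream query: reverse complement of ($X$, then first $L-1$ nt of the
  3′ flank) — i.e. the downstream side read on the negative strand —

so every query carries the variant base at its 3′ end. Because selection
keeps only perfect matches of fixed short lengths, BLAST adds nothing over
exact substring search; the package searches both strands exactly
(Biostrings, with an Aho–Corasick dictionary when batching) and converts
each occurrence to the implied 0-based variant coordinate. `N` never
matches: queries containing `N` are skipped, and `N` in a genome cannot
match an A/C/G/T query base.

**Locus consolidation.** A locus requires an upstream-derived and a
downstream-derived hit implying the *same* (scaffold, variant position,
orientation) — the only interpretation that reconstructs a single SNP site;
upstream hits anchor in their own orientation, downstream hits in the
opposite one. A 26-mer pair can only co-match where the 21-mer pair does
(suffix containment), so the 21-nt pair is the minimum evidence; requiring
the 26-nt pair instead is strictly stricter and available as
`require26 = TRUE` (`minFlank = 26` in the pipeline). Either allele may
anchor a locus, the reference being haploid; the matched allele is recorded.

**Uniqueness and intersection.** Exactly one locus ⇒ `unique`; several loci
⇒ `multi_scaffold` or `multi_within_scaffold` (both non-unique); none ⇒
`absent`. Only SNPs unique in *both* assemblies are retained — agreement of
two independent assemblies is the guard against assembly-specific collapse
or duplication artifacts.

**Contexts and conservation.** For each retained SNP the 101-nt
variant-centred window is extracted from the first assembly
(reverse-complemented for minus-strand loci, variant at 0-based index 50).
A variant within 50 nt of a scaffold edge yields a truncated, flagged
context excluded from conservation checks. Conservation against an outgroup
assembly means the full 101-mer — with either allele substituted at the
centre, on either strand — occurs there by perfect match.

## Annotation

Chromosome assignment is a scaffold lookup in a user-provided synteny map
(labels such as VPA1…VPA36, VPAX; evidence `synteny` or `cytogenetic`);
scaffolds absent from the map are reported `unassigned`, so assigned +
unassigned always equals the retained total. The nearest gene minimises the
distance from the variant base to the closest edge of the gene's full span
(GFF3 `gene` features, 1-based inclusive on file, converted internally),
strand-agnostic, 0 when inside; ties break to the smaller start coordinate,
then the lexicographically smaller gene id. No maximum distance is imposed.
Two SNPs may annotate to one gene.

## Reporting

Percentages are `100 · count/total` rounded half-away-from-zero to 1
decimal; reductions are `100 · (1 − after/before)`. Polymorphism
proportions are reported as the raw ratio `n/total` to 6 decimals, following
the field's convention of printing that ratio with a percent label; the
observed/expected ratio compares it against an expected proportion **on the
same convention** (default 0.000515, a config input typically taken from an
exponential-decay model of polymorphism retention over divergence time —
that model itself is out of scope). Hardy–Weinberg results on the final
retained set are reported, never used as a filter.

## The synthetic-data generator

`simulateGenotypeReport()` emulates the study design the package targets:
40 diploid samples, per-SNP archetypes with distinct score distributions,
all Beta-family for support on [0, 1] and analytic tail probabilities:

| archetype | scores | vendor no-call | GenTrain | genotypes |
|---|---|---|---|---|
| clean_polymorphic | Beta(18, 2) | 0 | U(0.55, 0.95) | HW at true MAF |
| monomorphic | Beta(18, 2) | 0 | U(0.55, 0.95) | one homozygote class |
| noisy_cluster | Beta(2, 2) | 0.05 | U(0.25, 0.75) | HW at true MAF |
| low_call | Beta(1, 3) | 0.15 | U(0.25, 0.75) | HW at true MAF |

True MAFs are drawn from allele-count multiples $k/80 \in [0.05, 0.5]$
(resolution of 40 diploid samples), or fixed via `trueMaf` — e.g. 0.0125,
one heterozygote, the design's detection limit. GenTrain is ≥ 0.25 for
every archetype, so the GenTrain stage removes nothing once avgGC ≥ 0.7 is
applied — the empirical behaviour this design reproduces; scores and
genotypes are independent within archetype (no intensity model), which is
sufficient to exercise every filter but does not emulate cluster-geometry
artifacts.

`simulateGenomes()` builds two target assemblies and an outgroup from
i.i.d. uniform background and plants each SNP's 101-nt context per fate:
`unique_both`, `duplicated` (two copies), `near_mutated` (one substitution
≤ 20 nt from the variant — inside the 21-mer window, so no locus),
`far_mutated` (substitution 26–50 nt away — loci intact at both lengths,
101-nt conservation broken; the unmutated context goes to the outgroup),
`absent`, `conserved_in_outgroup` (verbatim outgroup copy). About 30% of
plantings are reverse-complemented. At the default sizes (24 scaffolds ×
30 kb per genome) the accidental 21-mer match probability is about
$L \cdot 4^{-21} \approx 10^{-7}$ per query, so planted truth is exact and
recovery assertions can demand 100%/0% rather than bounds.

What the generator does **not** emulate: linkage disequilibrium, population
structure, ascertainment bias, intensity-space cluster shapes, assembly
gaps/N-runs, or sequencing error in the assemblies. Passing tests therefore
demonstrate correctness of the *pipeline logic* under controlled conditions,
not calling accuracy on real cross-species data.

## Numerical and degenerate-input choices

- All internal coordinates are 0-based half-open; file interfaces keep each
  format's native convention (GFF3 1-based inclusive).
- Scores are validated into [0, 1] at parse time with the offending line
  reported; half no-calls (`-` in one allele column only) are structural
  errors.
- Genotype-report parsing is row-order independent (SNPs take manifest
  order, samples sort); write-then-read round-trips are exact because
  simulated scores carry 4 decimals.
- Empty inputs flow through: zero-row metrics tables, empty cascades and
  empty reports are all valid and produce empty-but-well-formed outputs.
- `reductionPercent`/`percentOfTotal` refuse zero denominators; the HWE test
  returns NA (not applicable) rather than failing monomorphic SNPs.
- Deterministic serialisation throughout (fixed field order, fixed
  formatting): identical configuration and seed give byte-identical output
  bundles, verified by checksum in the test suite.

## Problem sizes

The shipped tests and the acceptance script run the generator at 40–500
SNPs × 40 samples and genomes of 12–24 scaffolds × 15–30 kb: large enough
that every archetype and fate occurs tens of times and small enough that the
whole suite runs in about a minute. The pipeline itself is linear in genome
size (dictionary search) and has been exercised at megabase scale; nothing
in the implementation assumes the simulated sizes.

## Known limitations

- Exact search means a single assembly error under a flank window loses the
  SNP (by design: that is the published selection rule being implemented).
- Uniqueness is assessed against the assemblies as given; collapsed repeats
  in *both* assemblies would pass undetected.
- The chi-square HWE test is asymptotic; at $n = 40$ with rare alleles an
  exact test would be preferable (the flag is reporting-only here, so the
  choice does not gate discovery).
- GO-term enrichment and the divergence-decay model for expected
  polymorphism are out of scope; the expected proportion is a configuration
  input.
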