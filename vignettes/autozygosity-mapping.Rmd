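---
title: "Mapping a fully penetrant recessive variant by linkage and autozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a fully penetrant recessive variant by linkage and autozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The mapping problem

In a closed, inbred population, a recessive disorder surfaces when two copies
of one ancestral haplotype meet in an offspring. Two independent signals
localise the responsible variant:

* **Parametric linkage.** With a disease model — here autosomal recessive,
  full penetrance, disease allele frequency $q$ — the pedigree likelihood
  $L(\theta)$ is a function of the recombination fraction $\theta$ between a
  marker and the unobserved disease locus, and
  $\mathrm{LOD}(\theta) = \log_{10} L(\theta) - \log_{10} L(1/2)$
  measures support for linkage.
* **Autozygosity.** Affected individuals are homozygous by descent across a
  segment surrounding the causal variant, visible as long runs of
  homozygosity (ROH) that all cases share *with identical alleles*.

Intersecting the linkage regions with the shared ROH, and conservatively
merging segments separated by short non-homozygous interruptions, yields the
critical intervals. Multi-sample sequencing then reduces those intervals to
candidate variants by Mendelian segregation (homozygous alternate in cases,
heterozygous in obligate carriers, absent or missing in controls) and by
consequence class; a premature stop codon is corroborated by depletion of the
mutant allele in a carrier's cDNA relative to gDNA (nonsense-mediated decay,
NMD).

`run_pipeline()` executes this chain end to end; `simulate_study()` generates
every input with known ground truth.

## The pedigree likelihood

The two-locus state of an individual is an ordered pair of
(disease allele, marker allele) haplotypes — 16 states. Founder haplotype
frequencies factorise as the product of the disease and marker allele
frequencies (linkage equilibrium); a transmitted gamete copies the disease
allele from one parental haplotype and the marker allele from the same
haplotype with probability $(1-\theta)/2$ each, or from the other with
probability $\theta/2$ each. Observed marker genotypes and affection
statuses enter as evidence: affection weights are the penetrances
$(f_0, f_1, f_2) = (0, 0, 1)$ for carriers of 0, 1, 2 disease alleles
(and $1 - f_i$ for unaffecteds).

The likelihood is computed by sum–product variable elimination on this
Bayesian network — the same quantity Elston–Stewart peeling computes, but the
elimination-order formulation handles arbitrary loop-free *and* looped
pedigrees exactly without the classical loop-breaking-by-duplication device,
which is why the package uses it. The whole $\theta$ grid is peeled at once
(factor values carry one column per $\theta$). Correctness is established in
the test suite against an independent oracle that enumerates the full joint
state space. Data that are impossible under the model yield
$\log L = -\infty$, a value, not an error.

Two practical choices:

* **Single point, not multipoint.** Each marker is scored on its own.
  This keeps the computation self-contained and exact; the cost is that one
  marker's information is never transferred to its neighbours. Region
  assembly over a dense map stands in for multipoint support regions.
* **Marker allele frequencies** are maximum-likelihood estimates from the
  founders with one pseudo-count per allele (0.5 if no founder is typed).

A consequence of the single-point choice in a half-sib design: only the
shared parent's meioses carry phase information, so every marker at which the
shared parent is homozygous has a LOD of exactly zero. Positive-LOD markers
are therefore interleaved with flat-zero ones even under perfect
cosegregation, and `linked_regions()` defines a region as a maximal run
uninterrupted by *opposing* markers (LOD $< 0$ somewhere on the grid) that
contains at least one supporting marker (max LOD $> 0$); flat-zero markers
pass through. Regions must span more than `min_length_bp` (default 1 Mb),
measured as the plain coordinate difference `end - start`.

## ROH detection and allelic sharing

`detect_roh()` implements the windowed scan popularised by PLINK's
`--homozyg`: a window of `window_snps` consecutive SNPs is *homozygous* when
it contains at most `max_het_in_window` heterozygous and
`max_missing_in_window` missing calls; a SNP is in-ROH when at least
`min_window_hit_fraction` of the windows covering it is homozygous; maximal
in-ROH runs passing `min_run_length_bp` and `min_run_snps` become segments.
`roh_params()` defaults mirror the tool's documented values (50 / 1 / 5 /
0.05 / 1 Mb / 100), since the original analysis cites the tool without
parameters.

Two refinements matter in practice:

* **Density scaling** (`run_pipeline(roh = NULL)`). The stock SNP-count
  parameters encode *physical* extents at dense-array spacing: 50 SNPs is
  roughly 0.15 Mb, and 100 SNPs roughly a third of the marker count expected
  in a 1 Mb run. On a sparser map those counts silently multiply the
  effective window and length thresholds; inside autozygous blocks the
  effect is compounded because family-based MAF pruning preferentially
  removes markers there (the shared haplotype's allele dominates the family
  chromosomes). The pipeline therefore rescales `window_snps` and
  `min_run_snps` to the pruned map's observed density, preserving the
  physical extents; the per-window missing allowance scales with the window.
  Explicitly passed `roh_params()` are always honoured unchanged.
* **Shared-segment trimming.** The windowed detector places segment
  boundaries with up to a window of slack, so the raw intersection of the
  cases' segments includes edge markers at which some case is not
  autozygous. `shared_roh()` trims each overlap inward to the outermost
  marker at which *all* cases are identically homozygous before applying the
  allelic-identity test: all cases identically homozygous at a fraction
  $\ge$ `allele_match_fraction` of the mutually non-missing markers
  (default 0.95, the tool's documented allelic-match default; missing calls
  are excluded from the denominator because they neither confirm nor break
  sharing). Genuinely discordant sharing — opposite homozygotes at half the
  markers — fails this test by a wide margin, while the sporadic genotype
  errors the simulator plants (~0.3% of marker–case calls) do not.

`compile_roh_boundaries()` replaces the manual inspection of raw genotypes
by a deterministic rule: each boundary is pushed outward marker by marker
while every case remains identically homozygous, stopping at the first
violating or missing call. Boundaries are marker positions. Because the
stretch between the last concordant and the first discordant marker is
unresolved by the array, `run_pipeline()` widens the final critical
intervals to end just inside the flanking markers before variant screening —
a few kilobases at real array density, and the conservative choice at any
density.

## Interval conventions

Coordinates are 1-based and inclusive at both ends everywhere inside the
package; BED's 0-based half-open convention exists only at the file
boundary (`write_bed()` / `read_bed()`). The span of an interval is defined
as the plain difference `end - start`, and `span_mb()` rounds half-up; both
choices reproduce printed interval sizes computed from printed boundary
coordinates (a 36,013,146–53,111,271 interval spans 17 Mb at 0 decimals; a
10,880,351–12,070,934 interval spans 1.2 Mb at 1 decimal). Merging bridges
gaps *strictly* smaller than `max_gap_bp` (default 1.5 Mb), encoding the
rule of treating segments interrupted only by sub-1.5 Mb non-homozygous
stretches as one interval.

## The segregation cascade

`run_cascade()` applies, in order: the case/carrier genotype pattern
(homozygous alternate in every case, heterozygous in every carrier — a
homozygous-alternate "carrier" would contradict obligate-carrier status
under full penetrance and is excluded); the control screen (homozygous
reference *or missing*, following the convention that an uncalled control
cannot contradict absence; a strict mode requires called reference);
restriction to the critical intervals (inclusive ends); and the
consequence-class restriction to protein-changing variants (missense,
nonsense, frameshift, canonical ±2 bp splice — the complement of
synonymous/noncoding). The report's five steps are monotone non-increasing
by construction; the per-chromosome in-interval counts, which are not a
nested sequence, are attached separately as the `by_chrom` attribute.

## Consequence annotation

A transcript model carries exon structure, strand, CDS boundaries and the
spliced CDS sequence. Genomic positions map to 1-based CDS coordinates
(counted from the 3' genomic side on the minus strand); codon index is
$\lceil p/3 \rceil$ with initiator Met = 1, so CDS position 388 is the first
base of codon 130. Substituted codons are translated with the standard
nuclear code; HGVS naming uses three-letter residues with `*` for a stop.
The truncated fraction of a stop at codon $k$ in an $L$-codon ORF is
$(L - (k-1))/L$: the stop's own position counts as lost. Indels whose length
change is not a multiple of 3 are frameshifts; in-frame coding indels are
reported in the protein-changing (missense) class. A reference-allele
mismatch against the CDS is a hard error, not a silent reclassification.

The packaged transcript fixture plants a GAG→TAG change at codon 130 of an
855-codon ORF. 855 is the package's ST14-like reference length — matriptase
protein length under the cross-species residue numbering the field uses —
adopted as a synthetic stand-in because the authoritative accession is not
bundled; at that length the truncation is 726/855 ≈ 84.9%, comfortably over
the 80% mark, and the >80% property holds for any length above 645 codons.

## The NMD allele-balance test

Chromatogram peak heights (or read counts) at the heterozygous site are
abstracted as integer allele counts per template source. Exact tests are
used throughout because depths may be small: each source against a 1:1
ratio by a two-sided exact binomial test, and gDNA against cDNA by Fisher's
exact test. Reported p-values are two-sided; direction (mutant
*under*-representation) is applied only at classification:
`complete_absence` (no mutant cDNA signal, balanced gDNA), `partial_nmd`
(cDNA significantly below ½, gDNA not off ½, sources significantly
different), `no_depletion` (nothing significant), else `inconclusive`.
At depth 100 and $\alpha = 0.05$ the suite verifies type-I error within
binomial slack of $\alpha$ under a true fraction of ½ and power ≥ 0.8 at a
true fraction of 0.2.

## What the simulator emulates — and what it does not

`simulate_study()` produces a 7-member mapping family (three affected
half-siblings and their four parents; the shared parent is configurable
because field pedigrees occur both ways), array genotypes, a sequencing tier
of 2 cases / 2 carriers / 75 controls, the transcript fixture and carrier
allele counts. Founders draw two distinct haplotypes from a pool of 8 in
which exactly one haplotype carries the causal allele; drawing with
replacement *across* founders models inbreeding, and autozygosity appears as
IBD copies of that single haplotype. Transmissions recombine with Poisson
crossover counts (linear map, 1 cM/Mb, no interference) at uniform
positions. Conditioning on the affection pattern is by rejection — founder
assignments and per-offspring gametes are redrawn until the realised causal
genotypes match the stated statuses, within a bounded retry budget. In
two-generation pedigrees the per-offspring rejection is exact conditional
sampling; in deeper pedigrees with downstream constraints it is sequential
and mildly approximate, which the package accepts for fixture purposes.

Study conditions are fixed at: 3 chromosomes × 50 Mb × 2000 evenly spaced
markers (≈40/Mb — a desk-scale stand-in for a 670k array's ≈280/Mb),
founder allele frequencies Beta(2, 2), missingness 0.005 and genotype error
0.001 per call (placeholders, since the real array's rates are unreported),
2000 background sequencing variants of which 1% mimic partial cosegregation,
and a carrier cDNA mutant fraction of 0.25 at depth 100. These sizes keep
the full simulation study (20 replicates) and the oracle-equivalence
property tests within a few minutes on one core.

Known departures from real data: no background linkage disequilibrium
beyond the causal haplotype (real arrays show block-wise LD, which makes
chance identical sharing likelier than simulated); background sequencing
variants ignore the family's relatedness; genotype error is symmetric
rather than allele-intensity driven; the population is a fixed 8-haplotype
pool rather than a coalescent sample. Passing tests therefore demonstrate
the machinery and its calibration under the stated model, not performance
on a real cohort.

## Numerical and degenerate-input conventions

Likelihood peeling rescales per elimination step and tracks the log scale,
so underflow cannot silently zero a likelihood; $-\infty$ propagates as a
distinguished value and LOD ties break toward the smaller $\theta$ on the
grid (step 0.01 by default). All-missing markers, and markers impossible
under single-locus transmission at every $\theta$, are flagged degenerate
with LOD 0. Chromosomes shorter than one ROH window collapse to a single
all-SNP window. Empty interval intersections and an empty merge input
return empty sets, not errors. A zero-survivor QC result is an error with
advice, since every downstream stage would be vacuous. The tie-free
rounding in `span_mb()` is half-up, not banker's.

## Limitations

Single-point LOD under-uses flanking information relative to multipoint
algorithms; the uninformative-marker handling in `linked_regions()`
recovers region structure but not multipoint LOD magnitudes. The ROH caller
is the windowed heuristic, not an HMM. Consequence annotation covers one
transcript model at a time with basic indel naming, not a full
multi-transcript annotator. The NMD test treats counts as exact binomial
draws, ignoring chromatogram saturation. X-linked models, liability
classes, and locus heterogeneity are out of scope.
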