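# autozyg

Autozygosity mapping and recessive candidate-variant prioritisation for
small inbred pedigrees.

In closed breeding populations, a monogenic autosomal recessive disorder can
be mapped with a handful of animals: a parametric linkage scan over a small
family, runs of homozygosity (ROH) shared with identical alleles among the
affected individuals, intersection and conservative merging of the two
interval sets into critical intervals, Mendelian segregation filtering of
multi-sample sequencing calls inside those intervals, transcript-aware
consequence annotation of the survivors, and — for a premature stop codon —
an allele-balance test for nonsense-mediated decay (NMD) in a carrier's
cDNA. `autozyg` implements that entire chain as tested R functions, plus a
gene-dropping simulator that generates every input with known ground truth.

The package is aimed at statistical geneticists and veterinary/medical
genomics groups who want a transparent, scriptable desk-scale version of
this classic mapping design (the kind usually run with PLINK + Merlin + an
annotation tool + spreadsheets), or a ground-truthed sandbox for teaching
and method checks.

## The core quantities

* **LOD score** under a fully penetrant autosomal recessive model with
  disease allele frequency *q* (default 0.7):
  `LOD(θ) = log10 L(θ) − log10 L(1/2)`, where `L(θ)` is the pedigree
  likelihood summing over founder two-locus ordered genotypes (linkage
  equilibrium) and transmissions with recombination fraction θ. Computed
  exactly by sum–product peeling, verified against full enumeration.
* **ROH**: PLINK-style sliding-window detection; shared segments require
  all cases identically homozygous at ≥ 95% of mutually non-missing
  markers, with marker-exact boundary refinement.
* **Critical intervals**: intersection of linkage regions (> 1 Mb) with
  shared ROH, merging segments whose gaps are strictly below 1.5 Mb.
  Coordinates are 1-based inclusive; a span is `(end − start)/1e6` Mb.
* **Segregation filter**: homozygous-alternate cases, heterozygous
  carriers, homozygous-reference-or-missing controls, then interval and
  protein-changing-consequence restriction, reported as a monotone cascade.
* **NMD test**: exact binomial tests of each source against a 1:1 allele
  ratio and Fisher's exact test of gDNA vs cDNA counts, classified as
  `no_depletion` / `partial_nmd` / `complete_absence` / `inconclusive`.

## Worked example

Simulate one complete study — a 7-member half-sib family (3 affected), a
planted recessive stop-gain, a 2-case / 2-carrier / 75-control sequencing
tier, the design used to map naked foal syndrome (NFS, a recessive
genodermatosis of an inbred horse breed; hence the `nfs_*` names) — and run
the pipeline:

```r
library(autozyg)
st  <- simulate_study(seed = 1)
res <- run_pipeline(st)
res
#> <nfs_pipeline_result>
#>   markers: 6000 in, 2695 after QC
#>   linked regions (>1 Mb, LOD > 0): 3
#>   shared ROH intervals: 1
#>   critical intervals: 1 (28.79 Mb total)
#>   cascade: input=2001 -> cases_hom_carriers_het=59 -> controls_clean=8 -> in_critical_intervals=2 -> protein_changing=1
#>   candidates: var_causal
#>     c.388G>T p.Glu130* (nonsense)
#>   NMD classification: partial_nmd
```

Reading the output: of 6000 array markers, 2695 survive the family QC
(noninformative, sex-chromosome, missingness, Mendel-error and MAF < 0.2
pruning). Linkage and shared-ROH evidence intersect to a single critical
interval on the causal chromosome. Of 2001 sequencing variants, 59 show the
case/carrier genotype pattern, 8 also pass the 75 controls, 2 fall inside
the critical interval, and exactly 1 is protein-changing — the planted
variant, annotated as a nonsense change at CDS position 388 that truncates
codon 130 onward (`p.Glu130*`, ~85% of the ORF). The carrier's cDNA shows
the mutant allele at 28% against 49% in gDNA, classified as partial NMD:

```r
res$nmd
#> <nmd_result> partial_nmd
#>   gDNA alt fraction 0.490 (p vs 0.5 = 0.92)
#>   cDNA alt fraction 0.280 (p vs 0.5 = 1.26e-05)
#>   gDNA vs cDNA p = 0.00353
```

Every stage is also callable on its own (`prune_markers()`,
`linkage_scan()` + `linked_regions()`, `detect_roh()` / `shared_roh()` /
`compile_roh_boundaries()`, `intersect_intervals()` / `merge_with_gaps()` /
`span_mb()`, `segregation_filter()` / `run_cascade()`,
`annotate_variant()`, `nmd_classify()`), and standard formats are read and
written with `read_ped_map()` / `read_vcf()` / `read_bed()` and their
writers; `write_study(st, dir)` materialises a simulated study as
PED/MAP + VCF + BED + FASTA/TSV files. See the vignette
(`vignettes/autozygosity-mapping.Rmd`) for the models, parameter meanings
and design decisions.

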