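---
title: "Pooled bulk-segregant mapping: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled bulk-segregant mapping: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmapr)
```

poolmapr maps a recessive causal mutation from two phenotype-pooled DNA
samples of an F2 population. This vignette is the package's own account of
the underlying models, the tunable parameters and the design decisions
where the design was genuinely open.

## The genetic model

An induced recessive mutation sits on the reference-background haplotype of
the mutant parent. Crossing the mutant to a diverged wild accession and
selfing the F1 gives an F2 in which every marker segregates 1:2:1 and the
phenotype segregates 3:1 wild-type:mutant. Pooling plants by phenotype and
sequencing the pools turns linkage into an allele-frequency signal:

* **Mutant pool.** Every member is homozygous for the mutant parent's
  haplotype at the causal locus, so at a marker at genetic distance $d$
  (Morgan) the expected frequency of the wild-parent allele equals the
  recombinant fraction under the Haldane map,
  $r(d) = \tfrac{1}{2}(1 - e^{-2d})$ — essentially 0 nearby, rising to
  1/2 when unlinked.
* **Wild-type pool.** The wild-type-phenotype class is a 2:1 mixture of
  heterozygotes and homozygous wild-parent plants at the causal locus, so
  fully linked markers have expected wild-parent allele frequency
  $\tfrac{2}{3}\cdot\tfrac{1}{2} + \tfrac{1}{3}\cdot 1 = \tfrac{2}{3}$,
  and the causal (mutant) allele itself sits at
  $\tfrac{2}{3}\cdot\tfrac{1}{2} = \tfrac{1}{3}$ — a heterozygous-looking
  frequency.

Two allele codings coexist in one VCF by design: background markers carry
the wild-parent allele as ALT (they are differences from the reference
assembly contributed by the wild accession), while the causal site carries
the induced mutation as ALT (it is a difference from the reference
contributed by mutagenesis, traveling on the reference-background
haplotype). The candidate filter depends on this asymmetry and the test
suite asserts it: linked background markers are homozygous *reference* in
the mutant pool and therefore fail the filter, while the causal site is
homozygous *alternative* there and passes.

## The simulator and what it does (not) emulate

`simulate_f2()` models F1 meiosis per chromosome with a Poisson crossover
count (mean = genetic length in Morgan), crossover positions uniform in
genetic distance, no interference (Haldane), and markers placed linearly
in genetic coordinates. `sample_pooled_reads()` draws, per marker and
pool, a Poisson read depth and binomial allele counts with a symmetric
per-read miscall probability. This reproduces the statistical structure
that the mapping stages consume — pooled allele counts with
linkage-decayed frequency signals — but deliberately not read-level
artifacts: no FASTQ simulation, alignment error, indels, structural
variants, segregation distortion or phenotyping error. Tests passing on
these simulations therefore validate the statistical logic of the
pipeline, not robustness to alignment or calling artifacts, which enter a
real analysis upstream of the VCF.

Defaults mirror the study design the package emulates: 117 F2 plants,
pools of 25 wild-type and 16 mutant plants, a fully penetrant recessive
causal SNP (a G>A transition) mid-chromosome-4. The genome default is
desk-scale but tomato-shaped: 12 chromosomes, 5 Mb and 100 cM each, 2,000
evenly spaced markers per chromosome — enough markers for the 1000/100
window parameters to yield 11 full windows per chromosome. Published pool
depth is not stated for the study data, so depth is a simulator choice:
Poisson mean 40 per pool with base error 0.001, the scale of pooled
HiSeq-class data, chosen once and not tuned. 90% of background markers are
flagged as previously reported: an interspecific cross's background
variants are mostly present in public catalogs, whereas an induced
mutation never is. A single seed governs all sampling (meiosis first,
then, under `seed + 1`, read depths and counts in pool order wt, mut), so
a fixed configuration reproduces a byte-identical VCF.

## Mapping parameters

* **`min_depth = 10`** (per pool, inclusive): the depth filter applied on
  reading the VCF; records where either pool has fewer than 10 reads are
  dropped, as are multiallelic records.
* **`window_size = 1000`, `step = 100`** (variants): windows are defined
  in variant-rank space, not base pairs — the averaging unit is "1000
  variants", so bp spans adapt to local variant density. Base-pair bounds
  are derived from the first and last member variants and never drive
  windowing. Trailing variants that cannot fill a final full window are
  covered by the last full window only; a chromosome with fewer variants
  than one window yields a single window flagged partial. This tail rule
  is deterministic and documented rather than canonical.
* **`mut_af_max = 0.2`, `delta_min = 0.25`**: no numeric cutoff for
  "strong reference bias" exists to reconstruct, so region detection
  exposes two thresholds chosen to separate the theoretical expectations
  (mutant pool near 0–0.1 after window dilution, wild-type pool near 2/3)
  with margin at the default depth. Flagged windows that overlap or abut
  in rank space merge into regions, ranked by mean wt−mut difference
  (ties: more windows, then chromosome name).
* **`het_low = 0.15`, `het_high = 0.85`**: pooled "genotype" calls have no
  published thresholds either; the defaults classify the expected 1/3
  (heterozygous mixture) and 1.0 (homozygous) frequencies correctly with
  margin at depth 20+. Both are exposed as arguments.

A quantitative note on window dilution: with 2,000 markers per 100 cM, a
1000-variant window spans roughly 50 cM, and integrating $r(d)$ over a
window centered on the causal site gives an expected mutant-pool window
mean near 0.107 — visibly depressed but not near zero. The site-level
frequency at the causal marker, not the window mean, carries the
near-zero signal; the detection threshold of 0.2 accommodates the
dilution. At realistic variant densities (thousands of variants per cM in
an interspecific cross) windows are genetically much narrower and dip
correspondingly deeper.

## Candidate filtering and annotation

Inside a detected region, a variant passes iff the wild-type pool call is
heterozygous, the mutant pool call is homozygous-alternative, and the
variant is absent from the known catalog (all four of chrom, pos, ref,
alt must match for a catalog hit; catalog provenance is the user's
choice). Every variant is returned annotated with its calls and the full
list of violated criteria, so the filter is auditable rather than silent.

Effect prediction uses the standard nuclear genetic code, residue
numbering 1-based from the initiator methionine, and VCF convention for
input bases (forward genomic strand, complemented internally for
minus-strand genes). Only single-nucleotide substitutions in the CDS are
classified; splice/UTR effects are out of scope. The worked missense
fixture places CGG at codon 268 because an exhaustive codon-table scan
shows CGA>CAA and CGG>CAG are the only arginine-to-glutamine changes
reachable by a single G>A; the real codon is not published, so the
fixture commits only to what is: R268Q via G>A.

## Restriction markers

Amplicons are linear (PCR products); only the top strand is scanned, which
is sufficient because the modeled enzymes (ClaI, XbaI, XhoI, KpnI, ...)
have palindromic recognition sites. IUPAC ambiguity is honored in
recognition sequences but not amplicons (designed sequences). The gel
model is fragment-size arithmetic only: a marker is usable when the two
alleles' fragment multisets differ and the smallest distinguishing size
difference reaches `min_diff_bp` (default 10 bp, about what 2% agarose
resolves). The shipped 96 bp dCAPS amplicon pair is synthetic — the true
amplicon sequence is not published — and reproduces exactly the published
arithmetic: one ClaI site cutting the wild-type allele into 72 + 24 bp,
ablated by the causal G>A in the mutant allele.

## Segregation and expression utilities

`chi_square_gof()` uses Pearson's statistic without continuity
correction: for 55:15 against 3:1 the statistic is
$6.25/52.5 + 6.25/17.5 = 0.476$, printing as 0.48 with $P = 0.49$, and
94:23 gives 1.78 with $P = 0.18$ — the continuity-corrected versions do
not reproduce these, which fixes the design choice. Values are rounded to
two decimals for display only. The chi-square approximation is a large-
sample one; with expected class counts below ~5 an exact test would be
preferable, which the package deliberately does not provide.

`tpm()` normalizes counts to transcripts-per-million with user-supplied
effective lengths (annotated transcript length is the intended source; no
internal definition of effective length is imposed).
`replicate_consistency()` keeps the `top_k = 5000` genes by cumulative
TPM (ties broken by gene id), Z-scores each gene across all retained
samples — matching heatmap convention, not per-group — and biclusters
genes and samples with complete-linkage Euclidean clustering. The outlier
rule — flag a replicate whose nearest sample-tree neighbour (smallest
cophenetic distance) is not a same-group replicate — is this package's
operationalization of the visual practice of discarding replicates that
cluster away from their group; it is a screening aid, not a test.
Differential-expression inference itself is out of scope: `stage_overlap()`
consumes externally produced per-stage DE lists and returns the full
7-region Venn partition plus direction consistency for the triple
intersection. `ddct()` implements relative qPCR quantification,
$2^{-\Delta\Delta C_t}$.

## Numerical and degenerate-input choices

Zero pool depth is allowed in simulation output but rejected by
`allele_frequency()` — the depth filter is the caller's contract. All
coordinates are 1-based inclusive, matching VCF. Constant genes get a
Z-score of 0 rather than NaN. Catalog matching, VCF writing and truth
sidecars are plain text. Empty inputs return empty, typed results
(header-only VCF, empty region list, zero-count report) rather than
errors, except where the spec of an operation makes emptiness a usage
error.

## Problem sizes used in validation

The shipped tests validate on desk-scale instances chosen as the package's
own validation design: 20-seed parameter-recovery runs on the default
12-chromosome genome (24,000 markers, 117 plants), a 10,000-plant
single-chromosome cross for segregation behaviour, 200+ randomized cases
per brute-force oracle (window means, site scanning, chi-square, Venn
partition), and 10,000 multinomial replicates for the type-I error of the
segregation test. Known limitations: no indels or structural variants, no
segregation distortion (common in wide crosses), two pools only, no
confidence bands on the allele-frequency difference, and a qualitative
gel model.
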