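# poolmapr

Mapping-by-sequencing of a recessive causal mutation from pooled
bulk-segregant data, as a tested, reusable R pipeline. The package is aimed
at plant geneticists who map induced mutations by crossing a mutant to a
diverged accession, pooling F2 plants by phenotype, and sequencing the two
pools — and at anyone who wants to test such a pipeline end to end without
access to raw sequencing runs: a built-in cross simulator generates pooled
variant data with known ground truth.

## What it computes

For each biallelic variant and pool the **allele frequency ratio** is the
non-reference read count over the total read count,

    AF = alt / (ref + alt).

For a fully penetrant recessive mutation on the reference-background
haplotype, markers linked to the causal locus show AF near 0 in the
mutant pool (every mutant-pool plant is homozygous for the mutant parent's
background) against an expectation of 2/3 in the wild-type pool
(a 2:1 mixture of heterozygous and homozygous non-reference plants), while
unlinked markers sit near 1/2 in both. The pipeline:

- filters a VCF to biallelic variants with >= 10 reads per pool
  (`read_pooled_vcf()`),
- averages AF in sliding windows of 1000 variants advancing by 100
  (`window_profile()`), per chromosome,
- flags and merges windows with a strong reference bias in the mutant pool
  into candidate regions (`detect_candidate_region()`),
- applies the two candidate criteria inside a region — ALT heterozygous
  (0/1) in the wild-type pool, homozygous (1/1) in the mutant pool, and
  absent from a known-variant catalog (`filter_candidates()`),
- predicts the protein-level consequence of a candidate SNV
  (`predict_effect()`), e.g. a G>A turning codon CGG (Arg) into CAG (Gln),
- designs the genotyping readout in silico: restriction-site scanning,
  allele digestion and CAPS/dCAPS marker evaluation (`scan_sites()`,
  `digest()`, `evaluate_marker()`),
- tests Mendelian segregation with a chi-square goodness-of-fit
  (`chi_square_gof()`), plus expression-QC utilities (`tpm()`,
  `replicate_consistency()`, `stage_overlap()`, `ddct()`).

The simulator (`genome_map()`, `cross_config()`, `simulate_f2()`,
`sample_pooled_reads()`, `write_sim_vcf()`) models F1 meiosis with a
Poisson crossover count per chromosome and a Haldane map (no
interference), recessive phenotype assignment, phenotype-stratified pool
draws, and Poisson-depth binomial read sampling with a per-read error
rate.

## Worked example

```r
library(poolmapr)

genome <- genome_map()                       # 12 chromosomes, desk scale
config <- cross_config(seed = 3)             # 117 F2, pools of 25 + 16
truth  <- simulate_f2(genome, config)
reads  <- sample_pooled_reads(truth)
kept   <- reads[(reads$wt_ref + reads$wt_alt) >= 10 &
                (reads$mut_ref + reads$mut_alt) >= 10, ]
prof   <- window_profile(kept)               # 1000/100 variant windows
(top   <- detect_candidate_region(prof)[1, ])
#> # A tibble: 1 x 8
#>   chrom start_bp  end_bp n_windows min_mut_af mean_delta start_rank end_rank
#>   <chr>    <dbl>   <dbl>     <int>      <dbl>      <dbl>      <dbl>    <dbl>
#> 1 chr04     2498 4996000        11     0.0955      0.508          1     2000

region <- kept[kept$chrom == top$chrom & kept$pos >= top$start_bp &
               kept$pos <= top$end_bp, ]
cand   <- filter_candidates(region)
cand[cand$passes, c("chrom", "pos", "ref", "alt", "af_wt", "af_mut")]
#> # A tibble: 1 x 6
#>   chrom     pos ref   alt   af_wt af_mut
#>   <chr>   <dbl> <chr> <chr> <dbl>  <dbl>
#> 1 chr04 2500498 G     A     0.333      1
```

The top-ranked region is the causal chromosome, and the single variant
passing both criteria is the injected causal G>A (wild-type pool AF 1/3 =
heterozygous mixture; mutant pool AF 1 = homozygous mutant), matching
`truth$causal_pos`. Downstream:

```r
chi_square_gof(c(55, 15), c(3, 1))
#> Segregation chi-square goodness-of-fit
#>   observed: 55:15   expected ratio: 3:1
#>   chi-square = 0.48, df = 1, P = 0.49

amp <- dcaps_fixture_amplicons()
digest(amp$wt, restriction_enzymes()$ClaI)
#> <digest_result> 96 bp; 1 cut(s); fragments: 72 + 24
digest(amp$mut, restriction_enzymes()$ClaI)
#> <digest_result> 96 bp; 0 cut(s); fragments: 96
```

The wild-type dCAPS allele cuts 96 -> 72 + 24 bp; the mutant allele, whose
G>A ablates the ClaI site, stays uncut — the two alleles are separable on
a 2% agarose gel.

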