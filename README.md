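# lincscd

Stop-codon density and splice-enhancer motif analysis for noncoding RNA.

## The problem

Long intergenic noncoding RNAs (lincRNAs) are spliced like mRNAs: the same
serine/arginine-rich (SR) proteins that direct the spliceosome bind short
exonic splice enhancer (ESE) motifs — typically hexamers concentrated near
exon 5′ ends — in both gene classes. Because ESEs inside protein-coding
exons cannot introduce an in-frame stop codon, the ESE vocabulary is
depleted of TAA/TAG/TGA, and transcripts that rely on the same vocabulary
for splicing inherit that depletion even though stop codons are meaningless
to them. The result is *transfer selection*: a constraint that originates
in coding sequence shows up in noncoding sequence via shared binding
factors. One practical consequence is that a lincRNA's longest possible
"ORF" is systematically longer than its nucleotide composition predicts,
which inflates false positives for ORF-length-based coding/noncoding
annotation.

`lincscd` implements the full analysis toolkit for quantifying these
effects, for anyone studying sequence composition constraints in
noncoding RNA or calibrating ORF-length annotation thresholds.

## The statistics

**Coverage density.** For a query motif set *M* and sequence *S* of length
*L*, the density is

```
D(M, S) = |{ positions of S covered by ≥1 occurrence of ≥1 motif in M }| / L
```

with every occurrence at every offset counted and overlapping occurrences
unioned at the position level, so `0 ≤ D ≤ 1`. The **stop codon density
(SCD)** is the density of `{TAA, TAG, TGA}` in any frame. Densities over a
sequence set are pooled (covered positions and lengths summed before
division).

**Null models.** Motif-level nulls are dinucleotide-matched pseudo-motif
sets (same set size and length multiset, motifs assembled from
dinucleotides sampled at the true set's overlapping-dinucleotide
frequencies). Sequence-level nulls are mononucleotide shuffles — within a
sequence, within each masked part, or by shuffling the pooled concatenation
and re-extracting length-matched sequences.

**Inference.** With observed statistic *O* and simulant mean *E*:

* fold enrichment `FE = (O − E) / E` (negative = depletion),
* `Z = (O − mean) / sd` over the simulants (sample sd),
* empirical `p = (m + 1) / (n + 1)` with *m* the simulants at or beyond *O*
  in the tested tail over *n* iterations.

**Compositional controls.** All 41,664 unordered sets of three distinct
codons are enumerated; control groups match the stop-codon set's total
G+C count (2/9) and/or purine count (6/9), optionally excluding sets with
stop-codon members or with mutually overlap-capable codons, to ask whether
a depletion is specific to the stop codons rather than their composition.

## Worked example

Densities follow the overlap-once convention:

```r
library(lincscd)
motif_density("AGATAGGGGA", c("GAT", "GGG"))
#> # A tibble: 1 × 3
#>   covered_count sequence_length density
#> 1             7              10     0.7
```

(`GAT` and the two overlapping `GGG` hits cover 7 of 10 positions.)

A synthetic cohort with stop-free ESEs planted in exon 5′ flanks
reproduces the lincRNA depletion signature end to end:

```r
cfg    <- synthetic_config(n_genes = 50, seed = 1)
cohort <- generate_cohort(cfg)

tidy(cohort_scd_fe(cohort$transcripts, n_iterations = 200, seed = 2))
#>   observed null_mean null_sd      fe     z p_lower
#> 1    0.150     0.161 0.00223 -0.0661 -4.75 0.00498
```

The cohort's pooled SCD (0.150) sits below every one of 200 shuffle
simulants (mean 0.161): FE = −0.066, a significant stop-codon depletion
(p ≈ 0.005). The depletion tracks the planted ESE gradient across exon
regions — strongest in the 5′ flank where ESE density is highest:

```r
region_analysis(cohort$transcripts, cohort$ground_truth$ese_set,
                n_iterations = 200, seed = 4)
#>   region n_exons ese_density observed null_mean      fe p_lower
#> 1 flank5     145       0.442    0.120     0.159 -0.2486 0.00498
#> 2   core     145       0.274    0.149     0.157 -0.0485 0.07463
#> 3 flank3     145       0.191    0.151     0.154 -0.0152 0.35821
```

and disappears once ESE-matched positions are masked out:

```r
fold_enrichment(masked_scd_fe(cohort$transcripts, cohort$ground_truth$ese_set,
                              n_iterations = 200, seed = 3))
#> [1] 0.0528
```

Pseudo-ORF tools (`longest_porf()`, `porf_null()`, `threshold_excess()`)
quantify how the depletion stretches ORF lengths beyond composition-null
expectations and locate the length threshold needed for a 5% excess rate.
`run_pipeline()` exposes every analysis as a config-driven subcommand with
TSV outputs and a JSON run manifest; a thin shell wrapper lives in
`inst/cli/lincscd.R`.

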