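---
title: "Measuring stop-codon depletion in noncoding RNA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stop-codon depletion in noncoding RNA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincscd)
```

## The model

Multi-exon lincRNAs are spliced by the same machinery as pre-mRNA, guided
by SR proteins binding exonic splice enhancers (ESEs). ESEs that also
function inside protein-coding exons cannot contain a stop codon in the
reading frame, so the shared ESE vocabulary is stop-depleted; transcripts
that need that vocabulary for splicing inherit the depletion regardless of
any coding role. `lincscd` operationalises this *transfer selection*
hypothesis as a chain of measurable quantities:

1. a coverage density for any motif set in any sequence;
2. null models that hold composition fixed — dinucleotide-matched
   pseudo-motif sets for motif collections, mononucleotide shuffles for
   sequences;
3. fold enrichment (FE), Z scores and empirical p values comparing the
   observed density with its null distribution;
4. compositionally matched codon-set controls that ask whether a depletion
   is specific to the stop codons or to their G+C / purine content;
5. spatial attribution: exon-region partitioning, ESE masking,
   exon-versus-intron pairing, per-stop-codon skew;
6. pseudo-ORF length consequences and annotation-threshold calibration.

## The density metric

`motif_density()` counts the positions of a sequence covered by at least
one occurrence of at least one query motif, at any offset, and divides by
the sequence length. Each position counts once however many occurrences
overlap it, so the metric is bounded by 0 and 1 and is comparable across
motif and sequence lengths. Hit scanning examines *every* offset;
overlapping self-matches (GGG twice inside GGGG) are found and unioned at
the position level. Densities over sequence sets are pooled — covered
positions and lengths are summed before dividing — so long sequences weigh
proportionally more; this matches the arithmetic of treating a motif
collection as one concatenated measurement while never letting windows
span motif boundaries. A per-sequence (pairwise) mode is available through
`per_gene_scd_fe()` where the aggregation choice matters.

`mask_and_split()` removes every covered position and returns the
unmatched runs as separate parts. Parts are never concatenated: joining
them could fabricate motif occurrences across the junction. Downstream
nulls shuffle within each part, preserving the part-length structure; this
is the conservative reading of "shuffle the remaining nucleotides", and
the choice is recorded in the function documentation and output metadata.

## Statistics and their conventions

With observed statistic $O$ and simulants $E_1, \dots, E_n$:

* $\mathrm{FE} = (O - \bar E)/\bar E$; negative values indicate depletion.
  FE is undefined when $\bar E = 0$ and the package raises an error rather
  than returning a sentinel.
* $Z = (O - \bar E)/s_E$ with $s_E$ the **sample** standard deviation
  ($n-1$ denominator): the simulants are a sample from the null, and the
  convention is fixed here so independent reimplementations can match it.
  Zero-variance simulant sets raise an explicit undefined-Z error.
* Empirical $p = (m+1)/(n+1)$, where $m$ counts simulants less than or
  equal to $O$ (lower tail) or greater than or equal (upper tail). Ties
  count toward $m$ in both tails, so $p$ is conservative and never below
  $1/(n+1)$.

Standard tests around these bespoke statistics — binomial, chi-square,
Wilcoxon, Kolmogorov–Smirnov — are delegated to base R's `stats` routines.

## Codon-set controls

`enumerate_tricodon_sets()` produces all $\binom{64}{3} = 41{,}664$
unordered sets of three distinct codons with their total G+C count (0–9),
purine count (0–9), stop-membership flag and internal-overlap flag. Two
conventions deserve explanation because published counts depend on them:

* **Reference exclusion.** The matched groups serve as *controls* compared
  against the stop-codon set, which is trivially its own compositional
  match. `filter_sets()` therefore drops the reference set by default
  (`drop_reference = TRUE`), giving control-group sizes 2,879 (GC-matched),
  473 (GC- and purine-matched), 2,121 (GC-matched, no stop members) and
  131 (GC-matched, mutually non-overlapping). The purine-only group is
  conventionally quoted with the reference retained (6,856); pass
  `drop_reference = FALSE` to reproduce that figure.
* **Overlap definition.** `codons_can_overlap(x, y)` is true when a
  length-1 or length-2 suffix of either codon equals the same-length
  prefix of the other; a codon can overlap itself (AAA). The *set-level*
  `has_internal_overlap` flag, however, tests only pairs of distinct
  members: a set passes the non-overlap filter when no member can abut
  another member at offset 1 or 2 in either order. This distinct-pair
  reading is the one that makes the stop-codon set non-overlapping and
  reproduces the 131-set control group; including self-pairs would
  disqualify any set containing a self-overlapping codon and shrink the
  group to 80.

Both conventions are locked by exact tests against an independent
brute-force enumeration.

## Null models

**Dinucleotide-matched pseudo-motifs.** The profile counts every
overlapping adjacent pair in every motif (both alignment phases jointly
cover all positions). Pseudo-motifs are assembled from independently
sampled dinucleotides — deliberately *not* a Markov chain and not a
dinucleotide shuffle; the product matches expected dinucleotide usage
while randomising order. Odd lengths append one nucleotide drawn from the
mononucleotide counts. Each iteration regenerates the full set (same size,
same length multiset); a pseudo-motif colliding with one already generated
in the same iteration is resampled individually (cheaper than restarting
the whole iteration and distributionally equivalent under independent
sampling), with a default cap of 1,000 retries per motif that turns
pathological profiles (fewer reachable motifs than the set size) into an
explicit saturation error. Pseudo-motifs may equal true motifs; only
within-iteration uniqueness is enforced.

**Sequence shuffles.** Mononucleotide permutations at three scopes:
whole transcript, per masked part, and pooled extraction
(`concat_shuffle_extract()`: concatenate, shuffle once, cut back to the
original lengths). Every scope preserves the base counts of its scope
unit exactly, which the test suite asserts as an invariant. Higher-order
(dinucleotide-preserving) sequence shuffles are out of scope by design:
the sequence-level question is about mononucleotide composition.

**Random streams.** Every simulation takes one master seed and derives
per-iteration child seeds deterministically, so results are reproducible
and iterations are order-independent.

## Exon regions

Exons longer than 207 nt are partitioned into three disjoint 67-nt
windows: the 5′ flank at 1-based positions 3–69, the mirrored 3′ flank at
L−68 to L−2, and the core centred on the midpoint. When $L - 67$ is odd
the core start is floored, biasing it one nucleotide toward the 5′ end —
a deterministic tie-break that is symmetric on average. The terminal
dinucleotides are never included (they carry splice-site signal). The
length cutoff is strict: a 207-nt exon cannot host three disjoint windows
clear of both termini. Per-region observed/expected ratios are computed
as observed pooled SCD over the mean of per-region shuffles, i.e. each
region is simulated separately.

## Pseudo-ORFs

`longest_porf()` scans every ATG in all three frames of the sense strand
and walks in-frame codons to the first stop. The recorded length runs
from the first base of the ATG through the last base of the stop codon
(minimum 6 nt, always divisible by 3); the stop-exclusive convention is
available via `include_stop = FALSE` for sensitivity analysis, but all
threshold comparisons use the inclusive convention. Transcripts are
oriented, so only the sense strand is scanned. In null iterations a
shuffle with no pORF scores 0 so the simulant count stays constant; real
sequences with no pORF are excluded from Z analysis (and reported as
such). `threshold_excess()` computes, per length threshold, the real
count of transcripts with a pORF at least that long minus the mean null
count, divided by the number of transcripts; the 5%-excess threshold is
located by locally weighted regression (span 0.75, degree 2 — the
smoothing parameters are a package choice) with linear interpolation to
the crossing, returning NA when the curve never crosses from above.

## The synthetic cohort generator

`generate_cohort()` builds multi-exon transcript models with i.i.d.
background sequence at a configurable GC content, ESE motifs planted by
overwriting background positions in the three exon windows, and optional
planted stop-free ORFs. Key design decisions:

* **Overwrite, not insert.** Planting preserves declared exon lengths and
  coordinates; insertion would shift everything downstream.
* **Non-overlapping plants, uniform feasible placement.** Sites are drawn
  uniformly among positions that fit without touching previous plants;
  when a window saturates before reaching its target coverage the
  generator warns and records what it achieved.
* **Composition-matched planting.** The default planted vocabulary is 84
  stop-free hexamers generated at the background GC, and planted ORF
  bodies draw codons from the background composition conditioned on not
  being a stop codon. Planting therefore perturbs stop-codon content
  specifically, not GC, so measured FE is attributable to the planted
  signal rather than to a composition shift between observed sequence and
  its shuffles.
* **Separate randomness streams.** Structure, background, ESE planting
  and ORF planting each use their own deterministic substream of the
  master seed. Cohorts generated with the same seed but different
  planting densities share identical backgrounds, making dose-response
  experiments paired.

Defaults describe a modest but realistic cohort: 100 genes of 2–4 exons,
exon lengths 250–450 nt (long enough for the region partition), intron
lengths 200–400 nt, background GC 0.46 (typical of multi-exon lincRNA
exons), planting densities 0.30 / 0.10 / 0.05 for 5′ flank / core / 3′
flank — the qualitative concentration of splice-enhancer signal at exon
5′ ends.

**What the generator does not emulate.** Real lincRNAs have
position-dependent composition, splice-site signal at exon termini,
paralogous redundancy, transcript-length and GC heterogeneity far beyond
uniform ranges, and ESE motifs that are purine-rich rather than
composition-matched. Passing calibration and recovery tests on synthetic
cohorts therefore demonstrates that the *pipeline* measures what it
claims under known ground truth — not that any particular real dataset
shows the effect, and published effect magnitudes from real data are not
reproduction targets here.

## Family grouping

Paralogous families are the connected components of the pairwise
similarity-hit graph (single linkage). A seed-and-absorb construction
reaches the same partition as full transitive closure for components, so
the deterministic component computation is used. Two representative
policies are supported: one random member per family (seeded) or
per-statistic medians across members.

## Test problem sizes

The suite exercises calibration at 200 replicate genes with 200 shuffle
iterations each (empirical-p uniformity via Kolmogorov–Smirnov),
planted-signal recovery on 120-gene cohorts with 120–150 iterations,
pORF oracle equivalence on 1,000 random sequences up to 60 nt, and
threshold-curve behaviour on 150-gene cohorts with 100 null sets — sizes
chosen so the full suite runs in a few minutes while leaving the
stochastic assertions comfortable margins.

## Known limitations

* Fuzzy or position-weight-matrix motif matching is out of scope; hits
  are exact string matches.
* Empirical p values are reported raw; no multiple-testing correction is
  applied across genes or codon sets.
* The dinucleotide-matched null does not preserve trinucleotide or
  higher-order structure.
* `concat_shuffle_extract()` exchanges bases freely between sequences, so
  per-sequence composition is not preserved in that scope (by design — it
  is the cohort-level null).
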