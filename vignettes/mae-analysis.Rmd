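---
title: "Methods: mutation rates, spectra and structural events from MAE data"
author: "mutacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation rates, spectra and structural events from MAE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

# The experiment and the rate model

A mutation accumulation experiment (MAE) propagates many independent
lines of a microbe through repeated single-colony bottlenecks. Because
each bottleneck reduces the population to one cell, selection has very
little opportunity to filter mutations, and the variants present at the
end of the experiment approximate an unbiased sample of what mutation
produces. Sequencing each line and counting events then turns directly
into rates.

The denominator model is the standard one for plate-based MAEs. Each
subculture cycle corresponds to the growth of one colony from one cell,
taken to be `t` cell divisions (default 25, the conventional estimate
for a yeast colony; it is a design parameter, not a fitted quantity,
and every rate scales as `1/t`). With `gen_tot` the summed cycles over
lines and `N` the genome size in bp:

* per-base rates (SNVs, InDels, and any class thereof):
  `mu_bp = n / (N * gen_tot * t)`, in events per base per cell
  division;
* structural event rates (aneuploidies, segmental rearrangements):
  `mu_lar = n / (gen_tot * t)`, per cell division — genome size does
  not enter because the unit of observation is the event, not the base.

`experiment_design()` carries the line table, `t` and `N`. `N` defaults
to the loaded FASTA's length but can be overridden by a constant to
reproduce published arithmetic exactly (assembly releases differ by
more than the rounding in a printed rate).

## Confidence intervals

The default interval is a nonparametric bootstrap over *whole lines*
(`bootstrap_ci()`): lines are resampled with replacement, numerator and
denominator are recomputed per resample, and the percentile 2.5/97.5
bounds are reported. Resampling lines rather than events respects the
experimental unit — lines differ in both event counts and cycle
numbers, and between-line variance (e.g. a mutator phenotype arising
mid-experiment) is what the interval should reflect. `n_boot` defaults
to 10,000 and the generator is always explicitly seeded. Two caveats
are inherent to the percentile method and documented rather than
patched: the interval is not guaranteed to contain the full-data point
estimate, and with a single line it is undefined (flagged, not an
error). A Poisson-exact interval on the count (via the gamma quantile
identity) is available as `ci_method = "poisson"` in the point-rate
constructors for the count-only setting.

Between-condition comparisons of per-line rates use the two-sided
Wilcoxon rank-sum test (`compare_line_rates()`), each line with its own
denominator; the exact null is used for small samples without ties,
otherwise the tie-corrected normal approximation. Two degenerate inputs
are defined explicitly: identical groups give p = 1, and all-identical
values (e.g. all-zero counts) give p = 1 with a warning.

# Substitution spectra

SNVs are classified on the pyrimidine-referenced strand (C>A, C>G,
C>T, T>A, T>C, T>G): a substitution called on a purine base is mapped
to its reverse complement, so G-to-A calls count as C>T. This is the
COSMIC single-base-substitution convention and makes spectra
strand-symmetric. The 96-category spectrum crosses the six classes with
the 16 flanking base combinations of the trinucleotide centered on the
mutated base, oriented so the center is a pyrimidine
(`sbs96_counts()`).

Context enrichment (`context_enrichment()`) compares observed
trinucleotide counts within one substitution class to the expectation
from genome composition: the genome's trinucleotide frequencies are
tabulated on both strands via the same pyrimidine normalization and
conditioned on the center base (`genome_context_expectation()`), so the
expected count for context `x` in a class with `n` SNVs is
`n * f(x | center)`. Design choices where the procedure was genuinely
open:

* conditioning on the center base (rather than on all 32 contexts)
  matches the question actually asked — "given that a C mutated, were
  its neighbours unusual?" — and keeps each class's expectations
  summing to its own total;
* each context is tested with a 1-df chi-squared goodness-of-fit
  against its complement within the class family; when an expected cell
  drops below 5 the test falls back to an exact binomial (the `method`
  column records which was used);
* multiple-testing adjustment is applied within each class family,
  Bonferroni by default (conservative, matching an "adjusted for
  multiple comparisons" reading), Benjamini–Hochberg selectable.

Flanking-sequence matrices (`flank_matrix()`, default window 4 bases
each side) report per-position base frequencies on the normalized
strand and information content `2 - H` bits per position — the
quantity sequence-logo tools draw. No small-sample correction is
applied; with the event counts these experiments produce (tens to
hundreds per class) the correction is negligible against the biases of
interest (e.g. a 90% pyrimidine fraction at the 5' position).
Contexts containing `N` or truncated by a chromosome end are excluded
and counted, never silently dropped.

The G/C site-composition test (`site_composition_test()`) is a
two-sided exact binomial test of the fraction of SNVs whose reference
base is G or C against the genome's GC fraction.

# InDels and replication slippage

InDels are classified by direction and size bin (1, 2, ≥3 bp;
`classify_indel()`), after left-alignment. All variants are normalized
on input (`normalize_variant()`): shared suffix trimmed (extending left
over the reference when an allele empties), then shared prefix trimmed
— the standard VCF normalization — so an event inside a repeat run is
always anchored at the run's leftmost position and size bins are
invariant to the caller's choice of representation.

A deleted or inserted sequence is a *slippage candidate* when it
consists of whole copies of a unit `u` (all divisors of the event
length are tried, shortest qualifying unit wins) and the reference
around the event carries at least `min_copies` tandem copies of `u`
(`repeat_context()`). `min_copies` defaults to 2 — the weakest locus
that can template slippage, i.e. a 1 bp deletion next to one identical
base counts — and is exposed because the boundary is a definition, not
a fact; `repeat_fraction()` reports sensitivity to it trivially by
re-running. The search window is 50 bp each side (longer arrays are
truncated and flagged). Events longer than 50 bp are not InDels for
this package's purposes; they belong to the structural module.

`mononucleotide_census()` tabulates all maximal single-base runs of a
minimum length genome-wide, the comparison quantity for between-species
arguments about slippage substrate availability.

# Coverage-based structural events

Windowed depth is normalized to relative coverage (RC) by the
genome-wide *median* window depth (`relative_coverage()`), which is
robust as long as copy-altered windows are a minority of the genome
(< 50%); a haploid genome then sits at RC ≈ 1 with deletions near 0 and
duplications near 2. Calls (`call_cnvs()`) are maximal runs of at least
`min_windows` (default 10) consecutive windows at or beyond the
thresholds (defaults 0.5 and 1.5 — the midpoints between copy states 0,
1 and 2). Runs covering ≥ 90% of a chromosome are aneuploidy
(whole-chromosome) calls; runs touching a chromosome end are terminal,
the rest interstitial. The caller is deliberately a transparent
run-length scan — its contract is checkable against a brute-force
threshold scan, and the detection problem at MAE depths (~100x) is not
hard: a single-copy change at 100x is ~10 standard deviations of
per-window Poisson noise. No GC-bias correction is applied by default
(the synthetic depth model is unbiased); real depth tracks with strong
GC bias should be pre-corrected upstream.

# Consequence annotation

Coding is defined as the CDS footprint from the GFF3 — introns and UTRs
count as non-coding, and the genomic coding fraction used in the
chi-squared partition test is always computed from the provided
annotation rather than taken from a publication, because that number is
genome-release-dependent. SNV consequences come from codon comparison
on the gene strand (standard nuclear code): synonymous, missense, stop
gained, stop lost, and start lost (an ATG-abolishing change at codon 1,
ranked more severe than missense). CDS InDels are frameshift when
length mod 3 is nonzero, in-frame otherwise; SNVs can never be
frameshift. Variants hitting several genes take the most severe
consequence with all genes listed; InDels spanning a CDS boundary are
counted coding and flagged. Genes whose CDS intervals overlap or whose
length is not a codon multiple are flagged at load and their variants
marked unannotatable rather than guessed at.

# The synthetic generator

`generate_genome()` + `condition_profile()` + `simulate_lines()` +
`simulate_depth()` produce complete datasets with ground truth. What
they emulate, and the reasoning behind the defaults:

* **Event counts** are Poisson per line and class with mean
  `rate * N * cycles * t` — the independent-divisions, no-selection
  idealization of an MAE. Real MAEs deviate mainly through residual
  selection against strongly deleterious mutations; the generator does
  not model that, so recovery tests validate the estimator arithmetic,
  not immunity to selection bias.
* **Genome composition** is a first-order Markov chain at the requested
  GC content; `homopolymer_boost` multiplies the self-transition
  probability to enrich mononucleotide runs the way real genomes are
  enriched over an i.i.d. model (boost 1 gives exactly i.i.d., with
  geometrically distributed run lengths — a closed form the tests
  check). Single-CDS genes (ATG + non-stop codons + stop, either
  strand) are written into the sequence; real gene structure (introns,
  multi-exon CDS, overlapping features) is not emulated, so passing
  consequence tests say nothing about splice-aware annotation.
* **Context bias** is importance sampling: SNV positions are drawn with
  probability proportional to per-context weights over all eligible
  sites. The condition presets store rates on the magnitudes measured
  for spontaneous growth and UV/MMS/Zeocin mutagenesis in haploid
  yeast (e.g. spontaneous totals of 2.07e-10 SNVs and 1.61e-10 InDels
  per base per division; a 5x weight on 5'-G, pyrimidine-centered
  contexts in the Zeocin preset, encoding the bleomycin-family damage
  rule). These presets are config data for producing realistic test
  inputs, not hard-coded truth, and every field is overridable.
* **Slippage InDels** change one unit copy inside a tandem run sampled
  length-weighted from the genome; non-slippage InDels are
  rejection-sampled away from loci where they would qualify as repeats,
  so the truth label and the analysis annotation agree
  record-for-record and a recovered repeat fraction estimates the
  generating slippage fraction directly.
* **Depth** is Poisson per window at `mean_depth * copy_state`, default
  100x — the coverage class of a typical small-eukaryote resequencing
  experiment. The model has no GC bias, mappability structure or
  dispersion beyond Poisson; CNV-recovery results on it demonstrate the
  caller's correctness, not robustness to real-data artifacts.

Everything is deterministic given a seed; the generator saves and
restores the caller's RNG state.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; all file interfaces
  (VCF, GFF3, BED) use their native conventions at the boundary.
* Zero observed events give rate 0 with an explicit "no events
  observed" flag (and a one-sided Poisson upper bound), mirroring
  rate tables that print NA for empty classes.
* A zero denominator rate in a fold change yields `Inf` with a warning
  carrying the count context.
* Multi-nucleotide substitutions are rejected with a warning rather
  than split into SNVs — splitting fabricates events the caller did
  not report.
* All-`N` genomes, empty variant sets, all-zero depth and single-line
  designs produce defined errors or flagged results, never silent
  zeros.

# Validation strategy and problem sizes

The test suite validates each operation against an independent oracle:
brute-force tallies for spectra and censuses, exhaustive enumeration
for the rank-sum and exact binomial tests, hand formulas for
chi-squared statistics, an exhaustive left-shift oracle for allele
normalization, and generator ground truth for round trips. The
simulation scale was chosen to mirror the real experiments at reduced
genome size: coverage checks run 100 replicate experiments of 20 lines
on 50 kb genomes with the per-base rate scaled up by the genome-size
ratio, which preserves the study-like ~11 expected events per line —
the quantity that controls bootstrap behaviour — while keeping each
replicate small. Spectrum tallies use ~10,000 simulated SNVs on 200 kb;
CNV recovery plants three events across a 5-chromosome 100 kb genome at
250 bp windows.

# Known limitations

* No correction for detection power or callable-genome fraction: rates
  are per assembled base, as in the underlying experimental analyses.
* No Luria–Delbrück / fluctuation-assay estimation; the denominator
  model assumes the plate-bottleneck design.
* CNV calling is coverage-only; breakpoint-resolution rearrangements
  (split-read or assembly evidence) are out of scope.
* Consequence annotation is CDS-codon level only — no splice sites,
  UTR classes, or protein-level effects.
* The percentile bootstrap undercovers slightly for very sparse lines
  (few expected events per line); with study-scale event densities its
  empirical coverage of the 95% interval is ~93–95%.
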