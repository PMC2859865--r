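---
title: "CNV and common deletion polymorphism discovery from SNP-array intensities"
author: "bovicnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV and common deletion polymorphism discovery from SNP-array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovicnv)
```

## The problem

Cohort-scale SNP genotyping arrays report two normalized signals per marker
and sample: the log R ratio (LRR), a log2-scaled total intensity that drops
under deletions and rises under duplications, and the B allele frequency
(BAF), an allelic intensity ratio in [0, 1] whose cluster structure changes
with copy number. `bovicnv` implements a complete discovery pipeline for
livestock cohorts genotyped on such arrays - the motivating design is a
bovine half-sib cohort (248 steers from 17 sires, 265 animals, 54,001
markers on 29 autosomes at ~51.5 kb mean spacing):

1. per-sample CNV segments from LRR/BAF (`call_cnvs()`);
2. population CNV regions (CNVRs) with frequency and gain/loss class
   (`build_cnvrs()`, `summarize_callset()`);
3. common deletion polymorphisms at marker scale, found two independent
   ways - parent-child Mendelian inconsistency (`pc_error_frequencies()`)
   and pairwise intensity-ratio scanning (`pairwise_scan()`) - and merged
   (`merge_methods()`);
4. copy-number validation from TaqMan qPCR replicates by the comparative CT
   method (`estimate_copy_numbers()`).

A synthetic-cohort generator (`simulate_cohort()`) provides
seed-reproducible inputs with a known copy-number truth table, so every
stage is testable without access to a proprietary cohort.

## Data model and coordinate conventions

Internal coordinates are 1-based marker positions as printed by genotyping
software. Interval lengths are reported as `end - start`, matching the
arithmetic of printed region coordinates (a region labelled
`chr15:1836732-2039483` has length 202,751 bp). On BED export the start is
shifted down by one, producing standard 0-based half-open records; the gene
reader inverts that shift. Two intervals overlap when they share at least
one position; a gene starting at the position after a region's end does not
overlap it. Missing LRR/BAF/R values are carried as `NA`, excluded from all
statistics, and never imputed.

## Sample quality control

`compute_sample_qc()` reports per-sample LRR noise and genotype call rate.
The LRR standard deviation is the population SD (dividing by *n*): the
choice is arbitrary at cohort sizes of interest but is fixed and documented
so tests can assert exact values. `filter_samples()` retains samples with
`sd_lrr` strictly below the threshold (default 0.30); the boundary value is
excluded. Whether that cut removes any animal depends on the data; the
synthetic generator's default noise (0.15) keeps event-free samples well
inside it, while samples carrying many null-copy markers can exceed it -
which is why recovery statistics downstream are scored over the samples
that actually entered the caller.

## The CNV caller

`call_cnvs()` decodes, per sample and chromosome, a four-state hidden
Markov model over copy states 0 (homozygous deletion), 1 (hemizygous
deletion), 2 (diploid), 3 (single-copy gain). It is a deliberately compact,
fully documented caller in the PennCNV tradition (Gaussian LRR emissions,
BAF mixtures, distance-dependent transitions), not a reimplementation of
any trained model; the pipeline around it consumes calls and does not care
which caller produced them, and `compare_callsets()` exists precisely to
quantify agreement between two call sets (fraction of calls in one set
overlapped by the other, same sample and chromosome).

Emissions. LRR follows a Gaussian per state with means (-3.0, -0.66, 0.0,
+0.40) log2 units and a shared SD (default 0.20). The means are the
conventional SNP-array signal model values; no claim is made that they are
fitted to any particular chip, and both the caller and the generator take
them as configuration. BAF uses a mixture over the state's allelic
clusters - state 2 at {0, 1/2, 1}, state 1 at {0, 1}, state 3 at {0, 1/3,
2/3, 1}, state 0 uniform - weighted binomially by the population frequency
of the B allele (`pfb`, default 0.5, config-suppliable per marker), with
cluster SD 0.05 and a 1% uniform outlier mass. Missing observations
contribute nothing to the likelihood.

Transitions. The probability of leaving the diploid state across a gap of
`g` bp is `p0 * exp(-g / d0)` (defaults `p0 = 0.01`, `d0 = 100 kb`), split
evenly over the three CNV states; a CNV state returns to diploid with
probability 0.2 per step (expected event length ~5 markers, matching
events of 50-250 kb at ~51.5 kb spacing) and switches directly to another
CNV state with probability 1e-4. Exact log-likelihood ties in the Viterbi
recursion resolve to the lowest copy state, making decoding deterministic.
Maximal runs of a constant non-diploid state with at least `min_markers`
markers (default 3, common practice for array callers) become calls whose
boundaries are the first and last marker positions of the run - so a call
can never span a chromosome boundary, and boundary precision is limited to
one marker by construction. The state-4 (double gain) class is accepted in
the data model but never emitted: distinguishing 3 from 4 copies at these
signal separations is unreliable, so the decoder uses a 3-copy gain
ceiling.

The decoder is verified two ways: against exhaustive maximization over all
`4^n` state sequences on chromosomes of up to 12 markers, and by recovery
of embedded events on synthetic cohorts (at default noise, at least 90% of
events spanning 5 or more markers must be recovered with the correct
gain/loss direction).

## CNV regions and cohort summaries

`build_cnvrs()` groups calls on a chromosome by transitive closure of
pairwise overlap and spans each group from the smallest member start to the
largest member end. The implementation rests on `IRanges::reduce()` with
`min.gapwidth = 0` (merge only on shared positions, never across abutting
ends); the test suite checks it against an independent brute-force
connected-components oracle on random call sets, plus idempotence and
partition properties.

`cnvr_frequency()` divides the member-call count by the cohort size. The
numerator is the call count, not the distinct-carrier count (a sample
called twice in one region counts twice); distinct-carrier counting is
available via `distinct_carriers = TRUE` but is not the reporting default,
because published common-region tables of this design are consistent with
call counting. Frequency thresholds in `summarize_callset()` are strict
(`> 1%`, `> 2.5%`, `> 5%`), and threshold counts are therefore monotone
non-increasing. `classify_type()` labels a region `gain_only`, `loss_only`
or `mixed` from its members' states. `annotate_genes()` lists genes
overlapping the region span by at least one position, deduplicated.
`summarize_callset()` rounds per-sample means, sizes (kb) and the
loss/gain ratio to one decimal for reporting, and reports an undefined
(`NA`) ratio instead of failing when there are no gains.

## Common deletion polymorphisms

A deletion segregating at a marker leaves three fingerprints in array data:
Mendelian-impossible parent-child genotype pairs, Hardy-Weinberg deviation,
and elevated missingness. The package uses the first as the primary screen
and exposes the other two (`marker_hwe_chi2()`, `marker_missing_rate()`) as
ancillary flags only.

Mendelian screen. For a biallelic marker in a parent-child duo (no second
parent genotyped), the only impossible configuration is opposite
homozygotes: `AA` vs `BB`. A hemizygous genotype is called as the
homozygote of its remaining allele, so a deletion transmitted from a `B/-`
sire to a steer that pairs it with a population A allele yields exactly
this signature. `pc_error_frequencies()` counts such errors per marker over
informative duos (both called); `pair_concordance()` provides the duo-level
QC view used to confirm pedigree relationships before screening (cohorts of
this design show duo concordance of 99.6% or higher).
`select_candidates()` applies a strict `> 3%` error-frequency threshold by
default; the inclusive `>=` variant is available via `strict = FALSE`
because both phrasings circulate for this screen, and strictness only
matters at the exact boundary.

Six-genotype confirmation. Visual genoplot inspection of candidates is
automated by `classify_six_genotypes()`: samples are split by BAF (A side
below 0.15, B side above 0.85) and by total-intensity tier relative to the
median R of diploid homozygotes - null below `0.15 m`, hemizygous in
`[0.15 m, 0.70 m)`, diploid above. The diploid reference `m` is seeded from
the upper decile of R, not the median: at a common deletion the hemizygous
cluster can hold the majority of samples, and a median anchor would slide
onto it. The classifier returns the six genotypes `AA`, `AB`, `BB`, `A/-`,
`B/-`, `-/-` and a `cluster_evidence` flag that is true when at least three
hemizygous samples sit at a BAF extreme - the six-cluster pattern a
genoplot would show. All thresholds are exposed in `sixgeno_params()` and
are validated only on synthetic data. Markers with fewer than 10 usable
samples return a missing classification. A mid-BAF sample at hemizygous
intensity has no single-allele explanation and is called `AB`.

Pairwise scan. `pairwise_scan()` screens `log2(R_target / R_reference)`
against a threshold of 1.5 (inclusive), with the reference chosen as the
QC-passing sample with the lowest LRR noise (`choose_reference_sample()`;
one reference is used, the minimal choice consistent with a "high-quality
reference" requirement). Under the package's linear intensity model a
hemizygous sample sits near ratio -1 and does not cross -1.5; homozygous
(null) carriers at near-zero R do, so the pairwise route discovers markers
through their null-copy individuals. Gain-side hits are recorded and
labelled but excluded from the deletion catalogue
(`pairwise_deletion_markers()`).

`merge_methods()` takes the union of the two catalogues with provenance
flags; the union size obeys inclusion-exclusion exactly, which the tests
assert on randomized inputs.

## qPCR quantification

`delta_ct()` subtracts the internal-control CT from the target CT per
replicate and averages the three differences (identical to differencing
replicate means at equal replicate counts; the per-replicate form is used
for clarity). `copy_number()` applies the comparative CT method against a
designated two-copy calibrator sample: `ddCT = dCT_sample -
dCT_calibrator`, `copy = 2 * 2^(-ddCT)`. The calibrator is an explicit
argument rather than an inferred sample, and should be validated against
expected class 2. Estimates are strictly decreasing in ddCT, halve per
cycle exactly, and are invariant to constant CT shifts; rounding to the
nearest integer gives the copy class compared by
`concordance_with_expected()`.

## The synthetic cohort generator

`sim_config()` defaults encode the motivating study design: 17 sires, 248
steers assigned round-robin (the cohort size is not divisible by the sire
count, so a per-sire count is only available as a convenience argument), 29
autosomes of 120 Mb, 54,001 markers with exponential inter-marker gaps of
mean 51.5 kb - right-skewed, so the median spacing falls below the mean, as
on the real chip. Tests and the acceptance script run scaled-down
configurations (typically 2 chromosomes, 400 markers, 100 animals) chosen
so that every stage still sees hundreds of informative observations; the
scale is a package choice and all knobs remain available.

Genotypes. Per-marker B allele frequencies are uniform on [0.05, 0.95];
sires are Hardy-Weinberg draws, steers inherit one sire haplotype plus an
independent population haplotype standing in for the ungenotyped dam.
Embedded events are copy-number alleles at a configured haplotype
frequency: deletion alleles make carriers hemizygous (homozygous carriers
null), duplication alleles add one copy (homozygous duplication is
collapsed to the single-gain state, the decoder's ceiling). For inherited
events the transmitted-haplotype choice is drawn once per event so the
deletion stays contiguous in the steer. Hemizygous genotypes are reported
as remaining-allele homozygotes; null samples as `NC` by default (the
alternative `random_hom` is available because genotype callers differ
here). A baseline miscall rate (0.001) and no-call rate (0.0043, matching a
99.57%-style call rate) apply on top.

Intensities. LRR is Gaussian around the per-state means above with default
noise SD 0.15; BAF clusters at the true allelic ratio with SD 0.03 (uniform
for null samples, clipped to [0, 1]); total intensity R is linear in copy
number around a diploid mean of 2.0 with SD 0.10, with null samples near a
residual 0.05. These noise levels are calibration knobs for testing, not
claims about any instrument.

qPCR. `simulate_qpcr()` produces three target and three internal-control
CT replicates per sample with `CT_target = base - log2(copy/2) + noise`;
zero-copy samples are reported at a CT ceiling of 40 (non-amplification).

What the generator does not emulate: linkage disequilibrium between
markers, sex chromosomes, genotype calling from raw theta/R, wave
artefacts, batch effects, or real gene content (annotation is
user-supplied). Passing tests therefore demonstrate internal correctness
of the algorithms under a clean signal model, not performance on any real
cohort.

Determinism: every generator entry point reseeds from `config$seed` plus a
fixed per-stage offset, so identical configurations produce byte-identical
outputs regardless of call order, and per-marker transmission draws agree
with the exhaustive-enumeration oracle used in the tests (each marker's
parent-child error count must fall within three binomial standard errors
of its enumerated expectation).

## Numerical and degenerate-input choices

- Viterbi ties resolve to the lowest copy state; `which.max` order encodes
  this.
- Zero informative duos at a marker yield a missing error frequency, not
  zero; an all-`NC` marker yields a missing rate of 1.
- A monomorphic marker has no HWE test (missing p-value).
- An empty call set summarizes to zeros with an undefined loss/gain ratio.
- `filter_calls()` with zero minima is the identity; negative minima are
  rejected.
- Zero-length intervals (`start == end`) have length 0 and form their own
  region.

## Known limitations

The caller's boundary precision is one marker; small events (< 3 markers)
are invisible at the default `min_markers`. The six-genotype classifier
assumes the upper decile of R at a marker is diploid, which fails for
deletions above roughly 90% carrier frequency and for markers inside
common duplications. The pairwise scan at threshold 1.5 cannot see purely
hemizygous deletion polymorphisms under a linear intensity model; its
power comes from null-copy carriers. The Mendelian screen's sensitivity
depends on allele frequency (opposite homozygotes require the right
parental configurations), so rarer deletions and extreme allele
frequencies reduce it - the direction, though not the exact rates, of what
frequency-stratified screens report on real cohorts.
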