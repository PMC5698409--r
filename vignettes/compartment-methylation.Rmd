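---
title: "Chromatin compartments and DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin compartments and DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartmeth)
library(dplyr)
```

`compartmeth` implements an integrative analysis of genome architecture and
DNA methylation during cell differentiation: A/B compartment inference from
binned Hi-C contact maps, TAD insulation scoring, CpG methylome
segmentation, threshold-based differential methylation calling, and the
statistics that relate the two data types. Because the scientific claim the
pipeline supports is one of *chronology* — compartments form first,
methylation signatures follow and are constrained by them — the package
ships a synthetic multi-stage cohort generator with complete planted ground
truth, so every stage of the pipeline is testable end to end without any
external data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic cohort does and
does not emulate. It states no empirical result that the package's tests
and acceptance script do not themselves compute.

## Coordinate frame and tracks

All coordinates are 0-based half-open (BED convention), internally and in
every text format read or written. A `cm_genome()` fixes the chromosome
order; `cm_bins()` tiles it with fixed-width bins (default 40 kb, the
resolution at which A/B patterns are called). Terminal bins shorter than
the bin width are retained — so bin index and coordinate remain a
bijection — but flagged, and compartment PCA masks them. Missing data is
always an explicit `NA` mask, never a sentinel: zero is a legal eigenvector
or methylation value.

## Contact matrices: ICE balancing and O/E correlation

`ice_balance()` performs per-chromosome iterative proportional fitting.
Bins whose raw coverage is zero, or falls below the 2% quantile of nonzero
row sums, are masked first; this quantile is an automated, reproducible
analogue of the per-dataset manual coverage thresholds such balancing
tools usually take and is exposed as `low_coverage_quantile`. Iteration
stops when every unmasked row sum is within `tol` (default 1e-5, relative)
of the mean row sum, or after `max_iter` (200) rounds with a warning. The
fixed point of iterative correction is unique up to scale for positive
matrices, which is why the test suite can compare it against a naive
alternating row/column normalization run to convergence.

`expected_by_distance()` gives the distance-decay background e(d) (mean
balanced contact at bin distance d), and `oe_correlation()` the Pearson
correlation matrix of observed/expected rows. The O/E diagonal is excluded
from the correlation computation because self-contacts dominate the
variance; analysis is intra-chromosomal only, and inter-chromosomal
records are dropped at load time with a message.

## Compartment calling

Per chromosome, `call_compartments()` takes the leading eigenvectors of
the O/E correlation matrix. Among the first three components it selects
the one with the largest absolute correlation with an activity track
(expression, gene density, or any active-chromatin proxy) and orients it
so that correlation is non-negative; A is positive, B negative, and an
exactly-zero value stays unassigned, since the sign rule leaves zero
undefined. The selection step replaces the manual curation that
per-dataset analyses apply when a later principal component carries the
compartment checkerboard on some chromosome: a fixed, logged rule is
reproducible where manual inspection is not. The chosen component and its
activity correlation are recorded per chromosome; a correlation below 0.2
flags the chromosome as unreliable (the no-signal control in the test
suite exercises this).

The eigenvector is scaled by the square root of its eigenvalue so that
magnitudes are comparable across chromosomes. Whether reference
implementations report eigenvalue-scaled values is tool-dependent, so the
scaling is a constructor argument (`scale_eigen`). For the differential
rule below, tracks are additionally variance-standardized per chromosome
by default (`standardize = TRUE` in `differential_compartments()`): the
conventional per-bin threshold of 1 presumes a particular eigenvector
scale, and a declared standardization makes that threshold meaningful on
any input. Both switches are exposed because the choice is genuinely open.

`differential_compartments()` implements the printed rule exactly: a bin
qualifies when the two samples' values have opposite signs and differ by
at least `delta = 1`; a region needs at least `min_bins = 2` consecutive
qualifying bins, and runs of mixed direction are split at direction
changes. `common_compartments()` labels bins positive in every stage
common-A, negative in every stage common-B, any masked/zero bin
unassigned, and everything else dynamic. `pc1_correlation()` compares two
tracks genome-wide after optional rebinning (mean of unmasked constituent
bins; a coarse bin more than half masked is masked) — 40 kb for
cross-genotype comparisons, 500 kb for biological replicates.

## TAD insulation

`tad_score()` computes, for window depths from 300 kb to 3 Mb in 300-kb
steps, the mean balanced contact in the diamond spanning the `w` bins on
either side of each inter-bin junction, z-transforms each per-scale
profile per chromosome, and averages across scales. The printed depths
are not integer multiples of a 40-kb bin, so each depth is rounded to the
nearest whole bin count. The diamond uses the balanced matrix (matching
the tool family these parameters come from), configurably the O/E matrix.
Bins whose diamond does not fit at a scale are masked at that scale
rather than padded.

`find_boundaries()` keeps local minima with prominence of at least 0.5
z-units and greedily accepts them in order of ascending score subject to a
400-kb minimum pairwise distance. The prominence criterion replaces the
reference tool's unpublished significance machinery with a minimal,
documented rule; only the depth and distance parameters above are fixed
by convention.

## Methylome segmentation

CpG calls from the two strands of a CpG are combined at the
forward-strand position before any analysis. `segment_methylome()` then
works in three passes over coverage-filtered (>= 4) CpG levels:

1. **PMDs.** A two-state segmentation (ordered vs disordered) over levels
   discretized to low (< 0.3), mid (0.3–0.7) and high (> 0.7). Emission
   probabilities are fixed — ordered (0.35, 0.05, 0.60), disordered
   (0.15, 0.70, 0.15) with stay-probability 0.99 — encoding that ordered
   methylomes are bimodal (unmethylated regulatory elements, highly
   methylated background) while partially methylated domains sit in the
   disordered middle. Maximal disordered runs become PMD candidates;
   candidates shorter than 100 kb are discarded (they are reported in a
   `short_pmds` attribute for inspection, since such regions typically
   reflect partially demethylated gene bodies rather than true domains).
2. **UMRs/LMRs.** Outside PMDs, levels are smoothed with a running mean
   over 3 CpGs; maximal runs below 0.5 with at least 4 CpGs are
   hypomethylated segments, split at 30 CpGs into UMRs (long, CpG-rich,
   promoter-like) and LMRs (short, enhancer-like).
3. **FMRs.** Remaining stretches with mean level >= 0.85 and at least 5
   CpGs; anything else is `unclassified`.

The 100-kb PMD floor and the 85% FMR threshold are fixed conventions; the
smoothing window, the 0.5 cutoff, the 30-CpG UMR/LMR split and the 5-CpG
FMR minimum are this package's declared defaults, all configurable.
`bin_chh()` pools CHH counts into 1-kb bins (summed counts, not mean of
ratios) to compensate for the low per-site coverage of non-CpG
methylation.

## DMR calling

`call_dmrs()` is purely threshold-based, with no p-values: eligible CpGs
are covered at least 4-fold in both samples and differ by at least 10%;
a window of 5 consecutive eligible CpGs — uniform difference sign,
adjacent genomic gaps at most 1 kb — qualifies when its mean absolute
difference reaches 40%; overlapping qualifying windows merge into one
region spanning first to last CpG (end = last CpG + 1, half-open).
Reading "over five CpGs" as a sliding window with merging yields maximal
regions; a fixed partition would drop boundary-straddling DMRs. Sign
uniformity is enforced because hyper- and hypomethylated regions are
reported as distinct classes; gaps are genomic distances between adjacent
eligible CpGs, and ineligible CpGs in between do not reset them.
`dmr_oracle()` re-derives the same rule by explicit enumeration with no
shared code, and the test suite requires exact agreement on a thousand
randomized inputs.

## Integration statistics

`feature_compartment_fractions()` assigns each feature to A or B by
majority base overlap (> 50%; exact ties unassigned — the assignment rule
is not standardized anywhere, so it is declared here) and compares the
fraction of features in A with the genomic A fraction.
`signal_compartment_enrichment()` compares mean signal in A bins (or in
an arbitrary region set) with the genome-wide mean, optionally within a
context such as fully methylated regions. 1-kb signal bins map to the
40-kb compartment bin containing their start.

Significance for both comes from seeded circular-shift permutations
(default 1000): features or signal vectors are rotated along each
chromosome by independent random offsets, preserving spacing and
autocorrelation, and p = (1 + #{perm >= obs}) / (n + 1). A parametric
group test would understate the variance of autocorrelated genomic
tracks; the permutation substitute is declared rather than a
reconstruction of any particular published test, and the test suite
checks its calibration on label-free null data (p <= 0.05 in 5% ± 2% of
400 trials). `sample_pca()` embeds samples from jointly unmasked,
mean-centered per-bin or per-CpG profiles, with axis signs fixed by the
first sample.

## The synthetic cohort

`cohort_truth()` plants the ground truth; `generate_contacts()`,
`generate_methylome()` and `generate_activity()` draw data from it. The
defaults define the package's study conditions and are chosen once, at
desk scale:

* **Genome**: 2 chromosomes x 20 Mb, 40-kb bins (500 bins per
  chromosome), so the full pipeline runs in about a minute per sample.
* **Stages**: ES, progenitor, fetal, newborn, adult, plus an adult
  knockout that shares the adult compartment truth exactly (ablating de
  novo methylation does not reorganize compartments — that invariance is
  what the cross-genotype comparison must recover).
* **Compartments**: alternating A/B blocks of 30 bins (1.2 Mb). Two
  blocks per chromosome switch label (one A->B, one B->A) at the
  progenitor or fetal stage, giving 12.5% dynamic bins. Block edges
  coincide with TAD boundaries (every 15 bins, 600 kb), as compartment
  transitions do in mammalian genomes; an earlier draft that placed
  compartment switches mid-TAD produced insulation valleys at non-TAD
  positions, a geometry real chromatin does not show.
* **Contacts**: expected counts follow a multiplicative plaid model —
  distance decay (1+d)^-1, x(1+0.4) same-compartment, x(1-0.4) cross,
  x(1+1) within-TAD — sampled multinomially, 1e6 pairs per chromosome.
  The simplest generative model whose PCA-recoverable structure matches
  the observed checkerboard; more elaborate noise models would add
  untestable complexity.
* **Methylome**: CpG positions are laid down once (geometric spacing,
  mean 100 bp; ~200k CpGs per chromosome) and shared by all stages and
  genotypes, so per-CpG deltas need no matching logic. Coverage is
  Poisson with mean 12. Background levels are Beta draws with mean 0.88
  in A and 0.95 in B (inactive chromatin of undifferentiated cells is
  the more methylated); LMRs (mean 0.12) and UMRs (0.04) are planted in
  A blocks, PMDs (per-CpG Uniform(0.3, 0.7), "disordered") cover the
  central 70% of B blocks, and CHH methylation (12% in adult A
  compartments over a 0.4% genome-wide background) exists only in the
  adult samples, with zero methylated counts in the knockout.
* **Chronology**: methylation features and expression follow a
  compartment switch with a lag of one stage (`meth_lag`, configurable —
  the real lag is qualitative, "first apparent" one stage later, so it is
  a parameter rather than a fixed constant), and PMDs additionally exist
  only from the fetal stage onward. Together these give the package's
  chronology analyses their planted signal: B-compartment
  hypermethylation before differentiation, A-compartment
  hypermethylation after.
* **Planted DMRs**: 1.32-kb intervals in stable A blocks carrying a
  fixed 120-bp CpG grid (11 CpGs, so the 5-CpG/1-kb-gap rules are
  satisfiable by construction), level 0.92 in adult vs 0.18 in knockout.
  Two generator contracts make planted recovery exact rather than
  probabilistic: DMR CpGs draw coverage as 4 + Poisson so the coverage
  filter never removes them, and binomial draws inside DMRs are redrawn
  when the realized level strays more than 0.15 from the planted level.
  Outside planted DMRs the knockout carries the adult sample's counts
  unchanged, isolating the planted differential signal.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: read-level noise and mapping
artifacts, restriction-fragment geometry, copy-number and allelic
effects, CpG-island clustering (spacing is memoryless), biological
replicate variability beyond the sampling noise of counts, chromosome-
scale heterogeneity (all blocks are the same size), and background
adult-vs-knockout methylation drift outside planted DMRs. Recovery rates
on this cohort validate the *implementations*, not the discriminative
power of the thresholds on real tissue.

## Numerical choices and degenerate inputs

* Sub-seeds for every generator and permutation stream are derived
  deterministically from one global seed, so adding a consumer never
  perturbs the others' randomness; all derived seeds stay below 2^31.
* ICE: all-zero rows are masked, not errors; an all-masked chromosome is.
* PCA: a chromosome with fewer than 3 unmasked bins, or a degenerate
  correlation matrix, yields all-unassigned bins with a warning.
* Viterbi ties in the two-state segmentation resolve to the ordered
  state (`>=` comparisons), so a single ambiguous CpG cannot open a PMD.
* `find_boundaries()` breaks score ties by position order within the
  greedy pass; prominence at chromosome ends treats the end as a wall.
* Empty call sets, empty feature sets and single-stage cohorts error
  early with named messages rather than returning silent zeros.

## Pipeline and reproducibility

`run_pipeline()` chains generation, balancing, compartments, TADs,
methylome segmentation, DMRs and the integration tables under a single
validated configuration (`validate_config()`, flat `key = value` text;
unknown keys rejected, all violations reported at once). Outputs are
plain BED/bedGraph/TSV plus a JSON run log capturing parameters, derived
seeds, per-chromosome component selections and convergence diagnostics.
Two runs with the same configuration and seed are byte-identical; the
test suite asserts this, and `scripts/acceptance.R` recomputes the
headline quantities from scratch at the default cohort scale (2 x 20 Mb,
~1e6 contacts and ~2e5 CpGs per chromosome — sizes chosen so the full
recomputation stays comfortably interactive).

## Known limitations

* Only intra-chromosomal analysis; no inter-chromosomal compartment
  phasing, no sub-compartments, no loops, no nested TADs.
* The PMD segmentation is a fixed-emission two-state model, not a fitted
  HMM; its boundaries are CpG-resolution, not base-resolution.
* The DMR rule is deliberately non-statistical (no multiple-testing
  control); it reproduces a printed threshold rule, and its error rates
  on real data depend entirely on coverage.
* bigWig/BAM/.cool readers are out of scope; matrices and calls enter as
  plain text.
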