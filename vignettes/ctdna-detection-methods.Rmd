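---
title: "Detecting circulating tumor DNA in low-shedding cancers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circulating tumor DNA in low-shedding cancers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnalite)
```

## The problem

Renal tumors shed very little DNA into blood and urine: circulating tumor
DNA (ctDNA) is often present at parts-per-thousand allele fractions or
below, where single assays routinely miss it. ctdnalite implements, as one
tested toolkit, the complementary assays used to squeeze detection out of
such samples:

* **tMAD** — an untargeted copy-number burden score from shallow
  whole-genome sequencing (sWGS);
* **in-silico size selection** — re-analysis of the 90–150 bp fragment
  pool, where tumor-derived molecules are enriched;
* **arm-level aneuploidy z-scores** — a rapid screen comparing
  per-chromosome-arm read fractions against a healthy cohort;
* **a simplified tumor-fraction estimator** — a grid fit of segment log
  ratios to integer copy states;
* **INVAR-lite** — patient-specific targeted detection that aggregates
  weak mutant signal across many loci after UMI error suppression;
* **variant post-filters** — the call-level hygiene rules (population
  allele frequency, normal-adjacent tissue, FFPE context artifacts,
  replicate concordance, synonymous filtering);
* **fragmentomics triage** — a random-forest model on ten fragment-length
  features, used to decide which samples merit expensive targeted work;
* **multi-region heterogeneity analysis** — whether fluids represent every
  spatially distinct tumor region.

Every assay runs on output of the built-in synthetic cfDNA generator, so
the full pipeline is testable without access to patient sequencing data.

## The synthetic data generator

The generator is first-class, tested code, not a fixture. A
`genome_model` is a desk-scale stand-in for a reference genome: by default
two 50-Mb chromosomes tiled by 1-kb windows carrying a smoothly
autocorrelated GC track (AR(1), clipped to [0.3, 0.7]), a mappability
track, clustered blacklist regions (~1% of windows), and a centromere
position per chromosome. All bin widths used on real data (30 kb, 500 kb,
1 Mb) remain expressible.

A sample is a set of fragments. The expected coverage of a region
carrying `c` tumor copies at tumor fraction `tf` follows the standard
mixing law

$$E[\text{coverage}] \propto \frac{2(1-tf) + c \cdot tf}{2},$$

modulated by a linear GC acceptance bias
(`1 + (gc - 0.5) * strength`, clipped to [0.2, 1]) that the correction
step must undo. Fragment lengths come from a two-component model:
truncated log-normals on 20–700 bp parameterized by their modes (normal
167 bp; tumor 145 bp by default), with a multiplicative 10-bp comb
`1 + A cos(2πL/10)` below 150 bp emulating the nucleosomal cleavage
periodicity. The normal spread (sdlog 0.06) was set so that ~3.8% of a
healthy sample's fragments fall in 90–150 bp, the short-fragment
proportion reported for healthy plasma; the magnitude of the tumor mode
shift in renal cancer is not an established number, so it is an exposed
parameter rather than an assertion. Targeted sequencing is emulated at
molecule level: each original molecule gets a UMI and a read family
(configurable size distribution), with per-read base errors at 1% by
default — a typical raw substitution rate that leaves a realistic ~1e-5
background per consensus molecule after collapsing.

What the generator deliberately does **not** emulate: read-level base
sequences and alignment artifacts, sequencing-instrument error profiles,
library-preparation chemistry, and the long-range wave artifacts of real
coverage data. Tests passing on this generator therefore demonstrate that
the *statistics* behave as designed under their stated assumptions, not
that the pipeline is robust to every artifact of real libraries.

## tMAD

Fragments are assigned to equal-width bins by midpoint; counts are
corrected by GC decile (each bin divided by the median count of its GC
decile, rescaled by the overall median, then divided by mappability),
with blacklisted, short-terminal, and low-mappability (< 0.5) bins
excluded — this exclusion is the "trimming". Normalization takes
`log2(case/reference)` against a cohort-median reference (or a single
control), after scaling both to equal totals, and then median-centers the
profile. The centering matters: scaling by totals alone biases the
neutral level whenever a sizeable genome share is aberrant (a 30%
one-copy loss at tumor fraction 0.4 shifts neutral bins by +0.044),
whereas the median bin is neutral for any genome that is majority
copy-neutral — the usual convention in copy-number pipelines. Urine cell
pellets, which have no matched control material, use self-normalization
(each bin over the sample mean, mean-centered).

Segmentation is recursive binary splitting minimizing within-segment
squared error, accepting a change-point only when the gain exceeds
`penalty * sigma^2 * log(n)` with sigma estimated robustly from first
differences (MAD of lag-1 diffs / sqrt(2)). The default penalty
multiplier 3 was calibrated so a flat profile with per-bin noise around
0.05 stays unsegmented at least 95% of the time; a noiseless step is
recovered exactly. Any change-point method honoring the same contract
(e.g. CBS) could stand behind this interface.

The tMAD score is the median over analyzable bins of the absolute
*segmented* log ratio, measured from 0 rather than from the sample
median, so genome-wide shifts count as signal. Per-bin segmented values
and bin-weighted segment means give identical medians; we use per-bin
values. The detection threshold is the maximum score over a healthy
cohort (each control scored leave-one-out against the reference of the
others), and detection requires *strictly* exceeding it — under
exchangeability a held-out null sample is detected with probability
1/(n+1), which the acceptance suite verifies at n = 46 controls.

Because the score is a median, it responds to tumor fraction only when
aberrant segments reach the median bin. The canonical test architecture
(`rcc_like_scna()`) therefore places a one-copy loss over 60% of one
chromosome and a one-copy gain over 60% of the other — a balanced design
that keeps the genome-wide median anchored in the neutral 40% while a
majority of bins respond to tumor fraction, mirroring the paired
arm-level loss/gain pattern of renal cell carcinoma.

## Size selection

`size_select()` keeps fragments with length in [90, 150], inclusive at
both ends (documented so results are bit-stable). The re-analysis
pipeline downsamples the selected pool to 2 million reads, uses 500-kb
bins, and normalizes against a similarly selected and downsampled control
cohort; samples with fewer than 2 million post-selection reads are
ineligible and receive no score. The enrichment factor is the ratio of
the selected to the unselected tMAD score.

## Aneuploidy z-scores

Fragments are partitioned by the chromosome arm of their midpoint
(targeted amplicon chemistry is emulated as uniform sampling; arm
fractions are the sufficient statistic). Per-arm
`z = (f_case − mean(f_controls)) / sd(f_controls)` with the unbiased sd;
the genome-wide statistic is the sum of squared arm z-scores standardized
against its leave-one-out control distribution, with detection at z ≥ 3
(inclusive). No arms are excluded by default on synthetic genomes; an
exclusion list is exposed for real acrocentric arms. The calibration
suite uses an 8-chromosome genome: with very few arms the sum-of-squares
null is noticeably skewed and the z ≥ 3 tail probability is unstable,
whereas 16 arms bring it comfortably under the 2% false-positive budget.

## Tumor fraction

The estimator grids `t` over 0–0.95 in steps of 0.01; each segment takes
the integer copy state in {0..4} minimizing squared deviation from its
expected log ratio `log2((2(1−t)+ct)/2)`, and the bin-weighted total
error is minimized over `t`. The model is exactly degenerate — a one-copy
loss at `t` equals a homozygous loss at `t/2`, a one-copy gain equals a
two-copy gain at `t/2` — so the fit carries a small diploid-parsimony
penalty (`2e-4` per bin per squared copy-state deviation from 2) that
resolves every such tie toward the milder state and larger fraction,
analogous to the diploid-favoring priors of HMM-based tools. The penalty
also suppresses copy calls on segments within noise of zero; its cost is
that true homozygous deletions and high-level amplifications (not
modeled) would be absorbed into milder states. Remaining exact ties break
toward smaller `t`, so an all-neutral profile is assigned `t = 0`.
Estimates below 0.03 are reported ctDNA-negative; samples with fewer
than 2 million reads are additionally gated by the frequent-SCNA rescue
rule (a matching arm-level change — for RCC, 3p/8p loss or 3q/8q gain —
covering more than half its arm).

Subclonality, ploidy estimation, and the full HMM machinery of dedicated
tumor-fraction callers are out of scope; this estimator is the stated
simplification and is validated by parameter recovery (|t̂ − t| ≤ 0.02
across t ∈ {0.05, 0.1, 0.2, 0.4} at 2e6 fragments).

## INVAR-lite

Raw targeted reads are collapsed by (locus, UMI): families need at least
2 members and a base reaching at least 90% of members (both inclusive);
surviving families each contribute one consensus molecule. Background
error rates are pooled per trinucleotide-substitution class from control
pileups (classes below 10,000 consensus molecules fall back to the global
pooled rate); an error-free class is floored at half an error rather than
zero so likelihood ratios stay finite.

Per locus, significance is the exact binomial tail
`P(X ≥ m | d, e_ctx)`. The sample-level score profiles a single allele
fraction `f` over `{0} ∪` 61 log-spaced points in 1e-6–1e-1, maximizing
the weighted log-likelihood `Σ w_i log Binom(m_i; d_i, e_i + f)` with
weights proportional to tissue mutant allele fraction (normalized to mean
1), and reports the log-likelihood ratio against `f = 0`; ties break
toward smaller `f`, so signal-free samples score exactly 0. The detection
threshold comes from ROC analysis of non-matched controls (samples scored
against other patients' mutation lists); the default operating point is
the smallest score achieving the target specificity (0.99 by default,
1.0 — the control maximum — in the acceptance analyses). One practical
caution the tests encode: the samples used to *estimate* the background
must not also serve as ROC controls, because self-fitted error rates
deflate their scores and break exchangeability with future samples.

Sample-level accounting: informative reads IR = Σd; IR < 20,000 is a
technical failure (no call is made), and fewer than 100 loci triggers a
warning. The global allele fraction is the background-subtracted,
depth-weighted mean `gmAF = max(0, (Σm − Σd·e) / Σd)`.

## Variant filters

All rules read the source prose strictly: callable regions require
germline depth strictly above 20×; population allele frequency strictly
above 0.02 (whole-exome lists) or 0.01 (panel calls) removes a variant;
any positive allele fraction in any normal-adjacent tissue removes it;
FFPE call sets drop C>A calls preceded by C/T and G>T calls preceded by
G/A (the reverse-strand image), leaving all other calls and all
fresh-frozen samples untouched; panel calls must appear in both
duplicate replicates (reported AF = replicate mean) and survive the
synonymous filter. Every stage appends to a conservation-checked report
(input = removed + retained).

## Heterogeneity

The multi-region matrix holds samples (tumor regions, then fluids) by
mutations, with per-mutation region counts computed from tumor regions
only. A covered fluid locus with zero mutant reads is a true 0; an
uncovered one is missing and excluded from that fluid's statistics.
Mutations are clustered by Euclidean distance with complete linkage
(compact clusters for allele-fraction vectors; the linkage is exposed
since the reference analysis did not state one), rows left unordered. A
region is represented in a fluid when at least one of its called
mutations is detected there; because shared mutations cannot attribute
signal to a region, the same computation restricted to private mutations
is always reported alongside, and the headline 90%/100% pattern refers to
the private-mutation reading. The allele-fraction-versus-region-count
trend uses unpaired two-sided rank-sum tests of each group against the
private (count 1) group — the exact pairing behind the original
"Wilcoxon" label is not stated, so the unpaired reading is used and
labeled.

## Cohort statistics

Combined detection is a logical OR over in-scope (assay, fluid) records,
with technical failures excluded from numerator and denominator alike.
Fisher's exact test uses the conditional two-sided rule (sum of
hypergeometric probabilities no larger than the observed table's) — the
convention that reproduces the printed triage association p = 9.4e-3 on
the unique 2×2 table consistent with 91.7% vs 36.4% detection at the
implied group sizes, [[11,1],[4,7]]. The rank-sum comparison of tumor
sizes is exact for small untied samples.

## Problem sizes and numerical choices

The test and acceptance suites run entirely on synthetic cohorts sized
for a desk: 10-Mb two-chromosome genomes with 200-kb bins for null
calibration (46 controls at 6e4 fragments, 200–250 held-out replicates),
the 50-Mb genome with 500-kb bins and 2e6-fragment samples for dilution
and recovery checks, 12 synthetic patients × 50 loci × 500 molecules for
targeted calibration, and 100 loci × 1000 molecules for gmAF recovery.
GC-decile correction needs bins whose GC varies slowly relative to
segment length (as on real genomes); on very small genomes with coarse
bins the decile medians can absorb segment signal, which is why
recovery analyses use the 50-Mb geometry. Random-forest training uses
500 trees and a mandatory seed; all simulation entry points require
seeds, and per-sample seeds derive deterministically from a master seed.

## Known limitations

The tMAD median responds to tumor fraction only when aberrant segments
cover enough analyzable bins; focal-only genomes score near the control
floor. The tumor-fraction estimator cannot represent homozygous
deletions, amplifications beyond 4 copies, or subclonal states. The
INVAR-lite aggregate uses context and tissue-AF weighting but not the
fragment-length likelihood weighting of the full published framework
(size selection can be applied upstream instead). The synthetic control
cohorts share the generator's assumptions, so thresholds derived here
are not transferable to real data without a real control cohort.
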