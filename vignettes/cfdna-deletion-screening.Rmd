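---
title: "Bin-depth detection and origin classification of 22q11.2 deletions from maternal plasma cfDNA"
author: "cfDNA22q authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-depth detection and origin classification of 22q11.2 deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfDNA22q)
```

## The problem

Prenatal cfDNA screening reads a mixture of maternal and placental
("fetal") DNA fragments from maternal plasma. 22q11.2 deletion syndrome
(DiGeorge / velocardiofacial syndrome) is the commonest microdeletion
syndrome, mediated by non-allelic homologous recombination between four
low-copy-repeat blocks, LCR22 A–D: about 85% of patients carry the common
~2.5 Mb A–D deletion and the rest smaller nested events (A–B, C–D, ...).
Because the plasma is a mixture, a screen-positive result may reflect a
deletion in the fetus, in the mother, or in both; because nested deletions
may lie proximal or distal to the standard FISH probe targets, the choice
of confirmatory assay matters. This package implements the full analysis
chain — simulation, detection, sizing, origin classification, testing
advice, and cohort statistics — as reusable, tested code.

## The mixture model

Let $f$ be the fetal fraction and $c$ the fraction of plasma cfDNA
molecules carrying a heterozygous deletion:

$$c = \begin{cases} f & \text{fetal event (de novo or paternal)} \\
1 - f & \text{maternal, not transmitted} \\
1 & \text{maternal, transmitted} \end{cases}$$

A heterozygous deletion removes one of two copies in the carrying
fraction, so the expected binned depth inside the deleted interval is
$1 - c/2$ relative to the diploid baseline (`expectedDepthRatio()`).
Inverting, the *event-specific fraction* estimated from the mean depth
ratio $r$ over the called bins is $\varepsilon = 2(1 - r)$, clipped to
$[0,1]$, and the *mosaicism ratio* is $\mathrm{MR} = \varepsilon / f$.
Its analytic values (`analyticMr()`) are 1 for fetal events at any $f$,
$(1-f)/f$ for non-transmitted maternal deletions and $1/f$ for
transmitted ones. At the cohort-typical $f = 0.105$ a maternal
non-transmitted event sits near MR 8.5 while fetal events sit at 1, so a
cutoff of 3 separates the two regimes; the classification degrades
exactly where the model says it must — a non-transmitted maternal
deletion at $f > 0.25$ has MR below 3 and is labelled fetal, the
documented late-gestation failure mode. Ties at the cutoff resolve to
`suspected_fetal`, the conservative choice for fetal follow-up. An
optional secondary rule flags `likely_maternal` whenever
$\varepsilon > 0.5$, which no purely fetal event can produce.

The event-fraction estimator $\varepsilon = 2(1-r)$ is this package's
definition, consistent with heterozygous-deletion dosage; commercial
implementations do not publish theirs.

## Coordinates and the bin grid

The default `RegionModel` places a 3.55-Mb analysis window on chr22 tiled
by 71 bins of 50 kb, with representative GRCh37-derived LCR22 A–D and
probe coordinates rounded to the bin grid so that the canonical A–D
deletion spans exactly 51 bins (2.55 Mb, within one bin of the commonly
quoted 2.54 Mb). The coordinates are deliberately *representative*: the
analysis never depends on their absolute values, only on the relative
geometry (probes strictly between A and B; nested C–D events distal to
all probes), and they can be replaced from BED files
(`loadRegionModel()`). Intervals are held as `GRanges` (1-based closed);
BED I/O through `rtracklayer` keeps the on-disk 0-based half-open
convention bit-exact. Windows that are not whole multiples of the bin
width are padded upward, and the padding recorded in the model.

## The synthetic cohort

`simulateSample()` draws each bin count independently with mean
`meanDepth * (1 - o_b * c/2) * bias_b`, where $o_b$ is the fraction of
bin $b$ covered by the deletion (boundary bins are depressed
proportionally). Counts are Poisson by default; one `dispersion` knob
switches to a negative binomial (variance $\mu + \phi\mu^2$) — the
simplest noise family sufficient for testing MR and size recovery.
GC/mappability bias is *not* simulated; a per-bin multiplicative bias
hook exists, defaulting to all ones.

`simulateCohort()` emulates a screen-positive cohort: 57.7% of events
maternal, a 50% transmission probability for maternal carriers, a small
paternal-inheritance probability (0.01) among fetal events, deletion
classes weighted 85% A–D with the remainder nested (A–B 6%, C–D 5%, B–D
2%, sub-A–B 2%), and fetal fractions lognormal with median 0.1048
(sdlog 0.45, chosen to match a reported 3%–41% range), truncated to
[0.02, 0.45]. Ultrasound flags, diagnostic-testing dispositions, cardiac
and postnatal-deferral flags are drawn at the corresponding cohort rates.
Diagnostic completeness follows the clinical rules: testing the
individual who carries the event (or a positive fetal result under a
transmitted maternal deletion) is complete; normal results from the
wrong individual are incomplete and never imputed. Every simulated
screen positive carries a real deletion, so the generator produces no
false-positive screens — specificity is studied separately on null
profiles.

The per-origin deletion-size distribution is a modelling choice, not an
estimate; only size medians by origin are reported in the source cohort.

What passing tests on this generator do **not** show about real data:
robustness to GC/mappability structure, to fetal-fraction estimation
error (ff is treated as a known input), to twin pregnancies, or to the
genome-wide segmentation context of a production assay.

## The deterministic fixture

`cohortFixture()` reconstructs, case by case, the dispositions of a
published 307-case screen-positive cohort: 177 suspected maternal / 130
suspected fetal; 194 with diagnostic results (83 fetal-only, 76
maternal-only, 35 both), 17 incomplete, 177 complete with 176 true
positives and one false positive; 157 ultrasound-flagged (95 cardiac);
118 fetal/neonatal-tested (54 deferred postnatally); 25 of 43
suspected-maternal cases with fetal testing showing inheritance. Joint
distributions beyond these published marginals are an arbitrary
deterministic allocation, and the 113 untested cases carry confirmation
status `unknown`, never imputed. All printed percentages and the five
PPV scenarios derive from these marginals exactly.

## Detection and sizing

`buildReference()` scales each of ≥10 unaffected panel profiles to unit
mean and records per-bin means and standard deviations (floored at 1e-3
to keep z-scores finite). `scanRegion()` computes per-bin z-scores
$(r_b - 1)/s_b$ and minimises the aggregate $\sum z_b / \sqrt{n}$ over
every contiguous window of ≥2 bins — a likelihood-ratio scan for one
depleted segment, preferred over a fixed per-bin-threshold run rule
because weak wide events (a fetal deletion at $f \le 0.10$ depresses
each bin by under 1.6 standard deviations) never produce long runs of
individually significant bins. The candidate window is then refined to
the maximum-likelihood window for its estimated depression depth $d$
(maximum-sum subarray of $-z_b - d/(2 s_b)$), iterating depth and
boundaries to a fixed point; boundary bins enter the call exactly when
the likelihood supports them, which is what limits breakpoint
uncertainty to about a bin at moderate signal. Reported sizes are
bin-quantised (multiples of 0.05 Mb) — a 2.54 Mb truth is reported as
2.55 — and a margin of error is intrinsic to all size and breakpoint
estimates.

**Depth normalisation.** Two scalings are provided. Self-scaling fixes
the mean ratio over non-candidate bins at 1; with only ~20 bins outside
a common A–D deletion this adds substantial scale noise and makes weak
wide fetal events essentially undetectable — an information limit of
region-only data, not an implementation artifact. A production
genome-wide assay measures each sample's average depth from tens of
thousands of bins outside the region, with negligible error; the
`depthAnchor` argument supplies that external estimate and is used by
the pipeline and the evaluation experiments. Acceptance thresholds were
calibrated per mode on 2000 null simulations at depth 1000 to hold the
false-detection rate under 1%: aggregate z ≤ −4.5 anchored, ≤ −5
self-scaled. Both are tunable.

Degenerate inputs: an all-zero profile, mismatched bin grids, and panels
smaller than 10 raise errors; a zero-variance panel bin is floored with
a warning; an undetected call carries no interval, size or fraction.

## FISH advice

A probe is "detectable" with ≥1 bp overlap between the predicted
interval and the probe target — the source data give no overlap
threshold, and hybridisation efficiency or the mosaicism limits of FISH
are out of scope. Consequently any interval wholly between LCR C and D
is invisible to all three default probes, enlarging an interval can only
gain probes (monotonicity), and microarray is always recommended first;
FISH is listed only when every configured probe overlaps the call.
Maternal testing is advised for `likely_maternal` calls because a
confirmed maternal deletion implies a 50% fetal transmission risk.

## Cohort statistics

PPV among screen positives depends on how unverified cases are counted,
so five scenarios are computed (complete-testing, fetal-only,
conservative-with-incompletes-as-FP, and upper/lower bounds counting all
unverified cases as TP or FP); the ordering
lower ≤ conservative ≤ complete ≤ upper holds on any cohort.
Confidence intervals default to the Wilson score interval without
continuity correction; the continuity-corrected and Clopper–Pearson
variants are selectable, since the exact algorithm behind the source
cohort's printed intervals is not documented and none of the three
reproduces them digit-for-digit. Reported percentages round half-up to
one decimal, matching clinical-report formatting (base `round()` would
round half-even).

The Wilcoxon rank-sum test enumerates all group labelings of the pooled
values (midranks for ties) when the pooled size is ≤ 20, doubling the
smaller tail and capping at 1; larger samples use the normal
approximation with tie and continuity corrections via
`stats::wilcox.test`. Enumeration is implemented in-package because the
standard exact path does not handle ties. Fisher's exact p-value comes
from `stats::fisher.test`; the odds ratio defaults to the sample value
$ad/bc$ (Haldane–Anscombe 0.5 on zero cells), with the conditional-MLE
estimate available. Size concordance is ordinary least squares of
confirmed on estimated size.

## Problem sizes and reproducibility

The packaged evaluation experiments use a 50-sample reference panel at
1000 reads per bin, 500-sample cohorts for origin recovery
(ff ∈ [0.05, 0.20], the range over which MR separation is assured), 100
detectable calls for size recovery (ff ∈ [0.05, 0.30], the range the
round-trip recovery property targets), and 500 null samples for
specificity — sizes at which every Monte-Carlo check is stable across
seeds while the whole suite runs in minutes on a laptop. All simulation
entry points accept seeds; `runPipeline()` stamps every output with the
seed and a config hash and is byte-reproducible.

## Known limitations

- The fetal fraction is an input, never estimated from the counts.
- No GC/mappability correction; no genome-wide calling, aneuploidy
  detection, or read-level (FASTQ/BAM) simulation.
- The origin classifier implements the documented MR rule only; the
  production designation it emulates also weighed unpublished metrics
  and laboratory-director review.
- Cohort-level medians of MR and deletion size are emergent properties
  of the simulated mixture, not calibrated targets; per-case source data
  are unavailable.
- Fetal events near $f \approx 0.05$ at depth 1000 sit close to the
  detection limit; their breakpoint estimates are correspondingly noisy.
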