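---
title: "Paired tumour–metastasis copy-number analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired tumour–metastasis copy-number analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pairedCNA)
```

# The question and the data model

Array CGH measures, per oligonucleotide probe, the log2 ratio of tumour DNA
to a normal reference: 0 is copy-neutral, positive is gain, negative is
loss. Given one primary breast tumour and one lymph-node metastasis (LNM)
per patient, the package asks three questions of increasing resolution:

* do metastases *globally* resemble their matched tumours (clustering)?
* is there any genomic region whose copy number *recurrently* differs
  between metastases and tumours, overall or within a subtype (group
  permutation test)?
* per pair, which individual segments changed between tumour and metastasis,
  how many, and do any such changes recur across patients (delta profiles)?

All functions operate on a `probe_grid` (probe midpoints, 0-based half-open
genomic coordinates, probes treated as points) and probe-aligned log2
vectors; a `cn_cohort` bundles the grid, a probes × samples matrix and the
sample sheet.

# Kernel smoothing

Probe-level profiles are noisy and platform densities differ (the original
study mixed a 720 K and a 135 K design), so all sample-level comparisons run
on kernel-smoothed profiles: at evaluation point `g`,

    s(g) = sum_i w_i x_i / sum_i w_i,   w_i = exp(-(p_i - g)^2 / (2 sigma^2)),

computed per chromosome with the kernel truncated at 5σ. Two choices matter:

* **σ = 1 Mb** (default): the scale at which recurrent CNAs are expected to
  align across samples. Smaller σ under-smooths (the code warns when σ is
  below half the probe spacing); larger σ blurs focal events.
* **Normalized (Nadaraya–Watson) weights** rather than raw kernel sums.
  Raw convolution sums scale with local probe density, so 720 K and 135 K
  profiles would live on different scales; the normalized form is
  mean-preserving, keeps flat signal flat at chromosome edges without any
  padding, and makes profiles of different densities directly comparable.
  Constant profiles are reproduced to machine precision (the weights sum to
  1 only up to floating-point rounding).
* The evaluation mesh defaults to σ/4 (250 kb), a standard over-sampling of
  a Gaussian; smoothed values at neighbouring mesh points are strongly
  dependent by construction.

The signed signal is smoothed directly (gains and losses together): the
smoothed profile here feeds clustering and group differencing, not
single-group gain/loss significance calls, so separating the two signs
would only discard cancellation information the comparison needs.

# Clustering and concordance

Distance is `1 − Pearson r` between genome-wide concatenated smoothed
vectors (range 0–2), clustered with average linkage (UPGMA). "The metastasis
clusters with its tumour" is operationalized as strict nearest-neighbour
concordance on the distance matrix — the most reproducible reading — with a
dendrogram-sibling variant (`method = "dendrogram"`, cophenetic distances)
reported for comparison. Exact ties count as discordant, with a warning;
clustering contains no randomness.

# The paired permutation test

With smoothing being linear, smoothing then differencing equals differencing
then smoothing; the implementation smooths once per sample and works with
per-pair difference curves. The test statistic is `max_g |D(g)|`, the
genome-wide maximum of the mean paired difference curve, which controls the
familywise error over the whole genome: under the paired null each pair's
difference curve is sign-symmetric, so the null distribution is built by
independently flipping each pair's sign (equivalently, swapping
tumour/metastasis labels within pairs). With `n` pairs and `2^n ≤ n_perm`
the 2^n sign patterns are enumerated exhaustively; otherwise `n_perm`
Monte-Carlo draws are used (default 1000, α = 0.05). Significant regions
are maximal grid-point runs where `|D|` exceeds the (1−α) null quantile,
each with direction and a +1-corrected empirical p-value. An unpaired
label-permutation mode exists for designs without pairing; the paired
sign-flip is the default because samples arrive as tumour/LNM pairs.

# CBS with the 2-SD undo

The delta-profile segmentation engine is a circular binary segmentation:
for the current interval the arc `(i, j]` of the circularized probe sequence
maximizing the pooled-variance two-sample t-statistic (arc vs complement,
each at least `min_width = 2` probes, ties broken to the smallest indices)
is the candidate split; it is accepted when its permutation p-value —
shuffling probe values within the interval, default 1000 shuffles — falls
below `alpha_split = 0.01`, and recursion continues in the sub-intervals.
The permutation loop stops early once the +1-corrected p-value can no
longer fall below the threshold, which leaves every accept/reject decision
unchanged while making null intervals cheap. Exact split α and permutation
count are era-typical segmentation defaults; they are stated here as
assumptions, not published values.

After segmentation, breakpoints are *undone*: while any two adjacent
segments have means closer than `undo_sd = 2` noise SDs, the breakpoint with
the smallest gap is removed, the segments merged and their mean recomputed
from the probes, and the new configuration re-examined. The noise SD is the
MAD of first differences of the whole delta profile scaled by
`1.4826/sqrt(2)` — robust to true steps, and more stable than per-segment
SDs on short segments. Smallest-gap-first removal makes the (otherwise
unspecified) order deterministic. Note the rule's fixed point depends on
segment sizes: in a 0 / 0.15 / 0.30 chain at noise SD 0.1, equal-sized
segments end as two (the first merge moves the boundary mean 2.25 SD from
its neighbour) while a short leading segment cascades to one.

# Delta profiles

Each pair is quantile-normalized *pairwise* (rank-k values replaced by the
two samples' rank-k mean, ties averaged) before subtraction, because the
subtraction is per pair and normalizing across differently noisy
hybridizations would propagate noise between samples. Pairwise quantile
normalization has one visible consequence worth knowing: a private event
occupying the extreme tail of a sample's value distribution is attenuated
(its rank-k values are averaged with the partner's tail), so on a flat
background a 0.8 event re-emerges in the delta at roughly 0.5–0.6. With a
realistic shared clonal backbone the two distributions are nearly identical
and the distortion is negligible.

Delta segments count as real tumour/metastasis differences when
`|mean| > 0.2` log2 (and, for the filtered count, span ≥ 10 probes); segment
states in the individual normalized samples use the same ±0.2 cut. Counts
are compared between subtypes by a two-sided Wilcoxon rank-sum test (exact
for small tie-free groups, normal approximation with tie correction
otherwise; all-identical counts short-circuit to p = 1). The filtered count
is the primary test input, the unfiltered count is reported alongside.

Recurrence across patients: delta segments with `|mean| > 0.1` enter an
interval-overlap graph whose edges join segments of *different* patients
sharing ≥ 1 bp; groups are connected components (transitive chaining; a
pairwise-only mode exists), annotated with member directions and a
`consistent_direction` flag — all members changing the same way is the
signature of a driving alteration rather than random divergence. Under
transitive chaining the global intersection of member spans can be empty,
in which case the group interval is reported as `NA` rather than invented.

Pairs whose delta noise SD exceeds 3× the cohort median are flagged as poor
hybridizations and excluded from group statistics, mirroring how
non-resembling pairs are handled in practice.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes — nothing more:

* a clonal CNA backbone per patient (`K ~ Poisson`, TNBC mean 12 vs ER+
  mean 5, reflecting the subtypes' genomic instability), non-overlapping
  intervals with log-normal lengths (meanlog log(3 Mb), sdlog 0.8 — focal to
  medium events scaled to the desk-size genome) and signed Gaussian
  amplitudes (±0.6 ± 0.15, truncated away from 0.2);
* tumour and metastasis inherit the clone *exactly*; divergence enters only
  through explicit private focal events (LNM-private with probability 0.8
  per pair — a calibration reflecting that most pairs show some focal
  difference — tumour-private 0.3; spans 0.5–2 Mb, |log2| 0.3–0.8), which
  keeps ground truth unambiguous;
* i.i.d. Gaussian probe noise (default SD 0.15 log2), with an optional
  poor-hybridization flag multiplying one sample's noise SD by 6;
* optional biphasic first patient: the tumour is a two-clone mixture in
  linear copy space, `log2(f 2^a + (1-f) 2^b)` with f = 0.5, since DNA mixes
  linearly in copy number, and the metastasis derives from clone A alone;
* optional recurrent injection (same region, same sign in every metastasis)
  for power testing;
* one root seed with per-patient child streams, so adding patients never
  perturbs existing ones.

Default desk-scale genome: 3 chromosomes × 60 Mb at 25 kb spacing (7 200
probes, a ~100× downscale of a 720 K whole-genome design); tests and the
acceptance script mostly use 100 kb spacing (1 800 probes), which keeps the
permutation-heavy CBS runs in seconds while every event of interest still
spans ≥ 15 probes. The generator deliberately omits FFPE artefacts, GC
waves, probe-specific response and shared recurrent CNAs across patients;
noise is i.i.d. So passing tests demonstrate that the *procedures* recover
the structure they assume, not that they are robust to correlated
real-world noise — in particular, cross-patient profile correlations are
near zero here, whereas real breast tumours share recurrent aberrations.

# Numerical and degenerate-input conventions

* Probes with a non-finite value in any sample are dropped from all samples
  with a warning (pairwise analyses need identical grids).
* Chromosome names are opaque strings in natural order; sex chromosomes are
  not special-cased (the reference is female DNA).
* A constant (zero-variance) smoothed profile is a hard error in
  correlation distance, naming the sample.
* `noise_sd = 0` in the undo rule merges only identical-mean neighbours;
  a zero-variance interval never splits (statistic 0).
* Segment boundaries tile each chromosome at probe midpoints, extended by
  half the local spacing at the ends; SEG output is 1-based inclusive, BED
  0-based half-open.

# Known limitations

* The max-statistic familywise test is conservative for weak broad signals;
  a pointwise threshold is not the default anywhere.
* Pairwise quantile normalization attenuates extreme-tail private events on
  near-flat backgrounds (see above).
* The 2-SD undo removes genuine events weaker than `2 sqrt(2) noise_sd`
  in the delta — at probe noise 0.15 that is ~0.42 log2, so recovery
  guarantees are stated for events ≥ 0.4 log2 at probe noise ≤ 0.1.
* The i.i.d. noise model cannot reproduce discordant clustering of a
  poor-quality pair: 1 Mb smoothing suppresses independent probe noise by
  ~99%, so even a 6× noise sample stays far closer to its matched partner
  than to any unrelated sample. Real discordance of that kind arises from
  autocorrelated hybridization artefacts, which are out of scope here.
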