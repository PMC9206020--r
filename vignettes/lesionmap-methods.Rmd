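---
title: "Methods: lesion-symptom mapping and stretch-reflex threshold estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-symptom mapping and stretch-reflex threshold estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmap)
```

This vignette documents the statistical models the package implements,
the parameters that matter and why their defaults are what they are, the
numerical decisions taken where several choices were defensible, and what
the synthetic-data tests do and do not establish about behavior on real
patient data.

## The voxel model

VLSM treats each voxel independently. At voxel $v$, the cohort splits
into subjects lesioned at $v$ (group $L_v$, size $n_1$) and intact there
(group $I_v$, size $n_2$). The behavioral score is compared between the
groups with the Mann–Whitney statistic. Because clinical scores are
ordinal and heavily tied (the FMA-UL takes integer values on 0–66), the
package uses the tie-corrected normal approximation:

$$
U = R_1 - \frac{n_1(n_1+1)}{2}, \qquad
z = \frac{n_1 n_2/2 - U}
         {\sqrt{\dfrac{n_1 n_2}{12}\left[(N+1) -
          \dfrac{\sum_j (t_j^3 - t_j)}{N(N-1)}\right]}},
$$

where $R_1$ is the rank sum of the lesioned group and $t_j$ are tie-group
sizes. No continuity correction is applied, so $z$ approximates the
*mid-p* of the discrete permutation distribution rather than the
inclusive tail. The sign convention puts $z > 0$ when damage predicts
worse performance — lower FMA-UL, lower TSRT — and the reported p value
is the one-sided upper normal tail $\Phi(-z)$. One-sidedness is a
deliberate inferential choice: the mapping question is whether damage
*worsens* performance, and the package's threshold correspondence
($z \ge 2.09 \iff p \le 0.018$) is exactly the one-sided tail.

Accuracy of the approximation: by exhaustive enumeration, the rank-sum
statistic always matches the permutation distribution exactly, and on
untied data with both groups of size at least two the normal p is within
0.03 of the exact mid-p for total group sizes up to 10 (the worst
measured deviation is 0.023). With heavy ties at very small $n$ the
discrete distribution is too coarse for any continuous approximation;
cohort-scale analyses ($n = 41$) are far from that regime. When every
observation is identical across both groups the comparison carries no
information and the implementation returns $z = 0$, $p = 0.5$ rather than
an error, so degenerate voxels cannot masquerade as signal.

### Inclusion (coverage) rule

Only voxels lesioned in at least `coverage` (default 20%) of the cohort
are tested; the threshold is `floor(coverage * n)` subjects — the floor,
not rounding, because 8 of 41 subjects (19.5%) must qualify under a 20%
rule. A voxel additionally needs at least two intact subjects: the rank
test is degenerate against an empty or single-subject reference group.
This guard is unobservable on realistic coverage patterns (maximum
overlap sits far below $n - 1$) but makes the operation total.

### Multiple comparisons and the lenient threshold

Benjamini–Hochberg step-up FDR control is applied to the one-sided p
values of tested voxels only — untested voxels have no p values. The
realized cutoff (largest rejected p, smallest rejected z) is recorded in
the result. When a companion analysis is under-powered (the spasticity
map, with its much smaller effect extent), it is thresholded at the
*minimal FDR-surviving z of the reference analysis* — the same criterion
the reference just met, applied voxelwise without further correction.
A fixed threshold mode (`z = 2.09`, one-sided `p = 0.018`) is available
for strict replication. The derived mode is the pipeline default; if the
reference analysis itself has no FDR survivors the derived threshold is
$+\infty$ and all selections are empty, which is the correct null
behavior.

### Clusters and reporting

Significant voxels are grouped into connected components *after*
thresholding, and components below `min_cluster` (default 10) voxels are
dropped. Adjacency defaults to 26-connectivity (the common volumetric
convention where faces, edges and corners all connect) and can be set to
18 or 6; the choice is exposed because "adjacent" is genuinely ambiguous
and corner-touching blobs merge under 26 but not under 6. Each cluster is
reported at a single voxel: among voxels attaining the cluster maximum
$z$, ties are resolved by world coordinate — most superior (largest z),
then most posterior (smallest y), then most left (smallest x). The
centroid is deliberately not reported: it need not attain the maximum nor
even be significant. Coordinates are world mm through the grid affine
(left hemisphere at negative x), so tables read like standard template
coordinates.

### Conjunction

The conjunction classification applies one common per-voxel threshold to
both z maps and labels voxels A-only / B-only / both. No cluster rule is
applied here — a structure whose significant voxels are scattered below
cluster size can still contribute counts, which is why conjunction tables
can list structures absent from cluster-based tables. The per-structure
row filter keeps structures with at least `min_report` (default 10)
voxels *in at least one* of the three categories; a summed-count variant
is available (`rule = "sum"`) because the reporting convention can be
read either way.

## TSRT estimation

The tonic stretch reflex threshold model says the reflex fires when the
muscle is stretched past an angle that decreases linearly with stretch
velocity: $\theta^*(v) = \lambda + \mu v$ with $\mu < 0$. Each passive
stretch trial contributes one dynamic threshold — the (angle, velocity)
pair at reflex EMG onset — and the TSRT is the zero-velocity intercept
$\lambda$ of the least-squares line through those points. Intercepts
above the 180-degree biomechanical limit are returned unchanged with
`in_range = FALSE`: a threshold beyond the reachable range is the
signature of a non-spastic muscle, and clamping would destroy exactly the
information the measure exists to carry.

### Onset detection

The EMG is full-wave rectified and smoothed with a **causal** 5 ms
moving-average envelope. Two widths matter here and they must be
separated by an order of magnitude: the onset criterion requires the
envelope to remain `k_sd` (default 3) baseline SDs above the baseline
mean for `persist_ms` (default 25 ms), and a long envelope defeats that
criterion — a 20 ms envelope is autocorrelated over more than 25 ms, so a
single noise excursion can satisfy "persistence" on burst-free data. With
a 5 ms envelope the persistence window spans several independent
envelope samples and the false-positive rate on Gaussian baseline noise
is negligible, while a genuine burst still crosses within 1–2 samples.
The envelope is causal (trailing) so smoothing cannot raise the envelope
before the burst begins. Baseline statistics come from the 200 ms
immediately preceding stretch start, detected as the first sample where
the smoothed angular velocity exceeds 5 °/s; a zero baseline SD is a
degenerate recording and an error, not a zero threshold.

### Dynamic thresholds and exclusions

The angle at onset is read off the raw trace; the velocity is a centered
five-point finite difference on an angle trace smoothed with a 50 ms
moving average (goniometer noise differentiates badly; the smoothing
window is short against the slowest stretch). Trials are excluded, and
tallied, when (a) no onset satisfies persistence, (b) the velocity at
onset is not positive, or (c) the onset angle lies within
`early_margin_deg` (default 5°) of the starting angle. The last rule
deserves emphasis: with a negative velocity slope, a sufficiently fast
stretch can push the dynamic threshold to or below the starting position,
and a muscle that is active from the first stretched sample never
exhibits a threshold *crossing* — the measured angle would be the start
angle plus detection latency, a floor artifact, not a threshold. The same
exclusion catches incomplete relaxation. At least `min_trials` (default
5) usable trials are required; a two-point regression is formally defined
but clinically meaningless.

## The synthetic cohort generator

The generator's defaults encode the study conditions the pipeline is
meant for: 41 subjects, one lesion per subject grown by randomized
frontier expansion inside a single-hemisphere territory box (the
post-flip configuration of a middle-cerebral-artery cohort), volumes
drawn from a lognormal solved to mean 31.7 cc and SD 44.7 cc in cc units
(meanlog 2.909, sdlog 1.046) and clipped to 0.4–182.3 cc. Lesion seed
voxels are drawn from a Gaussian around a territory core (per-axis SD
3, 5, 4 voxels): single-territory strokes overlap heavily in the core,
and without that concentration no voxel reaches the 20% coverage floor at
$n = 41$.

Two critical regions are planted: region A (7×10×8 voxels at 4 mm,
driving the FMA-like score) and a smaller region B (5×8×7, driving the
TSRT-like angle) that overlaps A partially but is not contained in it, so
a conjunction has all three categories by construction. Scores follow
`baseline − effect × |lesion ∩ region| + N(0, noise)`, the FMA-like score
clipped to [0, 66]. Effects (0.45 and 0.52 score units per overlapping
voxel, noise SDs 6 and 10) were set once so the cohort means land near
the reference values (FMA ≈ 32.3, TSRT ≈ 107.4°) and the per-voxel
lesioned-vs-intact contrast is strong (several noise SDs); the resulting
cohort SDs are wider than the reference cohort's because a linear
overlap–deficit model with lognormal lesion volumes disperses more than
real scores do — a known, accepted divergence. Stretch trials are
constant-velocity ramps (bands 30–70, 90–140, 160–200 °/s, seven-ish
trials per band in randomized order) whose EMG burst begins when the
angle crosses the planted threshold perturbed by angle noise; the fast
band's upper edge was chosen so the cohort-mean planted threshold stays
measurably above the 40° starting angle at every protocol velocity.

What the generator does *not* emulate: vascular-territory geometry beyond
a bounding box, hemorrhagic versus ischemic morphology, registration
error, spatially correlated score noise, or spastic co-contraction in the
EMG. Passing the recovery tests therefore shows that the statistical
chain detects the assumed lesion–deficit model at realistic coverage and
noise — not that real lesions obey that model.

### Scale of the test problems

Cohorts are generated on a 40×48×40 grid at 4 mm isotropic (2 mm grids
are supported through `volume_grid`); at this resolution a full
41-subject pipeline run takes about half a second, which is what makes
the 10-cohort recovery and 100-cohort null-calibration suites routine.
The mapping mathematics is resolution-agnostic.

## Calibration properties the tests enforce

- Exact agreement of the rank statistic with exhaustive permutation
  enumeration for all group splits up to total size 10, ties included,
  and BH selections identical to a brute-force step-up oracle on random
  p maps.
- Type-I control: with lesion–score coupling switched off, the voxelwise
  p < 0.05 rate stays within binomial bounds of 5%, and the FDR selection
  is empty in the overwhelming majority of null cohorts.
- Recovery: lenient significance maps of the default cohort overlap their
  planted regions at Dice ≥ 0.5 across seeds, and the conjunction's
  shared category lands inside the planted overlap.
- TSRT: exact (1e-9) recovery of intercept and slope from noiseless
  thresholds; mean absolute intercept error below 1.5° over 500
  replicates at 3° angle noise with 20 trials.

## Known limitations

- Mass-univariate inference: no lesion-volume covariate, no multivariate
  or machine-learning mapping, no permutation-based FWE option.
- The lenient threshold is, by design, uncorrected voxelwise inference;
  maps produced under it are trends, not FDR-controlled findings.
- The rank test's normal approximation degrades for tied data at very
  small group sizes (see the voxel model section); the package does not
  switch to exact enumeration automatically.
- EMG preprocessing is the minimal standard chain (rectification plus
  moving average); no band-pass filtering or artifact rejection is
  implemented, and real recordings may need both upstream.
- Hemisphere flipping mirrors voxel indices about the grid mid-plane,
  which is exact on a shared symmetric template but is not a substitute
  for registration to a symmetric template upstream.
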