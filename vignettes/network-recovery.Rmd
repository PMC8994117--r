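---
title: "Quantifying functional-network normalization during language recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying functional-network normalization during language recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcRecovery)
```

## The analysis in one paragraph

`fcRecovery` quantifies whether a patient's resting-state functional
networks return toward the healthy-control distribution ("network
normalization") in step with behavioural recovery after surgery near
language cortex. The chain is: ROI time series → cleaning (nuisance
regression, band-pass, motion scrubbing) → pairwise Pearson correlation →
Fisher-z weights, thresholded at `r > 0.2` → three global graph properties
(connectivity strength, global efficiency, local efficiency) → Z-scores
against a control cohort → longitudinal recovery statistics (aphasia
quotient, good/poor classification, recovery ratios) → group-level
inference. A synthetic-cohort generator provides controls and longitudinal
patients with known ground truth, so the whole chain is testable without
imaging data.

## The generative model

Controls are draws from a stationary multivariate Gaussian AR(1) process.
The cross-sectional correlation matrix is block structured: 0.45 between
nodes of the same network, 0.08 between networks, unit diagonal. These
defaults put within-network edges comfortably above and between-network
edges below the `r > 0.2` analysis threshold, the regime the analysis
assumes; the AR(1) coefficient (default 0.3 at TR = 2 s) gives the slow
temporal autocorrelation typical of BOLD-like signal. The temporal model
is deliberately minimal: the innovation covariance is scaled by
`1 − φ²` so the stationary covariance equals the target exactly, making
Monte-Carlo verification of the generator a direct check
(empirical correlations within ±0.01 of target at 10⁵ volumes).

Each *observed* scan adds removable structure on top of the neural signal:

- a shared global artifact (unit-variance AR(1), loading 0.5) added to
  every node, measured by the `global` nuisance channel — this emulates a
  whole-brain global signal, which in practice is estimated from far more
  tissue than the analysis node set, and is what global-signal regression
  is meant to remove;
- `wm`/`csf` channels: independent AR(1) series with a 0.3 loading on the
  artifact;
- a six-parameter motion trace: translations follow a 0.01 mm/step random
  walk with (default 2) sustained 0.8 mm step events that exceed the
  0.5 mm framewise-displacement threshold, so each event is caught by
  scrubbing; rotations are held at zero. Scrubbing robustness to rotation
  spikes is exercised separately through the FD formula itself.

Patients are observed at up to five timepoints (`pre, w2, m1, m3, m6`).
At each post-operative timepoint the control covariance is attenuated by
`disruptionFrac × recoveryProfile[t]` on every edge incident to the
peritumoral node set — the first `tumourNodeFrac` (default 0.25) of the
left-hemisphere nodes of the first network, tumours being left-hemispheric
in this design — and to their contralateral homologues (same
within-hemisphere index on the other side, exploiting the hemispheric
symmetry of the node sets). The default recovery profile
`(pre = 0, w2 = 1, m1 = 0.5, m3 = 0, m6 = 0)` encodes full disruption at
two weeks, half remaining at one month, and full recovery in the chronic
phase — the modal trajectory of a good-recovery patient. Language scores
follow a noisy linear link: `AQ(t) = AQ₀ − 0.4 × attenuation(t) × 100 +
N(0, 2)`, clamped to [0, 100], with baseline AQ₀ ~ N(90.1, 9) matching the
pre-operative population. Subscores are back-solved proportionally
(`S = max_S × AQ/100`), which reproduces the composite formula exactly; no
claim is made about real subscore coupling, which the composite formula
does not constrain.

No effect-size estimates for post-surgical connectivity attenuation exist
to calibrate against; the defaults (disruption 0.5, link slope 0.4) are
chosen once to make subgroup separation detectable at realistic scan
lengths, not to match patient physiology. What passing tests show is that
the *pipeline* recovers what the generator planted — monotone Z-score
drops, normalization, behavioural classification — not that real fMRI has
these effect sizes. The generator also omits haemodynamic smoothing,
physiological noise spectra, scanner drift and lesion geometry; the
band-pass and regression stages are therefore validated on their frequency
and orthogonality contracts, not on realism of the input spectrum.

## Preprocessing conventions

Order is fixed: discard the first 10 volumes → nuisance regression →
band-pass → scrubbing. Scrubbed volumes are dropped, never interpolated.

- **Framewise displacement.** `FD(t) = Σ|Δd| + 50 mm × Σ|Δθ|`, the Power
  formulation; `FD(1) = 0`. The 50 mm sphere is the conventional
  rotation-to-arc conversion. FD is invariant to constant offsets in the
  motion parameters.
- **Scrubbing.** Volumes with FD > 0.5 mm are removed with one volume
  before and two after; windows overlap freely and clip at the series
  ends. Fewer than 140 survivors raises a classed error
  (`minimumVolumesError`) so callers can exclude the scan and continue —
  `runPipeline()` lists such scans and proceeds.
- **Nuisance design.** 9 base signals (6 motion + WM + CSF + global),
  their backward-difference derivatives (0 at the first volume, matching
  the censoring convention at the series start), and the squares of all
  18 — 36 columns. Without the global signal the whole column family goes:
  8 + 8 + 16 = 32 columns. An intercept is always added at fit time.
  Constant columns are dropped from the fit (they are collinear with the
  intercept; residuals are trivially orthogonal to them); genuinely
  rank-deficient designs fall back to the least-norm (pseudo-inverse)
  solution with a warning. Residual orthogonality is verified to
  `max|Xᵀe|/n < 1e−8`.
- **Band-pass.** Zero-phase (forward–backward) 4th-order Butterworth,
  0.01–0.1 Hz. The contract is stated in the frequency domain: a 0.05 Hz
  tone passes with ≥ 95% amplitude, a 0.2 Hz tone (twice the upper edge)
  is attenuated to ≤ 10%, and DC is annihilated. Band edges must be below
  the Nyquist frequency of the TR.

## Connectivity and graph-metric conventions

Correlations use all surviving volumes; zero-variance nodes get zero edges
with a warning rather than NaNs. Fisher `z = atanh(r)` is the default edge
weight (correlations of |r| = 1, which arise only in degenerate inputs,
are clamped to 1 − 1e−7). **Thresholding is always on r**, whatever the
weight semantics, with strict inequality `r > threshold` — so at the 0.2
default a 0.2000 correlation is removed and negative edges never survive.
Edge sets are therefore nested across the 0.1/0.2/0.3 variants, which the
tests assert on every matrix.

Efficiency metrics use the standard weighted convention, edge length
`ℓ = 1/w`:

- `gE` = mean over unordered pairs of `1/d(i, j)` (Dijkstra distances via
  igraph); disconnected pairs contribute 0; empty or single-node networks
  score 0.
- `lE` = mean over *all* nodes of the global efficiency of the subgraph
  induced by each node's neighbours (original weights kept, no
  centre-mediated rescaling); nodes with fewer than two neighbours
  contribute 0.

A binary reading of path length ("minimal number of edges") would conflict
with using weighted networks at all; the weighted convention is adopted
and is what the closed forms in the tests encode (complete equal-weight
graph: `gE = w`; triangle: `lE = w`; star: `lE = 0`). Implementations are
cross-checked against independent Floyd–Warshall and exhaustive
path-enumeration oracles to 1e−10 on all random graphs up to six nodes.

Z-scores use the control mean and n−1 SD; at least two controls with
non-zero spread are required. "Within the control envelope" is
operationalized as |Z| ≤ 3 throughout.

Hemisphere classes: L–L → `ipsi_left`, L–R → `interhemispheric`; a midline
endpoint counts as ipsilateral to the other endpoint's side, and
midline–midline edges are reported as their own class rather than forced
into either bin. The fair/moderate/strong bins ([0.2, 0.4), [0.4, 0.6),
[0.6, 1]) are a descriptive convention only — they are declared in the
edge-classification call and never enter the metrics.

## Recovery statistics

`AQ = (S_ss + S_com/23 + S_rep/10 + S_nam/10) × 2`, range [0, 100].
Classification: good recovery iff AQ(3 m) ≥ 0.80 × AQ(pre) or
AQ(6 m) ≥ 0.85 × AQ(pre); a missing timepoint skips its clause. On the
packaged 34-patient table, two patients (P044, P106) satisfy the stated
rule yet are listed as poor recoverers; the package reports these as
rule-vs-listing mismatches rather than silently adopting either label,
and grouped summaries follow the listed group.

The recovery ratio is `(chronic − subacute)/(pre − subacute)` with
subacute = the earliest post-operative observation (2 weeks if present,
else 1 month) and chronic = the latest available chronic observation.
This convention — rather than "prefer 3 months" — is the one that
reproduces all four published group-range endpoints on the packaged table
(1.17 and 0.49 for the good group, 0.13 and 0.68 for the poor group).
The ratio is capped at 1 (and flagged) in two degenerate situations:

1. no transient decline (denominator ≤ 1e−9);
2. the subacute score had already re-attained the 80%-of-baseline
   criterion and did not rise further (non-positive numerator) — the
   decline and recovery then both happened before the first post-operative
   measurement, and a raw ratio would be a small negative number with no
   recovery meaning. On the packaged table this applies to exactly the two
   patients whose language had recovered within one month (P204, P210).

Condition 2 deliberately does **not** fire for genuinely deteriorating
trajectories (chronic < subacute < 0.8 × pre), which keep their
uninformative negative ratio and are caught by the poor classification
instead.

Group inference uses the classical forms: paired t against baseline,
pooled-variance two-sample t (matching the df convention n₁ + n₂ − 2),
Pearson χ² without continuity correction, and partial correlation as the
correlation of covariate-residualized variables with `n − k − 2` df. No
multiple-testing correction is applied by default. Network recovery ratios
reuse the AQ ratio machinery verbatim on Z-score trajectories.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; identical
configuration + seed yields bit-identical cohorts, metrics tables and
report files, and matrices round-trip through the TSV writers bit-exactly
(17 significant digits). The test suite runs the parameter-recovery study
at the package's chosen demonstration scale — two toy networks of 10 and 8
nodes, 240 volumes, 20 controls, 50 seeds per disruption level
{0.2, 0.5, 0.8} — which cleanly separates the three levels (mean subacute
Z ≈ −1.1 / −2.8 / −4.7) while keeping the whole suite fast. A full
desk-scale run (26 controls, 34 patients × ≤5 timepoints, the 68-node
language network and 18-node control network at 240 volumes) completes in
well under five minutes on one CPU.

## Known limitations

- The packaged node sets carry the documented structure (language: 68
  nodes, 34 per hemisphere across nine gyral regions; CO 7 + FP 11; DMN 6;
  MEN 18) with *schematic* region labels and no coordinates; they are not
  a reproduction of any atlas parcellation. Supply your own node sets via
  `readNodesetJSON()` for real data.
- Voxel-level processing (segmentation, normalization, lesion masking,
  smoothing) is out of scope; the package starts at node-level time
  series. Lesion handling is limited to dropping excluded nodes from both
  patient and control matrices.
- The synthetic link between network integrity and language is linear by
  construction; it demonstrates pipeline sensitivity, not a physiological
  dose–response.
- No mixed-effects longitudinal modelling or survival analysis; the
  statistics are the classical tests described above.
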