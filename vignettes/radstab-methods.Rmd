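---
title: "How radstab measures inter-observer radiomic stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How radstab measures inter-observer radiomic stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

When several readers (or an automatic algorithm) segment the same pulmonary
nodule on CT, their regions of interest differ — inter-observer variation
(IOV). Radiomic features computed from those regions inherit that
disagreement. A feature is useful for downstream modelling only if it is
*stable*: its value should depend on the nodule, not on who drew the
contour. `radstab` quantifies this by simulating a full multi-observer
study end to end and measuring, per feature, the overall concordance
correlation coefficient (OCCC) across observers.

Because clinical CT cohorts of this kind are rarely shareable, the package
treats the synthetic study as a first-class component: phantoms stand in
for the CT data, simulated observer profiles stand in for readers, and
every downstream statistic is the same one a real study would compute.

## The phantom and observer model

A phantom is a sphere of diameter $d$ on a lung-like background
(default $-800$ HU) with additive Gaussian noise (default sd 20 HU), on a
$64{\times}64{\times}32$ grid at 1 mm isotropic spacing. Three density
classes follow the clinical taxonomy:

* **SN** (solid): uniform $+60$ HU;
* **pGGN** (pure ground-glass): uniform $-450$ HU — strictly between
  background and solid, so its boundary has roughly a quarter of the SN
  edge contrast;
* **pSN** (part-solid): a ground-glass shell (midpoint attenuation) around
  a solid core occupying `core_fraction` (default 0.5) of the radius.

The default cohort mirrors the emulated study: class mix
$81{:}40{:}111$ (SN:pSN:pGGN) over 232 nodules, diameters log-normal with
median 5.6 mm and IQR 4.0 mm (the closed-form fit
$\sigma = \operatorname{asinh}(\mathrm{IQR}/2m)/z_{0.75}$), truncated to
(2, 30) mm.

An **observer** perturbs the reference mask by thresholding its signed
Euclidean distance transform (negative inside, in mm) at a spatially
smooth Gaussian random field with mean `bias_mm`, sd `jitter_mm` and
correlation length `smoothness` (default 2 mm). This family was chosen
because it gives near-linear control of the boundary offset in physical
units and always produces closed regions. Zero bias and jitter reproduce
the reference bit for bit. A perturbation that would empty the mask is
retried with halved jitter (at most five times), mirroring the fact that
a reader never hands in an empty contour.

Two couplings make the simulation behave like the clinical observations
rather than like white noise:

* **Contrast.** The jitter is multiplied by
  $(\mathrm{CNR}_{SN}/\mathrm{CNR}_{class})^{1/4}$, where CNR is the edge
  contrast over noise (for pSN the segmented edge is the ground-glass
  shell). Ground-glass boundaries are therefore traced less consistently,
  which reproduces the pGGN < SN/pSN Dice ordering by construction.
* **Size.** The jitter stays in absolute millimetres, so the same boundary
  error costs a small nodule more overlap than a large one — this alone
  produces the positive diameter–Dice correlation. We deliberately did
  *not* scale jitter with nodule size: combined with the empty-mask retry
  rule (which nudges tiny masks back toward the reference) a size-scaled
  jitter inverts the coupling.

Observer panels are *calibrated*, not hand-tuned: each non-reference
profile carries a target mean Dice (defaults 0.75, 0.76, 0.80, 0.72,
0.66, 0.69 — six readers plus an automatic-algorithm stand-in, against an
exact reference reader), and `calibrate_profile_to_dice()` bisects on the
jitter until the mean Dice over 20 seeds, simulated against a solid
median-diameter phantom, is within ±0.02 of target. Calibration is valid
because expected Dice is monotone in jitter (a tested invariant). In the
mixed study the realised per-class medians shift with the difficulty
couplings above; that shift is the modelled effect, not calibration error.

## The feature catalogue

All 1,246 features are computed from scratch, with the standard
definitions, on 14 image types:

| image type | classes | count |
|---|---|---|
| original | first-order 18, shape 14, GLCM 24, GLRLM 16, GLSZM 16, GLDM 14 | 102 |
| 5 LoG scales | first-order + 4 texture families (88 each) | 440 |
| 8 wavelet sub-bands | first-order + 4 texture families (88 each) | 704 |

Key numerical choices (all configurable through `radstab_config()`):

* **Discretisation**: fixed bin width, default 25 HU, applied to the raw
  intensities of whichever image type is being analysed
  (`level = floor((x - min)/w) + 1`). Default intensity normalisation is
  *none* — Hounsfield units are already calibrated; `unit_range` and
  `zscore` are available.
* **LoG scales**: $\sigma \in \{1,\dots,5\}$ mm, spacing-aware, built as
  the sum of three separable second-derivative-of-Gaussian terms sampled
  from the closed form with an exact zero-DC correction, applied by FFT
  (periodic boundary). A constant volume maps to exactly zero; the impulse
  response matches the analytic kernel to better than $10^{-4}$ relative.
* **Wavelet**: single-level *undecimated* Coiflet-1 transform, periodic
  boundary, sub-band letters ordered (x, y, z). The adjoint filter bank
  reconstructs the input to $10^{-8}$, which is the tested guarantee that
  the eight sub-bands carry the complete signal.
* **Texture aggregation**: GLCM and GLRLM are computed for the 13 unique
  distance-1 directions, symmetrised (GLCM), normalised per direction,
  and feature values averaged with equal weight; GLSZM uses 26-connected
  zones; GLDM uses $\alpha = 0$ and 26-connectivity, with the dependence
  count stored at column `dependence + 1`.
* **Moments**: population ($1/n$) convention throughout (first-order
  variance/skewness/kurtosis and the CCC family), so the two-observer
  OCCC reduction is exact.
* **Degenerate ROIs**: single-level GLCMs fall back to Correlation 1,
  Imc1 0, Imc2 0, MCC 1; a single-voxel mask yields NaN
  skewness/kurtosis with a warning; any per-class failure inside
  `extract_all()` becomes NaN entries rather than an aborted study.

**Shape meshing.** The surface mesh is extracted by marching tetrahedra on
the Kuhn cube subdivision — watertight by construction — applied to the
zero level of the mask's signed Euclidean distance field, lightly smoothed
(Gaussian, 0.7 voxel) to remove the voxel-scale wiggle of the raw midpoint
surface. On a 10 mm digital sphere at 0.5 mm spacing this gives mesh
volume within 1.5% of $\pi d^3/6$ and sphericity 0.988; the raw midpoint
surface would inflate the area by 10–17%. Masks too thin to survive the
smoothing fall back to the raw field; masks with fewer than four
non-coplanar voxels get NaN mesh features with a warning. Axis lengths
are $4\sqrt{\lambda}$ of the physical voxel-coordinate covariance (note
this gives $4r/\sqrt{5} \approx 0.894\,d$ — not $d$ — for a uniform ball,
a property of the standard definition, frozen into the tests from the
closed form).

## Agreement statistics

* **Dice**: $2|A\cap B|/(|A|+|B|)$; two empty masks are an error, not 1.
* **Lin's CCC** and **OCCC** (the multi-observer generalisation):
  $\mathrm{OCCC} = 2\sum_{j<k} s_{jk} \big/ \big[(J-1)\sum_j s_j^2 +
  \sum_{j<k}(m_j-m_k)^2\big]$ with population moments. For $J=2$ this
  equals Lin's CCC to machine precision, and it equals the
  variance-weighted average of pairwise CCCs (both are tested identities).
  Mathematically the OCCC can be negative; negatives are reported as
  computed and classified as poor — we do not clamp to the nominal
  $[0, 1]$ range.
* **Stability classes**: poor $<0.5$, average $[0.5, 0.75)$, good
  $[0.75, 0.90)$, very good $\ge 0.90$; boundaries inclusive on the left.
* **ICC**: fixed to the two-way random-effects, absolute-agreement,
  single-measure flavour (ICC(2,1)) with the standard F-based interval,
  since no flavour is canonical for diameter-reproducibility reporting;
  this is stated prominently rather than made configurable.
* **Diameter**: on the axial slice with the largest in-plane extent (ties
  to the lowest slice), the mean of the maximal boundary distance and the
  maximal extent perpendicular to it, floored at one voxel, in cm.

## The study pipeline

`run_study()` runs generate → segment → extract → agree → OCCC →
classify → summarise, with the filtered images computed once per nodule
and shared across observers. The OCCC design matrix has nodules as rows
and observers as columns — one OCCC per feature per study — and is
recomputed within each density-class stratum for the subgroup comparison.
Group comparisons use Kruskal–Wallis with pairwise rank-sum post-hoc
tests under Bonferroni adjustment (the rank-sum choice keeps the
post-hoc test in the same nonparametric family). Every run is a pure
function of `master_seed`.

## What the tests do and do not show

The test suite checks: exact agreement of all four texture-matrix
families with independent brute-force counters; the analytic filter,
sphere, ellipse and nested-sphere oracles; the OCCC identities; the
zero-variation limit (identical observers ⇒ every computable feature
very good); monotonicity of stability in observer divergence across four
calibrated Dice levels (30 phantoms of 4–13 mm on $32^3$ grids, five
observers — sizes chosen so every sphere fits the grid); the nominal
5% size of the subgroup test under permuted labels (200 replicates); and
the density-class effect in a paired design (two studies sharing one
seed and diameter sequence, all-solid versus all-ground-glass, so that
the lower ground-glass stability is attributable to the contrast
coupling rather than to the diameter mix). In an unpaired study with a
few dozen nodules the per-class OCCC medians are dominated by which
diameters land in which stratum, so class orderings there should be
read as noisy.

The phantoms are homogeneous spheres: no spiculation, vascular
attachment, lobar anatomy or reconstruction-kernel texture, and observer
error is a stationary Gaussian field rather than anatomically informed
disagreement. Passing tests therefore demonstrate that the *measurement
chain* is correct and that stability responds to segmentation divergence
in the expected direction — not that any particular clinical stability
percentage generalises. Desk-scale synthetic cohorts (tens of nodules at
$\le 48^3$) also sit well below a clinical cohort in between-nodule
variance, which depresses absolute OCCC values relative to studies on
real data; the package reports its own percentages and never asserts
anyone else's.
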