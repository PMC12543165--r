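---
title: "Models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vesselleak` quantifies blood–brain-barrier (BBB) leakage vessel by vessel
from two-photon time-lapse stacks. This vignette documents the models the
package implements, the tunable parameters that matter, what the synthetic
phantoms emulate (and deliberately do not), and the numerical and design
choices made where the method left them open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The forward model behind the phantoms

All validation rests on synthetic worlds with known truth, because no
deposited in vivo data exist for this design.

**Geometry.** A phantom volume (default voxel size 2 × 0.692 × 0.692 µm,
mirroring a 25×/0.95 NA two-photon acquisition) contains, per class,
vertical 0th-order penetrating tubes with up to second-order branches,
plus randomly oriented capillary tubes. Diameters: order-0 ≥ 6 µm
(default 10 µm mean), capillaries < 6 µm (default 4 µm mean, matching the
capillary diameter rule used for classification). Capillaries are placed
with rejection sampling so lumens never interpenetrate the penetrating
trees — solid tubes cannot cross, and allowing crossings dices the
penetrating vessel's skeleton into unusable fragments. Geometry depends on
(seed, animal) but not condition, so paired condition contrasts share
vasculature. Every lumen voxel carries exactly one segment id (first
painted wins, deterministic).

**Kinetics.** The plasma input is a bi-exponential bolus
$C_{iv}(t) = A_{iv}\,(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$ with
$\tau_r = 0.1$ min and $\tau_d = 600$ min: an intravenous bolus circulates
within seconds, and the slow decay keeps the intravascular signal
near-flat over 60 min, consistent with intravascular traces being
experimentally indistinguishable across conditions. The perivascular
compartment of each segment obeys
$\dot C_p = K^{trans} C_{iv} - k_{out} C_p$, solved on the frame grid by an
exponential-integrator trapezoid step (exact for constant input at
$k_{out} = 0$; within 0.5 % of a 10-ms explicit integration otherwise —
asserted in the tests).

**Condition contrast.** The default Ktrans table elevates arterioles only
under "SE" (2×10⁻³ vs 10⁻⁴ min⁻¹ control) and venules only under "NI"
(1.6×10⁻³ min⁻¹), with per-animal (sdlog 0.15) and per-vessel (sdlog 0.35)
log-normal multipliers. These magnitudes put late-window fold changes near
1.3–1.5 for affected vessels and near 1 for controls, the range the method
is designed to resolve.

**Rendering.** Intravascular voxels carry $C_{iv}(t)$; the 0–15 µm rind
around each segment carries
$C_p(t)\,e^{-d/5\,\mu m} + 0.3\,C_{iv}(t)\,e^{-d/10\,\mu m}$, where $d$ is
the EDT distance to the lumen. The first term is the extravasated halo
(5 µm length constant, so perivascular means are dominated by the kinetic
model rather than geometry); the second is vessel-scatter bleed, which
gives perivascular traces the nonzero baseline every normalized index
needs. Frames are then PSF-blurred (1 µm FWHM), multiplied by a smooth
vignette field, and corrupted by additive Gaussian noise (detector-
dominated regime; σ = 2 intensity units per voxel against a 100-unit
plasma signal).

**What the phantoms do not emulate:** pulsatile hemodynamics,
photobleaching, tissue autofluorescence, motion, and nonlinear
fluorescence-to-concentration response. A green test therefore establishes
algorithmic correctness against the stated forward model, not robustness
to every in vivo artifact.

**Cohort scale.** Virtual cohorts default to 4 Control / 4 SE / 3 NI
animals (the study design) with 8/20/12
arterioles/capillaries/venules per animal — scaled down roughly fourfold
from real fields of view to keep the suite inside its runtime budget.
Cohort-level validation simulates traces directly (same kinetics, scatter
baseline, and frame noise, with per-vessel geometry weights) rather than
rendering 11 × 241-frame volumes; volumetric rendering, segmentation, and
trace extraction are exercised separately on small volumes by the pipeline
tests, and everything downstream of trace extraction runs identically on
both.

## 2. Preprocessing contracts

Rolling-ball background subtraction and flat-field normalization are
**refused on leakage-role stacks** unless explicitly overridden; both
distort the faint halos being quantified. The default pipeline passes
leakage frames through untouched (asserted by checksum). The rolling-ball
radius defaults to 25 µm — larger than any vessel radius, so foreground
tubes survive the opening. The flat-field is a 20 µm-FWHM-smoothed MIP
rescaled to mean 1, with optional pial-slice exclusion (apical pial vessels
otherwise dominate the projection). All convolutions use reflective
boundaries; boundary reflection slightly flattens the recovered field near
edges, which bounds the vignette-recovery correlation (~0.99 on dense
texture).

Registration is rigid (3 translations + 3 rotations about the volume
center), seeded by a coarse integer-translation sweep and refined by
Nelder-Mead on normalized cross-correlation of pre-smoothed volumes, with
trilinear resampling. Each frame registers to the structural stack
independently (no chaining, so errors do not accumulate). Recovery on
phantoms: ≤ 0.25 voxel for translations, ≤ 0.2° for in-plane rotations.

## 3. Skeletons, classification, shells

**Thinning.** The centerline is extracted by topology-preserving
directional thinning with three refinements that proved necessary (each
failure mode is pinned by a test): a deletable voxel must have foreground
behind it (otherwise a sequential pass sweeps one-voxel sheets and
even-width bundles to nothing); candidates are processed in increasing
EDT order (anchoring the curve to the medial ridge); and the erosion front
is gated by physical depth in steps of the smallest voxel size (per-layer
schedules erode the coarse 2-µm z axis three times faster than the
0.692-µm lateral axes and destroy short vertical vessels). Terminal spurs
shorter than 5 µm — stair-step artifacts of voxelized surfaces — are
pruned before graph conversion; genuine segments are tens of µm long.
Closed node-free cycles receive a synthetic node so the cycle rank
$|E| - |N| + |C|$ is exact.

**Diameters** are $2\times$ the anisotropy-aware EDT (physical units) at
each centerline voxel; segment means are step-length weighted. On digital
cylinders this recovers the true diameter within one in-plane voxel.

**Classification.** Within each seeded tree, the 0th-order vessel is the
thickest segment whose mean centerline direction is within 30° of z
("oriented vertically"; mean diameter is used for "thickest" — both
configurable). Orders propagate outward to 2; ordered segments inherit the
seed's arteriole/venule class. Tree connectivity is computed on the
≥ 6 µm subgraph: capillary bridges must not merge an arteriolar and a
venular tree (in tissue, arterioles and venules *are* connected through
capillary beds). Remaining segments: < 6 µm → capillary, ≥ 6 µm →
unlabeled (excluded from class-stratified statistics). Conflicting seed
classes on one tree raise an error.

**Perivascular shells** are the voxels with lumen distance in (5, 15] µm
(physical radii — "spherical" dilation read as isotropic in µm on the
anisotropic grid). Each shell voxel is owned by the segment containing its
nearest lumen voxel, via the exact EDT feature transform; exact-tie voxels
(a measure-zero set) resolve by the transform's deterministic scan order.
The inner margin excludes intravascular bleed and small lumen drift; the
outer bound limits cross-contamination between vessels.

## 4. Leakage indices

$F_0$ is the mean of 5 early frames **skipping the injection frame**:
frame 1 precedes bolus arrival, and folding it into the baseline inflates
every fold index (control ΔF/F₀ lands near 1.9 instead of near 1). ΔF/F₀
is implemented as the fold ratio $\mathrm{mean}(F)/F_0$ over 50–60 min —
not $(F - F_0)/F_0$ — because reported control values sit near 1 on that
convention. AUC integrates the *normalized* trace (unit-free across
animals; raw-intensity AUC available behind a flag). ΔF/Δt is the mean of
successive finite differences, which telescopes to
$(f_N - f_1)/(t_N - t_1)$ on a uniform grid; both forms are computed and
their equality asserted. Vessels with $F_0 \le 0$ or ROIs under 20 voxels
are excluded with a logged reason.

## 5. UMAP distance, clustering, diagnostics

The feature matrix contains baseline-normalized traces (fold units, not
z-scores: fold preserves the magnitude information the conventional
indices use, and a z-score alternative sits behind a flag). The embedding
is seeded, single-threaded uwot UMAP (Euclidean, `n_neighbors = 5`,
`min_dist = 0.4` — the cell that maximizes the mean Spearman correlation
between the UMAP distance and the conventional indices; `tune_umap()`
reproduces that selection on ladder cohorts).

The UMAP distance of vessel $i$ is the mean embedded Euclidean distance to
control-group reference vessels. Controls exclude themselves from their
own reference (including self-distance 0 would bias controls downward),
and class-stratified indices restrict the reference to same-class
controls. The index is invariant to rigid motions of the embedding.

ROC diagnostics operate **per animal** by default (vessel indices averaged
within animal before ranking): with 4 vs 7 animals, the attainable
p-values and the published style of ROC analysis are animal-level;
per-vessel mode exists behind a flag. ROC-AUC is the Mann–Whitney
$U/(n_1 n_2)$ with ties counted ½; p-values are exact (full enumeration)
for small groups, tie-corrected normal otherwise. The positive condition
is tested against all other animals pooled.

Two different validation worlds feed these operations, and the distinction
matters:

- *Correlation properties* use the severity-continuum ladder
  (`simulate_ktrans_ladder()`, five log-spaced Ktrans rungs, sdlog 0.3):
  rank correlations are only meaningful when leakage actually varies. On
  the disease cohort most vessels are exact control-level leakers whose
  index ranks are pure noise, and no embedding could correlate there
  (measured mean ρ ≈ 0.35, vs ≈ 0.94 on the ladder).
- *Cluster recovery* uses three distinct regimes (rungs 10⁻⁴, 1.5×10⁻³,
  6×10⁻³ min⁻¹, within-regime sdlog 0.15, fixed rendering geometry) and an
  `n_neighbors = 30` embedding. With the distance-tuned `n_neighbors = 5`
  the severe regime's filament shatters at roughly 40 % of seeds — an
  over-localization artifact of small neighborhoods, not a failure of
  regime recovery (at `n_neighbors = 30`, ARI = 1 at 10/10 seeds).
  k-means uses k-means++ seeding with 100 restarts; cluster labels are
  relabeled by ascending mean ΔF/F₀ so cluster 1 is always the
  least-leaky tier.

## 6. Velocimetry

Line scans are space–time images: rows are 0.5-ms lines, columns 0.144-µm
pixels; RBCs are dark streaks whose slope (px/line) times dx/dt is the
velocity, with a vertical streak meaning stationary. The simulator renders
super-Gaussian dips (flat 6-µm cell body, sharp edges): with soft Gaussian
shadows a 40-line window cannot resolve the angle of a single wide streak
(measured +18 % bias at 0.5 mm/s, vanishing with window height), and sharp
edges are the physically right model of a cell body.

Estimation per window: Sobel filtering along the space axis, then a
shear-projection Radon evaluated on a 0.5° angle grid — binning along
$c - s\,r$ with linear-interpolation weights keeps one-column bin widths
at every slope, where a rotation-grid Radon loses all resolution in
$\tan\theta$ above ~85° (arteriolar velocities) — followed by a local
slope-space refinement with parabolic peak interpolation.

Validity gating went through three designs; the final statistic is an
excess-variance z-score computed on the **raw** window at the estimated
slope: under independent pixel noise the weighted variance of projection
bin means scales as $\sigma^2 n_{bins}/n_{px}$ with χ² fluctuations, so
the standardized excess is ≈ N(0,1) for structureless windows at every
angle. (The same statistic on the Sobel image is invalid — Sobel output is
spatially correlated — and simple peak/median variance ratios do not
discriminate at all.) Measured separation: true streaks z ∈ [160, 430],
noise and single-line dash artifacts z ∈ [−4, 3.3]; the gate is z > 6.
Windows whose implied per-line displacement exceeds half the spatial
window are rejected as aliased, never reported.

## 7. Permeability

Patlak regression fits $F_{peri}/F_{iv}$ against
$\int_0^t F_{iv}\,d\tau / F_{iv}(t)$ from $t \ge 5$ min (post-bolus; the
plot is only linear once the input is quasi-steady). The slope is Ktrans,
the intercept the apparent blood-volume fraction; negative slopes are
flagged, not clipped. $k_{out} > 0$ violates Patlak's irreversibility
assumption — such fits report r² and the validation ladders use
$k_{out} = 0$.

Plasma flow $F_p = v \cdot \pi (d/2)^2 (1 - Hct)$ with Hct fixed at 0.45
is normalized by the segment's perivascular ROI volume (the distribution
volume the trace actually measures) and converted to min⁻¹ so it shares
units with Ktrans; both the fit window and the normalization volume are
configurable, and the extraction-limit and round-trip properties are
normalization-independent. The Renkin–Crone inversion
$PS = -F_p \log(1 - K^{trans}/F_p)$ satisfies $PS \ge K^{trans}$ and
$PS \to K^{trans}$ as $F_p \to \infty$; $K^{trans} \ge F_p$ is the
flow-limited regime where PS is undefined — an error, so such vessels are
flagged and excluded from summaries rather than silently extrapolated.

## 8. Histology

Local thresholding (Sauvola default, 25 µm window) carries a global Otsu
noise floor: a purely local threshold always "finds" structure in
noise-only regions (roughly half the pixels clear a local mean-based
threshold when no bright class exists in the window), which would wreck
area-fraction recovery at low leak levels. Perivascular rings are 15-µm
disk dilations minus the vessel mask; the vessel (AQP4) mask nulls
intravascular pixels before TRITC quantification. Vessel components are
α-SMA⁺ when their overlap fraction with the SMA mask exceeds 0.3
(configurable; the partition is exhaustive and disjoint). ZO-1 is the mean
intensity within CD31 ROIs, normalized per group to the control mean
(control ≡ 1 exactly).

## 9. Known limitations

- Tie-break for shell ownership follows the EDT feature transform's scan
  order, not "lower segment id" — the difference is confined to exactly
  equidistant voxels.
- The thinning end-retraction (~one radius per open tube end) shortens
  measured segment lengths slightly; diameters are unaffected.
- OME-TIFF I/O is replaced by a plain-text stack format (JSON header +
  CSV voxels): the target environment has no R TIFF reader. The read/write
  surface is format-shaped, so a TIFF backend can be swapped in.
- The Patlak normalization volume and fit window are field conventions,
  not uniquely determined; results depending on them should be reported
  with the configuration echoed by the pipeline manifest.
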