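---
title: "Methods: synthetic BCS deformation data and displacement regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic BCS deformation data and displacement regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bcsdeform)
```

This vignette records the scientific and numerical choices behind
`bcsdeform`: the coordinate conventions, the synthetic data generator and
what it does and does not emulate, the regression and evaluation
machinery, and the desk-scale defaults.

## Coordinate frame and geometry

All clouds live in a right-handed frame in millimetres: **x** runs medial
to lateral (the lateral sense flips with breast laterality), **y**
posterior to anterior (the direction the breast protrudes from the chest
wall), **z** inferior to superior. This frame is forced by the quadrant
construction: the superior–inferior boundary plane is defined as parallel
to the xy-plane (its normal is z) and crossing the nipple, so the
inferior-to-superior axis must be z; the pectoral (chest wall) plane's
normal is the normalized cross product of the two edges spanned by three
annotated pectoral corner points; the lateral–medial plane is
perpendicular to the pectoral plane through the nipple, with normal
`n_pect × ẑ`. Quadrants (UOQ/UIQ/LOQ/LIQ) follow from the two signed
distances, with a deterministic tie rule — points exactly on a boundary
go superior / lateral — and the outer side flips with laterality.

The excision volume is a cylinder whose axis runs from the tumor center's
orthogonal projection on the pectoral plane toward the skin (the
continuous stand-in for the "nearest point of the pectoral muscle" on a
discrete muscle mesh, which is out of scope). The height is the largest
axial projection among the ten radially-nearest surface points — the
skin-to-muscle extent along the axis; ten points smooth over the surface
sampling noise without letting distant skin inflate the height. The
radius then follows from the prescribed excision fraction:
`r = sqrt(f · V / (π h))`, with `f ∈ {0.05, 0.075, 0.10}` for
small/medium/large tumors and a hard eligibility bound of `f ≤ 0.20`.
Points inside the cylinder are *damaged*.

## The synthetic data generator

No paired pre-/post-surgery dataset is public, so the package generates
its own study population. The generator replaces a coupled
finite-element wound-healing simulator with a closed-form displacement
field; this makes the repository self-contained and testable, at the
price of emulating only the published, checkable structure of the
simulated deformations rather than their full physics.

**Anatomy.** Each patient is a half-ellipsoid breast attached to a flat
chest wall at y = 0, with fixed anisotropy (vertical/lateral semi-axis
ratio 0.9, depth/lateral ratio 0.65 — breast-like proportions), nipple at
the apex, and semi-axes set so the analytic enclosed volume matches the
patient's target volume. The six-patient roster spreads size (2 small,
2 medium, 2 large; target volumes 495 948–1 314 990 mm³) and laterality
(3 L / 3 R); left breasts are exact x-mirrors. Surface points are sampled
on the anterior dome (approximately uniform via scaled hemisphere
directions), interior points uniformly by rejection. The desk-scale
default is 400 surface + 600 interior points per cloud; the
full-resolution source data would be ≈ 1900 + 2500.

**Factorial design.** Cases enumerate patients × densities (A–D) ×
tumor quadrants × tumor sizes in a deterministic order: 24, 96, and 288
cases at the successive levels for six patients. Each case carries a
sub-seed derived from the root seed by a small string hash, so any case
is reproducible in isolation. Tumor centers are drawn uniformly inside
the breast (restricted to 25–75 % of the anterior depth), rejected until
they fall in the target quadrant and the full cylinder cross-section
fits inside the chest-wall ellipse.

**Displacement field.** With `e = exp(−d/λ)` (`d` = distance to the
cylinder solid, zero inside; decay length λ = 30 mm) and class factor
`k = b·s` from the density multipliers {A:4, B:3, C:2, D:1} and size
multipliers {L:3, M:2, S:1}, each point's displacement magnitude is

```
m = A₀ · e · (1 + (k − 1) · e · q) · (1 + ε),
```

where `q` indicates the quadrant containing the tumor and
ε ~ N(0, 0.05²) clipped at ±0.5 is multiplicative noise. Half of the
magnitude budget (settle fraction 0.5) moves the point along the
cylinder axis toward the chest wall (posterior settling); the rest moves
it radially toward the axis, capped at 95 % of its radial distance so
points never cross the axis. Damaged points have `d = 0` and therefore
collapse toward the axis at the full class amplitude.

The structure encodes the documented behaviour of simulated BCS
deformations: magnitudes decay with distance from the excision, decrease
with breast density (fibroglandular tissue is stiffer than fat), grow
with excised volume, and mirror with laterality. Two choices deserve
explanation:

* *Class scaling is confined to the operated quadrant.* A field whose
  entire extent scales 12-fold with density/size class would mean the
  farthest tissue moves 12× more for a fatty breast with a large tumor —
  physically implausible, and inconsistent with the near-flat per-class
  error tables of the experiments this package mirrors. Wound-size and
  stiffness effects act where the wound is; remote tissue settles
  generically. This also makes the per-quadrant heuristic's model (a
  class-independent displacement outside the tumor quadrant) a correct
  first-order description of the data, which is precisely the regime in
  which a knowledge-only baseline is a meaningful comparator.
* *Deterministic geometric noise.* ε is computed by hashing each point's
  coordinates together with the seed, not by drawing in row order, so
  the displacement field is a pure function of geometry: reordering the
  cloud cannot change any point's displacement. This makes the
  correspondence invariants exactly testable.

The amplitude A₀ = 5 mm was calibrated once, at design time, so that the
no-method baseline (prediction = pre-surgery cloud) lands near 2 mm mean
pair-wise error — the scale of the reference experiments; it is
calibration of the study conditions, not a fitted quantity, and is not
revisited.

**What the generator does not emulate.** No wound-healing biochemistry
or angiogenesis, no gravity/pose transformation (prone/supine/upright),
no MRI artefacts, no anatomical asymmetries beyond mirroring, and a
smooth single-component field rather than FEM heterogeneity. Tests that
pass on this data therefore validate the machinery — geometry, features,
training, evaluation — and the qualitative orderings, not clinical
accuracy on real breasts.

## Features

Each point contributes 23 features: centered coordinates (the cloud's
centroid is translated to the origin; cylinder-relative quantities are
translation-invariant), signed per-axis differences to the nearest point
of the cylinder axis segment, the Euclidean distance to the cylinder
solid (zero inside, so the damaged-point zero rule is a special case
rather than an override), cylindrical coordinates (ρ, φ, z) in the frame
anchored at the cylinder base — φ measured from the breast's lateral
direction projected into the axis-normal plane, an arbitrary but fixed
convention since the models only need consistency — and one-hot
encodings of tumor size (3), laterality (2), density (4) and tumor
quadrant (4). All seven distance-family features are exactly zero for
damaged points. Targets are per-axis displacements, never absolute
coordinates, so breasts of different laterality and size share one
feature space. Laterality is two one-hot columns (R, L), which is what
brings the count to 23 and matches the per-feature importance tables the
package reproduces.

"Difference to the excised cylinder" is measured to the nearest point of
the axis segment (not the tumor center, not the wall); the convention is
applied consistently to dispx/y/z and (ρ, φ, z) and flagged here because
the source material leaves it ambiguous.

## Models and tuning

Per-axis random forests (via `ranger`) are the primary model; gradient
boosting (via `xgboost`, weak learners constrained to ≤ 3 leaves and
depth ≤ 5, squared-error splits — the Friedman-MSE variant is not
available in this backend) and a joint multi-output forest are
comparators. The multi-output forest is implemented in the package
itself: bagged multivariate trees whose splits maximize the summed
variance reduction of the per-target-standardized displacement vector (a
diagonal approximation to covariance weighting, flagged as such), with
leaf-mean vector predictions.

Evaluation is leave-one-patient-out: all 48 cases of one patient form a
test fold, preventing leakage between the near-identical clouds of a
single patient. Tuning happens inside the training patients only; the
objective is either the pooled mean pair-wise distance (*average*) or
the pooled maximum (*Hausdorff*) on inner-validation patients, and the
published sampling-rate optima (65 % / 75 % of training points for the
two objectives) are the defaults. Training tables subsample per case
with `ceil(rate · n)` rows; test rows are never subsampled.

Grid ranges follow the published protocol (trees {5,…,500}, max features
{2,…,23}, leaf size {1,…,5}, learning rate {0.01,…,1}), available via
`train_config(grid = "full")`. The default *desk* configuration is a
deliberately small subset — trees {5, 10}, max features {4, 8}, leaf
size 5, a randomized subset of candidates scored on at most 30 000
subsampled rows, one inner fold, hyperparameters tuned once per
objective and reused across outer folds. Grid size is an experiment
knob, not method content: single-threaded forest training at
~150 000-row fold sizes costs seconds per tree, and the desk grid keeps
the full 288-case LOPO comparison in the minutes range (the acceptance
suite runs it with trees {5}, max features {4, 8} at 400 + 600 points
per cloud; the acceptance script at 150 + 200). Ties in the grid argmin
break toward the cheapest model (fewest trees, then fewest features).

**Adaptive weighting.** Starting from unit weights, each iteration fits
the per-axis forests with the current per-row weights, computes each
training point's residual pair-wise distance — in-sample by default, the
minimal reading of the published loop; out-of-bag via a flag — and sets
the new weight to the clamped ceiling `max(1, min(6, ⌈d⌉))`. The loop
stops after 100 iterations or when the objective has not improved for 3
consecutive iterations, and returns the best-objective model seen. The
weights deliberately distinguish well-fit from poorly-fit points (in
practice: healthy far-field points from damaged/near-wound points).

## The heuristic baseline

The knowledge-only comparator predicts each point's displacement as its
quadrant's mean training displacement, scaled by `b·s` in the tumor
quadrant. One estimator detail matters: because prediction re-applies
`b·s`, the fit divides each training displacement by the multiplier its
own case would receive under the rule before pooling (still pooled over
all cases, not stratified). This is the estimator consistent with the
rule's own generative model — on data generated by the rule it recovers
it exactly for any training mix — whereas pooling raw displacements
bakes the average training multiplier (5, over the balanced factorial)
into the mean and overshoots every prediction by a factor of about two.
Multipliers apply to all three axes uniformly, and the model is
deliberately discontinuous across quadrant boundaries.

## Metrics and reports

Pair-wise distance uses the index correspondence; global distance is the
directed mean nearest-neighbour distance, reported in both directions
(nearest-neighbour ties break to the lowest index, and the minimum
located by the squared-norm expansion is recomputed directly for full
precision). σ is the population standard deviation (divisor N) — the
convention is not fixed by the source material, so it is documented
here. Multi-case reports pool per-point distances across all test cases
of all folds, so μ is the grand mean and Max the global maximum;
per-fold maxima remain available from per-case reports. Evaluation is
restricted to surface points; training uses surface and interior points.

## Degenerate inputs and numerical choices

Collinear pectoral corners, a tumor on the pectoral plane, non-positive
cylinder height, empty clouds, broken pre/post correspondence and empty
training quadrants all raise immediate, named errors. An excision radius
exceeding the breast's lateral extent is a warning, not an error. Points
exactly on the cylinder axis get zero radial direction (and φ = 0 at
ρ = 0). The cylinder-volume identity `π r² h = f · V` holds to 1e-6
relative by construction; plane containment and centering are exact to
1e-9.

## Known limitations

The generator's field is a two-component closed form; real post-surgical
fields are heterogeneous and pose-dependent, so absolute error values on
synthetic data are not clinically meaningful — orderings and machinery
are what transfer. The multi-output forest is a compact reference
implementation, not a large-scale learner. The half-ellipsoid anatomy
has no ptosis and a planar chest wall. The published error tables from
the original MRI-derived experiments are not reproducible without that
non-public dataset; this package reproduces their structure (metrics,
protocol, orderings, worked-example constants) instead.
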