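---
title: "Regional volumetric lung strain from paired CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional volumetric lung strain from paired CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungstrain)
```

This vignette is the package's account of the science it implements: the
strain model, the processing chain, the choices that were genuinely open and
how they were settled, and what the synthetic validation does and does not
demonstrate.

## The strain model

Lung strain is relative volume change. Globally, with lung volumes segmented
from CT at end-expiration (EELV) and end-inspiration (EILV) under zero
(ZEEP) and positive (PEEP) end-expiratory pressure:

$$LS_{STATIC} = \frac{EELV_{PEEP} - EELV_{ZEEP}}{EELV_{ZEEP}} \times 100,
\qquad
LS_{DYNAMIC} = \frac{EILV_{PEEP} - EELV_{PEEP}}{EELV_{PEEP}} \times 100,$$

$$LS_{TOTAL} = LS_{STATIC} + LS_{DYNAMIC}, \qquad
LS_{DYNAMIC,ZEEP} = \frac{EILV_{ZEEP} - EELV_{ZEEP}}{EELV_{ZEEP}} \times 100.$$

The end-expiratory ZEEP state is taken as the zero-strain reference, so the
total strain at ZEEP equals the dynamic strain at ZEEP. This is an
assumption, not a measurement: any tonic deformation already present at
relaxed end-expiration is invisible to the method.

Regionally, the same quantity is the local relative volume change of the
tissue. If `u(x)` is the displacement field mapping a reference-state point
to its target-state position, the deformation gradient is `F = I + grad(u)`
and the volumetric tissue strain is

$$TS = (\det F - 1) \times 100.$$

This choice — the Jacobian determinant rather than any tensor norm — is
forced by consistency: the volume-weighted average of `det F - 1` over the
lung is exactly the global volume-ratio strain, so the regional measure
reduces to the global one. The package verifies this reduction numerically
(the acceptance script reports the discrepancy between the lung-mean
recovered strain and the segmented-volume strain).

Total regional strain is composed additively, `TS_TOTAL = TS_STATIC +
TS_DYNAMIC`, mirroring the global definition. Exact kinematic composition
is multiplicative (`det` of a composed deformation is the product of the
parts), so the additive total is an approximation that understates the
composed strain by the cross term; with static ~47% and dynamic ~24% the
difference is about 11 strain points. The additive convention is retained
deliberately because the global quantities are defined that way and the two
must stay comparable. Before summation the PEEP-referenced dynamic map is
pulled back into the ZEEP frame by evaluating it at `x + u_static(x)`
(`pullback_dynamic()`); summing maps that live on different material frames
would be meaningless. Dynamic strain *reported on its own* stays in its own
condition's frame, matching how per-condition regional maps are usually
presented.

## Processing chain

1. **Segmentation** (`segment_lungs()`): voxels with HU in the closed
   interval [-1000, -50] are lung candidates; connected components touching
   the volume boundary (outside air) are discarded; the two largest
   components become the left and right lungs (split by an
   erosion-relabel-dilation pass if merged); a morphological closing
   (radius 1 voxel, configurable) fills vessel-sized holes. The interval is
   closed on both printed bounds. Trachea and main bronchi are *not*
   excluded: intraluminal air is retained in the mask, which is why
   hyperaeration can appear in mid-dorsal regions as a bronchial artifact —
   the phantom generator can reproduce exactly this signature
   (`phantom_config(bronchus = TRUE)`).
2. **Volumes** (`lung_volume()`): voxel count times voxel volume, in ml;
   `global_strains()` applies the formulas above.
3. **Registration** (`register_ffd()`): multiresolution cubic B-spline
   free-form deformation, described below.
4. **Strain recovery** (`recover_strain()`): `F` by central differences of
   `u` scaled by the physical spacing; strain at every lung voxel; then a
   lumped L2 projection onto a regular hexahedral mesh with trilinear shape
   functions (node spacing >= voxel spacing, default 2-4 voxels) and
   interpolation back to voxels. The projection is the finite-element
   smoothing step: it suppresses voxel-scale differentiation noise at the
   mesh scale while leaving smooth fields essentially unchanged (halving
   the node spacing moves the lung mean by well under one strain point on
   smooth fields — a property the test suite checks).
5. **Aeration** (`gas_fraction()`, `classify_aeration()`): gas fraction
   `-HU/1000` clamped to [0, 1]; compartments hyper [-1000, -901], normo
   [-900, -501], poor [-500, -101], non [-100, +100] HU, closed on the
   printed bounds, config-exposed (`aeration_thresholds()`). These are the
   conventional CT compartment bounds; computation is voxelwise.
6. **ROI grid** (`partition_rois()`): per lung, 9 cutting planes along the
   apicobasal axis and, independently, 9 along the dorsoventral axis,
   placed so the ten slabs along each axis hold equal tissue volume (voxel
   count — tissue, not gas, is what the partition balances). Plane
   positions are chosen by dynamic programming minimizing the worst slab
   imbalance, which achieves the 10% +- 1% balance whenever the lung spans
   roughly 64+ voxels along the axis; at coarser resolution the partition
   remains exact as a partition (union of ROIs equals the mask) but slab
   balance is limited by slice granularity. ROIs without tissue are
   flagged missing and excluded from every statistic.
7. **Regional statistics** (`aggregate_to_roi()`, `quadrant_summary()`,
   `roi_paired_tests()`, `correlate_static_delta()`): per-ROI mean and SD;
   quadrant summaries over the four 5x5 blocks; per-ROI two-sided paired t
   tests across subjects with Bonferroni correction over the ROIs actually
   tested; Pearson correlation of static strain with per-ROI aeration
   change. The paired-t-plus-Bonferroni scheme replaces a repeated-measures
   ANOVA whose factor structure would be underdetermined here; for
   per-ROI inference with family-wise control the two are operationally
   equivalent, and the deviation is deliberate.
8. **Capnography** (`segment_phases()`, `alveolar_pco2()`,
   `mixed_expired_pco2()`, `bohr_dead_space()`): phase III is the longest
   terminal segment of the pCO2-vs-volume curve whose linear fit has
   residual SD below 1 mmHg *and* whose first sample lies on the fitted
   line within the same tolerance (without the second condition the
   detector absorbs the smooth tail of the phase II upstroke); the segment
   must span >= 30% of expired volume by default — for high-dead-space
   breaths (Bohr > ~0.65 at canine tidal volumes) the plateau is genuinely
   shorter and the span threshold should be lowered (the validation
   experiments use 15%). PACO2 is the fit evaluated at the phase III
   volume midpoint; PECO2 is the volume-axis trapezoidal mean of the trace
   (integrating on volume, not time, so flow irregularities cancel); Bohr
   dead space is `(PACO2 - PECO2)/PACO2`. Mechanics: driving pressure
   `Pplat - PEEP_total`, static compliance `Vt / driving pressure`;
   `PEEP_total` at ZEEP is 0 unless an intrinsic-PEEP measurement is
   supplied.
9. **Study orchestration** (`run_study()`): per subject, the four
   segmentations, three registrations (static EE_ZEEP->EE_PEEP; dynamic
   EE->EI within each condition), strain recovery, pull-back and
   composition, aeration deltas, per-lung and tissue-weight-pooled ROI
   maps; group-level paired tests and correlations on the pooled maps with
   equal subject weighting. A subject failing at any stage is marked
   incomplete with the reason; the rest of the report is still produced.

## The registration

No reusable deformable-registration engine exists in this package's R
dependency universe, so the FFD registration is implemented here:
tensor-product cubic B-spline control grids (control spacing 4 voxels at
the finest level by default), a 3-level image pyramid with coefficient
refitting between levels, L-BFGS-B on the control coefficients, and a
bending-energy surrogate (squared second differences of the coefficients,
weight 1e-3 relative to the variance-normalized image term). The
interpolant's spatial gradient is computed exactly, so the analytic
objective gradient matches finite differences to optimizer precision — a
property the test suite checks directly, because an inconsistent gradient
is the classic silent failure of hand-written registration.

Two metrics are provided. `ssd` is the plain intensity difference,
appropriate when the two states have comparable intensities. The default
configuration for strain work is `sstvd`: the *tissue-volume* residual
`det(F) * rho(x + u(x)) - rho(x)` with `rho = 1 + HU/1000` clamped to
[0, 1]. Inflation changes lung HU (the same tissue spreads over more
volume), so plain SSD is biased exactly where strain is largest; the
Jacobian-compensated residual vanishes at the true deformation whenever
tissue mass is conserved, which is the physical situation in tidal
breathing and exactly the generator's construction. A normalized
cross-correlation metric was considered and omitted: the pipeline is
single-modality, and global NCC would not address the spatially varying
intensity change that motivates `sstvd`.

The metric region is the fixed-lung mask *eroded by one voxel*
(`mask_margin_vox = -1`). Boundary voxels are partial-volume mixtures of
parenchyma and chest wall whose residual cannot vanish at the true
deformation; including them measurably biases the recovered interior
strain, while the interior parenchyma (with its intensity gradient and
texture) carries enough information to drive the alignment. A
`boundary_weight` option can re-include the boundary band at reduced
weight for images with structureless interiors. Both images are smoothed
with one pass of a separable 1/4-1/2-1/4 kernel at the finest level
(`presmooth = 1`) to suppress voxel noise; coarser pyramid levels are
already band-limited by pooling.

Registration accuracy is validated by parameter recovery on phantoms, not
by matching any external tool: the registration hyperparameters of the
original analyses behind this kind of study are generally unreported, so
recovery of known warps is the only meaningful test. For the recovery
experiments a slightly coarser control grid (5 voxels) is used: at the
phantom's texture scale it regularizes the large-deformation (45% peak)
case without limiting the representable strain field.

## The synthetic data generator

`make_phantom()` builds a supine thorax: a soft-tissue body ellipsoid
(+40 HU) in air, containing two ellipsoidal lungs (semi-axes 58 x 42 x 25
mm, together ~510 ml — a plausible end-expiratory volume for a ~12 kg dog
at about 41 ml/kg) with a linear dorsoventral HU ramp from -900 (ventral,
well aerated) to -300 (dorsal, poorly aerated), emulating the
gravitational aeration gradient of a supine anesthetized subject. The
default grid is 96^3 voxels at 2 mm — the reconstructed slice thickness of
the thoracic CT protocol the pipeline targets. Options add Gaussian HU
noise (default 20 HU in study simulations), an air-filled bronchial tube
(the hyperaeration artifact), and a material-attached parenchymal texture:
a fixed set of Gaussian blobs, evaluated at source coordinates so they
deform with the tissue, standing in for the vascular markings that make
real lung CT registrable. The texture is off by default because it
perturbs the ramp's analytic class volumes; registration experiments
enable it (amplitude 120 HU), aeration experiments do not.

`make_warp()` supplies deformations with closed-form displacement,
Jacobian and inverse: rigid translation, anisotropic affine scaling,
radial inflation (`u = beta * exp(-(r/R)^2) (x - c)`, peak strain at the
centre), and the graded dorsoventral stretch whose volumetric strain rises
linearly from a ventral to a dorsal value. The graded strain gradient
continues linearly over the whole domain rather than plateauing at the
lung edges — globally quadratic displacement, no curvature kinks for the
B-spline model to chase — and is anchored at the lung centre so expansion
splits ventrally and dorsally instead of accumulating as a large dorsal
shift. `apply_warp_to_phantom()` produces the deformed image by evaluating
the *analytic* source HU at inverse-warped voxel positions (no resampling
error) and rescales lung HU under tissue conservation: `1 - gf_new =
(1 - gf_old) / det F`, i.e. inflation only adds gas. This single rule is
what makes all three strain routes — segmented volumes, displacement-field
Jacobians, and HU-derived gas fractions — mutually consistent, and it is
the property the consistency checks exercise.

Ground truths (class volumes from the ramp-ellipsoid slab integral,
strains from the closed-form Jacobians, Bohr fractions from the piecewise
capnogram integrals) are computed from the generator's parameters by
separate closed-form code, never by the pipeline under test.

`make_capnogram()` builds one expiration on the volume axis: zero CO2 over
the airway dead space, a half-cosine phase II of configurable width, and a
linear phase III; PACO2, PECO2 and the Bohr fraction follow in closed
form, and a target Bohr fraction can be requested directly (the dead-space
volume is solved for). Defaults emulate the study's ventilation: 186 ml
tidal volume (15 ml/kg at 12.4 kg), plateau near 38 mmHg, 0.5 mmHg trace
noise.

The study simulator (`simulate_study_inputs()`) assembles subjects with
graded warps whose lung-mean strains sit at the study's global levels —
static 47% (ventral 30% to dorsal 64%), dynamic 33.5% at ZEEP (20-47%),
24% at PEEP (10-38%, referenced to the inflated lung extent) — scaled per
subject by a ~10% SD factor, plus capnograms at Bohr 0.62 (ZEEP) and 0.55
(PEEP) and the study's pause pressures (Pplat 8.3/12.3 cmH2O, PEEP 0/5).

**What passing these tests shows, and what it does not.** The phantoms
have smooth single-scale warps, piecewise-analytic anatomy, stationary
Gaussian noise and mass-conserving intensity change. Real lungs add
sliding at the pleura, cardiac motion, airway secretions, scanner-specific
noise and calibration drift, and deformations with more spatial detail
than a 10-15 mm control grid. Recovery of known warps therefore validates
the *machinery* (metric, optimizer, strain recovery, partition,
statistics), not the claim that any particular in-vivo scan pair is
registered to a given accuracy; on real data, registration QC (convergence
diagnostics in the field's `info`, warped-image inspection, the
volume-transport check) remains the user's responsibility.

## Numerical choices and degenerate inputs

- Volume/tissue integrals are plain voxel sums; no partial-volume
  modelling anywhere (consistent between numerator and denominator, so
  ratios are unbiased to first order).
- Strain differentiation: central differences, one-sided at volume faces;
  inside the registration metric a zero-padded variant keeps the operator
  exactly self-adjoint with its gradient.
- Trilinear interpolation throughout; NaN-aware variants renormalize the
  weights of valid corners and return NA below 25% valid weight
  (pulled-back maps near the lung edge).
- `det F <= 0` on more than 1% of lung voxels raises a warning with the
  count (a folded registration); non-finite fields are errors.
- Ties in the ROI partition are settled by the dynamic program (first
  optimal cut); empty slabs cannot occur because cuts are drawn from the
  occupied slice range, and a lung spanning fewer slices than slabs is an
  error rather than a degenerate grid.
- Registration determinism: no stochastic sampling anywhere, so identical
  inputs and configuration give bitwise-identical fields; the stored seed
  is provenance only.
- Capnography degenerate cases: a flat zero trace has no phase III
  (error); a plateau starting at zero volume is accepted (phase I/II
  empty); PECO2 > PACO2 warns rather than errors, since slight phase III
  mis-segmentation on noisy traces can produce it.

## Problem sizes used in validation

The strain-recovery oracle runs at the generator default, 96^3 at 2 mm.
Registration recovery experiments run at 64^3 at 3 mm (the same 192 mm
thorax, chosen to keep the three-seed experiment in the minutes range on a
single core) with peaks spanning 10-45%; the ROI partition balance check
runs a single lung at 1.2 mm so both partition axes exceed 64 voxels; unit
tests use a 32^3 at 6 mm version of the same anatomy. The single-subject
end-to-end study test runs at 48^3 at 4 mm. These sizes are stated so the
reported tolerances can be reproduced exactly; accuracy improves with
resolution in every experiment we ran, so the coarse settings are the
conservative ones.

## Known limitations

- The additive total strain understates the exact composed strain (see
  above); the package reports components so users can compose differently.
- Left and right lungs are partitioned separately; pooled maps match ROIs
  by grid index, not by anatomical correspondence, and cross-state ROI
  comparisons likewise use positional (i, j) matching of per-state grids.
  This mirrors the usual presentation of per-state 10 x 10 maps but means
  ROI (i, j) is not the identical tissue parcel across states.
- No diffeomorphic guarantee: large or adversarial deformations can fold;
  the Jacobian warning and QC diagnostics surface this but nothing
  prevents it.
- HU calibration, beam hardening, DICOM assembly, and airway-tree
  segmentation are out of scope; inputs are assumed HU-calibrated NIfTI.
- Mechanics are pause-based scalars only; esophageal/transpulmonary
  pressures and dead-space subcomponents (airway vs alveolar) are not
  modelled.
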