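---
title: "Simulating a tight-margin sub-fractionation MR-Linac workflow"
author: "subfracdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a tight-margin sub-fractionation MR-Linac workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subfracdose)
```

## The workflow being simulated

In MR-guided prostate radiotherapy on an MR-Linac, a treatment session
can be split into two sequential *sub-fraction* deliveries of half the
session dose (2 x 3.625 Gy per session, 5 sessions, 36.25 Gy in total).
Each session acquires four MR volumes: MR1 drives daily re-contouring
and re-planning (adapt-to-shape), MR2 and MR3 drive rigid
adapt-to-position corrections of the planned dose before each
sub-delivery, and MR4 is acquired during the second delivery purely for
analysis. Because the plan is re-positioned mid-session, the
uncorrected ("residual") prostate motion per delivery is small, which
permits tight CTV-to-PTV margins of 2 mm (LR, SI) / 3 mm (AP) instead
of the conventional 5 mm.

The package simulates this workflow end to end on synthetic pelvic
anatomy: cohort generation with calibrated intrafraction and
interfraction motion, deformable registration of the in-session images,
a traffic-light protocol that escalates margins for patients with
unexpectedly large residual shifts, idealized per-subfraction planning,
dose warping and accumulation within and across fractions, DVH
constraint evaluation, and counterfactual re-planning of switched
fractions with the original tight margins.

No patient data are involved anywhere: every input is generated by
`simulateCohort()`, and every downstream estimate can be checked
against the generator's ground truth.

## Synthetic anatomy

`buildPhantom()` places ellipsoidal prostate, GTV, bladder and rectum
on a regular grid (axes ordered LR/AP/SI; positive directions left,
posterior, superior; world mm = origin + 0-based index x spacing).
Organs get distinct mean intensities, boundaries are smoothed over
2 mm, and Gaussian noise (SD 2 a.u. against ~140 a.u. of contrast) is
added. This is deliberately *not* an MR physics simulation: the
registration engine only needs smooth, distinct contrast patterns, and
any richer texture model would not change what the tests can conclude.
The CTV is built clinically: prostate plus a 4 mm isotropic GTV
expansion, with bladder and rectum voxels excluded
(`ctvFromGtv()`).

Consequences for interpretation: passing tests show that the pipeline's
geometry, registration and dosimetry chain is self-consistent and
recovers known truths on smooth anatomy. They cannot certify
performance on clinical images with rectal gas, susceptibility
artefacts, or intensity non-uniformity, none of which are modeled.

## The motion model and its calibration

Per-subfraction prostate shifts are rigid translations drawn per axis
from a two-level normal model: a per-patient systematic offset (SD 0.3
/ 0.4 / 0.4 mm in LR/AP/SI) plus a per-subfraction random component.
Motion is anisotropic (LR scale 0.4 of the AP/SI scale) because
bladder filling and rectal gas drive predominantly AP/SI motion. A
small mixture tail (probability 0.10, scale x3 for typical movers;
0.15 and x3.5 for the "large mover" subgroup) emulates transient
filling/gas events; without it the magnitude distribution of a pure
normal model is too light-tailed to reach the observed SD.

The scales were calibrated once by Monte Carlo so that the cohort mean
3D shift magnitude is 1.0 mm (SD 0.6 mm) for typical movers and 1.9 mm
(SD 1.5 mm) for large movers, matching the treated-cohort statistics
the simulator is meant to emulate; the calibration is frozen in the
`cohortConfig()` defaults and verified by the test suite at n = 10^4
draws. The interfraction model adds a rigid prostate shift (SD 0.5/1/1
mm) and a bladder-filling deformation: a radial Gaussian bump centred
in the bladder with amplitude drawn at SD 1.5 mm per fraction.

The source did not report a per-axis breakdown of the per-subfraction
shift distribution, only 3D summaries and per-axis systematic errors;
the anisotropy ratio is therefore a modeling choice, fixed before any
dosimetric analysis and not revisited.

Seeding is counter-based: one master seed, with per-(patient, fraction,
interval) streams derived by integer hashing, so enlarging a cohort
never perturbs existing patients (`sampleMotion()` is reproducible in
isolation).

## Deformable registration

`registerDeformable()` is a demons-style variational scheme: the data
term is the intensity difference between the lightly smoothed fixed
image and the warped moving image (both normalised by the fixed-image
range), minimised by normalised symmetric-gradient forces with
diffusion regularization (Gaussian smoothing of the field, sigma =
1.5 mm x `regWeight`) over a two-level coarse-to-fine pyramid,
followed by a full-resolution *refinement* pass with annealed
regularization (`refineRegWeight = 0.75`, data smoothing 1.0 mm).
The refinement exists because homogeneous diffusion shrinks the field
where a moving structure abuts a static one (prostate against bladder
and rectum): converging first under stronger smoothing and then
relaxing it recovers most of that bias while remaining stable. The
displacement convention is pull-back (fixed coordinates to moving
coordinates) everywhere, recorded in the NIfTI headers.

Accuracy at the package defaults, 2.5 mm grids: a registration of an
image to itself returns a field that is numerically zero; rigid
prostate shifts of 1-5 mm are recovered with a 95th-percentile CTV
shift error below 0.5 mm over 20 seeded cases (the test suite runs
this exact experiment). Accuracy degrades quickly at coarser voxels
(about 1 mm error at 3.75 mm spacing), which is why the smoke preset
is a liveness check only.

`registerContourGuided()` adds, inside the ring around the PTV, a
force aligning signed distance maps of the daily bladder, prostate and
rectum contours; it is used for interfraction registration where
day-to-day bladder volume change defeats pure intensity matching. With
`guidanceWeight = 0` it reduces exactly to the unguided engine.

`medianOfRepeats()` re-runs a registration (clinical default 30
times) from seeded jittered initialisations (zero-mean constant
offsets, SD 0.2 mm per component) and takes the component-wise
per-voxel median field. The original account of the repeat procedure
does not state what varies across runs nor at what level the median is
taken; we jitter the initialisation (the minimal mechanism that makes
distinct local optima reachable) and take the median at field level,
which makes the wrapper usable for every downstream consumer of the
field. The wrapper is exact against a sort-based oracle and its
variance-reduction is verified empirically.

## Planning and dose model

`expandMargin()` dilates the CTV with an ellipsoidal structuring
element whose semi-axes are the per-axis margins (tight preset 2/3/2
mm; large preset 5 mm isotropic) -- standard margin semantics rather
than box dilation. `makeRing()` expands the PTV by 20/20/10 mm
(LR/AP/SI) and subtracts it. `makePlan()` is geometric: the
per-subfraction prescription inside the PTV and a Gaussian falloff
`exp(-d^2 / 2s^2)` of the Euclidean distance to the PTV outside, with
penumbra scale s = 3 mm (80-20% falloff of roughly 5 mm, typical of
MR-Linac prostate plans). Machine plan optimisation is out of scope:
the analysis needs plausible dose gradients, not machine-accurate
fluence. Large-margin plans are assumed to differ from tight-margin
plans only through the margin; prescription and penumbra are
identical.

`adaptToPosition()` translates a dose grid rigidly by the estimated
target shift with trilinear resampling, erroring if significant dose
would leave the grid. `sessionPlans()` composes the daily chain:
ATP1 is the base plan shifted by the MR1-to-MR2 CTV shift, ATP2 by the
cumulative MR1-to-MR3 shift.

## Accumulation and DVH

Dose maps are warped by pull-back interpolation without Jacobian or
energy rescaling: dose is an intensive per-voxel quantity, and the
delivered maps are warped directly. Intrafraction accumulation
registers MR3 and MR4 to MR1 and sums the warped subfraction doses;
the first subfraction dose is associated with MR3 (acquired during its
delivery) rather than MR2, the choice that avoids under-estimating
residual shifts. Interfraction accumulation registers each later
fraction's MR1 to the fraction-1 MR1 with the contour-guided engine
and sums the warped intrafraction doses on the fraction-1 frame.

`dvhQuery()` implements Dp% (near-minimum dose received by the hottest
p% of the structure volume) and Dv cm3 (minimum dose of the hottest v
cm3) on the sorted voxel doses with linear interpolation between order
statistics at fractional rank `r = q (N-1) + 1`. The engine is tested
for exact agreement with an independent sort-and-index oracle.
Accumulated metrics are evaluated on the *fraction-1* contours (a
config switch in `accumulateInterfraction()` would admit warped daily
contours instead; fraction-1 contours were chosen as the least
assumption-laden reading of "structures on the reference frame").
Rectum and bladder metrics are annotated as reliable only near the
target, because contours are corrected (and guidance applied) only
within the ring.

Default constraints: CTV D99% at or above 34.4 Gy, rectum D1cm3 below
38.0 Gy, bladder D5cm3 below 37.0 Gy.

## The traffic-light protocol

Per fraction, the larger of the two subfraction 3D shift magnitudes is
classified green / orange / red. The published protocol's exact
thresholds live in a figure that the available text does not
transcribe; the defaults here -- green below 3 mm, red at or above
5 mm -- are config values chosen to be consistent with the stated
rationale that the 2-3 mm margin values themselves were deliberately
*not* used as triggers. **They are defaults, not the clinical
thresholds**, and every threshold is exposed in
`trafficLightConfig()`. Fractions 1-3 are monitored; an orange light
at fraction 3 extends monitoring to fraction 4; a red light in a
monitored fraction switches all subsequent fractions to the large
margins, absorbingly. Missing shift records make a fraction
unevaluable and it is treated conservatively as orange. Red detection
uses both subfraction shifts; either may trigger.

`cohortErrorStats()` reports per-axis systematic error (SD over
patients of the per-patient mean shift) and random error (RMS of the
within-patient SDs), printed in LR, SI, AP order as mean +/- SD.
`vanHerkMargin()` applies the community-standard population recipe
2.5 Sigma + 0.7 sigma per axis (the cited margin values imply a recipe
of this family but none is printed; the coefficients are
configurable).

## Counterfactual re-planning

For patients who switched, `replanCounterfactual()` substitutes
tight-margin plans for the post-switch fractions on the same anatomy
and the same estimated shifts, and the accumulation is repeated. The
displacement fields depend only on the images, so both scenarios share
one set of registrations (`sessionFields()`, `interfractionFields()`),
halving the cost and removing registration noise from the scenario
difference. `compareScenarios()` tabulates both panels (delivered
large-margin vs re-planned tight-margin), per-patient deltas,
median/IQR, and threshold pass counts.

## Numerical choices and problem sizes

* Grids: the package default is 48^3 at 2.5 mm (a 120 mm pelvic cube).
  Dose-conservation experiments use 60^3 at 2 mm: a 2 mm margin is
  sub-voxel at 2.5 mm spacing, so in places the discrete PTV adds no
  buffer voxel around the CTV and any interpolation mixes penumbra
  into CTV edge voxels; at 2 mm spacing the tight margin covers at
  least one voxel everywhere and the full pipeline conserves the
  36.25 Gy prescription to well within 1%. The smoke preset (24^3 at
  5 mm, 2 patients, single-run registrations) exists for liveness and
  determinism checks only -- at 5 mm voxels the tight margins are not
  representable and DVH values are not meaningful.
* The default experiment preset uses 4 patients and a median of 3
  registration repeats; the clinical repeat count of 30 remains the
  `registrationSettings()` default for single registrations.
* Registration tolerance: a level stops when the mean update falls
  below 0.01 mm; per-iteration updates are capped at 2 mm.
* Distance transforms are separable squared EDTs truncated at the
  queried distance (exact below it); anisotropic metrics are obtained
  by scaling the spacing by the margin vector.
* Ties and degenerate inputs: empty rings fall back to unguided
  registration with a warning; empty structures raise errors naming
  the deficit; zero margins and zero fields are exact identities.

## Known limitations

* Rigid prostate motion only: no rotation, no seminal-vesicle
  articulation, no intra-organ deformation of the target.
* The bladder-filling bump is a generic radial deformation, not a
  biomechanical model; rectal gas is not modeled at all.
* The dose model has no beam geometry, so OAR sparing trade-offs of
  real optimisers are absent; OAR metrics are indicative only.
* DIR accuracy claims hold on this phantom class at 2.5 mm spacing
  and below; clinical image quality is a different regime.
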