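---
title: "Models and methods behind caninegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caninegait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninegait)
```

`caninegait` models the pelvis and pelvic limbs of a small dog as a
tree of rigid segments, drives that model with marker-based inverse
kinematics, balances it with Newton–Euler inverse dynamics, and
distributes net joint moments into muscle activations by static
optimization. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions taken where the
methodology left genuine choices open.

## The rigid-body model

Nine bony segments (pelvis plus bilateral femur, tibia, tarsus, and
phalanges) and a torso point mass form a tree rooted at the pelvis.
The root joint is a full 6-DOF free joint (translations in mm,
rotations in degrees); the hip is a ball joint (flexion, adduction,
internal rotation), the stifle a sliding hinge (flexion plus
femorotibial translations prescribed as a cubic-spline function of
flexion — the default knot set gives zero translation, a pure hinge,
which keeps every closed-form test exact), the tarsus a hinge, and the
phalanges are fixed to the tarsus. In the neutral pose all segment
frames are world-aligned with x cranial, y up, and z lateral; each
frame's origin sits at the proximal joint center.

**Units.** Morphometry is in mm and g (the natural units of CT-derived
inputs); dynamics is in SI (m, kg, N, N·m). Conversion happens at the
module boundaries, never inside a recursion.

### Segment inertial properties

Segment mass is the density-weighted voxel sum
$m = \sum_{i=1}^{4}\rho_i P^2 S N_i$ over cortical bone
(2.003 g/cm³), trabecular bone (1.911), muscle (1.06), and fat
(0.95 g/cm³). The inertia tensor about the segment COM is the
voxel-wise parallel-axis sum
$I = \sum_v m_v (\lVert r_v\rVert^2 \mathbb{1} - r_v r_v^\top)$,
optionally re-expressed in anatomical axes. The voxel-summation
realization is this package's own choice of discretization; it is
validated against the closed-form cuboid tensor (agreement within 2%
at 50³ voxels) and is exactly linear in density and equivariant under
rigid rotation of the voxel cloud.

The torso point mass encodes the assumption that body mass is shared
equally between thoracic and pelvic limbs: it equals half the total
body mass minus all bony segments, and is rejected (with a clear
error) if the segments alone reach half the body mass.

### Anatomical coordinate systems

`build_coordinate_system()` implements the landmark constructions for
the pelvis, femur, tibia, tarsus and phalanges with side-specific
ordering of the condylar, malleolar and metatarsal reference axes, so
mirrored limbs produce properly mirrored frames. The published
construction names different origin landmarks for the left and right
phalanges rows; the implementation follows that table verbatim per
side and the asymmetry is preserved deliberately — users supplying
their own landmark sets should provide both `MP25D` and `MPMT`.

### Musculotendon parameters

The packaged roster (`canine_muscles()`) lists 33 musculotendon
actuators with volumes, pennation angles, optimal fiber lengths,
tendon slack lengths and maximum isometric forces; left and right
limbs share one parameter set. Subject scaling uses the bony-segment
length ratio, the fiber/tendon split is then adjusted so that
$f_{adj} + TSL_{adj}$ equals the mid-stance musculotendon length
(an algebraic identity of the adjustment formulas, tested to 1e-10),
and maximum isometric force follows the PCSA rule
$F_{iso} = T \cdot Vol \cdot \cos\alpha / f_{adj}$ with specific
tension $T = 22.5\ \mathrm{N/cm^2}$.

**The pennation term is the cosine.** The projection of pennate fiber
force onto the tendon line of action is $\cos\alpha$, and the roster's
printed forces are reproducible only under the cosine form (21 of 33
rows to better than 1%, including every muscle used as a worked
example; a sine term would give, e.g., 14 N instead of 202 N for the
adductor magnus et brevis). One roster row (rectus femoris, printed
17.3 N against ~64 N from its printed inputs) is internally
inconsistent under either form and is excluded from the
force-reproduction checks.

**Operating-range tuning.** `tune_fiber_operating_range()` rescales
$f_{adj}$ and $TSL_{adj}$ by a common factor (preserving their
proportional split) until the normalized fiber length lies in
[0.8, 1.2] at mid-stance and [0.5, 1.5] over the whole cycle. The
update is a damped (0.5) multiplicative iteration toward the factor
that satisfies the currently most-violated band, aiming 0.02 inside
the band edge to avoid boundary chatter, with a 50-iteration cap;
muscles whose band intervals cannot intersect are flagged untunable
rather than silently accepted. Forces are recomputed from the tuned
fiber lengths.

## Kinematics

Marker preprocessing follows standard practice: a 4th-order
zero-phase (forward–backward) Butterworth low-pass at 6 Hz — the
filter order is unstated in the methodology this package follows, so
4th order is a declared default, not an inference — and quintic-spline
filling of marker gaps shorter than 5 frames. The quintic fit uses
exactly three support frames on each side, so six points determine
the polynomial uniquely and smooth trajectories are recovered without
error; longer gaps and boundary gaps flag the trial invalid. The
filter subtracts the endpoint-to-endpoint linear trend and pads by
odd reflection before filtering, which suppresses the edge transients
of the forward–backward pass and passes constant and linearly
trending signals through unchanged.

Gait cycles are segmented from the vertical ground reaction with a
contact threshold of 2% body weight and a 50 ms debounce (both
declared defaults; the methodology states neither), and all cycle
series are resampled by linear interpolation onto 100 points from 0
to 100% of the cycle.

Marker-based joint angles are included angles (arccos of normalized
dot products) between the pelvis cranial axis and femur axis (hip),
femur and tibia axes (stifle), and tibia and tarsus axes (tarsus),
built purely from marker difference vectors and therefore invariant
under any global rigid transformation of the capture volume.

**Inverse kinematics** solves, frame by frame,
$\min_q \sum_m w_m \lVert \mathrm{virtual}_m(q) - \mathrm{measured}_m
\rVert^2$ by Levenberg–Marquardt with a central-difference Jacobian.
Two numerical details matter. First, the Jacobian uses a fixed
absolute step (1e-4 in mm or degrees): the mixed parameter units make
relative step sizes collapse to machine noise for near-zero
coordinates, which silently stalls the optimizer. Second, each frame
warm-starts from the previous solution (the first frame initializes
the root translation from the pelvis marker centroid), which both
speeds convergence and breaks ties between kinematic branches
consistently. Coordinates that no measured marker can inform are
locked at the model default pose and reported, rather than being left
to drift.

## Dynamics

`inverse_dynamics()` runs a distal-to-proximal Newton–Euler recursion.
Segment angular velocities come from $\dot R R^\top$ with central
differences, accelerations from second central differences of the COM
trajectories (endpoint frames copy their nearest interior neighbor),
matching the 6 Hz-filtered signals they derive from. Ground reactions
sampled at 1000 Hz are block-averaged (anti-aliased) into kinematic
frames rather than decimated; the force is applied at the center of
pressure — the application point is this package's decision — together
with the vertical free torque. The unbalanced root wrench is reported
as the pelvis residual force and moment, the quantities the residual
actuators of a tracking pipeline would supply.

Joint moments are reported work-conjugate to each generalized
coordinate, so moment × coordinate rate is power by construction;
this makes the energy bookkeeping exact (on conservative motions the
integrated joint power matches the mechanical energy change within
2%, dominated by finite-difference error) and means extension-positive
plots are sign flips of the flexion-positive coordinates.

**Simplified residual reduction.** A full tracking-controller residual
reduction is out of scope; `reduce_residuals()` implements an
auditable two-step stand-in: re-filter the coordinates at 6 Hz, then
shift the torso COM cranio-caudally to null the mean pelvis residual
z-moment over stance. Because the torso weight is constant, that
residual is exactly linear in the shift, so the nulling shift comes
from a two-point slope evaluation rather than an opaque search. The
shift is clamped at ±30% of pelvis length and only applied if the
residual RMS does not increase; before/after RMS is always reported
so the simplification stays auditable.

## Muscle mechanics and static optimization

Musculotendon lengths are polyline lengths through origin, via and
insertion points ("via points only": anatomical wrapping is
approximated by fixed intermediate points, not analytic surfaces);
moment arms come from tendon excursion,
$r = -\partial L/\partial\theta$, by central differences with a 0.1°
perturbation, validated against pulley geometry to 0.5%.

The Hill curves are deliberately simple and fully configurable: a
Gaussian active force–length curve (width 0.45), an exponential
passive curve reaching one $F_{iso}$ at 60% strain, and a Hill
hyperbola force–velocity factor ($a/F_{iso} = 0.25$, maximal
shortening velocity 10 fiber lengths/s, eccentric plateau 1.4).
The tendon is rigid: fiber length is the musculotendon length minus
tendon slack, projected through the pennation angle. The rigid tendon
keeps the per-frame force affine in activation, which makes static
optimization a convex quadratic program with a unique optimum —
the standard trade-off for static analyses, at the cost of ignoring
tendon compliance transients.

Static optimization minimizes $\sum_j a_j^2 + \sum_i
(\mathrm{reserve}_i/\mathrm{reserve}_{opt})^2$ subject to moment
balance and $0 \le a_j \le 1$. The methodology this package follows
states the minimum-squared-activation objective in its methods and a
min–max muscle-stress objective in its discussion; the methods wording
is implemented, and the alternative is deliberately not emulated — an
interested user can re-weight the quadratic objective, but no claim is
made about which objective the original platform actually used.
Reserves are eliminated algebraically (reserve = demanded moment minus
muscle torque), leaving a box-constrained QP solved by an exact
active-set method; balance therefore holds to machine precision and
the reserve penalty (optimal moment 1 N·m, so one N·m of reserve costs
as much as a fully active muscle) keeps reserves expensive relative to
muscles. The solver is cross-checked in the tests against a
brute-force activation grid and an independent QP implementation.

## The synthetic gait generator

`generate_morphology()` and `generate_trial()` emulate the study
conditions a desk-scale user cannot collect: a 5.4 kg dog walking at
0.6 m/s with a 0.7 s cycle and 60% stance. Joint waveforms are
3-harmonic Fourier series fitted to plausible hip/stifle/tarsus
knot patterns (hip ~30° stance range, stifle swing flexion ~30°,
tarsus ~35°); they are plausible fixtures, not reproductions of any
measured dog. The vertical ground reaction is a calibrated double-hump
template whose first peak is placed exactly at 51% body weight and
16% of the cycle, with braking for the first third of stance and
propulsion after, a 5% body-weight mediolateral component, and the
center of pressure under the paw. Markers are forward kinematics of
the ground-truth pose plus seeded isotropic Gaussian noise (default
SD 2 mm); ground-truth moments are noise-free inverse dynamics, so
the pipeline closes exactly on clean data.

Two honest limitations follow. First, the contralateral limb is held
at the standing posture by default (markers instrument one limb, as
in single-limb capture protocols; a phase-shifted option exists), so
whole-body dynamic consistency is absorbed by the pelvis residuals —
exactly the role residual actuators play in real pipelines, but it
means the synthetic trials carry larger baseline residuals than a
fully consistent simulation would. Second, the noise model is
isotropic and white: passing the recovery tests demonstrates
robustness to measurement noise, not to soft-tissue artifact, which
is structured, correlated, and larger — real-data performance will be
worse than the synthetic numbers, which is why the validity metrics
are exposed as first-class outputs rather than assumed.

Morphology generation uses coarsened voxel grids (3.25 mm pixels,
5 mm slices — ten times the resolution of a typical CT protocol) so
the grids stay small; the mass formula is resolution-agnostic. The
segment mass budget sums to 0.9 kg at 5.4 kg body mass, so the torso
closes to 1.8 kg under the half-body-mass rule, and voxel counts scale
with body mass (linearity holds up to integer rounding of counts).

## Problem sizes and runtimes

The test suite and the acceptance script run the generator at its
native sizes: 71-frame cycles at 100 Hz, 1000 Hz force plates,
33 muscles, and 20 replicate noisy trials for the recovery
experiment; grid oracles use a 0.001 activation resolution. These
sizes were chosen as the smallest that exercise every code path at
realistic signal bandwidths.

## Known limitations

* Via-point muscle paths cannot wrap smoothly around bone; arms are
  step-continuous where a via point engages.
* The rigid tendon overestimates fiber velocity for long-tendon
  muscles, biasing the force–velocity factor during rapid transients.
* The simplified residual reduction adjusts only the torso COM's
  cranio-caudal position; vertical and mediolateral inconsistencies
  remain in the residuals (visibly reported).
* Angles from the arccos formulas are included angles in (0°, 180°);
  flexion/extension sign conventions ride on the model coordinates,
  not the marker-derived angles.
* No activation dynamics, no metabolic cost, no forward simulation.
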