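---
title: "Forward modelling of T-wave alternans: model, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modelling of T-wave alternans: model, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasim)
```

`twasim` simulates T-wave alternans (TWA) by imposing beat-to-beat changes
of the cellular action potential (AP) in chosen parts of a ventricular
model and solving the forward problem of electrocardiography onto an
inhomogeneous torso. This vignette documents the model in enough detail to
judge what its results do — and do not — say: the governing assumptions,
every tunable parameter with its default and rationale, the numerical
choices, and the design decisions taken where the construction was
genuinely open.

## The ventricular model

Both ventricles are shells between two ellipsoids, truncated by a basal
plane, voxelized on a cubic grid (1 mm by default) and labelled with five
transmural layers: L1 (endocardial, standing in for the sub-endocardial
Purkinje system), L2–L4 (mid-myocardium) and L5 (epicardium). The septum —
left-ventricular wall lying inside the right-ventricular outer ellipsoid —
is labelled LV. The transmural coordinate of a voxel is found by bisection
on the one-parameter family of ellipsoids interpolating the endocardial and
epicardial surfaces (40 iterations, far below voxel resolution), and layers
are slabs of that coordinate.

The published description of this model family fixes the *relative layer
volumes* (as percentages of the whole model) rather than the ellipsoid
dimensions. The default geometry is therefore a calibration product:
semi-axes and wall thicknesses were chosen by hand to land the left/right
volume split, and the per-ventricle layer thickness fractions were then
iterated (`scripts/calibrate_geometry.R`) until the mid-myocardial (L2–L4)
and epicardial shares match the reference table; the apex/base and
posterior/anterior partition planes were placed by scanning voxel-plane
candidates on the 1 mm model. Two points are worth noting:

* equal-thickness layers cannot reproduce the reference volumes — the
  right-ventricular wall needs a relatively thick epicardial slab (its
  thin, strongly curved shell weights volume toward the outer surface
  differently than the LV's); the thickness fractions are therefore
  per-ventricle parameters;
* the partition planes (`ab_split_z`, `pa_split_y`) and the septum-to-LV
  convention are frozen constants of the default geometry, exposed in
  `ellipsoid_params()`.

Ten regional masks follow the AHA 17-segment naming idea: long-axis thirds
(apical/mid/basal, equal thirds of the myocardial z-extent) crossed with
60° circumferential sectors about each ventricle's own axis, measured from
the anterior direction; half-open sector intervals make boundary
tie-breaking deterministic (the lower sector index wins). The septal
regional mask is defined independently on the septal wall (basal third,
inferior half).

The heart sits in the torso under a rigid transform. The default pose
(center `(40, −30, 40)` mm; apex pointing left, anterior and moderately
caudal) was chosen by inspecting the simulated reference 12-lead ECG:
upright T waves in I, II and V2–V6, an inverted T in V1, and the largest
precordial T in V2 — the conventional pattern. No TWA quantity was used in
choosing the pose.

## Action potentials

Each layer's AP is a smooth piecewise template: resting potential −90 mV,
2 ms cosine upstroke to +25 mV, a 10 ms phase-1 decline to the +10 mV
plateau, a constant phase II ending at 62% of the APD, and a cosine-power
phase-3 repolarization that reaches rest *exactly* at a finite time. APD
means APD90 (90% repolarization of the peak-to-rest amplitude); the
end-of-phase-3 time is solved in closed form from the APD90 condition. The
default phase-3 shape exponent is 0.5, which brings the curve from APD90 to
rest in roughly a dozen milliseconds — recorded ventricular APs terminate
briskly, and a slow terminal approach would smear an unphysiological
late-repolarization tail across the end of the T wave.

Layer APDs are `L1 = 378`, `L2 = 312`, `L3 = 334`, `L4 = 330`,
`L5 = 292` ms. The published constraint fixes L1 at 378 ms and the rest to
the range 292–334 ms with L3/L4 longest (the M-cell region) and the
epicardium shortest; the individual values inside that range are this
package's choice and are exposed in `layer_ap_table()`.

The two alternans transformations are `scale_apd()` (scales the APD and the
phase-2/3 boundaries, leaving the upstroke and all voltage levels alone;
composes multiplicatively) and `scale_phase2()` (scales the plateau height
above rest, with a smooth weighting that leaves the upstroke and every
value at or beyond the APD untouched, so amplitude alternans never moves
the APD).

## Activation

Activation times are shortest travel times on the 26-neighbour voxel graph
(Dijkstra), edge cost = Euclidean length ÷ mean of the two node speeds.
Baseline velocity is 0.5 m/s; L1 conducts three times faster, standing in
for the Purkinje network. Four pacing sites (three LV endocardial —
anterior paraseptal, posterior, mid-septal — and one RV septal) start at
0 ms; the classical human isochrone studies motivate the sites but give no
coordinates, so they are placed programmatically on the endocardial layer
and snapped to the nearest L1 node. A graph-distance wavefront
overestimates Euclidean distance by at most ≈12.5% (worst near direction
(2,1,1)); the test suite asserts this bound. The J-point anchor is
`qrs_end()` = last activation + upstroke duration, exact in a noise-free
simulation.

## Equivalent generator

At each time step every pair of face-adjacent voxels contributes an
elementary dipole along the face normal, proportional to the transmembrane
potential difference across the face, split equally between the two voxels;
faces against non-myocardium contribute nothing. A spatially uniform
potential field is therefore *exactly* silent — in particular the ST
segment of the reference beat, where the whole myocardium sits on the
plateau, is flat by construction.

Two scalars complete the generator:

* **Purkinje source weight** (default 0.02). The L1 layer occupies a solid
  shell in the geometry (about 13% of the model volume), but the tissue it
  represents is a sparse network of fiber strands whose membrane-current
  density per unit wall volume is on the order of a few percent of working
  myocardium. Faces touching L1 inherit this weight (the face takes the
  smaller of its two node weights, preserving exact silence of uniform
  fields). Without the weighting, the solid L1 shell's long repolarization
  (378 ms APD) radiates a late wave comparable to the T wave itself — a
  giant "U wave" seen neither in real ECGs nor in published simulations of
  this model family — which buries the end of the T wave and with it every
  QT-alternans effect.
* **Global gain** (default 0.30 × resolution² per face): fixed once by
  `scripts/calibrate_gain.R` so the reference beat's best precordial T wave
  is ≈0.4 mV, which puts imposed-alternans amplitudes in the
  tens-of-microvolts range typical of recordings. The resolution² factor
  makes surface amplitudes grid-independent (the number of faces crossing a
  front scales as resolution⁻²).

For the torso solution, voxel dipoles are summed into cubic blocks (5 mm
default) placed at the block centroid. Halving/doubling the block size
changes body-surface signals by under 3% RMS (tested), and the total heart
vector is conserved exactly, so the vectorcardiogram is
aggregation-invariant.

## Torso volume conductor

The torso is an elliptic cylinder (350 × 250 mm section, 550 mm tall) with
capped ends; lungs and the two ventricular blood pools are ellipsoids with
conductivities ¼ and 3× the torso mean. All compartment surfaces are
closed triangulations (Euler characteristic 2, verified at build time),
mutually non-intersecting (verified analytically against the generating
ellipsoids). The right-ventricular blood pool deserves a note: the true RV
cavity is a crescent between the RV endocardium and the septum, which a
single ellipsoid cannot fill; the model uses a conservative inscribed
ellipsoid, so the RV blood conductivity effect is somewhat
under-represented.

The boundary-element solution uses vertex collocation with the double-layer
formulation: triangle solid angles are analytic (the van Oosterom–Strackee
formula), distributed in equal thirds to triangle vertices; the singular
self-term is fixed by the auto-solid-angle condition (own surface subtends
exactly 2π at each of its vertices); the constant-potential null space is
removed by deflation against the area-weighted torso vertex weights; and
potentials are referenced to a zero *area-weighted* mean over the outer
surface (a plain vertex mean would depend on mesh grading; re-referenced
lead systems are insensitive to the choice either way). Against the
closed-form potential of a central dipole in a homogeneous sphere the
solver is below 2% relative RMS error at 1280 triangles, converging under
refinement (tested). Electrode values are barycentric interpolations on the
torso mesh.

Electrode layouts: a 192-lead body-surface grid (12 rows from z = +165 to
−165 mm × 16 columns starting at the anterior midline and proceeding
leftward, row-major order) and the 9 electrodes of the standard 12-lead
system, with V1/V2 at the parasternal 4th-intercostal level and V3–V6
descending toward the apex. Lead III is computed as II − I so the Einthoven
identity holds bit-for-bit. XYZ leads are the components of the summed
heart vector (x left, y posterior, z cranial).

## Alternans scenarios

Within a chosen topology ∩ layer mask:

* **APD, concordant/discordant**: ×0.96 on even beats, ×1.04 on odd beats;
  discordant pairs apply opposite factors to the two complementary regions
  and swap them with parity.
* **APD, regional**: one-sided ×1.10 on odd beats, reference on even
  beats. The published wording ("a 10% change") contrasts with the explicit
  ± phrasing of the concordant protocol; the one-sided reading is adopted
  and exposed via `magnitude`.
* **Amplitude**: phase-II ×0.90 on the odd beat only; across discordant
  topologies the scaling alternates between the two regions (region A on
  odd, region B on even beats), mirroring the discordant APD construction —
  the published description covers only the concordant case.

Beats are simulated independently on a 0–540 ms window (1 ms step; AP
curves pre-sampled at 0.5 ms and linearly interpolated); there is no
restitution coupling — alternans is imposed, not emergent. The full
catalog is 72 scenarios: APD × {1 concordant + 3 discordant + 10 regional}
× {L2..L5}, plus amplitude × {concordant + 3 discordant} × {L2..L5}.

## TWA metrics

The analysis window is shared by all leads of a recording: it starts at the
J-point and ends at the first sample after the global T peak where the
*across-lead* RMS falls to ≤0.005 mV. A pooled (rather than per-lead) rule
keeps the mean T-wave vectors of the two beats co-registered, which the
vector metrics require; for a beat pair the union of the two windows is
used so both means share one support. The mean T-wave value divides by the
number of samples (not by the window length in ms), making it a true mean
at any sampling rate. Per-lead TWA amplitude is the absolute difference of
mean T-wave values (the differential method); VMA divides the Euclidean
norm of the difference vector by the lead count; VAA is the angle between
the two mean vectors with the cosine clamped to [−1, 1]; identical null
beats get VAA = 0 by convention. The QT interval runs from the global QRS
onset (earliest pacing onset) to the window end; QT alternans is the
absolute beat-to-beat QT difference on the 12-lead recording. Detection
uses the conventional 10 µV threshold, boundary inclusive; maximal-lead
ties resolve in canonical lead order.

A structural consequence worth understanding: the T-wave end is a property
of the *last-repolarizing* tissue. Lengthening the APD of a layer that
still finishes before the longest mid-myocardial layer (L3 here) cannot
move the window end, so QT alternans responds to alternans in the
longest-APD mid layers and is zero for the epicardium — which repolarizes
first — exactly the depth asymmetry the metrics section of the test suite
checks.

## Problem sizes

The default analysis resolution for volume fractions is the 1 mm grid
(~170k myocardial nodes; builds in ~2 s). Scenario catalogs and the
property tests run on a 2 mm grid (~21k nodes) with the default-density
torso (~1900 surface vertices) and finish in about a minute; a 4 mm "tiny"
configuration runs end-to-end in under a second and backs the fast unit
tests. Signal amplitudes are resolution-independent by the gain's
resolution² scaling; volume fractions agree between 1 mm and 2 mm grids to
within 2 percentage points (tested).

## Known limitations

* Fiber anisotropy is omitted; conduction is isotropic within a layer.
* Alternans is imposed (no restitution dynamics, rate dependence or
  electrotonic coupling), and beats are framed independently.
* No noise or interference is added; detection-threshold statements
  describe the noise-free forward model only.
* The torso, lungs and blood pools are analytic shapes, not image-derived
  anatomy; the RV pool is an inscribed-ellipsoid approximation.
* Depth discrimination from body-surface TWA *map patterns* is weaker in
  this geometry than reported for the model family it follows: maps for
  alternans at different depths of the same topology are close to
  proportional here, so map-pattern classifiers for depth should not be
  built on this default geometry without further calibration.
* Which 12-lead location most often carries the maximal TWA amplitude is
  sensitive to the heart-torso geometry; with the default pose the hot
  region sits between the lower precordial electrodes, and V1 — though
  frequently among the top leads — is not the modal maximum.
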