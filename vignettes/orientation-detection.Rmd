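---
title: "Detecting directional DBS lead orientation from CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting directional DBS lead orientation from CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dbsorient)
```

## The problem

A directional deep-brain-stimulation lead carries segmented contacts that
steer current perpendicular to the lead axis. Programming it against the
patient's anatomy requires the lead's rotational (yaw) orientation, which
cannot be assumed from surgery: leads twist during implantation and can
rotate afterwards. On postoperative CT the lead is visible only through its
metal hyperdensity and the streak artifacts it generates, and the dominant
artifact — the hypodense streak pair emitted by the asymmetric stereotactic
marker — is periodic under a 180° rotation. Any method reading orientation
off that artifact therefore ends with two inverse candidates, and the real
problem is deciding between them.

This vignette documents how the package models and solves that problem, the
parameters that matter, and the design decisions that were genuinely open.

## Geometry and conventions

All computation happens in world millimetres (RAS+, as encoded by the NIfTI
affine; sform preferred over qform). A trajectory is a tip point plus a
superior-pointing unit direction, so the polar angle — between the lead and
the scanner z axis — is well defined in [0°, 90°]. Bearings around the lead
are measured from the in-plane projection of world anterior (+Y), increasing
counterclockwise when viewed from superior (towards the patient's left), and
reported in (−180°, 180°]. When the lead axis is numerically parallel to
anterior the +X projection is used instead (with a logged note); this cannot
occur for gate-passing leads, whose polar angle is at most 55°.

Every angular measurement is made on planes *perpendicular to the refined
lead axis*, not on native axial slices. This generalizes the perpendicular
resampling used by the center-of-mass method to all levels and removes any
need for a trigonometric polar-angle correction of measured bearings.

## Pipeline

1. **Trajectory refinement.** For each native axial slice crossed by the
   tip-to-marker segment, the center of mass of voxels above 2000 HU within
   4 mm of the current trajectory is computed; least-squares lines x(z) and
   y(z) are fitted and the procedure iterates (at most 5 times, stopping when
   the tip moves < 0.01 mm). Only the rotationally symmetric shaft below the
   marker band is used: the marker's angular window is asymmetric by design
   and would bias the fit. The 2000 HU threshold reuses the binarization
   threshold of the COM method; the regression is unweighted because slice
   artifact mass carries no obvious information about center quality.
2. **Polar gate.** ≤ 40° ok; 40–55° warn (reduced confidence); > 55°
   refuse. The artifacts the pipeline depends on fade with polar angle, and
   beyond 55° detection is not meaningful.
3. **Slice selection.** The marker slice is found by scanning offsets of
   ±1.5 mm (step 0.25 mm) along the axis and maximizing the second-harmonic
   amplitude of the angular profile; ties break towards the nominal center,
   and a maximum at the search boundary raises a truncated-search warning.
   Star slices are selected the same way per directional level, maximizing
   the third harmonic (the dark-star pattern is 120°-periodic).
4. **Candidate detection.** With intensities I(αk) sampled on a circle of
   radius 3 mm (360 samples) and c2 = Σ I(αk)·exp(2·i·αk), the dark-streak
   axis is arg(−c2)/2. The phase of one Fourier mode is used rather than
   discrete valley-picking: it has sub-degree resolution, is exactly
   invariant to constant offsets, first-harmonic asymmetries and affine
   intensity rescaling, and is analytically testable (the suite asserts
   exact recovery, to 1e-6 degrees, on a closed-form profile). The facing
   candidate is the streak axis plus a configurable streak-to-face offset
   (0° by default, see *Lead geometry* below).
5. **Ambiguity resolution.** Four methods decide between θ and θ + 180°,
   described next; the final answer follows COM, with the others as
   cross-checks. Disagreement of any non-degenerate method raises a mismatch
   flag. If COM is degenerate the decision falls back to COMsagittal, then
   STARS, then ASM, and confidence drops to "reduced"; when all four are
   degenerate an unresolved-ambiguity error reports both candidates rather
   than guessing.

## The four ambiguity methods

**COM.** The marker band is resampled perpendicular to the axis at 0.1 mm
into a slab of slices (one per 0.25 mm over marker ± 1.5 mm) and binarized
at 2000 HU. The marker's angular window removes metal on the side opposite
the facing direction, so the pooled center of mass shifts toward the true
orientation. The deviation is measured *differentially*: the same pooled COM
is computed for two reference slabs on the cylindrically symmetric shaft
just below and above the marker (0.5 mm clearance, 2 mm span), and their
mean is subtracted. Because the reference slabs see the same voxel grid and
the same residual trajectory error, partial-volume bias and small
misalignments cancel and only the marker asymmetry survives. This matters:
the binarized COM of a ~1.3 mm metal disk sampled at 0.5 mm voxels carries
grid-quantization bias of the same order as the genuine asymmetry signal
(~0.12 mm), and without the reference the decision degrades noticeably at
moderate tilts. The candidate whose in-plane unit vector has the larger
projection on the deviation wins; the margin is that projection times the
deviation magnitude over a 0.1 mm scale.

**COMsagittal.** An in-line slice containing the lead axis and the candidate
axis (marker ± 1.5 mm axially, ± 5 mm transversely, 0.1 mm pixels) is
binarized the same way; the sign of the transverse COM component makes the
decision, again referenced against the shaft above and below.

**ASM.** The marker artifact is brighter towards the facing direction, so
the heights of the two bright peaks of the angular profile are compared:
peak height for a candidate is the raw maximum intensity within ±30° of its
bearing ("peak height" is not defined more precisely by the method's
originators; the raw maximum is the simplest faithful reading). The margin
is the height difference in units of the profile standard deviation.

**STARS.** At each directional level the expected one-sided streak bearings
for candidate θ are θ + 60° + 120°·m (the inter-segment gaps; segments sit
at facing and facing ± 120°). The score is the mean profile intensity minus
the mean intensity in ±15° windows at those bearings, normalized by the
profile standard deviation — observed dark streaks at the expected bearings
make the score large. Scores are summed over both directional levels (the
method is defined "at the level of the segmented contacts" without
specifying one; using both maximizes signal). Because 180° ≡ 60° (mod 120°),
the two candidates probe interleaved bearings and separate cleanly. Levels
whose third-harmonic amplitude never reaches the artifact floor are skipped;
if no level has a detectable star pattern the method is degenerate rather
than an amplifier of numerical noise.

**Margins and degeneracy.** Each method reports a nonnegative normalized
margin; a single floor (0.05) defines degeneracy across methods, and COM
deviations below 0.02 mm are degenerate outright (indistinguishable from the
geometric center). Margins are constructed to be invariant under affine
intensity rescaling (ASM, STARS) or global volume translation
(COM, COMsagittal).

## Profile pooling

The candidate bearing is estimated from a pooled profile: angular profiles
are averaged over a slab of axial offsets (± 1 mm, step 0.25 mm) around the
selected marker slice and over sampling radii 2.5/3/3.5 mm. The marker
artifact fills that axial and radial envelope, so pooling keeps most of its
amplitude while averaging down HU noise; on the standard noisy suite it
brings worst-case orientation error from ~5° to below 2°. ASM uses the same
pooled profile as candidate detection (the slice ASM should use is not
specified by its originators; sharing the auto-selected marker slice keeps
the two measurements consistent).

## Lead geometry

The shipped `cartesia` profile places the marker center 10.6 mm and the two
directional levels 2.75/4.75 mm above the tip, with a 0.65 mm shaft radius
and a ± 1.5 mm marker half-length. Only the marker half-extent is documented
in the method literature; the remaining constants are configuration values
that must be verified against manufacturer documentation before any
clinical-style use. Tests use the same profile for the phantom and the
detector, so their correctness is self-consistent by construction. Two
angular offsets keep physical conventions configurable rather than baked in:
`marker_streak_offset_deg` (streak axis vs. facing direction, default 0°)
and `star_gap_offset_deg` (first dark-star streak vs. facing direction,
default 0°, i.e. streaks at the inter-segment gaps). If calibration against
real leads showed e.g. the COM shifting *away* from the facing direction,
the phantom and decision conventions would be flipped together by
reconfiguring these offsets — they encode exactly the facts the method
literature leaves open.

## The synthetic phantom

The phantom models artifact *phenomenology*, not CT physics: there is no
beam-hardening or photon-starvation simulation, only the HU geometry that
the detection operations actually consume. In the lead frame it contains

- a metal shaft (3000 HU) of radius 0.65 mm, with a central 0.2 mm stylet;
- the marker band (marker center ± 1.5 mm) with an angular window of 90°
  centred opposite the facing direction — metal mass, and hence the
  binarized COM, shifts toward the true orientation;
- the marker streak artifact: two hypodense Gaussian streaks (depth 150 HU,
  angular σ 10°) along facing and facing + 180°, plus a first-harmonic
  brightness asymmetry (+60 HU toward the facing direction), under a shared
  axial (σ 1.5 mm) and annular radial (peak 3 mm, σ 1.5 mm) envelope;
- a one-sided dark star at each directional level: three 100 HU dips at the
  gap bearings, axial σ 1 mm;
- i.i.d. Gaussian HU noise (default σ 15) from a per-phantom seed, and an
  optional 3D Gaussian smoothing emulating a reconstruction kernel.

Voxel values are *volume averages*, not point samples: near the metal
boundary the field is averaged over a 3×3×3 sub-voxel grid. Partial-volume
mass at the windowed marker is the very signal the COM methods measure, and
point sampling under-models it badly — with point-sampled voxels the
binarized marker COM at 0.5 mm voxels is dominated by grid quantization.

The artifact amplitudes (60/150/100 HU) and the 90° window are not
real-lead measurements; they were chosen once so that all four methods have
workable signal at σ = 15 HU noise and 0.5 mm voxels. Consequently the
phantom suite demonstrates that the *pipeline logic* is correct under
realistic noise and tilt — it cannot validate the physical conventions
(which direction the COM actually shifts on a Cartesia lead, where streaks
sit relative to the marker face), which only real, X-ray-confirmed scans
can. Passing tests therefore show algorithmic correctness, not clinical
calibration.

The standard suite crosses the full yaw circle (0–345°, 15° steps) with
polar angles {0°, 15°, 30°, 45°} at noise σ 15 HU and 0.5 mm voxels — 96
phantoms with per-phantom seeds. On it, COM resolves the ambiguity in 96/96
cases and the final orientation stays within 2° of truth up to 40° polar;
the secondary methods are held to a ≥ 90% floor on the polar ≤ 30° subset.
These suite sizes keep the whole validation run at around a minute on one
CPU; unit tests use a smaller 30×30×42 mm volume with the same lead.

## Numerical choices and degenerate inputs

- Interpolation is trilinear everywhere. It is exact on multilinear fields,
  which gives the resampler a closed-form correctness test, and is as smooth
  as HU averaging requires.
- Out-of-volume samples return −1024 HU (air) instead of erroring; sampling
  circles may legitimately graze the volume edge. A resampling plane wholly
  outside the volume is an error.
- The trajectory must produce suprathreshold centers of mass in at least 5
  slices, otherwise an insufficient-artifact error names the problem.
- A marker profile whose second-harmonic amplitude is below 10 HU is treated
  as artifact-free (no-artifact error): with 360 samples, pure noise at
  realistic σ produces amplitudes well below this, while a real marker
  artifact at gate-passing tilts sits far above it.
- Slice-search ties break toward the nominal center; an argmax at the search
  boundary is returned but flagged with a truncated-search warning.
- Exactly symmetric inputs (a windowless, asymmetry-free lead) drive every
  method's margin to zero and produce the unresolved-ambiguity error; this
  is asserted in the suite rather than left to chance.

One validation detail deserves a note: the analytic oracle for the COM
method (the closed-form center of mass of the windowed annulus) is compared
on a noise-free 0.2 mm phantom tilted by 7°. A mathematically perfectly
grid-aligned lead at polar 0° makes every slice share one voxel-grid phase,
so voxelization bias adds coherently — a pose with measure zero in practice;
the small tilt restores the phase averaging that any real acquisition has.

## Known limitations

- Geometry constants and artifact conventions for the Cartesia lead are
  configuration, not validated measurements; other manufacturers' leads are
  configurable via `lead_spec()` but entirely unvalidated.
- One lead per hemisphere is assumed: a second lead's hyperdensity inside
  the 4 mm refinement tube or the 10 mm COM window would corrupt both.
- Trajectory refinement assumes an axially acquired CT (third voxel axis
  along the scanner z).
- MRI–CT coregistration and automatic lead *detection* are out of scope; the
  two trajectory coordinates are inputs.
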