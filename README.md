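# dbsorient

Fully automated detection of the rotational orientation of a directional
deep-brain-stimulation (DBS) lead from a postoperative CT scan.

Directional DBS leads steer current perpendicular to the lead axis through
radially segmented contacts, so relating stimulation to the surrounding
anatomy requires knowing how the lead is rotated about its own axis (its
*yaw*, reported here relative to anterior). Leads rarely end up at the
intended orientation and may rotate after implantation, so the orientation
must be read off postoperative imaging. On CT, the lead's asymmetric
stereotactic marker and its segmented contacts produce characteristic metal
streak artifacts whose angular pattern encodes the orientation — but the
dominant marker artifact is symmetric under a 180° rotation, so analyzing it
naively leaves two inverse candidate solutions.

`dbsorient` implements the complete pipeline:

1. **Trajectory refinement** — from two user-supplied points on the lead, the
   trajectory is refined by fitting least-squares lines x(z), y(z) to
   slice-wise centers of mass of the metal hyperdensity (> 2000 HU) inside a
   4 mm tube around the current estimate.
2. **Polar-angle gate** — artifacts fade as the angle between lead and
   scanner axis grows: ≤ 40° ok, 40–55° reduced confidence, > 55° refused.
3. **Artifact slice selection** — the marker slice is auto-selected by
   scanning ±1.5 mm along the axis for the strongest 180°-periodic streak
   pattern (second circular harmonic of the angular intensity profile).
4. **Candidate orientations** — HU intensities are sampled on a circle
   perpendicular to the lead axis; with `c2 = Σ I(αk) exp(2 i αk)`, the
   hypodense streak axis is `arg(−c2)/2`, giving the candidate pair
   {θ, θ + 180°} with sub-degree resolution.
5. **Ambiguity resolution** — four independent methods pick between θ and
   θ + 180°:
   - **COM**: binarized (> 2000 HU) center of mass of the marker metal in
     perpendicular 0.1 mm slices; the asymmetric marker shifts the COM
     toward the true orientation (measured differentially against the
     symmetric shaft above and below the marker).
   - **COMsagittal**: the same decision from an in-line slice through the
     lead axis spanning the marker ± 1.5 mm.
   - **ASM**: compares the heights of the two bright peaks of the angular
     profile (the marker artifact is brighter toward the true orientation).
   - **STARS**: compares similarity of the observed 120°-periodic one-sided
     "dark star" streaks at the segmented-contact levels with the streak
     template expected under each candidate.

   The final orientation follows COM; the other methods cross-check it and
   disagreements are flagged for review.

A synthetic phantom generator (`generate_phantom()`, `phantom_suite()`)
produces CT volumes with known ground-truth orientation, embedding every
artifact feature the methods rely on, so the whole pipeline is testable
without patient data.

## Worked example

```r
library(dbsorient)

# a synthetic lead: true yaw 30 deg (from anterior), polar tilt 20 deg,
# realistic HU noise
spec <- phantom_spec(yaw_true_deg = 30, polar_deg = 20,
                     noise_sigma_HU = 15, seed = 1L)
ph <- generate_phantom(spec)

report <- run_detect(ph$ct,
                     tip  = ph$truth$tip_world,
                     head = ph$truth$tip_world + 10 * ph$truth$unit_dir)
print(report)
#> <detection_report> orientation 29.39 deg (polar 20.4 deg, gate ok, confidence ok)

round(report$candidate_pair, 2)
#> [1]  29.39 209.39
```

The candidate pair are the two inverse solutions read off the marker streak
axis (the true yaw is 30°; the estimate is 0.6° off at this noise level).
All four ambiguity methods picked the 29.39° member, each with its decision
margin (a normalized distance of the decision statistic from indifference;
below 0.05 a method is flagged degenerate and excluded):

```r
for (m in report$methods)
  cat(sprintf("%-11s -> %6.2f deg  margin %5.2f\n",
              m$method, m$chosen_theta_deg, m$margin))
#> COM         ->  29.39 deg  margin  1.25
#> COMsagittal ->  29.39 deg  margin  1.65
#> ASM         ->  29.39 deg  margin  1.76
#> STARS       ->  29.39 deg  margin  4.33
```

A command-line front end is installed with the package
(`system.file("cli", "dbsorient", package = "dbsorient")`):

```sh
dbsorient phantom --yaw 30 --polar 20 --seed 42 --out phantom.nii --truth truth.json
dbsorient detect  --ct phantom.nii --tip 0,0,-15 --head 2.59,0,-5.3 --out report.json
dbsorient suite   --out results.csv --summary summary.json
```

`detect` exits 0 on success, 2 when the polar gate refuses the scan, 3 when
the ambiguity is unresolved, 4 on I/O errors and 5 on invalid arguments.

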