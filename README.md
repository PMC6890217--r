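# tripoint

Accuracy analysis for guided dental-implant placement from three anatomical
landmark pairs.

## The problem

After guided implant surgery, the placed implant is compared with the
surgical plan. The plan lives in the preoperative CBCT volume (image space
**P**), the outcome in the postoperative volume (image space **R**); the two
volumes are unrelated coordinate systems, so planned and placed implant
positions cannot be compared directly. Commercial registration software is
closed, expensive, and — crucially — reports no *registration system error*,
so the measurement uncertainty of published accuracy studies is unknown.

`tripoint` implements an open tri-point method for researchers evaluating
guide templates: it registers the two spaces from anatomical landmarks
digitized in both images (pulp angles, crown pits, root tips), grades the
landmarks, reports a per-case system error, and computes ten standard
implant accuracy indicators. No DICOM/STL handling — landmark and implant
endpoint coordinates are digitized upstream in any viewer and fed in as CSV
(millimetres).

## The method

**Relative frame from three points.** Three noncollinear points A, B, C
define an orthonormal right-handed frame: origin A, x̂ = AB/|AB|,
ŷ = unit rejection of AC from x̂ (in-plane, on C's side),
ẑ = unit(AB × AC). Expressing a point G in this frame is the projection of
G − A onto the axes — an isometry. Building the frame from the *same three
anatomical landmarks* in P and in R realizes one common anatomical system
**N** in which both implants are directly comparable.

**Landmark grading by triangle congruence.** For landmarks i, j the edge
discrepancy is the relative length difference of segment ij between the two
images, ‖ij‖ = ||P_ij| − |R_ij|| / (½(|P_ij| + |R_ij|)). A triangle's error
is E_t = ‖ab‖ + ‖ac‖ + ‖bc‖ + t with t = max − min of the three
discrepancies (side-side-side congruence: E_t = 0 iff the two triangles are
congruent; proportional edge changes are penalized less than uneven ones).
A landmark's error E_i sums E_t over every triangle it forms with the pool.
While more than three landmarks remain, the worst (max E_i) is eliminated
and the scores recomputed; the three survivors are the **basic triple** used
for registration, and the residual distance in N of the held-out 4th-ranked
pair is the reported **system error** — a self-check every case carries.

**Ten indicators.** With â the planned axis (coronal → apical, unit):

| | coronal | apical |
|---|---|---|
| global (3-D distance) | CGD | AGD |
| vertical = signed depth, (Δ·â) | CVD | AVD |
| lateral = ⊥ component | CLD | ALD |
| rectified (depth-matched) | CRD | ARD |

plus **AD**, the angle between the two implant axes (degrees), and **HS**,
the cover-screw height used to correct the digitized coronal point when the
platform is hidden on CBCT. CVD/AVD are positive when the implant sits
*deeper* than planned. CRD/ARD slide the placed implant along its own axis
until its coronal depth matches the plan, isolating template accuracy from
the surgeon's manual depth adjustment (CBCT underestimates new bone, so
depth is often adjusted intraoperatively on purpose).

## Worked example

A synthetic case with known ground truth: 16 landmark pairs over a jaw-scale
region, 0.05 mm digitization noise in both images, and a true deviation of
5° angular, 0.5 mm coronal lateral, 1 mm depth:

```r
library(tripoint)
case <- generate_case(synthetic_config(noise_sigma = 0.05, seed = 42))
res <- analyze_case(case$landmarks, case$planned, case$real)
res$registration
#> <trip_registration>
#>   basic triple   : L07, L10, L16
#>   system error   : 0.0356 mm (held-out pair 'L15')
#>   implant length : planned 10.000 mm, real 10.000 mm
res$report
#> <accuracy_report>  (CVD/AVD sign: + = deeper than planned)
#>   HS    0.000 mm   AD    4.696 deg
#>   CGD   0.987 mm   CVD  +0.849 mm   CLD   0.503 mm   CRD   0.437 mm
#>   AGD   1.541 mm   AVD  +0.815 mm   ALD   1.308 mm   ARD   1.239 mm
#>   system error: 0.0356 mm
```

Reading: the registration self-check (0.036 mm) is far below the measured
deviations, so they are real. The recovered AD of 4.70° against a true 5°,
and CGD 0.99 mm against a true 1.12 mm, show the residual effect of 0.05 mm
landmark noise; with `noise_sigma = 0` the pipeline recovers
`case$truth` to 1e-6 (this is an acceptance test).

From the command line (the same pipeline):

```sh
Rscript inst/exec/tripoint simulate --seed 42 --noise-sigma 0.05 \
    --out-landmarks landmarks.csv --out-implants implants.csv
Rscript inst/exec/tripoint analyze --landmarks landmarks.csv \
    --implants implants.csv --out report.json
```

Subcommands: `rank`, `register`, `analyze`, `simulate`, `sweep-count`,
`sweep-spread`; see `--help` on each. Every error path exits nonzero naming
the file, line and rule violated.

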