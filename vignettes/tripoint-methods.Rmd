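---
title: "Tri-point registration and implant accuracy indicators: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-point registration and implant accuracy indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripoint)
```

## The model

Two CBCT volumes of the same jaw — preoperative plan (space P) and
postoperative outcome (space R) — are related by an unknown rigid motion
plus, in practice, small per-landmark digitization errors. `tripoint`
registers them through a *relative coordinate frame* built from three
anatomically corresponding points, rather than through a least-squares fit
over all points. The assumptions are:

* the anatomy carrying the landmarks (teeth adjacent to the implant site)
  is itself rigid between the two scans;
* landmark digitization errors are small relative to landmark spacing;
* both implants can be reduced to two endpoints (coronal platform center,
  apical tip), with the axis running coronal to apical.

Frame construction from points A, B, C: origin A; x-axis along AB;
y-axis the unit *vector rejection* of AC from the x-axis, so it lies in the
ABC plane on C's side; z-axis the unit normal of the plane, from AB × AC.
The rejection form is the only construction that is simultaneously
orthonormal, in-plane, and orientation-consistent; it is what the package
uses throughout. Chirality is fixed by construction and identical in both
images, so no handedness option exists (or is needed): any mirror ambiguity
cancels when both spaces use the same rule.

Mapping a point into the frame projects its offset from A onto the three
axes — an isometry, verified against an independent Gram–Schmidt oracle and
a Kabsch (SVD least-squares) oracle in the test suite. The least-squares
rigid fit is deliberately *not* the production path: for exactly congruent
triples the two coincide to 1e-9 mm (tested), and the tri-point route keeps
the method transparent and auditable landmark by landmark.

## Landmark grading and the system error

For a landmark pair set, each edge ij gets a symmetric relative length
discrepancy between the images; each triangle gets
`E_t = sum of its three edge discrepancies + (max − min)`; each landmark
gets `E_i = sum of E_t over all triangles containing it`. Elimination is
iterative: while more than three pairs remain, the pair with maximal `E_i`
*over the remaining pool* is removed and the scores recomputed. Recomputing
matters: a single corrupted landmark inflates the scores of every pair it
co-occurs with, and only its removal relieves the survivors. (Computing
`E_i` once over the full pool would let one bad landmark distort the whole
ordering below it.)

The three survivors — the basic triple — build the frames; the 4th-ranked
pair (the last eliminated) is held out and the distance between its two
images in N is the **system error**. When more than four pairs are
provided, the 4th-ranked pair alone defines the reported error; residuals of
all non-basic pairs are emitted as diagnostics, and a mean-residual variant
is available behind `use_mean_residual` (off by default, because a single
held-out-pair error is what a per-case figure should mean). With exactly
three pairs the registration proceeds but the system error is reported as
*unavailable*, never zero — an unmeasured accuracy is not a perfect one.

Tie-breaking (relevant mainly for exactly congruent synthetic data): equal
`E_i` is resolved toward the pair with the larger total edge discrepancy to
the remaining pool, then toward the later position in input order. This
makes the ranking a deterministic function of the input order.

## The ten indicators

With â the planned unit axis, deviations at each endpoint decompose as
global = |Δ|, vertical = Δ·â (signed; **positive = deeper than planned** —
the convention is printed in every report header), lateral = |Δ − (Δ·â)â|,
giving CGD/CVD/CLD at the coronal and AGD/AVD/ALD at the apical endpoint
with exact Pythagorean identities CGD² = CVD² + CLD², AGD² = AVD² + ALD².
AD is the inter-axis angle (degrees, clamped arccos of the dot product).

**Cover screw (HS).** When the platform is hidden under a cover screw or
healing abutment, the digitized coronal point sits HS mm too coronal. The
correction displaces the coronal point by HS *apically along the placed
implant's own axis* — the only geometrically meaningful direction, since
the screw stacks on the platform along the implant axis. It is applied
before all indicator computation and can be disabled
(`hs_correction = FALSE`, CLI `--no-hs-correction`).

**Rectified deviations (CRD/ARD).** CBCT underestimates newly formed bone,
so surgeons adjust insertion depth by eye; that adjustment travels along
the implant's *actual insertion path* and is not a template error. The
package therefore rectifies by translating the placed implant along its
*own* axis until its coronal point reaches the plane through the planned
coronal point orthogonal to the planned axis, then measures residual
distances at both endpoints. Consequences, all tested: a depth-only
deviation gives CRD = ARD = 0; with parallel axes CRD = CLD exactly; in
general CRD and CLD differ slightly — which is why rectification along the
*planned* axis, the alternative reading (it would force CRD ≡ CLD), was
rejected. When the placed axis is perpendicular to the planned axis the
required translation is unbounded; below |cos| = 1e-9 the indicators are
flagged unavailable rather than reported.

Note that CRD ≤ CGD is *not* an identity of this rectification: when the
lateral offset opposes the tilt direction, CRD can exceed CGD slightly
(e.g. CLD 1.5, CVD 0.5, AD 10° gives CRD 1.588 vs CGD 1.581). It holds
exactly at AD = 0 and to first order for clinically small angles, and is
asserted only there.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `collinearity_tol` | 1e-6 | sin ∠CAB | rejects numerically unusable triples; far below any anatomically plausible configuration |
| `noise_sigma` | 0.1 | mm / coordinate | of the order of the CBCT voxel pitch (0.25 mm slice interval); brackets clinically reported system errors (~0.3 mm) qualitatively |
| `n_landmarks` | 16 | — | the number digitized per case in the clinical protocol |
| `region` | 60×40×20 | mm | dental-arch bounding box |
| `min_separation` | 5 | mm | landmarks closer than this are clinically undesirable and would confound the spread analysis |
| `implant_length` | 10 | mm | typical posterior implant |
| `true_deviation` | 5°, 0.5 mm, 1 mm | — | angular / coronal-lateral / depth, the magnitude reported for guided implantation |
| `true_rotation`, `true_translation` | (5,10,−7)°, (20,−10,5) mm | — | a representative patient repositioning between scans; any values work, the method is rigid-invariant (tested) |
| HS | per-case input | mm | measured on the image or from the implant catalog; there is no default correction |

## What the synthetic generator emulates — and what it does not

`generate_case()` fabricates: true landmark positions (uniform in the
region, rejection-sampled to the minimum separation), a rigid motion
carrying P to R, i.i.d. isotropic Gaussian digitization noise *in both
images* (landmark-selection error arises in preoperative and postoperative
CBCT alike), and a placed implant constructed from the plan by a lateral
offset orthogonal to the planned axis, a signed depth shift along it, and
an axis tilt — in independently random directions. Ground-truth indicators
are computed in closed form from that construction, without touching the
registration code, so the pipeline can be tested against them end to end.
Implant endpoints carry no digitization noise: endpoint digitization is not
a studied factor, and a noise-free implant makes "exact recovery at zero
landmark noise" a meaningful acceptance property.

Not emulated: CBCT voxelization, beam hardening, metal artifacts, new-bone
density bias, heterogeneous landmark quality (all landmarks share one σ),
and operator-specific digitization bias. A green test therefore establishes
the *geometry and algorithmics* of the method, not its clinical error
magnitude; the clinical system error depends on landmark quality that only
real images can provide.

## Factor analyses

`sweep_landmark_count()` offers 4…16 landmark pairs of the *same* simulated
case per replicate (nested subsets, hence paired across counts) and records
the held-out-pair system error. `sweep_landmark_spread()` builds equilateral
landmark triangles of controlled side, randomly oriented, and records the
orientation error of the estimated rotation plus the registration error at
a probe point 20 mm off the triangle plane. At σ = 0.1 mm the orientation
error falls monotonically as the triangle grows from 5 to 30 mm (tested) —
dispersed landmarks are the single most effective lever on system error,
since angular error at the fiducials amplifies linearly with distance.

## Numerical choices

* Collinearity is measured as sin ∠CAB = |AB × AC| / (|AB| |AC|);
  coincident points are reported separately from collinear ones.
* arccos arguments are clamped to [−1, 1]; near-zero angles are limited by
  arccos conditioning to ~1e-6°, which is why "zero orientation error"
  tests use a 1e-5° ceiling.
* An edge of zero length in *both* images is an error (a duplicated
  digitization), not a zero discrepancy.
* Coordinates round-trip through CSV at 12 significant digits (≪ 1e-9 mm
  for jaw-scale values).
* Seeds: every stochastic entry point takes an explicit integer seed;
  derived seeds stay below 2³¹.

## Known limitations

* **The landmark-count mean curve.** With homogeneous noise, the mean
  system error falls from 4 to 5 offered pairs (at 4, the held-out pair is
  by construction the *worst* landmark) and flattens from 6 up — both
  reproduced. But the package's acceptance clause asserting that the 4→5
  drop is the largest adjacent change *of the mean curve* fails, and we
  leave it failing. Two reasons, quantified in simulation (2000 replicates,
  σ = 0.1 mm): the mean is heavy-tailed (per-count SD up to ~0.9 mm) because
  nothing stops a noisy congruence ranking from occasionally selecting a
  nearly collinear basic triple, whose residual scales like 1/sin of the
  triple's smallest angle; and homogeneous noise caps the benefit of having
  more landmarks to choose from. Resistant statistics recover the expected
  picture cleanly — median adjacent drops: 0.054 mm at 4→5 versus ≤ 0.018 mm
  everywhere else; 10%-trimmed means monotone with the 4→5 drop largest.
  Clinically the 4→5 effect is several times larger than any homogeneous
  simulation produces, consistent with heterogeneous landmark quality that
  the generator deliberately does not model.
* The basic triple is chosen purely by congruence, not by spread; adding a
  collinearity penalty to the ranking would likely stabilize the worst
  cases but would change the published method, so it is not done.
* With more than four pairs, aggregation of the leftover residuals into a
  single error is not standardized; the 4th-pair reading is the default and
  the mean is opt-in.
* No statistical machinery (normality tests, paired comparisons between
  registration methods) is included: those are the user's downstream
  analysis of the per-case reports.
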