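---
title: "Calibrating a six degree-of-freedom joint-testing robot: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a six degree-of-freedom joint-testing robot: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointcal)
```

## The problem

Biomechanical joint testing with an industrial six degree-of-freedom robot
needs three quantities before the robot can reproduce a physiological motion:

1. the **coordinate transformation** between the optical tracker that records
   the manual motion (here called the ARAMIS frame) and the robot world frame;
2. the **tool centre point (TCP)** — for a ball joint such as the hip, the
   joint rotation centre (JRC) about which the robot must pivot;
3. the **length of tool (LOT)** — the distance from the TCP to the centre of
   the robot flange, i.e. the specimen-plus-holder length.

`jointcal` implements the full calibration chain: paired calibration poses are
recorded in both frames, the frame transform is estimated, the manually
recorded joint trajectory is fitted with a robust sphere model to locate the
JRC, and the trajectory itself is mapped into robot coordinates. All lengths
are millimetres, frames are right-handed, and pose indices are 1-based.

## Frame transformation: zeroing plus unconstrained least squares

The estimate proceeds in two steps. First both recordings are *zeroed*: the
first calibration sample is subtracted from every sample in its frame
(`zero_shift()`), which removes the translation and pins the two frames
together at pose 1. Second, with zeroed coordinates collected column-wise in
$3 \times n$ matrices $A$ (optical) and $R$ (robot), the linear map is the
normal-equation solution of $R = T_{A \to R} A$:

$$T_{A \to R} = R\,A^{\mathsf T}\,(A\,A^{\mathsf T})^{-1},
\qquad T_{R \to A} = T_{A \to R}^{-1}.$$

Two properties of this estimator matter in practice:

* **It is not a Procrustes fit.** No orthogonality constraint is imposed; the
  solution is the unconstrained least-squares $3\times3$ map. On noise-free
  rigid data it comes out orthogonal anyway (the suite checks
  $\lVert T^{\mathsf T}T - I\rVert_\infty < 10^{-9}$); under noise it absorbs
  small shears. This is deliberate: the package reproduces the published
  estimator exactly. Users who want a guaranteed rotation can pass
  `orthogonalize = TRUE` to `estimate_transform()`, which projects the
  solution onto the nearest proper rotation by polar decomposition — off by
  default.
* **Conditioning is guarded, not assumed.** $A A^{\mathsf T}$ is "generally
  invertible", but real pose schedules can be degenerate (all poses near one
  plane through the origin after zeroing). The estimator refuses when
  $\mathrm{cond}(A A^{\mathsf T}) > 10^{12}$ (`cond_limit`) and requires
  $n \ge 4$ poses (`min_n`; three suffice generically but give no margin).

Orientation angles that trackers export alongside positions are parsed and
carried through I/O as metadata, but never enter the estimation — the
transformation equations use positions only.

## Locating the joint rotation centre: robust sphere fitting

A ball-joint trajectory satisfies
$(x-x_m)^2 + (y-y_m)^2 + (z-z_m)^2 = R^2$. Substituting
$p_1 = x_m^2+y_m^2+z_m^2-R^2$, $p_2 = -2x_m$, $p_3 = -2y_m$, $p_4 = -2z_m$
linearises it to $p_1 + p_2 x + p_3 y + p_4 z = -(x^2+y^2+z^2)$, so $n$
samples give an $n \times 4$ linear system solvable through its normal
equations (`fit_sphere_linear()`). That direct solve is fast but fragile: an
unfavourable condition number or a handful of disturbed samples can ruin it.

The robust route (`fit_sphere_robust()`) therefore solves the *exact* 4×4
system for **every four-point combination** of the measurements
(`enumerate_4pt_combinations()`, all $\binom{n}{4}$ quadruples; the published
count formula $n!/4!$ disagrees with its own worked five-measurement example,
so the complete enumeration is used). Degenerate quadruples — coplanar points,
or a non-positive squared radius — are flagged invalid rather than thrown, so
the sweep never aborts. The ensemble of per-quadruple parameters
$(x_m, y_m, z_m, R)$ is then pruned by **iterative sigma-threshold
rejection**: per iteration, the mean and population standard deviation of each
parameter are computed over the survivors and every fit whose *any* parameter
deviates from its mean by more than `k_sd` standard deviations is removed.
The conjunction rule ("any parameter") is the conservative reading of the
procedure; `k_sd` defaults to 1 (a plain ±SD band) and the rule is applied
`iterations = 4` times, stopping early on a fixed point or when a further cut
would leave fewer than two survivors. The final sphere is the arithmetic mean
of the surviving parameters, reported with their population SDs.

### Sphericity, and why the default tolerance is 5 mm

The surviving parameter SDs measure how sphere-like the trajectory is
(`assess_sphericity()`); the cut-off is the caller's, since it depends on the
positional tolerance of the test that follows. The pipeline default is
`sphericity_tol = 5` mm, which deserves justification: exact minimal
(four-point) solves amplify marker noise roughly tenfold, so at the rig's
0.1 mm noise a *genuine* ball joint shows ensemble SDs of 1–2 mm, while even a
mildly aspherical joint (a few percent radius anisotropy) shows tens of
millimetres. A 1 mm gate would reject real spheres at realistic noise; 5 mm
separates the two regimes cleanly at the default noise level. The TCP route
(`compute_tcp()`) refuses non-spherical trajectories unless overridden,
because reproducing motion about a fixed centre is only meaningful for ball
joints; the trajectory route has no such gate and works for any joint shape.

### Combinatorial cost

$\binom{n}{4}$ grows quickly (a 230-sample recording has ~115 million
quadruples). Above `max_combinations` (default 200,000) the sweep uses a
seeded uniform subsample of quadruples (drawn directly and deduplicated),
which is deterministic for a given `seed`. The batch 4×4 solves are compiled
code (RcppArmadillo); a 200,000-quadruple sweep takes a few seconds.

## The calibration pipeline

`run_calibration()` composes the stages on a `calibration_inputs()` bundle
(commanded robot poses, the same poses measured optically, and the manual
trajectory), tagging any error with its stage name:

1. zero both pose recordings and estimate $T_{A \to R}$;
2. reconstruct the robot world origin and report its per-axis deviation;
3. *TCP/LOT method*: robust sphere fit on the manual trajectory, map the
   centre into robot coordinates (TCP), derive the tool length;
   *trajectory method*: map every manual sample into robot coordinates.

**Origin reconstruction.** The calibration schedule measures five poses on
the robot's YZ plane and six on its XZ plane. The published procedure states
the inputs and the output semantics (per-axis deviations whose ideal value is
zero) but not the algebra, so the construction here is the package's own:
both planes are fitted (total least squares, `fit_plane()`) to the measured
poses after mapping them into robot coordinates, and their intersection line
is the reconstructed vertical axis; the reference point is the intersection
line of the *commanded* planes pinned at $z = 0$; the reported deviation is
the closest point on the reconstructed axis minus that reference. On
noise-free data this is identically zero; plane fits with fewer than 3 points,
collinear points, or near-parallel planes (|n₁·n₂| > 0.999) are errors.

**Tool length.** By default the tracked marker is taken to sit at the point
where the flange attaches (the top of the specimen holder), so the tool
length is the fitted sphere radius, minus an optional `sensor_offset` for a
force-torque sensor that the controller accounts for separately. Whether
published tool lengths include such a sensor is not stated, hence the
explicit parameter (default 0). When the flange centre is known in robot
coordinates, passing `flange_center` switches to the distance definition
$\mathrm{LOT} = \lVert \mathrm{TCP} - \mathrm{flange} \rVert -
\mathrm{offset}$ (`compute_lot()`).

**Method agreement.** For a perfect ball joint the two reproduction routes
coincide: projecting the transformed trajectory radially onto the sphere of
radius LOT about the TCP (`reproduce_sphere_motion()`) returns the trajectory
itself. The acceptance suite checks this agreement at $10^{-6}$ mm on
noise-free data.

## Summary-statistic conventions

The validation tables of this calibration procedure follow conventions that
`summary_stats()` reproduces exactly — they were confirmed by recomputing
every printed summary cell from the printed per-position cells:

* **population standard deviation** (divisor $n$, not $n-1$): decisive, since
  the sample SD of the normalized TCP x-column would print 1.84 where the
  table prints 1.68;
* **even-$n$ median** = mean of the two middle order statistics, reported as
  *median deviation* (median minus mean);
* **extreme deviations** reported two ways: mean-relative
  (`max_dev_pos = max - mean`, `min_dev_neg = mean - min`, the tool-length
  table convention) and raw signed extremes (`max`, `min`, the origin and TCP
  table convention). Both are returned so either table style reproduces.

Two printed cells do not recompute from their own per-position values under
any of these conventions (the origin table's z-axis SD, and the median/min
cells of the transformation column of the tool-length table); they are
documented as irreproducible and not asserted.

`compare_trajectories()` reports trajectory-reproduction accuracy in the
published layout: signed per-axis deviations (test − reference), per-point
Euclidean distances, and an average/max/min summary. The published average
Euclidean value averages the per-point norms (it exceeds the norm of the
average axis deviations, which the suite checks on the shipped table). Since
manual (10 Hz) and robotic recordings have different sample counts, the
default pairing resamples both curves to the reference's count at equal
arc-length spacing and pairs by index; nearest-neighbour pairing is available
(`pairing = "nearest"`). Rounding to table precision happens only in report
rendering, never internally.

## The synthetic rig

`synthetic_scenario()` fixes a ground-truthed virtual rig; everything is
reproducible from one integer seed (R's Mersenne-Twister; every stochastic
operation seeds locally and restores the caller's RNG state). Defaults mirror
the physical rig's scale and are *stated*, not tuned:

| quantity | default | basis |
|---|---|---|
| joint centre (robot frame) | (1010, −125, 60) mm | ~1 m from the robot origin, the rig's working distance |
| tool length | 367 mm | femur-plus-holder length of the reference specimen |
| marker noise SD | 0.1 mm | optical-system accuracy class on this volume |
| calibration poses | 11 (5 on YZ, 6 on XZ) | the stage-II schedule |
| flexion–extension arc | 90°, 90 samples | conservative hip range of motion |
| abduction–adduction arc | 45°, 60 samples | conservative hip range of motion |
| circumduction cone | 30°, 80 samples | conservative hip range of motion |
| mounting offsets | six positions on a 50 mm grid | the hole-matrix mounting plate |

The manual-motion angular extents and sampling duration of the physical
experiment are not reported anywhere, so the arc defaults above are the
package's choice (conservative physiological ranges, totalling 230 samples to
match the scale of a real recording). The hidden rigid motion linking the
frames is drawn from the seed (QR-orthogonalised Gaussian rotation, uniform
translation within ±1 m).

**What the generator does and does not emulate.** It produces kinematically
exact rigid-frame geometry with isotropic Gaussian marker noise, optional
gross outliers (`add_outliers()`: chosen samples displaced by exactly the
requested magnitude in random directions), and optional per-axis scaling of
the joint surface to emulate non-ball joints. It does **not** model soft
tissue, joint laxity, capsule deformation, marker occlusion, tracker
calibration drift, or robot positioning error. A green synthetic test
therefore establishes the correctness of the *algorithms* under the stated
noise model — not the field accuracy of a physical rig, which adds all of the
above error sources.

## Numerical choices

* Conditioning guards: $10^{12}$ on the transform normal matrix and on
  $K^{\mathsf T}K$ of the direct sphere fit; degenerate geometry errors
  instead of silently solving.
* Four-point solves flag degeneracy (`valid = FALSE`) instead of erroring;
  fits with $R^2 \le 0$ or non-finite parameters are excluded before the
  first rejection iteration.
* Plane-fit normals get a deterministic sign (largest component positive);
  collinearity is detected on the second singular value.
* The zeroed first point is set to exactly (0,0,0), leaving no roundoff
  residue in the anchor row.
* Rejection uses strict inequality, so a zero-variance ensemble (all
  quadruples identical) is a fixed point at iteration 1.
* Ties in nearest-neighbour pairing break to the first (lowest-index) point.

## Known limitations

* The TCP/LOT route assumes the tracked marker is rigid with the specimen and
  at the flange attachment point; a lever-arm between marker and flange would
  bias the tool length by that offset.
* The unconstrained map estimator trades rigidity for fidelity to the
  published algorithm; under heavy noise the mapped trajectory inherits the
  small non-orthogonality unless `orthogonalize = TRUE`.
* Arc-length pairing assumes the two curves trace the same path once; it is
  not a general curve-registration method and will mis-pair trajectories
  with repeated passes at different speeds.
* No angular (rotation) reproduction metrics: positional deviations only.
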