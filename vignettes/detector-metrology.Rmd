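---
title: "Joint detector and crystal refinement for serial crystallography stills"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint detector and crystal refinement for serial crystallography stills}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillsgeom)
```

## The problem

Serial crystallography collects one still diffraction image per crystal on
a multi-panel pixel-array detector.  The geometric description of the
panels (the *metrology*) is known only approximately when the instrument
is assembled, and errors of a few pixels are enough to degrade indexing,
distort refined unit cells and dilute the integrated signal.  Because a
still shot constrains a crystal model only weakly, metrology cannot be
refined one image at a time: the detector must be refined *jointly*
against thousands of crystal models at once.  `stillsgeom` implements
that machinery end to end on synthetic experiments with known ground
truth: a hierarchical detector model, still-shot spot prediction, initial
quadrant alignment from virtual powder patterns, four interchangeable
refinement engines over the joint parameter space, staged refinement
protocols with reindexing cycles, time-batched refinement, and intensity
error models.

## The detector model

A detector is a tree of frames.  Each node carries an origin vector
$\mathbf{d}_0$ (mm, in its parent's frame) and orthonormal fast/slow axis
vectors $\mathbf{d}_x,\mathbf{d}_y$; the plane normal
$\mathbf{d}_n=\mathbf{d}_x\times\mathbf{d}_y$ is always derived.  A frame
is equivalently a homogeneous $4\times4$ matrix with columns
$\mathbf{d}_x,\mathbf{d}_y,\mathbf{d}_n,\mathbf{d}_0$, so mapping a point
through the hierarchy is a chain of matrix products, and the cumulative
vectors of any panel follow from that product.  The default layout mimics
a CSPAD-class device: 4 quadrants in a pinwheel (successive 90°
rotations about the beam), 8 sensors per quadrant, and two
194×185-pixel ASICs per sensor separated by a fixed three-pixel gap that
is never refined (a deviation there would merely absorb error from
elsewhere).  Pixels are 0-based with the panel origin at the outer corner
of pixel (0,0) and pixel $(f,s)$ centred at
$((f+0.5)\,p,(s+0.5)\,p)$ mm.

The laboratory frame puts the crystal at the origin with the beam along
$-\hat z$; the detector sits near the plane $z=-D$ for sample-to-detector
distance $D$.  The quadrant-internal sensor coordinates of the real
device are not public at this level of detail, so the package lays
sensors on a 2×4 slot grid *designed* so that the radial order of sensors
from the beam equals the admission order 1, 0, 7, 3, 2, 6, 4, 5 used by
the expanding protocol.

Rigid moves of any node use six degrees of freedom: distance (along
$\mathbf{d}_n$), Shift1/Shift2 (along $\mathbf{d}_x,\mathbf{d}_y$) and
$\tau_1,\tau_2,\tau_3$ (right-handed rotations about
$\mathbf{d}_n,\mathbf{d}_x,\mathbf{d}_y$, applied in that order about the
pre-move axes; in the small-angle regime the ordering is second-order).
Angles are radians internally and degrees at user surfaces.

```{r}
det <- cspad_detector(distance = 130)
head(panel_table(det)[, c("path", "d0x", "d0y", "d0z")], 3)
```

## Still-shot prediction and the delta-psi restraint

A crystal is an orthonormal orientation $U$ plus a symmetry-constrained
cell (hexagonal: free $a,c$; orthorhombic: free $a,b,c$), with the
upper-triangular reciprocal orthogonalization $B$ recomputed on any cell
change; reciprocal-lattice points are $\mathbf{r}=UB\mathbf{h}$.  For a
still, a generic $\mathbf{r}$ is not exactly in the reflecting condition.
$\Delta\psi$ is the smallest rotation about
$\mathbf{e}=\mathbf{r}\times\mathbf{s}_0/|\mathbf{r}\times\mathbf{s}_0|$
that places it on the Ewald sphere; the closed form reduces to
$P\cos\psi+Q\sin\psi=-|\mathbf{r}|^2$ with $P=2\,\mathbf{s}_0\!\cdot\!\mathbf{r}$,
$Q=2\,|\mathbf{r}\times\mathbf{s}_0|$, taking the smaller-magnitude root.
Positive $\psi$ rotates the point outward through the sphere, so the sign
tracks the Ewald offset and is invariant to rotating $\mathbf{r}$ about
the beam axis.  Prediction enumerates indices to the resolution limit,
keeps $|\psi|$ within an acceptance window (0.05° in the fixtures; this
window stands in for an explicit mosaicity model), rotates the ray and
intersects it with every panel plane.  The predicted centroid of a
reflection with non-zero $\psi$ is taken at the fully rotated ray (the
partiality-weighted alternative is not modelled).

Index assignment inverts this: a centroid's unit ray is scaled to the
Ewald sphere, fractional indices $(UB)^{-1}\mathbf{q}$ pick a candidate
integer triple, and $\mathbf{q}$ is rotated back through the candidate's
own $\Delta\psi$ so that noiseless data recover their indices to
$10^{-9}$; assignment requires all three fractional distances strictly
below the 0.3 cutoff.

## The refinement target and engines

With $m$ matched reflections the target is

$$ L=\sum_{i=1}^{m} w_{i,x}(x^{\rm calc}_i-x^{\rm obs}_i)^2
   + w_{i,y}(y^{\rm calc}_i-y^{\rm obs}_i)^2
   + w_{i,\psi}(\psi^{\rm calc}_i)^2, $$

with statistical weights equal to the inverse centroid variance (falling
back to pixel$^2$/12 when unknown) and a constant $w_\psi=10^6$, which
puts the $\psi$ term on the scale of the positional terms.  The restraint
matters because crystal rotations about axes perpendicular to the beam
barely move low-angle spot positions; without it the orientation block of
the normal matrix becomes nearly singular (the package tests the
eigenvalue contrast directly).  There are $3m$ residuals; internally the
system is pre-whitened (residuals scaled by the square-root weights),
which is the same algebra with better conditioning.

Parameters are owned either by one detector node or by one crystal, so
distinct crystals share no residuals and the normal matrix
$A=J^{\sf T}WJ$ is structurally sparse: the only generally non-zero
cross-terms couple detector parameters with crystals.  The Jacobian is
assembled by a chain rule: the sensitivity of $(x,y,\psi)$ to the
reciprocal-lattice vector is computed once by central differences in
rlp-space, crystal-parameter directions ($\partial\,\mathrm{rlp}$ per
orientation angle and free cell length) are analytic, and detector
columns come from rigid perturbations applied directly to the panel
table.  A pure finite-difference mode (central differences, step
$10^{-6}$) is kept and the two agree to a relative $10^{-5}$ in the test
suite.

Four engines minimize $L$:

* **LevMar (dense)** — damped normal equations $(A+\lambda\,\mathrm{diag}A)\,
  \delta=-J^{\sf T}Wr$ solved by dense Cholesky; Marquardt schedule
  $\lambda_0=10^{-3}$, ×2 on reject, ÷3 on accept.  The solve is done in
  Jacobi-scaled variables (diag $A$ = 1), which is algebraically the same
  step.
* **sparse LevMar** — identical algebra with a sparse Cholesky
  factorization under a fill-reducing ordering (CHOLMOD via the Matrix
  package); the engine records the non-zero counts of $A$ and of its
  factor.  Because both factorizations solve the same damped system, the
  per-iteration steps agree to solver round-off; the engine can record a
  companion solve with the other factorization for exactly this check.
* **LBFGS** and **LBFGS + curvatures** — limited-memory quasi-Newton with
  a strong-Wolfe line search; the curvature variant seeds the inverse
  Hessian with the Gauss–Newton diagonal $2\sum_i w_i(\partial r_i/
  \partial p)^2$, which is exact for linear residuals and improves toward
  convergence.  Both work in unit-scaled variables (rotations in
  milliradians) — without that, plain LBFGS cannot traverse the mm/radian
  gradient disparity at all.

Convergence: relative decrease of $L$ below $10^{-6}$ on two consecutive
accepted steps, gradient $\infty$-norm below tolerance, or the step cap
(LevMar 100; LBFGS up to 10 000).  Step-cap exhaustion is reported, never
raised.

## Quadrant alignment from virtual powder patterns

The composite maximum over many randomly oriented stills is a virtual
powder pattern.  A correctly placed quadrant correlates with a copy of
itself rotated about the beam centre; a misplaced one does not.  For each
integer offset in a ±25-pixel window the quadrant is translated, the
pattern rotated (45° by default; bilinear resampling) and the sample
correlation computed over the overlapping pixels of the quadrant's own
near-beam sensor — correlating the quadrant against *its own* rotated
pattern makes the noiseless argmax exact regardless of how the other
quadrants are misplaced, which is the package's resolution of the
unspecified overlap definition.  The argmax is the correction to apply;
ties break toward the smallest offset, then lexicographically.  The
multi-angle variant takes, per offset, the maximum CC over 20–70° in
2.5° steps (21 angles), suppressing the beat-pattern aliases a strictly
periodic ring set would produce — the synthetic fixtures therefore use
irregularly spaced rings, as real lattice spacings are.

## Protocols, cycles and ensembles

Two staged recipes refine from coarse to fine, always co-refining every
crystal's orientation and free cell lengths with the listed detector
degrees of freedom, tying the distance offsets of the refined groups (a
single shared parameter keeps the detector coplanar), and fixing
$\tau_1$ of the whole detector plus the first member of any multi-group
$\tau_1$ set (only $N-1$ of the rotations about the common normal are
independent):

* *hierarchical*: detector → quadrants → sensors (3 optimizations);
* *expanding*: the same start, then sensors admitted in order of
  increasing radius (1, 0, 7, 3, 2, 6, 4, 5 per quadrant; 9
  optimizations), so the best-constrained panels anchor the solution
  before the weakly constrained ones enter.

A cycle = reassign indices with the current geometry → drop outlier
images by Tukey's rule ($\mathrm{rmsd}>Q_3+1.5\,\mathrm{IQR}$,
one-sided) → drop outlier reflections by a per-component scaled-MAD rule
(4.5 MAD, floored at half a pixel so a wholly mis-set sensor is not
discarded when the bulk residuals are tiny; this robust rule is a
pluggable stand-in, not a reproduction of any published rejection
algorithm) → run the protocol.  Cycle reports include the r.m.s.d. over
the *common set* of reflections indexed in every cycle (keyed by the
observed centroid pixel, an invariant of a reflection), so cycles remain
comparable as the indexed set shrinks.  Convergence is declared when the
r.m.s.d. stops decreasing and the mean sensor shift falls below 0.1 px
(about 10 µm at a 110 µm pitch, matching the observed cycle-to-cycle
precision plateau).

Ensemble operations: `refine_per_image_detector()` gives every image its
own detector distance and in-plane shift (the historical approach);
`refine_joint_detector()` refines one detector against all crystals.
With a single true cell, the per-image protocol inflates the spread of
cell lengths — most strongly for axes nearly parallel to the beam, which
a still constrains only through the shallow sampling depth along
$\mathbf{s}_0$ — while joint refinement tightens every axis.  The
axis-to-beam statistics use bins with edges $\cos^{-1}(1-i/6)$, which
subtend equal solid angle.  `batch_refine()` splits images
chronologically, refines distance + xy per batch, and compares
resolution-binned $\langle I/\sigma_c\rangle$ (10 equal-volume
reciprocal-space bins) under batch vs baseline geometry.  The
"integration" behind that metric is a 3×3-pixel window sum on simulated
spot stamps at the predicted centroid — a stand-in whose only purpose is
to make the signal sensitive to centroid error; it is not a production
integrator.  Fixture batches hold 50 images, scaled from the
3000–4500-image batches a full experiment would use.

## Intensity error models

Counting statistics underestimate measurement error.  Two inflation
models are fitted to grouped intensity tables:

* the **negative-tail model**: over-predicted reflections integrate to
  pure noise, so the negative values of $I/\sigma_c$ form the lower half
  of a zero-mean Gaussian whose standard deviation $\sigma_{\rm neg}$
  (the root mean square of the negative normalized intensities; the
  zero-mean constraint is used rather than a fitted mean) becomes a
  constant multiplicative inflation $\sigma' = \sigma_{\rm neg}\sigma_c$;
* the **three-parameter model** $\sigma'^2 = \mathrm{SdFac}^2(\sigma_c^2 +
  \mathrm{SdB}\,\langle I_h\rangle + (\mathrm{SdAdd}\,\langle
  I_h\rangle)^2)$, fitted so the normalized deviates
  $(I_{hl}-\langle I_h\rangle)/(\sqrt{1-1/n_h}\,\sigma')$ have unit
  variance in mean-intensity bins, by Nelder–Mead from $(1,0,0)$.
  Whether the linear and quadratic terms should use $I_{hl}$ or $\langle
  I_h\rangle$ is a convention; the group mean is adopted and the algebra
  is isolated in one function so it can be swapped.  Groups with
  multiplicity below 2 are excluded and counted.

## The synthetic-experiment generator

`make_experiment()` draws per-shot orientations uniformly over rotations
(normalized-quaternion method), cells from a configurable mean ± s.d.
(default: a single thermolysin-like hexagonal cell, a = b = 92.9,
c = 130.4 Å), and per-shot wavelengths (9.75 keV with 0.1% jitter, stored
and never refined), predicts noiseless spots on the true detector, and
corrupts them with per-axis Gaussian centroid noise (default 0.2 px, the
variance recorded in the table), optional uniform outliers, and a
perturbed working detector: integer quadrant offsets (±3 px), sub-pixel
sensor shifts (±1.5 px) and normal-axis rotations (±0.3°), and a global
distance error (0.5 mm) — all recorded in a manifest for recovery
scoring.  An optional mid-run step change of the true distance emulates
sample drift.  Everything is a pure function of the configuration seed.

What the generator does *not* emulate: physical diffraction intensities,
profile shapes, radially streaked partials, background structure from
the injection medium, shutter jitter, or multi-lattice images.  Passing
tests therefore demonstrate the correctness and conditioning of the
geometry machinery under the stated noise model, not performance on real
images.

One scoring subtlety is intrinsic to the problem: rotating the whole
detector about the beam axis while counter-rotating every crystal leaves
the data exactly unchanged for stills, so that direction is a gauge mode
anchored only by the convention of fixing one $\tau_1$ per group.
`recovery_errors()` therefore fits and removes the single best global
in-plane rotation before scoring sensor positions (the fitted angle and
the — observable, hence not removed — global translation are reported).

## Problem sizes and numerical choices

The shipped tests run on one CPU at desk scale: geometry recovery uses
200 images (~350 reflections each at 2.2 Å) over a 5-seed battery;
ensemble contrasts use 500 orthorhombic images per seed; quadrant
alignment and image-space work use a reduced-panel detector (48×44-pixel
ASICs at 0.5 mm pitch — the frame algebra is identical, only the raster
is smaller); engine-concordance runs on a few images at quadrant level,
because the plain-LBFGS engine pays a finite-difference-priced Jacobian
on every one of its several hundred steps.  Key numerical defaults:
Marquardt $\lambda_0=10^{-3}$; FD steps $10^{-6}$ (parameters) and
$10^{-7}$ Å$^{-1}$ (rlp-space); indefinite damped systems retry with
10× damping; degenerate $\Delta\psi$ axes (rlp parallel to the beam) are
errors, not silent zeros; crystals with fewer than 6 admitted reflections
are held fixed for a step; ties in the near-beam-sensor choice break
lexicographically.

## A worked example

```{r, eval = FALSE}
ee <- end_to_end(seed = 5, n_images = 30, n_cycles = 2, d_min = 2.6)
ee$cycles$report
max(ee$recovery$sensor_err_px)
```

On this 30-image run the two cycles report overall r.m.s.d. values of a
few hundred µm falling to the noise floor, and the recovery score is a
fraction of a pixel for every data-carrying sensor; `scripts/acceptance.R`
prints the same quantities at the full study scales.

## Known limitations

Real-data ingestion (facility raw formats, spot finding), ab initio
indexing, mosaicity estimation beyond the fixed $\Delta\psi$ window,
parallax and sensor-thickness corrections, full integration,
post-refinement and merging statistics are out of scope.  The panel tilt
angles $\tau_2,\tau_3$ are supported by the frame algebra but never
refined by the shipped protocols, and the fast chain-rule Jacobian falls
back to pure finite differences if they are freed.
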