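# stillsgeom

Joint refinement of multi-panel detector geometry against ensembles of
still-shot crystal models, for serial crystallography.

## The problem

Serial crystallography records one still diffraction pattern per crystal
on a segmented pixel-array detector (CSPAD-class devices: 4 quadrants ×
8 sensors × 2 ASICs).  The relative positions and orientations of the
panels — the *metrology* — are known only to a few pixels when the
instrument is assembled, and errors at that level distort indexing,
inflate the apparent spread of unit-cell parameters, and dilute the
integrated Bragg signal.  Because one still constrains a crystal model
only weakly, the detector cannot be calibrated image by image: it has to
be refined *jointly* with thousands of crystal models at once.

`stillsgeom` implements that machinery on synthetic ground-truth
experiments:

- a **hierarchical detector model** (frames with origin d0 and axis
  vectors dx, dy per node; homogeneous-matrix algebra; rigid moves of any
  node with distance / Shift1 / Shift2 / tau1 / tau2 / tau3);
- **still-shot spot prediction** with the delta-psi restraint: for each
  reciprocal-lattice point r = U B h, the smallest rotation psi about
  e = r × s0 / |r × s0| that puts it on the Ewald sphere, and the rotated
  ray projected onto the panels; Miller-index assignment with the 0.3
  fractional cutoff; a distance scan by indexing success;
- **quadrant alignment** by rotational autocorrelation of virtual powder
  patterns (composite maximum images; single-angle 45° and multi-angle
  20–70° in 2.5° steps);
- the **joint least-squares target**
  `L = sum w_x dx^2 + w_y dy^2 + w_psi psi^2` (inverse-variance positional
  weights, constant w_psi = 1e6) minimized by four interchangeable
  engines — LBFGS, LBFGS with Gauss–Newton curvatures, dense
  Levenberg–Marquardt, and **sparse** Levenberg–Marquardt exploiting the
  block structure of the normal equations (distinct crystals share no
  residuals) through a fill-reducing sparse Cholesky factorization;
- staged **hierarchical / expanding refinement protocols** (sensors
  admitted by increasing radius in the order 1, 0, 7, 3, 2, 6, 4, 5 per
  quadrant), reindex–refine **cycles** with Tukey image filtering,
  second-detector refinement with fixed crystals, per-image vs joint
  **ensemble refinement**, and chronological **batch refinement** with a
  resolution-binned signal metric ⟨I/σc⟩;
- intensity **error models**: the negative-tail multiplicative inflation
  (sigma_neg from negatives of I/sigma_c) and the three-parameter
  SdFac/SdB/SdAdd model fitted on normalized deviates of repeated
  measurements;
- a seeded **synthetic-experiment generator** (thermolysin-like hexagonal
  or orthorhombic cells, uniform orientations, per-shot wavelengths,
  0.2-px centroid noise, recorded detector perturbations) so every stage
  is testable against known truth.

## A worked example

```r
library(stillsgeom)

ee <- end_to_end(seed = 5, n_images = 30, n_cycles = 2, d_min = 2.6)
ee$alignment$offsets_px     # per-quadrant pixel corrections from powder
ee$cycles$report            # per-cycle r.m.s.d. and metrology shifts
max(ee$recovery$sensor_err_px)
```

On this run the quadrant scan returns the integer corrections for all
four quadrants, the cycle report shows the overall r.m.s.d. falling from
several hundred micrometres to the centroid-noise floor within the first
cycle (with the common-set r.m.s.d. flat thereafter), and the recovery
score — sensor positions compared against the generator's ground truth,
net of the unobservable global rotation about the beam — is a small
fraction of a pixel for every sensor that carries reflections.

A larger standard run:

```r
bun <- make_experiment(sim_config(seed = 2, n_images = 200))
cyc <- run_cycles(bun$work_det, bun$crystals, bun$beams, bun$obs,
                  n_cycles = 2, mode = "expanding")
rec <- recovery_errors(bun$true_det, cyc$det)
c(max(rec$sensor_err_px), max(abs(rec$tau1_err_deg)), rec$z_err_mm)
#> 0.0138 px    0.0054 deg    0.0028 mm
cyc$report$rmsd_um[2]
#> 30.9
```

Two reindex-refine cycles recover injected quadrant offsets of a few
pixels, sub-pixel sensor shifts and rotations of up to 0.3° to about
0.01 px / 0.005° under 0.2-px centroid noise, with the final r.m.s.d. at
the centroid-noise floor (~31 µm for 110 µm pixels).

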