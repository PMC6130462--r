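# Seeded synthetic-experiment generator.
#
# Generates a ground-truth experiment (true detector, per-shot crystal and
# beam models, noiseless predictions) together with the corrupted
# observables the refinement machinery sees: a perturbed working detector
# and noisy spot centroids.  Everything downstream is testable against the
# recorded ground truth without any external data.

#' Simulation configuration
#'
#' Collects the study conditions for a synthetic stills experiment.  The
#' defaults emulate a thermolysin-like run on a CSPAD-class detector:
#' hexagonal cell a = b = 92.9, c = 130.4 Angstrom, 9.75 keV beam, 130 mm
#' nominal distance, 0.2-pixel centroid noise, and detector perturbations
#' of a few pixels at quadrant level plus sub-pixel sensor errors.
#'
#' @param seed mandatory integer seed; the generated bundle is a pure
#'   function of the configuration including the seed.
#' @param n_images number of still shots.
#' @param detector named list of arguments to [cspad_detector()].
#' @param tag cell constraint tag (see [crystal_model()]).
#' @param mean_lengths mean free cell lengths (Angstrom).
#' @param length_sd per-length standard deviation (0 = single true cell).
#' @param wavelength mean wavelength, Angstrom.
#' @param wavelength_jitter fractional per-shot wavelength s.d.
#' @param d_min resolution limit for prediction, Angstrom.
#' @param psi_window delta-psi acceptance half-window, radians.
#' @param centroid_noise_px per-axis centroid noise s.d., pixels.
#' @param outlier_frac fraction of observations replaced by uniform
#'   off-position centroids.
#' @param quad_offset_px_max quadrant perturbations are integer pixel
#'   offsets drawn uniformly in `[-max, max]` (excluding all-zero only by
#'   chance).
#' @param sensor_shift_px_max sensor in-plane perturbations drawn uniformly
#'   in `[-max, max]` pixels (sub-pixel allowed).
#' @param sensor_tau1_deg_max sensor rotations about the normal drawn
#'   uniformly in `[-max, max]` degrees.
#' @param distance_err_mm global distance error added to the working
#'   detector, mm.
#' @param distance_drift_mm mid-run step change of the TRUE
#'   sample-to-detector distance: images in the second half of the run are
#'   generated with the distance increased by this amount (emulates a
#'   time-dependent drift of the sample position).
#' @param mean_intensity mean of the exponential true-intensity
#'   distribution used to decorate reflections.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_images = 200L,
                       detector = list(distance = 130),
                       tag = "hexagonal",
                       mean_lengths = c(92.9, 130.4),
                       length_sd = 0,
                       wavelength = 12.3984 / 9.75,
                       wavelength_jitter = 1e-3,
                       d_min = 2.0,
                       psi_window = 0.05 * pi / 180,
                       centroid_noise_px = 0.2,
                       outlier_frac = 0,
                       quad_offset_px_max = 3L,
                       sensor_shift_px_max = 1.5,
                       sensor_tau1_deg_max = 0.3,
                       distance_err_mm = 0.5,
                       distance_drift_mm = 0,
                       mean_intensity = 500) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  stopifnot(centroid_noise_px >= 0, outlier_frac >= 0, outlier_frac < 1,
            length_sd >= 0, wavelength_jitter >= 0)
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Inject perturbations into a copy of the true detector; returns the
# detector and a manifest of what was injected.
perturb_detector <- function(det, cfg) {
  manifest <- list()
  pixel <- if (!is.null(cfg$detector$pixel)) cfg$detector$pixel else 0.110
  if (cfg$distance_err_mm != 0) {
    det <- move_node(det, det$root$name, distance = cfg$distance_err_mm)
    manifest[[length(manifest) + 1L]] <-
      data.frame(path = det$root$name, dof = "distance",
                 value = cfg$distance_err_mm)
  }
  for (qp in nodes_at_level(det, "quadrant")) {
    off <- sample(-cfg$quad_offset_px_max:cfg$quad_offset_px_max, 2, replace = TRUE)
    det <- move_node(det, qp, shift1 = off[1] * pixel, shift2 = off[2] * pixel)
    manifest[[length(manifest) + 1L]] <-
      data.frame(path = paste(qp, collapse = "/"), dof = c("shift1", "shift2"),
                 value = off * pixel)
  }
  for (sp in nodes_at_level(det, "sensor")) {
    sh <- stats::runif(2, -cfg$sensor_shift_px_max, cfg$sensor_shift_px_max) * pixel
    t1 <- stats::runif(1, -cfg$sensor_tau1_deg_max, cfg$sensor_tau1_deg_max) * pi / 180
    det <- move_node(det, sp, shift1 = sh[1], shift2 = sh[2], tau1 = t1)
    manifest[[length(manifest) + 1L]] <-
      data.frame(path = paste(sp, collapse = "/"),
                 dof = c("shift1", "shift2", "tau1"), value = c(sh, t1))
  }
  list(det = det, manifest = do.call(rbind, manifest))
}

#' Generate a synthetic ground-truth experiment
#'
#' Draws per-shot crystal orientations (uniform over rotations), cells and
#' wavelengths, predicts noiseless spot positions on the true detector,
#' corrupts them with Gaussian centroid noise (and optional uniform
#' outliers), and builds a working detector with recorded perturbations for
#' recovery scoring.  Deterministic given the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return a list (class `"experiment_bundle"`) with `config`, `true_det`,
#'   `work_det`, `crystals`, `beams`, `obs` (observation table: `image_id`,
#'   `panel`, `sensor`, `quadrant`, `h`, `k`, `l`, `x_obs`, `y_obs`,
#'   `var_x`, `var_y`, `x_true`, `y_true`, `psi_true`, `intensity`,
#'   `sigma_c`, `is_outlier`), and `manifest` (injected perturbations).
#' @export
make_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    true_det <- do.call(cspad_detector, cfg$detector)
    ptab <- panel_table(true_det)
    # panel -> sensor/quadrant ordinals from the node paths
    parts <- strsplit(ptab$path, "/", fixed = TRUE)
    depth <- lengths(parts)
    quad <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
    sens <- vapply(parts, function(p) if (length(p) >= 3) paste(p[2], p[3], sep = "/") else p[length(p)], "")
    quadrant_of_panel <- match(quad, unique(quad))
    sensor_of_panel <- match(sens, unique(sens))

    nf <- n_free_cell_params(cfg$tag)
    stopifnot(length(cfg$mean_lengths) == nf)
    B0 <- cell_to_B(constrained_cell(cfg$tag, cfg$mean_lengths))
    hkl <- hkl_candidates(B0, cfg$d_min, margin = 1.08)

    crystals <- vector("list", cfg$n_images)
    beams <- vector("list", cfg$n_images)
    obs_list <- vector("list", cfg$n_images)
    pixel <- ptab$psz_f[1]
    noise_mm <- cfg$centroid_noise_px * pixel
    true_dist <- rep(detector_distance(true_det), cfg$n_images)
    det_drift <- NULL; ptab_drift <- NULL
    if (cfg$distance_drift_mm != 0) {
      half <- seq_len(cfg$n_images) > cfg$n_images / 2
      true_dist[half] <- true_dist[half] + cfg$distance_drift_mm
      det_drift <- move_node(true_det, true_det$root$name,
                             distance = -cfg$distance_drift_mm)
      ptab_drift <- panel_table(det_drift)
    }
    for (i in seq_len(cfg$n_images)) {
      lens <- cfg$mean_lengths + stats::rnorm(nf, 0, cfg$length_sd)
      crystals[[i]] <- crystal_model(random_orientation(), cfg$tag, lens)
      beams[[i]] <- beam_model(cfg$wavelength *
                                 (1 + stats::rnorm(1, 0, cfg$wavelength_jitter)))
      drift_i <- cfg$distance_drift_mm != 0 && i > cfg$n_images / 2
      pred <- predict_still(crystals[[i]], beams[[i]],
                            if (drift_i) det_drift else true_det,
                            d_min = cfg$d_min, psi_window = cfg$psi_window,
                            hkl = hkl,
                            ptab = if (drift_i) ptab_drift else ptab)
      if (nrow(pred) == 0L) next
      m <- nrow(pred)
      x_obs <- pred$x_calc + stats::rnorm(m, 0, noise_mm)
      y_obs <- pred$y_calc + stats::rnorm(m, 0, noise_mm)
      is_out <- rep(FALSE, m)
      if (cfg$outlier_frac > 0) {
        n_out <- stats::rbinom(1, m, cfg$outlier_frac)
        if (n_out > 0) {
          oi <- sample.int(m, n_out)
          pr <- ptab[pred$panel[oi], ]
          x_obs[oi] <- stats::runif(n_out, 0, pr$n_fast * pr$psz_f)
          y_obs[oi] <- stats::runif(n_out, 0, pr$n_slow * pr$psz_s)
          is_out[oi] <- TRUE
        }
      }
      inten <- stats::rexp(m, 1 / cfg$mean_intensity)
      sig_c <- sqrt(inten + 100)   # counting noise on spot + local background
      obs_list[[i]] <- data.frame(
        image_id = i, panel = pred$panel,
        sensor = sensor_of_panel[pred$panel],
        quadrant = quadrant_of_panel[pred$panel],
        h = pred$h, k = pred$k, l = pred$l,
        x_obs = x_obs, y_obs = y_obs,
        var_x = noise_mm^2, var_y = noise_mm^2,
        x_true = pred$x_calc, y_true = pred$y_calc, psi_true = pred$psi,
        intensity = inten, sigma_c = sig_c, is_outlier = is_out)
    }
    pb <- perturb_detector(true_det, cfg)
    structure(list(config = cfg, true_det = true_det, work_det = pb$det,
                   crystals = crystals, beams = beams,
                   obs = do.call(rbind, obs_list), manifest = pb$manifest,
                   true_distance_per_image = true_dist),
              class = "experiment_bundle")
  })
}

#' Per-node frame differences between two detectors
#'
#' For each node at `level`, expresses the difference between the node's
#' cumulative (laboratory) frames in the two detectors as in-plane shifts
#' along the reference frame's axes, an offset along the normal, and the
#' rotation of the fast axis about the normal.  Used to score recovery of
#' injected perturbations.
#'
#' @param det_ref reference (e.g. true) [detector()].
#' @param det_cmp comparison (e.g. refined working) [detector()].
#' @param level hierarchy level name.
#' @return data.frame with `path`, `dshift1`, `dshift2`, `ddist` (mm) and
#'   `dtau1_deg`.
#' @export
frame_difference <- function(det_ref, det_cmp, level = "sensor") {
  paths <- nodes_at_level(det_ref, level)
  out <- lapply(paths, function(p) {
    fa <- cumulative_frame(det_ref, p)
    fb <- cumulative_frame(det_cmp, p)
    dna <- frame_dn(fa)
    t <- fb$d0 - fa$d0
    ang <- atan2(sum(cross3(fa$dx, fb$dx) * dna), sum(fa$dx * fb$dx))
    data.frame(path = paste(p, collapse = "/"),
               dshift1 = sum(t * fa$dx), dshift2 = sum(t * fa$dy),
               ddist = sum(t * dna), dtau1_deg = ang * 180 / pi)
  })
  do.call(rbind, out)
}

#' Score geometry recovery against the ground truth
#'
#' Compares sensor positions and normal-axis rotations of a refined
#' detector with the true detector.  A common in-plane rotation of the
#' whole detector about the beam axis is unobservable for still shots (it
#' is exactly compensated by rotating every crystal, and is anchored only
#' by the convention of fixing one tau1), so the comparison first fits and
#' removes the best-fitting global rotation; the fitted gauge angle and
#' the (observable, not removed) global translation are reported
#' separately.
#'
#' @param true_det,det true and refined [detector()]s.
#' @return list with `sensor_err_px` (per-sensor residual in-plane error,
#'   pixels), `tau1_err_deg` (net of the gauge angle), `z_err_mm` (mean
#'   panel-plane offset), `gauge_rot_deg`, `gauge_txy_mm`.
#' @export
recovery_errors <- function(true_det, det) {
  sens <- nodes_at_level(true_det, "sensor")
  pt_t <- panel_table(true_det)
  pixel <- pt_t$psz_f[1]
  ctr <- function(d, p) {
    f <- cumulative_frame(d, p)
    node <- find_node(d, c(p, "a0"))
    w <- (2 * node$panel$n_fast + 3) * node$panel$pixel_size_fast / 2
    h <- node$panel$n_slow * node$panel$pixel_size_slow / 2
    f$d0 + w * f$dx + h * f$dy
  }
  E <- t(vapply(sens, function(p) {
    ct <- ctr(true_det, p); cr <- ctr(det, p)
    c(ct[1], ct[2], cr[1] - ct[1], cr[2] - ct[2])
  }, numeric(4)))
  ns <- nrow(E)
  A <- rbind(cbind(1, 0, -E[, 2]), cbind(0, 1, E[, 1]))
  fit <- stats::lm.fit(A, c(E[, 3], E[, 4]))$coefficients
  phi <- fit[3]
  # residual in-plane errors after removing the rotation gauge only
  rx <- E[, 3] - (-phi * E[, 2])
  ry <- E[, 4] - (phi * E[, 1])
  fd <- frame_difference(true_det, det, "sensor")
  z_t <- mean(panel_table(true_det)$d0z)
  z_r <- mean(panel_table(det)$d0z)
  list(sensor_err_px = sqrt(rx^2 + ry^2) / pixel,
       tau1_err_deg = fd$dtau1_deg - phi * 180 / pi,
       z_err_mm = z_r - z_t,
       gauge_rot_deg = phi * 180 / pi,
       gauge_txy_mm = c(fit[1], fit[2]))
}

# --- virtual powder patterns -------------------------------------------------

#' Render a virtual powder pattern onto an assembled raster
#'
#' Physical powder rings (concentric annuli about the beam axis, Gaussian
#' radial profile) are painted onto each panel at its TRUE pixel positions;
#' the assembled raster then places every panel pixel at its WORKING
#' geometry position, so detector perturbations appear as ring
#' discontinuities across panel borders, as on a mis-calibrated device.
#' The composite is the pixelwise maximum over `n_images` Poisson
#' realizations (`n_images = 0` gives an all-zero composite).
#'
#' @param true_det,work_det true and working [detector()]s (may be equal).
#' @param ring_radii ring radii, mm, in the true detector plane.
#' @param ring_sigma_mm radial Gaussian width of each ring, mm.
#' @param peak expected peak counts per ring.
#' @param n_images number of images entering the composite maximum; 0
#'   gives an all-zero composite.
#' @param poisson draw Poisson counts per image (`FALSE` renders the
#'   noiseless expectation).
#' @param background flat background expectation, counts.
#' @return object of class `"powder_image"`: `raster` (matrix, NA outside
#'   panels), `x0`, `y0` (mm of raster pixel (1,1) centre), `pitch` (mm),
#'   `owner` (quadrant ordinal per raster pixel, 0 = none).
#' @export
render_powder <- function(true_det, work_det = true_det,
                          ring_radii, ring_sigma_mm = NULL,
                          peak = 1000, n_images = 1L, poisson = FALSE,
                          background = 5) {
  pt_true <- panel_table(true_det)
  pt_work <- panel_table(work_det)
  pitch <- pt_work$psz_f[1]
  if (is.null(ring_sigma_mm)) ring_sigma_mm <- 1.2 * pitch
  # raster extent from working panel corners (+margin)
  corners <- do.call(rbind, lapply(seq_len(nrow(pt_work)), function(p) {
    r <- pt_work[p, ]
    fs <- rbind(c(0, 0), c(r$n_fast * r$psz_f, 0), c(0, r$n_slow * r$psz_s),
                c(r$n_fast * r$psz_f, r$n_slow * r$psz_s))
    cbind(r$d0x + fs[, 1] * r$dxx + fs[, 2] * r$dyx,
          r$d0y + fs[, 1] * r$dxy + fs[, 2] * r$dyy)
  }))
  marg <- 30 * pitch
  x0 <- min(corners[, 1]) - marg; y0 <- min(corners[, 2]) - marg
  nx <- ceiling((max(corners[, 1]) + marg - x0) / pitch) + 1L
  ny <- ceiling((max(corners[, 2]) + marg - y0) / pitch) + 1L
  raster <- matrix(NA_real_, nx, ny)
  owner <- matrix(0L, nx, ny)
  quad_px <- list()
  parts <- strsplit(pt_work$path, "/", fixed = TRUE)
  quad <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  quad_id <- match(quad, unique(quad))
  profile <- function(r) {
    v <- numeric(length(r))
    for (R in ring_radii) v <- v + exp(-(r - R)^2 / (2 * ring_sigma_mm^2))
    background + peak * v
  }
  for (p in seq_len(nrow(pt_true))) {
    rt <- pt_true[p, ]; rw <- pt_work[p, ]
    f <- (seq_len(rt$n_fast) - 0.5) * rt$psz_f
    s <- (seq_len(rt$n_slow) - 0.5) * rt$psz_s
    ff <- rep(f, times = rt$n_slow); ss <- rep(s, each = rt$n_fast)
    # true lab position -> physical ring intensity
    tx <- rt$d0x + ff * rt$dxx + ss * rt$dyx
    ty <- rt$d0y + ff * rt$dxy + ss * rt$dyy
    lam <- profile(sqrt(tx^2 + ty^2))
    if (n_images == 0L) {
      vals <- numeric(length(lam))
    } else if (poisson) {
      vals <- stats::rpois(length(lam), lam)
      if (n_images > 1L)
        for (im in 2:n_images) vals <- pmax(vals, stats::rpois(length(lam), lam))
    } else vals <- lam
    # working lab position -> raster bin
    wx <- rw$d0x + ff * rw$dxx + ss * rw$dyx
    wy <- rw$d0y + ff * rw$dxy + ss * rw$dyy
    ix <- floor((wx - x0) / pitch) + 1L
    iy <- floor((wy - y0) / pitch) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    idx <- ix[ok] + (iy[ok] - 1L) * nx
    raster[idx] <- vals[ok]
    owner[idx] <- quad_id[p]
    # per-quadrant pixel layer: with large mis-sets panels of different
    # quadrants can claim the same assembled bin, and the combined raster
    # keeps only the last writer; the per-quadrant layers stay clean
    qi <- quad_id[p]
    if (qi >= 1L) {
      if (length(quad_px) < qi || is.null(quad_px[qi][[1]]))
        quad_px[[qi]] <- list(idx = integer(0), vals = numeric(0))
      quad_px[[qi]]$idx <- c(quad_px[[qi]]$idx, idx)
      quad_px[[qi]]$vals <- c(quad_px[[qi]]$vals, vals[ok])
    }
  }
  structure(list(raster = raster, x0 = x0, y0 = y0, pitch = pitch,
                 owner = owner, quad_px = quad_px),
            class = "powder_image")
}

#' Powder ring radii implied by a unit cell
#'
#' Low-resolution lattice d-spacings converted to ring radii in the
#' detector plane, `r = D tan(2 asin(lambda / 2d))`.  Because lattice
#' spacings are not periodic, the resulting ring set is irregular, which
#' is what makes the rotational-autocorrelation maximum unambiguous.
#'
#' @param tag,lengths cell constraint tag and free lengths (see
#'   [crystal_model()]).
#' @param wavelength Angstrom.
#' @param distance sample-to-detector distance, mm.
#' @param r_max largest radius to keep, mm.
#' @param max_index largest Miller index considered per axis.
#' @return sorted numeric vector of ring radii (mm), duplicates within a
#'   quarter pixel merged.
#' @export
powder_ring_radii <- function(tag, lengths, wavelength, distance,
                              r_max = 120, max_index = 8L) {
  B <- cell_to_B(constrained_cell(tag, lengths))
  H <- as.matrix(expand.grid(h = 0:max_index, k = 0:max_index, l = 0:max_index))
  H <- H[rowSums(H) > 0, ]
  q <- sqrt(rowSums((H %*% t(B))^2))
  sin_th <- wavelength * q / 2
  keep <- sin_th < sin(pi / 5)
  r <- sort(unique(round(distance * tan(2 * asin(sin_th[keep])), 1)))
  r <- r[r > 5 & r < r_max]
  # thin the dense high-order spacings so individual rings stay resolved;
  # the surviving set keeps its irregular (non-periodic) gaps
  keep_r <- r[1]
  for (v in r[-1]) if (v - keep_r[length(keep_r)] >= 2) keep_r <- c(keep_r, v)
  keep_r
}

#' Irregularly spaced ring radii for alignment fixtures
#'
#' Seeded draw of ring radii with uniformly random gaps.  Aperiodic ring
#' spacing is essential for single-angle rotational autocorrelation: with
#' periodic rings the heat map develops beat-pattern aliases at multiples
#' of the ring period.
#'
#' @param r_max largest radius, mm.
#' @param gap_range uniform gap range between consecutive rings, mm.
#' @param r_min first ring radius, mm.
#' @param seed integer seed.
#' @return numeric vector of radii (mm).
#' @export
fixture_ring_radii <- function(r_max = 120, gap_range = c(5, 13),
                               r_min = 10, seed = 1L) {
  with_seed(seed, {
    r <- r_min + cumsum(stats::runif(ceiling(r_max / gap_range[1]),
                                     gap_range[1], gap_range[2]))
    r[r < r_max]
  })
}

#' Pixelwise composite maximum of images
#'
#' @param images list of equally sized matrices; masked (NA) pixels stay
#'   masked only where masked in every image.
#' @return the pixelwise maximum matrix.
#' @export
composite_max <- function(images) {
  if (length(images) == 0L) stop("composite_max: need at least one image")
  out <- images[[1]]
  for (im in images[-1]) {
    stopifnot(all(dim(im) == dim(out)))
    out <- pmax(out, im, na.rm = TRUE)   # pixels masked everywhere stay NA
  }
  out
}

# --- intensity sets for the error models ------------------------------------

#' Simulate grouped intensity measurements
#'
#' Per-group true intensities follow an exponential (Wilson-like)
#' distribution; a configurable fraction of groups are noise-only (true
#' intensity zero, emulating predictions that contain no photons, whose
#' integration produces pure Gaussian noise).  Measurements are the truth
#' plus Gaussian noise of width `inflate * sigma_c`, while the reported
#' uncertainty stays `sigma_c` -- the mismatch the error models estimate.
#'
#' @param n_groups number of symmetry-unique groups.
#' @param multiplicity measurements per group.
#' @param inflate true-noise inflation factor relative to `sigma_c`.
#' @param noise_only_frac fraction of groups with true intensity zero.
#' @param mean_intensity mean of the exponential intensity distribution.
#' @param seed integer seed.
#' @return data.frame with `group`, `image_id`, `I_true`, `I`, `sigma_c`.
#' @export
simulate_intensity_set <- function(n_groups, multiplicity, inflate = 1,
                                   noise_only_frac = 0, mean_intensity = 20,
                                   seed = 1L) {
  with_seed(seed, {
    I_true <- stats::rexp(n_groups, 1 / mean_intensity)
    nil <- stats::runif(n_groups) < noise_only_frac
    I_true[nil] <- 0
    g <- rep(seq_len(n_groups), each = multiplicity)
    sigma_c <- stats::runif(n_groups * multiplicity, 0.8, 1.2)
    I <- I_true[g] + stats::rnorm(n_groups * multiplicity, 0, inflate * sigma_c)
    data.frame(group = g,
               image_id = rep_len(seq_len(multiplicity), n_groups * multiplicity),
               I_true = I_true[g], I = I, sigma_c = sigma_c)
  })
}

#' Integrate reflections in a window at predicted centroids
#'
#' Integration stand-in used by the time-batched signal metric: for each
#' reflection a small pixel stamp is simulated around the TRUE spot
#' position (Gaussian spot profile plus flat background, Poisson counts)
#' and summed over a `window x window` box centred on the PREDICTED
#' centroid pixel, with the background expectation subtracted.  The
#' integrated signal therefore degrades as the predicted centroid moves
#' away from the true spot -- making the signal metric sensitive to
#' geometry error.  Not a production integration algorithm.
#'
#' @param dx_px,dy_px predicted-minus-true centroid offsets, pixels.
#' @param intensity true integrated spot intensities, counts.
#' @param spot_sigma_px Gaussian spot width, pixels.
#' @param window odd integration box width, pixels.
#' @param background flat background expectation per pixel, counts.
#' @param seed integer seed.
#' @return data.frame with `I` (background-subtracted window sum) and
#'   `sigma_c` (counting error of the window sum).
#' @export
integrate_window <- function(dx_px, dy_px, intensity, spot_sigma_px = 0.7,
                             window = 3L, background = 5, seed = 1L) {
  stopifnot(window %% 2L == 1L)
  hw <- (window - 1L) / 2L
  # stamp covers the window around the predicted centroid; the spot sits at
  # the true position, i.e. displaced by (-dx, -dy) from the window centre
  off <- seq(-hw, hw)
  with_seed(seed, {
    m <- length(dx_px)
    tot <- numeric(m); var_tot <- numeric(m)
    for (ox in off) for (oy in off) {
      # expected spot fraction in pixel (ox, oy) relative to predicted centre
      ex <- (stats::pnorm(ox + 0.5 + dx_px, 0, spot_sigma_px) -
             stats::pnorm(ox - 0.5 + dx_px, 0, spot_sigma_px))
      ey <- (stats::pnorm(oy + 0.5 + dy_px, 0, spot_sigma_px) -
             stats::pnorm(oy - 0.5 + dy_px, 0, spot_sigma_px))
      lam <- intensity * ex * ey + background
      cnt <- stats::rpois(m, lam)
      tot <- tot + cnt - background
      var_tot <- var_tot + cnt
    }
    data.frame(I = tot, sigma_c = sqrt(pmax(var_tot, 1)))
  })
}
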