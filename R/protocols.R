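# Staged refinement protocols, convergence cycles, outlier filters,
# ensemble and time-batched refinement.

#' Calculated spot positions for an assigned reflection table
#'
#' Convenience wrapper around the vectorized prediction core: computes
#' (x_calc, y_calc, psi) for reflections with known Miller indices and
#' panel assignment under the given models.
#'
#' @param det a [detector()].
#' @param crystals,beams model lists indexed by `image_id`.
#' @param refl table with `image_id`, `panel`, `h`, `k`, `l`.
#' @return `refl` with `x_calc`, `y_calc`, `psi` columns replaced/added.
#' @export
predict_matched <- function(det, crystals, beams, refl) {
  imgs <- sort(unique(refl$image_id))
  refl$.img <- match(refl$image_id, imgs)
  cp <- calc_positions(ub_matrix(crystals, imgs), s0_matrix(beams, imgs),
                       panel_matrix(det), refl)
  refl$x_calc <- cp$x; refl$y_calc <- cp$y; refl$psi <- cp$psi
  refl$.img <- NULL
  refl
}

positional_rmsd_um <- function(refl) {
  1000 * sqrt(mean((refl$x_calc - refl$x_obs)^2 + (refl$y_calc - refl$y_obs)^2))
}

# Sensor ordinal (0-7, within quadrant) for each reflection, from the
# global tree-order sensor id carried by the observation table.
sensor_within_quadrant <- function(sensor) (sensor - 1L) %% 8L

#' Build the step sequence of a refinement protocol
#'
#' Hierarchical mode: three optimizations (whole detector, then quadrants,
#' then sensors), each over all reflections.  Expanding mode: nine
#' optimizations; the detector and quadrant rounds use only reflections on
#' the innermost sensor of each quadrant, after which sensors are admitted
#' in order of increasing radial distance from the detector centre
#' ([sensor_admission_order()]), refining the admitted sensors against the
#' reflections they carry.  At every step the distance offsets of the
#' refined groups are tied (coplanarity), tau2/tau3 stay fixed, tau1 is
#' fixed for the whole detector and for the first node of each multi-node
#' tau1 group, and all crystal parameters co-refine unless
#' `crystals_free = FALSE`.
#'
#' @param det a [detector()].
#' @param mode `"hierarchical"` or `"expanding"`.
#' @param crystals_free co-refine crystal parameters.
#' @return list of lists with `step` (a [refine_step()]) and
#'   `admit_sensors` (0-7 sensor indices whose reflections are used; NULL =
#'   all).
#' @export
protocol_steps <- function(det, mode = c("expanding", "hierarchical"),
                           crystals_free = TRUE) {
  mode <- match.arg(mode)
  quad_paths <- nodes_at_level(det, "quadrant")
  sens_paths <- nodes_at_level(det, "sensor")
  sens_num <- vapply(sens_paths, function(p)
    as.integer(sub("^s", "", p[length(p)])), 0L)
  out <- list()
  if (mode == "hierarchical") {
    out[[1]] <- list(step = refine_step("detector",
                                        c("distance", "shift1", "shift2"),
                                        coplanar = FALSE,
                                        crystals_free = crystals_free),
                     admit_sensors = NULL)
    out[[2]] <- list(step = refine_step("quadrant",
                                        c("distance", "shift1", "shift2", "tau1"),
                                        crystals_free = crystals_free),
                     admit_sensors = NULL)
    out[[3]] <- list(step = refine_step("sensor",
                                        c("distance", "shift1", "shift2", "tau1"),
                                        crystals_free = crystals_free),
                     admit_sensors = NULL)
  } else {
    adm <- sensor_admission_order()
    out[[1]] <- list(step = refine_step("detector",
                                        c("distance", "shift1", "shift2"),
                                        coplanar = FALSE,
                                        crystals_free = crystals_free),
                     admit_sensors = adm[1])
    out[[2]] <- list(step = refine_step("quadrant",
                                        c("distance", "shift1", "shift2", "tau1"),
                                        crystals_free = crystals_free),
                     admit_sensors = adm[1])
    for (k in 2:8) {
      sel <- adm[1:k]
      nodes <- sens_paths[sens_num %in% sel]
      out[[k + 1L]] <- list(step = refine_step("sensor",
                                               c("distance", "shift1", "shift2", "tau1"),
                                               nodes = nodes,
                                               crystals_free = crystals_free),
                            admit_sensors = sel)
    }
  }
  out
}

#' Run a staged refinement protocol
#'
#' Executes the hierarchical (3-step) or expanding (9-step) protocol: each
#' step jointly refines the admitted detector degrees of freedom with all
#' crystal models against the admitted reflections, and its output models
#' seed the next step.
#'
#' @param det working [detector()].
#' @param crystals,beams model lists indexed by `image_id`.
#' @param refl assigned reflection table (`image_id`, `panel`, `sensor`,
#'   `h`, `k`, `l`, `x_obs`, `y_obs`, `var_x`, `var_y`).
#' @param mode `"expanding"` or `"hierarchical"`.
#' @param engine engine name (see [run_engine()]).
#' @param w_psi constant psi weight.
#' @param crystals_free co-refine crystal parameters.
#' @param max_steps per-optimization step cap.
#' @param verbose print one line per step.
#' @return list with updated `det`, `crystals`, `rmsd_um` (final, all
#'   reflections), `trajectory` (per-step data.frame) and `results`.
#' @export
run_protocol <- function(det, crystals, beams, refl,
                         mode = c("expanding", "hierarchical"),
                         engine = "sparse_levmar", w_psi = 1e6,
                         crystals_free = TRUE, max_steps = 50,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  steps <- protocol_steps(det, mode, crystals_free = crystals_free)
  traj <- list()
  results <- list()
  swq <- sensor_within_quadrant(refl$sensor)
  for (si in seq_along(steps)) {
    st <- steps[[si]]
    use <- if (is.null(st$admit_sensors)) rep(TRUE, nrow(refl))
           else swq %in% st$admit_sensors
    refl_k <- refl[use, ]
    if (nrow(refl_k) == 0L) {
      warning("protocol step ", si, " has no admitted reflections; skipped")
      next
    }
    sys <- make_refine_system(det, crystals, beams, refl_k, st$step,
                              w_psi = w_psi)
    res <- run_engine(sys, engine, max_steps = max_steps)
    det <- apply_theta_det(sys$pset, res$theta)
    crystals <- apply_theta_crystals(sys$pset, res$theta)
    results[[si]] <- res
    traj[[si]] <- data.frame(step = si, level = st$step$level,
                             n_refl = nrow(refl_k), n_par = res$n,
                             iterations = res$steps, L = res$L,
                             rmsd_um = res$rmsd_um)
    if (verbose)
      message(sprintf("step %d (%s): n=%d, m=%d, L=%.4g, rmsd=%.1f um",
                      si, st$step$level, res$n, nrow(refl_k), res$L,
                      res$rmsd_um))
  }
  pr <- predict_matched(det, crystals, beams, refl)
  list(det = det, crystals = crystals, rmsd_um = positional_rmsd_um(pr),
       trajectory = do.call(rbind, traj), results = results)
}

#' Tukey rule-of-thumb image filter
#'
#' Keeps an image iff its r.m.s.d. does not exceed `Q3 + k * IQR`
#' (one-sided, matching the usual serial-crystallography usage).
#'
#' @param rmsd per-image r.m.s.d. values.
#' @param k multiplier of the inter-quartile range (default 1.5).
#' @return logical keep mask.
#' @export
tukey_image_filter <- function(rmsd, k = 1.5) {
  if (length(rmsd) == 0L) return(logical(0))
  if (!is.finite(k)) return(rep(TRUE, length(rmsd)))
  q <- stats::quantile(rmsd, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  rmsd <= q[2] + k * (q[2] - q[1])
}

#' Robust per-component reflection outlier filter
#'
#' Drops a reflection iff any residual component deviates from its median
#' by more than `c_mad` median-absolute-deviations (scaled MAD).  A simple
#' robust stand-in for production outlier rejection; pluggable.
#'
#' @param residuals data.frame or matrix of residual components (columns).
#' @param c_mad rejection multiplier (default 4.5).
#' @param floor smallest rejection half-width, same units as the
#'   residuals; prevents the scale estimate from collapsing on
#'   noise-free or strongly clustered residuals (e.g. half a pixel for
#'   positional components).
#' @return logical keep mask.
#' @export
reflection_outlier_filter <- function(residuals, c_mad = 4.5, floor = 0) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) == 0L) return(logical(0))
  keep <- rep(TRUE, nrow(residuals))
  for (j in seq_len(ncol(residuals))) {
    x <- residuals[, j]
    md <- stats::median(x); s <- stats::mad(x)
    keep <- keep & abs(x - md) <= max(c_mad * s, floor)
  }
  keep
}

#' Reindex-refine convergence cycles
#'
#' Each cycle reassigns Miller indices with the current geometry, drops
#' outlier images by the Tukey r.m.s.d. rule and outlier reflections by
#' the robust component filter, then runs the staged protocol.  Cycles
#' report the overall r.m.s.d. and, once all cycles have run, the
#' r.m.s.d. over the common set of reflections indexed in every cycle
#' (keyed by observed centroid pixel, an invariant property of a
#' reflection).  Convergence is declared when the overall r.m.s.d. stops
#' decreasing (within `rmsd_tol_um`) and the mean sensor shift falls below
#' `shift_tol_px`.
#'
#' @param det working [detector()].
#' @param crystals,beams model lists.
#' @param obs observation table (unassigned; `x_obs`, `y_obs`, variances,
#'   `panel`, `sensor`, `image_id`).
#' @param n_cycles maximum number of cycles (<= 4 in routine use).
#' @param mode protocol mode.
#' @param engine engine name.
#' @param cutoff fractional-index assignment cutoff.
#' @param tukey_k image-filter multiplier.
#' @param c_mad reflection-filter multiplier.
#' @param rmsd_tol_um,shift_tol_px convergence thresholds.
#' @param ... passed to [run_protocol()].
#' @return list with final `det`, `crystals`, `report` (per-cycle
#'   data.frame incl. common-set r.m.s.d.) and `converged_cycle` (NA if
#'   not reached).
#' @export
run_cycles <- function(det, crystals, beams, obs, n_cycles = 4L,
                       mode = "expanding", engine = "sparse_levmar",
                       cutoff = 0.3, tukey_k = 1.5, c_mad = 4.5,
                       rmsd_tol_um = 1, shift_tol_px = 0.1, ...) {
  report <- list()
  keys_by_cycle <- list()
  resid_by_cycle <- list()
  prev_rmsd <- Inf
  converged_cycle <- NA_integer_
  pixel <- panel_table(det)$psz_f[1]
  for (cy in seq_len(n_cycles)) {
    det_start <- det
    # reassign indices with the current models
    ptab <- panel_table(det)
    refl <- do.call(rbind, lapply(sort(unique(obs$image_id)), function(im) {
      oi <- obs[obs$image_id == im, ]
      assign_indices(oi, crystals[[im]], beams[[im]], det,
                     cutoff = cutoff, ptab = ptab)
    }))
    refl <- refl[!is.na(refl$h), ]
    refl <- predict_matched(det, crystals, beams, refl)
    # per-image Tukey filter
    im_rmsd <- tapply(
      (refl$x_calc - refl$x_obs)^2 + (refl$y_calc - refl$y_obs)^2,
      refl$image_id, function(v) sqrt(mean(v)))
    keep_img <- tukey_image_filter(as.numeric(im_rmsd), k = tukey_k)
    ok_ids <- as.integer(names(im_rmsd))[keep_img]
    refl <- refl[refl$image_id %in% ok_ids, ]
    # robust reflection filter (floored at half a pixel so whole mis-set
    # sensors are not discarded when the bulk residuals are tiny)
    keep <- reflection_outlier_filter(
      data.frame(dx = refl$x_calc - refl$x_obs,
                 dy = refl$y_calc - refl$y_obs), c_mad = c_mad,
      floor = pixel / 2)
    refl <- refl[keep, ]
    pro <- run_protocol(det, crystals, beams, refl, mode = mode,
                        engine = engine, ...)
    det <- pro$det; crystals <- pro$crystals
    # per-level shifts over this cycle
    fd_sens <- frame_difference(det_start, det, "sensor")
    fd_quad <- frame_difference(det_start, det, "quadrant")
    fd_det <- frame_difference(det_start, det, "detector")
    shift_um <- function(fd) 1000 * mean(sqrt(fd$dshift1^2 + fd$dshift2^2))
    pr <- predict_matched(det, crystals, beams, refl)
    rmsd <- positional_rmsd_um(pr)
    key <- paste(pr$image_id, round(pr$x_obs / pixel), round(pr$y_obs / pixel))
    keys_by_cycle[[cy]] <- key
    resid_by_cycle[[cy]] <- data.frame(
      key = key, d2 = (pr$x_calc - pr$x_obs)^2 + (pr$y_calc - pr$y_obs)^2)
    sens_shift_px <- mean(sqrt(fd_sens$dshift1^2 + fd_sens$dshift2^2)) / pixel
    report[[cy]] <- data.frame(
      cycle = cy, n_images = length(ok_ids), n_refl = nrow(refl),
      rmsd_um = rmsd, common_rmsd_um = NA_real_,
      detector_shift_um = shift_um(fd_det),
      quadrant_shift_um = shift_um(fd_quad),
      sensor_shift_um = shift_um(fd_sens),
      sensor_tau1_deg = mean(abs(fd_sens$dtau1_deg)))
    if (is.na(converged_cycle) &&
        prev_rmsd - rmsd < rmsd_tol_um && sens_shift_px < shift_tol_px)
      converged_cycle <- cy
    prev_rmsd <- rmsd
  }
  common <- Reduce(intersect, keys_by_cycle)
  report <- do.call(rbind, report)
  for (cy in seq_len(nrow(report))) {
    rc <- resid_by_cycle[[cy]]
    report$common_rmsd_um[cy] <-
      1000 * sqrt(mean(rc$d2[rc$key %in% common]))
  }
  list(det = det, crystals = crystals, report = report,
       converged_cycle = converged_cycle, n_common = length(common))
}

#' Refine a second detector against fixed crystal models
#'
#' Hierarchical refinement of an independently positioned detector (e.g. a
#' back detector at a much larger distance) using reflections indexed with
#' crystal models that were refined against another detector; all crystal
#' parameters are held fixed.
#'
#' @param det2 the second [detector()].
#' @param crystals,beams fixed models.
#' @param refl2 assigned reflections on the second detector.
#' @param engine engine name.
#' @param ... passed to [run_protocol()].
#' @return as [run_protocol()], plus `level_rmsd_um`: r.m.s.d. after each
#'   hierarchy level (initial, detector, quadrants, sensors).
#' @export
refine_second_detector <- function(det2, crystals, beams, refl2,
                                   engine = "sparse_levmar", ...) {
  pr0 <- predict_matched(det2, crystals, beams, refl2)
  level_rmsd <- c(initial = positional_rmsd_um(pr0))
  out <- run_protocol(det2, crystals, beams, refl2, mode = "hierarchical",
                      engine = engine, crystals_free = FALSE, ...)
  level_rmsd <- c(level_rmsd, stats::setNames(out$trajectory$rmsd_um,
                                              out$trajectory$level))
  out$level_rmsd_um <- level_rmsd
  out
}

#' Ensemble refinement: one detector per image
#'
#' Re-refines each crystal together with an independent detector position
#' (sample-to-detector distance and in-plane xy translation) for its own
#' image -- the historical serial-crystallography approach whose biased
#' cell-length distributions motivate joint ensemble refinement.
#'
#' @param det starting [detector()].
#' @param crystals,beams model lists.
#' @param refl assigned reflections.
#' @param w_psi psi weight.
#' @param max_steps per-image step cap.
#' @return list with `crystals`, `distances` (per image, mm), `dist_mean`,
#'   `dist_sd`.
#' @export
refine_per_image_detector <- function(det, crystals, beams, refl,
                                      w_psi = 1e6, max_steps = 30) {
  step <- refine_step("detector", c("distance", "shift1", "shift2"),
                      coplanar = FALSE, crystals_free = TRUE)
  imgs <- sort(unique(refl$image_id))
  dist <- numeric(length(imgs))
  for (ii in seq_along(imgs)) {
    im <- imgs[ii]
    refl_i <- refl[refl$image_id == im, ]
    sys <- make_refine_system(det, crystals, beams, refl_i, step,
                              w_psi = w_psi)
    res <- engine_levmar_dense(sys, max_steps = max_steps)
    det_i <- apply_theta_det(sys$pset, res$theta)
    crystals[im] <- apply_theta_crystals(sys$pset, res$theta)[im]
    dist[ii] <- detector_distance(det_i)
  }
  list(crystals = crystals, distances = dist, dist_mean = mean(dist),
       dist_sd = stats::sd(dist))
}

#' Ensemble refinement: one detector for all images
#'
#' Jointly refines a single detector position (distance and in-plane xy)
#' against the ensemble of all crystal models, using the sparse engine.
#'
#' @inheritParams refine_per_image_detector
#' @param engine engine name.
#' @return list with `det`, `crystals`, `distance` (mm), `result`.
#' @export
refine_joint_detector <- function(det, crystals, beams, refl, w_psi = 1e6,
                                  engine = "sparse_levmar", max_steps = 50) {
  step <- refine_step("detector", c("distance", "shift1", "shift2"),
                      coplanar = FALSE, crystals_free = TRUE)
  sys <- make_refine_system(det, crystals, beams, refl, step, w_psi = w_psi)
  res <- run_engine(sys, engine, max_steps = max_steps)
  list(det = apply_theta_det(sys$pset, res$theta),
       crystals = apply_theta_crystals(sys$pset, res$theta),
       distance = detector_distance(apply_theta_det(sys$pset, res$theta)),
       result = res)
}

#' Cell-axis statistics binned by axis-to-beam angle
#'
#' Bins every real-space cell axis by its angle rho to the beam direction,
#' using bin edges `acos(1 - i/n_bins)` so each bin subtends equal solid
#' angle, and reports the per-bin mean and standard deviation of the axis
#' length.  Beam-parallel bins (low bin index) expose the poorly
#' determined axis lengths characteristic of still shots.
#'
#' @param crystals list of [crystal_model()].
#' @param beam a [beam_model()] (or unit direction vector).
#' @param n_bins number of equal-solid-angle bins (default 6).
#' @return data.frame with `axis` (a/b/c), `bin` (0-based), `rho_lo_deg`,
#'   `rho_hi_deg`, `n`, `mean_len`, `sd_len`.
#' @export
cell_axis_beam_angle_stats <- function(crystals, beam, n_bins = 6L) {
  dirn <- if (inherits(beam, "beam_model")) beam$direction else beam
  dirn <- dirn / sqrt(sum(dirn^2))
  rows <- list()
  for (cry in crystals) {
    ax <- real_space_axes(cry)
    for (j in 1:3) {
      v <- ax[, j]; len <- sqrt(sum(v^2))
      cosr <- abs(sum(v * dirn)) / len
      bin <- min(floor((1 - cosr) * n_bins), n_bins - 1L)
      rows[[length(rows) + 1L]] <- c(j, bin, len)
    }
  }
  m <- do.call(rbind, rows)
  out <- list()
  for (j in 1:3) for (b in 0:(n_bins - 1L)) {
    lens <- m[m[, 1] == j & m[, 2] == b, 3]
    out[[length(out) + 1L]] <- data.frame(
      axis = c("a", "b", "c")[j], bin = b,
      rho_lo_deg = acos(1 - b / n_bins) * 180 / pi,
      rho_hi_deg = acos(1 - (b + 1) / n_bins) * 180 / pi,
      n = length(lens),
      mean_len = if (length(lens)) mean(lens) else NA_real_,
      sd_len = if (length(lens) > 1) stats::sd(lens) else NA_real_)
  }
  do.call(rbind, out)
}

# Equal-volume resolution bin index (1..n_bins) from |rlp| values.
resolution_bins <- function(inv_d, n_bins = 10L) {
  v <- inv_d^3
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
}

#' Time-batched ensemble refinement with the signal metric
#'
#' Splits the images chronologically into contiguous batches, jointly
#' refines one detector position (distance + in-plane xy) with the batch's
#' crystal models, and compares the resolution-binned mean signal strength
#' <I/sigma_c(I)> of window-integrated intensities under the batch
#' geometry versus the baseline geometry.  Batches smaller than
#' `min_batch` are merged into their predecessor.
#'
#' @param det baseline working [detector()].
#' @param crystals,beams model lists.
#' @param refl assigned reflections with `x_true`, `y_true` (generator
#'   truth used by the integration stand-in) and `intensity`.
#' @param batch_size images per chronological batch.
#' @param n_bins resolution bins.
#' @param min_batch minimum batch size before merging.
#' @param seed seed for the integration stand-in.
#' @param w_psi psi weight.
#' @return list with `report` (per batch: `batch`, `first_image`,
#'   `last_image`, `n_images`, `distance_mm`, `dist_shift_mm`) and
#'   `signal` (per batch x bin: percent change in <I/sigma_c>).
#' @export
batch_refine <- function(det, crystals, beams, refl, batch_size = 50L,
                         n_bins = 10L, min_batch = 10L, seed = 1L,
                         w_psi = 1e6) {
  imgs <- sort(unique(refl$image_id))
  nb <- max(1L, floor(length(imgs) / batch_size))
  bounds <- round(seq(0, length(imgs), length.out = nb + 1L))
  sizes <- diff(bounds)
  if (any(sizes < min_batch) && nb > 1L) {
    warning("small batches merged into neighbours")
    while (nb > 1L && any(sizes < min_batch)) {
      j <- which.min(sizes)
      into <- if (j == 1L) 2L else j - 1L
      sizes[into] <- sizes[into] + sizes[j]
      sizes <- sizes[-j]
      nb <- nb - 1L
    }
  }
  batch_of <- rep(seq_len(nb), sizes)
  base_dist <- detector_distance(det)
  pixel <- panel_table(det)$psz_f[1]
  # resolution of each reflection from the baseline models
  prb <- predict_matched(det, crystals, beams, refl)
  imgs_all <- sort(unique(refl$image_id))
  ubm <- ub_matrix(crystals, imgs_all)
  A <- ubm[match(refl$image_id, imgs_all), , drop = FALSE]
  inv_d <- sqrt((A[, 1] * refl$h + A[, 4] * refl$k + A[, 7] * refl$l)^2 +
                (A[, 2] * refl$h + A[, 5] * refl$k + A[, 8] * refl$l)^2 +
                (A[, 3] * refl$h + A[, 6] * refl$k + A[, 9] * refl$l)^2)
  bins <- resolution_bins(inv_d, n_bins)
  report <- list(); signal <- list()
  for (b in seq_len(nb)) {
    ims <- imgs[batch_of == b]
    sel <- refl$image_id %in% ims
    refl_b <- refl[sel, ]
    jr <- refine_joint_detector(det, crystals, beams, refl_b, w_psi = w_psi)
    # predicted centroids under batch vs baseline geometry
    pb <- predict_matched(jr$det, jr$crystals, beams, refl_b)
    p0 <- prb[sel, ]
    int_b <- integrate_window((pb$x_calc - refl_b$x_true) / pixel,
                              (pb$y_calc - refl_b$y_true) / pixel,
                              refl_b$intensity, seed = seed + b)
    int_0 <- integrate_window((p0$x_calc - refl_b$x_true) / pixel,
                              (p0$y_calc - refl_b$y_true) / pixel,
                              refl_b$intensity, seed = seed + b)
    bb <- bins[sel]
    sig_b <- tapply(int_b$I / int_b$sigma_c, bb, mean)
    sig_0 <- tapply(int_0$I / int_0$sigma_c, bb, mean)
    signal[[b]] <- data.frame(batch = b, bin = as.integer(names(sig_b)),
                              signal_batch = as.numeric(sig_b),
                              signal_baseline = as.numeric(sig_0),
                              pct_change = 100 * (as.numeric(sig_b) /
                                                    as.numeric(sig_0) - 1))
    report[[b]] <- data.frame(batch = b, first_image = min(ims),
                              last_image = max(ims), n_images = length(ims),
                              distance_mm = jr$distance,
                              dist_shift_mm = jr$distance - base_dist)
  }
  list(report = do.call(rbind, report), signal = do.call(rbind, signal))
}
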