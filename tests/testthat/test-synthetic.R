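test_that("the generator is deterministic and exact at zero noise", {
  bun <- noiseless_bundle()
  expect_lt(max(abs(bun$obs$x_obs - bun$obs$x_true),
                abs(bun$obs$y_obs - bun$obs$y_true)), 1e-12)
  expect_false(any(bun$obs$is_outlier))
  bun2 <- make_experiment(bun$config)
  expect_identical(bun$obs, bun2$obs)
  expect_identical(bun$manifest, bun2$manifest)
  expect_identical(panel_matrix(bun$work_det), panel_matrix(bun2$work_det))
})

test_that("recorded perturbations match the true/working frame differences", {
  bun <- small_bundle()
  man <- bun$manifest
  for (sp in nodes_at_level(bun$true_det, "sensor")) {
    key <- paste(sp, collapse = "/")
    ft <- find_node(bun$true_det, sp)$frame
    fw <- find_node(bun$work_det, sp)$frame
    inj <- man[man$path == key, ]
    t <- fw$d0 - ft$d0
    expect_close(sum(t * ft$dx), inj$value[inj$dof == "shift1"], 1e-12)
    expect_close(sum(t * ft$dy), inj$value[inj$dof == "shift2"], 1e-12)
    ang <- atan2(sum(stillsgeom:::cross3(ft$dx, fw$dx) * frame_dn(ft)),
                 sum(ft$dx * fw$dx))
    expect_close(ang, inj$value[inj$dof == "tau1"], 1e-12)
  }
})

test_that("simulated intensity sets have the configured error structure", {
  d1 <- simulate_intensity_set(4000, 5, inflate = 1, seed = 11)
  z <- (d1$I - d1$I_true) / d1$sigma_c
  expect_lt(abs(sd(z) - 1), 0.02)
  # inflate 2: half-Gaussian oracle on the noise-only negatives
  d2 <- simulate_intensity_set(20000, 5, inflate = 2, noise_only_frac = 0.5,
                               seed = 12)
  neg <- with(d2, (I / sigma_c)[I < 0 & I_true == 0])
  expect_lt(abs(sqrt(mean(neg^2)) - 2), 0.1)
  d3 <- simulate_intensity_set(2000, 4, inflate = 1, noise_only_frac = 1,
                               seed = 13)
  expect_lt(abs(mean(d3$I)), 0.1)
  expect_identical(d1, simulate_intensity_set(4000, 5, inflate = 1, seed = 11))
})

test_that("powder rendering respects geometry bookkeeping", {
  args <- small_panel_args()
  det <- do.call(cspad_detector, args)
  rr <- fixture_ring_radii(seed = 2)
  # zero images -> all-zero composite
  p0 <- render_powder(det, det, ring_radii = rr, n_images = 0)
  expect_true(all(p0$raster[is.finite(p0$raster)] == 0))
  # noiseless ring with unperturbed geometry: value at a painted pixel is
  # the radial profile at that pixel's true position
  pw <- render_powder(det, det, ring_radii = 20, background = 0, peak = 100)
  iy <- which.max(pw$raster[200, ])
  expect_gt(max(pw$raster, na.rm = TRUE), 99)
  # quadrant shifted by (3, 2) px: the painted value moves with the
  # quadrant by exactly that offset in the raster
  inj <- rbind(c(3, 2), c(0, 0), c(0, 0), c(0, 0))
  detw <- apply_quadrant_offsets(det, inj)
  pws <- render_powder(det, detw, ring_radii = 20, background = 0, peak = 100)
  q1 <- which(pw$owner == 1, arr.ind = TRUE)
  vals0 <- pw$raster[q1]
  shifted <- cbind(q1[, 1] + 3L, q1[, 2] + 2L)
  ok <- shifted[, 1] <= nrow(pws$raster) & shifted[, 2] <= ncol(pws$raster)
  vals1 <- pws$raster[shifted[ok, , drop = FALSE]]
  keep <- is.finite(vals0[ok]) & is.finite(vals1)
  expect_close(vals0[ok][keep], vals1[keep], 1e-9)
})

test_that("composite maximum is a pixelwise order-independent maximum", {
  set.seed(5)
  A <- matrix(rpois(100, 10), 10)
  B <- matrix(rpois(100, 10), 10)
  Z <- matrix(0, 10, 10)
  expect_identical(composite_max(list(A)), A)
  expect_equal(composite_max(list(A, Z)), A)
  expect_equal(composite_max(list(A, B)), composite_max(list(B, A)))
  expect_error(composite_max(list()), "at least one")
})

test_that("a mid-run distance drift enters the generated truth", {
  cfg <- sim_config(seed = 3, n_images = 8, d_min = 3, distance_drift_mm = 0.2,
                    centroid_noise_px = 0)
  bun <- make_experiment(cfg)
  expect_equal(unique(bun$true_distance_per_image), c(130, 130.2))
  # second-half observations are consistent with the drifted detector
  im <- 7
  oi <- bun$obs[bun$obs$image_id == im, ]
  det_d <- move_node(bun$true_det, "detector", distance = -0.2)
  pred <- predict_still(bun$crystals[[im]], bun$beams[[im]], det_d,
                        d_min = 3, psi_window = cfg$psi_window)
  key_o <- paste(oi$h, oi$k, oi$l, oi$panel)
  key_p <- paste(pred$h, pred$k, pred$l, pred$panel)
  idx <- match(key_o, key_p)
  expect_lt(max(abs(pred$x_calc[idx] - oi$x_obs)), 1e-9)
})
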