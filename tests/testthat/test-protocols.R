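test_that("the Tukey image filter drops only one-sided outliers", {
  expect_true(all(tukey_image_filter(rep(3.2, 50))))
  r <- c(rnorm(99, 30, 0.5), 300)
  keep <- tukey_image_filter(r)
  expect_identical(which(!keep), 100L)
  expect_true(all(tukey_image_filter(c(r, 1e6), k = Inf)))
  expect_length(tukey_image_filter(numeric(0)), 0L)
})

test_that("the robust reflection filter has the expected behaviour", {
  set.seed(8)
  res <- data.frame(dx = rnorm(5000), dy = rnorm(5000))
  keep <- reflection_outlier_filter(res)
  expect_lt(mean(!keep), 0.01)
  res2 <- rbind(res, data.frame(dx = rep(30, 10), dy = 0))
  keep2 <- reflection_outlier_filter(res2)
  expect_true(all(!keep2[5001:5010]))
  expect_length(reflection_outlier_filter(res[0, ]), 0L)
})

test_that("protocol step sequences follow the admission schedule", {
  det <- cspad_detector()
  hs <- protocol_steps(det, "hierarchical")
  expect_length(hs, 3L)
  expect_equal(vapply(hs, function(s) s$step$level, ""),
               c("detector", "quadrant", "sensor"))
  es <- protocol_steps(det, "expanding")
  expect_length(es, 9L)
  expect_equal(es[[1]]$admit_sensors, 1L)
  expect_equal(es[[3]]$admit_sensors, c(1L, 0L))
  expect_equal(es[[9]]$admit_sensors, sensor_admission_order())
  # tau1 never refined for the whole detector; tau2/tau3 never refined
  expect_false("tau1" %in% es[[1]]$step$dofs)
  for (s in es) expect_false(any(c("tau2", "tau3") %in% s$step$dofs))
  # admitted sensor nodes at step 3 are sensors 0 and 1 of each quadrant
  nn <- vapply(es[[3]]$step$nodes, function(p) p[length(p)], "")
  expect_setequal(nn, c("s0", "s1"))
  expect_length(nn, 8L)
})

test_that("expanding step 1 uses only the innermost sensors' reflections", {
  bun <- small_bundle()
  refl <- assigned_refl(bun)
  swq <- stillsgeom:::sensor_within_quadrant(refl$sensor)
  es <- protocol_steps(bun$work_det, "expanding")
  admitted <- swq %in% es[[1]]$admit_sensors
  expect_true(any(admitted))
  expect_true(all(swq[admitted] == 1L))
})

test_that("a noiseless experiment converges within the first cycles", {
  bun <- make_experiment(sim_config(seed = 77, n_images = 12, d_min = 2.7,
                                    centroid_noise_px = 0,
                                    quad_offset_px_max = 1L,
                                    sensor_shift_px_max = 0.5,
                                    sensor_tau1_deg_max = 0.1,
                                    distance_err_mm = 0.2))
  cyc <- run_cycles(bun$work_det, bun$crystals, bun$beams, bun$obs,
                    n_cycles = 2L)
  expect_equal(nrow(cyc$report), 2L)
  # common-set r.m.s.d. non-increasing and essentially zero on exact data
  expect_true(all(diff(cyc$report$common_rmsd_um) < 1e-3))
  expect_lt(cyc$report$rmsd_um[2], 5)
  # sensors that carry data are restored; an unhit sensor cannot move
  rec <- recovery_errors(bun$true_det, cyc$det)
  counts <- tabulate(bun$obs$sensor, nbins = 32)
  expect_lt(max(rec$sensor_err_px[counts >= 10]), 0.1)
})

test_that("hierarchical and expanding modes converge to the same geometry", {
  bun <- make_experiment(sim_config(seed = 55, n_images = 12, d_min = 2.7,
                                    centroid_noise_px = 0.1,
                                    quad_offset_px_max = 1L,
                                    sensor_shift_px_max = 0.5,
                                    sensor_tau1_deg_max = 0.1,
                                    distance_err_mm = 0.2))
  refl <- assigned_refl(bun)
  ph <- run_protocol(bun$work_det, bun$crystals, bun$beams, refl,
                     mode = "hierarchical")
  pe <- run_protocol(bun$work_det, bun$crystals, bun$beams, refl,
                     mode = "expanding")
  fd <- frame_difference(ph$det, pe$det, "sensor")
  counts <- tabulate(refl$sensor, 32)
  dxy_px <- sqrt(fd$dshift1^2 + fd$dshift2^2) / 0.110
  expect_lt(max(dxy_px[counts >= 10]), 0.1)
})

test_that("the second detector refines with crystals fixed, level by level", {
  cfgb <- sim_config(seed = 9, n_images = 25, detector = list(distance = 2500),
                     d_min = 30, mean_lengths = c(400, 500),
                     psi_window = 0.1 * pi / 180, sensor_shift_px_max = 1,
                     sensor_tau1_deg_max = 0.1, quad_offset_px_max = 3L)
  bunb <- make_experiment(cfgb)
  # zero free crystal parameters in every step's parameter set
  st <- refine_step("quadrant", c("shift1", "shift2"), crystals_free = FALSE)
  ps <- build_parameter_set(bunb$work_det, bunb$crystals, bunb$obs, st)
  expect_equal(sum(ps$par$type == "cry"), 0L)
  out <- refine_second_detector(bunb$work_det, bunb$crystals, bunb$beams,
                                bunb$obs)
  expect_true(all(diff(out$level_rmsd_um) < 0))
  expect_lt(out$level_rmsd_um[["sensor"]], out$level_rmsd_um[["initial"]] / 3)
  # the crystal models were not touched
  expect_identical(out$crystals, bunb$crystals)
})

test_that("cell-axis statistics bin by equal solid angle", {
  cr <- crystal_model(diag(3), "orthorhombic", c(60, 70, 90))
  st <- cell_axis_beam_angle_stats(rep(list(cr), 5), beam_model(1.27))
  expect_true(all(st$sd_len[st$n > 1] == 0))
  expect_equal(sum(st$n), 15L)
  expect_equal(max(st$rho_hi_deg), 90)
  # uniform orientations occupy the bins near-uniformly
  set.seed(10)
  crs <- replicate(400, crystal_model(stillsgeom:::random_orientation(),
                                      "orthorhombic", c(60, 70, 90)),
                   simplify = FALSE)
  st2 <- cell_axis_beam_angle_stats(crs, beam_model(1.27))
  counts <- tapply(st2$n, st2$bin, sum)
  expect_gt(chisq.test(counts)$p.value, 1e-3)
})

test_that("batch refinement merges undersized batches with a warning", {
  bun <- small_bundle()
  refl <- assigned_refl(bun)
  expect_warning(
    br <- batch_refine(bun$work_det, bun$crystals, bun$beams, refl,
                       batch_size = 2L, min_batch = 5L, n_bins = 3L),
    "merged")
  expect_true(all(br$report$n_images >= 2))
})
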