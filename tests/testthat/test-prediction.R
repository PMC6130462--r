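test_that("delta_psi satisfies the Ewald condition and matches a 1-D scan", {
  bm <- beam_model(1.27)
  set.seed(7)
  for (i in 1:20) {
    rlp <- rnorm(3, 0, 0.2)
    dp <- delta_psi(rlp, bm)
    R <- rotation_about_axis(dp$e, dp$psi)
    expect_lt(abs(sqrt(sum((bm$s0 + R %*% rlp)^2)) - 1 / bm$wavelength), 1e-12)
    # brute-force oracle: minimize | |s0 + R(e, th) rlp| - |s0| | over th
    f <- function(th) abs(sqrt(sum((bm$s0 +
      rotation_about_axis(dp$e, th) %*% rlp)^2)) - 1 / bm$wavelength)
    br <- optimize(f, c(dp$psi - 0.3, dp$psi + 0.3), tol = 1e-12)
    # optimize() locates the minimizer to ~sqrt(eps); the Ewald condition
    # above pins the root itself to 1e-12
    expect_lt(abs(br$minimum - dp$psi), 1e-7)
  }
})

test_that("delta_psi trivial and degenerate cases behave", {
  bm <- beam_model(1.0)
  # rlp already on the sphere -> psi = 0
  q <- c(0.3, 0, 1 - sqrt(1 - 0.3^2))   # |s0 + q| = 1 by construction
  expect_lt(abs(delta_psi(q, bm)$psi), 1e-12)
  # sign convention: positive psi rotates the rlp outward through the
  # Ewald sphere, so the sign tracks the inside/outside offset and is
  # invariant to rotating the rlp about the beam axis
  set.seed(4)
  for (i in 1:10) {
    r <- rnorm(3, 0, 0.25)
    off <- sqrt(sum((bm$s0 + r)^2)) - 1 / bm$wavelength
    psi <- delta_psi(r, bm)$psi
    expect_equal(sign(psi), -sign(off))
    expect_equal(delta_psi(c(-r[1], -r[2], r[3]), bm)$psi, psi,
                 tolerance = 1e-9)
  }
  expect_error(delta_psi(c(0, 0, 0.1), bm), "parallel")
  expect_error(delta_psi(c(0, 0, 0), bm), "nonzero")
})

test_that("predict_still output satisfies its own contracts", {
  cr <- crystal_model(random_orientation(), "hexagonal", c(92.9, 130.4))
  bm <- beam_model(12.3984 / 9.75)
  det <- cspad_detector(130)
  expect_equal(nrow(predict_still(cr, bm, det, d_min = 3, psi_window = 0)), 0L)
  pred <- predict_still(cr, bm, det, d_min = 2.6)
  expect_gt(nrow(pred), 10)
  expect_false(any(pred$h == 0 & pred$k == 0 & pred$l == 0))
  # deterministic ordering
  expect_false(is.unsorted(order(pred$h, pred$k, pred$l)))
  # per-record re-check: every prediction reproduces its psi and lands
  # on its panel
  pt <- panel_table(det)
  UB <- cr$U %*% cr$B
  for (i in seq_len(min(20, nrow(pred)))) {
    dp <- delta_psi(as.numeric(UB %*% c(pred$h[i], pred$k[i], pred$l[i])), bm)
    expect_lt(abs(dp$psi - pred$psi[i]), 1e-10)
    expect_lt(abs(dp$psi), 0.05 * pi / 180 + 1e-12)
    r <- pt[pred$panel[i], ]
    expect_true(pred$x_calc[i] >= 0 && pred$x_calc[i] <= r$n_fast * r$psz_f)
    expect_true(pred$y_calc[i] >= 0 && pred$y_calc[i] <= r$n_slow * r$psz_s)
  }
})

test_that("generator and predictor close the loop exactly without noise", {
  bun <- noiseless_bundle()
  for (im in 1:2) {
    oi <- bun$obs[bun$obs$image_id == im, ]
    pred <- predict_still(bun$crystals[[im]], bun$beams[[im]], bun$true_det,
                          d_min = bun$config$d_min,
                          psi_window = bun$config$psi_window)
    key_o <- paste(oi$h, oi$k, oi$l, oi$panel)
    key_p <- paste(pred$h, pred$k, pred$l, pred$panel)
    idx <- match(key_o, key_p)
    expect_false(anyNA(idx))
    expect_lt(max(abs(pred$x_calc[idx] - oi$x_obs),
                  abs(pred$y_calc[idx] - oi$y_obs)), 1e-9)
  }
})

test_that("index assignment inverts generation and honours the cutoff", {
  bun <- noiseless_bundle()
  det <- bun$true_det
  ptab <- panel_table(det)
  oi <- bun$obs[bun$obs$image_id == 1, ]
  ai <- assign_indices(oi, bun$crystals[[1]], bun$beams[[1]], det, ptab = ptab)
  expect_equal(ai$h, oi$h)
  expect_equal(ai$k, oi$k)
  expect_equal(ai$l, oi$l)
  expect_lt(max(ai$frac_resid), 1e-9)
  # cutoff 0: only exact lattice points assigned
  a0 <- assign_indices(oi, bun$crystals[[1]], bun$beams[[1]], det,
                       cutoff = 0, ptab = ptab)
  expect_true(all(is.na(a0$h)))
  # a centroid generated from a fractional index 0.31 away stays unassigned
  cr <- bun$crystals[[1]]; bm <- bun$beams[[1]]
  UB <- cr$U %*% cr$B
  h0 <- c(oi$h[1], oi$k[1], oi$l[1])
  rlp_f <- as.numeric(UB %*% (h0 + c(0.31, 0, 0)))
  dp <- delta_psi(rlp_f, bm)
  pr <- project_to_panels(matrix(dp$s1, 1), oi$panel[1], ptab_matrix(ptab))
  obs_f <- data.frame(image_id = 1, panel = oi$panel[1],
                      x_obs = pr$fast, y_obs = pr$slow)
  af <- assign_indices(obs_f, cr, bm, det, ptab = ptab)
  expect_true(is.na(af$h[1]))
  expect_gt(af$frac_resid[1], 0.25)
})

test_that("the distance scan picks the true distance on clean data", {
  bun <- noiseless_bundle()
  obs <- bun$obs[, c("image_id", "panel", "x_obs", "y_obs")]
  truth <- detector_distance(bun$true_det)
  n_refl <- nrow(obs) / length(unique(obs$image_id))
  sc <- scan_distance(obs, bun$crystals, bun$beams, bun$true_det,
                      grid = truth + c(-4, -2, 0, 2, 4),
                      min_assigned = floor(0.8 * n_refl))
  expect_equal(sc$distance, truth)
  expect_equal(scan_distance(obs, bun$crystals, bun$beams, bun$true_det,
                             grid = 117)$distance, 117)
  expect_warning(
    sc0 <- scan_distance(obs[1:40, ], bun$crystals, bun$beams,
                         bun$true_det, grid = c(400, 500),
                         min_assigned = 1000L),
    "no images")
  expect_equal(sc0$distance, 400)
})
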