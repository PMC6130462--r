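align_fixture <- function(seed, max_off = 8L) {
  det_t <- do.call(cspad_detector, small_panel_args())
  set.seed(seed)
  inj <- matrix(sample(-max_off:max_off, 8, replace = TRUE), 4, 2)
  det_w <- apply_quadrant_offsets(det_t, inj)
  pw <- render_powder(det_t, det_w, ring_radii = fixture_ring_radii(seed = seed))
  list(det_t = det_t, det_w = det_w, inj = inj, pw = pw)
}

test_that("noiseless quadrant offsets are recovered exactly", {
  fx <- align_fixture(seed = 101)
  for (q in 1:4) {
    hm <- autocorrelation_map(fx$pw, fx$det_w, q, search_radius = 10L)
    expect_identical(hm$argmax, -fx$inj[q, ])
    expect_true(all(hm$cc[is.finite(hm$cc)] >= -1 &
                      hm$cc[is.finite(hm$cc)] <= 1))
    expect_gt(hm$cc_max, 0.9)
  }
})

test_that("the heat map is invariant to affine intensity rescaling", {
  fx <- align_fixture(seed = 102)
  hm1 <- autocorrelation_map(fx$pw, fx$det_w, 2, search_radius = 6L)
  pw2 <- fx$pw
  pw2$raster <- 3.7 * pw2$raster + 40
  hm2 <- autocorrelation_map(pw2, fx$det_w, 2, search_radius = 6L)
  fin <- is.finite(hm1$cc)
  expect_close(hm1$cc[fin], hm2$cc[fin], 1e-9)
  expect_identical(hm1$argmax, hm2$argmax)
})

test_that("multi-angle maps dominate the single-angle map", {
  expect_length(seq(20, 70, by = 2.5), 21L)
  fx <- align_fixture(seed = 103, max_off = 4L)
  angles <- c(30, 45, 60)
  hm45 <- autocorrelation_map(fx$pw, fx$det_w, 1, search_radius = 5L)
  hmm <- multi_angle_map(fx$pw, fx$det_w, 1, search_radius = 5L,
                         angles = angles)
  fin <- is.finite(hm45$cc) & is.finite(hmm$cc)
  expect_true(all(hmm$cc[fin] >= hm45$cc[fin] - 1e-12))
  expect_identical(hmm$argmax, -fx$inj[1, ])
})

test_that("quadrant offsets apply in lab axes and compose additively", {
  det <- do.call(cspad_detector, small_panel_args())
  expect_equal(panel_matrix(apply_quadrant_offsets(det, matrix(0, 4, 2))),
               panel_matrix(det))
  o1 <- rbind(c(2, -1), c(0, 3), c(-4, 0), c(1, 1))
  d1 <- apply_quadrant_offsets(apply_quadrant_offsets(det, o1), o1)
  d2 <- apply_quadrant_offsets(det, 2 * o1)
  expect_close(panel_matrix(d1), panel_matrix(d2), 1e-12)
  # the shift is in the detector plane regardless of quadrant rotation
  dq <- apply_quadrant_offsets(det, rbind(c(0, 0), c(5, 0), c(0, 0), c(0, 0)))
  dd <- panel_matrix(dq)[, 1:3] - panel_matrix(det)[, 1:3]
  moved <- rowSums(abs(dd)) > 0
  expect_close(dd[moved, 1], 5 * 0.5, 1e-12)
  expect_close(dd[moved, 2:3], 0, 1e-12)
})

test_that("applying recovered corrections restores the quadrant geometry", {
  fx <- align_fixture(seed = 104)
  al <- align_quadrants(fx$pw, fx$det_w, search_radius = 10L)
  fd <- frame_difference(fx$det_t, al$det, "quadrant")
  expect_lt(max(sqrt(fd$dshift1^2 + fd$dshift2^2)) / 0.5, 1)  # < 1 px
})
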