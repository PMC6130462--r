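test_that("frame homogeneous matrices follow the column convention", {
  expect_equal(frame_to_matrix(frame()), diag(4))
  m <- frame_to_matrix(frame(d0 = c(1, 2, 3)))
  expect_equal(m[1:3, 1:3], diag(3))
  expect_equal(m[1:3, 4], c(1, 2, 3))
  expect_equal(m[4, ], c(0, 0, 0, 1))
  # 90-degree frame applied to (1,0,0): verified against the explicit
  # longhand product R %*% p with R = [dx dy dn]
  f <- frame(d0 = c(0, 0, 0), dx = c(0, 1, 0), dy = c(-1, 0, 0))
  R <- cbind(f$dx, f$dy, frame_dn(f))
  p <- c(1, 0, 0)
  expect_equal(as.numeric(frame_to_matrix(f) %*% c(p, 1))[1:3],
               as.numeric(R %*% p))
  expect_equal(as.numeric(frame_to_matrix(f) %*% c(1, 0, 0, 1))[1:3],
               c(0, 1, 0))
})

test_that("non-orthonormal frames are rejected", {
  expect_error(frame(dx = c(1, 0, 0), dy = c(0.6, 0.8, 0)), "dx . dy")
  expect_error(frame(dx = c(2, 0, 0)), "\\|dx\\|")
})

test_that("frame composition equals the homogeneous matrix product", {
  f1 <- frame(d0 = c(0, 0, -10), dx = c(0, 1, 0), dy = c(-1, 0, 0))
  f2 <- frame(d0 = c(1, 0, 0))
  expect_equal(frame_to_matrix(compose_frames(frame(), f1)),
               frame_to_matrix(f1))
  # two translations add
  t12 <- compose_frames(frame(d0 = c(1, 2, 3)), frame(d0 = c(4, 5, 6)))
  expect_equal(t12$d0, c(5, 7, 9))
  # rotation then translation: d0 is the rotated translation (oracle:
  # explicit 4x4 product)
  expect_equal(frame_to_matrix(compose_frames(f1, f2)),
               frame_to_matrix(f1) %*% frame_to_matrix(f2))
  expect_equal(compose_frames(f1, f2)$d0, c(0, 1, -10))
  # associativity
  f3 <- frame(d0 = c(0, 2, 0), dx = c(1, 0, 0), dy = c(0, 0, 1))
  a <- compose_frames(compose_frames(f1, f2), f3)
  b <- compose_frames(f1, compose_frames(f2, f3))
  expect_close(frame_to_matrix(a), frame_to_matrix(b), 1e-12)
})

test_that("matrix inverse round trip holds to 1e-12", {
  f <- frame(d0 = c(3, -2, -100), dx = c(0, 1, 0), dy = c(-1, 0, 0))
  m <- frame_to_matrix(f)
  expect_close(m %*% solve(m), diag(4), 1e-12)
})

test_that("cumulative frames equal explicit homogeneous chain products", {
  det <- cspad_detector(distance = 130)
  # trivial chains
  expect_equal(cumulative_frame(det, "detector")$d0, c(0, 0, -130))
  # chain oracle on a path through a rotated quadrant
  path <- c("detector", "q1", "s3", "a1")
  M <- diag(4)
  node <- det$root
  M <- M %*% frame_to_matrix(node$frame)
  for (nm in path[-1]) {
    node <- node$children[[match(nm, vapply(node$children, `[[`, "", "name"))]]
    M <- M %*% frame_to_matrix(node$frame)
  }
  dv <- cumulative_d_vectors(det, path)
  expect_close(dv$d0, (M %*% c(0, 0, 0, 1))[1:3], 1e-12)
  expect_close(dv$dx, (M %*% c(1, 0, 0, 1))[1:3] - dv$d0, 1e-12)
  expect_close(dv$dy, (M %*% c(0, 1, 0, 1))[1:3] - dv$d0, 1e-12)
  expect_error(cumulative_frame(det, c("detector", "nope")), "broken")
})

test_that("a rotated quadrant places its sensors where the matrix chain says", {
  det <- cspad_detector(distance = 100)
  # quadrant q1 is rotated 90 degrees about the beam: a sensor origin at
  # (x, y) in quadrant coordinates must appear at (-y, x) in the lab
  f_loc <- find_node(det, c("detector", "q1", "s0"))$frame
  f_cum <- cumulative_frame(det, c("detector", "q1", "s0"))
  expect_close(f_cum$d0[1:2], c(-f_loc$d0[2], f_loc$d0[1]), 1e-12)
})

test_that("panel/lab mapping round-trips and flags off-panel points", {
  det <- cspad_detector()
  pt <- panel_table(det)
  expect_equal(nrow(pt), 64L)
  # (0,0) mm maps to the cumulative origin
  expect_equal(lab_from_panel(det, 5, 0, 0, ptab = pt),
               as.numeric(pt[5, c("d0x", "d0y", "d0z")]))
  set.seed(1)
  for (i in 1:25) {
    p <- sample.int(64, 1)
    fx <- runif(1, 0, pt$n_fast[p] * pt$psz_f[p])
    sx <- runif(1, 0, pt$n_slow[p] * pt$psz_s[p])
    lab <- lab_from_panel(det, p, fx, sx, ptab = pt)
    back <- panel_from_lab(det, lab, p, ptab = pt)
    expect_lt(abs(back$fast_mm - fx) + abs(back$slow_mm - sx), 1e-9)
    expect_true(back$on_panel)
  }
  off <- panel_from_lab(det, lab_from_panel(det, 1, -1, 0, ptab = pt), 1,
                        ptab = pt)
  expect_false(off$on_panel)
})

test_that("move_node is a rigid-body move about the pre-move axes", {
  det <- cspad_detector()
  expect_equal(panel_matrix(move_node(det, "detector")), panel_matrix(det))
  # shift1 on the root moves every pixel by dx(root)
  d2 <- move_node(det, "detector", shift1 = 1)
  delta <- panel_matrix(d2)[, 1:3] - panel_matrix(det)[, 1:3]
  expect_close(delta, matrix(rep(c(1, 0, 0), each = 64), 64), 1e-12)
  # tau1 on a quadrant rotates child sensor origins about the quadrant
  # normal through the quadrant origin (rotation-matrix oracle)
  qpath <- c("detector", "q2")
  fq <- cumulative_frame(det, qpath)
  R <- rotation_about_axis(frame_dn(fq), 0.1)
  d3 <- move_node(det, qpath, tau1 = 0.1)
  s_before <- cumulative_frame(det, c(qpath, "s4"))$d0
  s_after <- cumulative_frame(d3, c(qpath, "s4"))$d0
  expect_close(s_after, as.numeric(R %*% (s_before - fq$d0)) + fq$d0, 1e-9)
  # pairwise pixel distances unchanged (rigid body) at quadrant level
  d4 <- move_node(det, qpath, distance = 0.7, shift1 = -0.3, tau1 = 0.05)
  pm0 <- panel_matrix(det); pm1 <- panel_matrix(d4)
  pick <- which(startsWith(panel_table(det)$path, "detector/q2"))
  pts0 <- pm0[pick, 1:3]; pts1 <- pm1[pick, 1:3]
  expect_close(dist(pts0), dist(pts1), 1e-9)
})

test_that("moving a quadrant equals moving each of its sensors", {
  det <- cspad_detector()
  qpath <- c("detector", "q1")
  dq <- move_node(det, qpath, shift1 = 0.4, shift2 = -0.2)
  # the same lab-frame displacement applied to every sensor
  fq <- cumulative_frame(det, qpath)
  lab_shift <- 0.4 * fq$dx - 0.2 * fq$dy
  ds <- det
  for (sp in nodes_at_level(det, "sensor")) {
    if (!startsWith(paste(sp, collapse = "/"), "detector/q1/")) next
    fs <- cumulative_frame(det, sp)
    ds <- move_node(ds, sp, shift1 = sum(lab_shift * fs$dx),
                    shift2 = sum(lab_shift * fs$dy))
  }
  expect_close(panel_matrix(dq), panel_matrix(ds), 1e-9)
})

test_that("sensor slots respect the radial admission order and ASIC gap", {
  det <- cspad_detector()
  pt <- panel_table(det)
  radii <- vapply(0:7, function(si) {
    f <- cumulative_frame(det, c("detector", "q0", paste0("s", si)))
    ctr <- f$d0 + 24.75 * f$dx + 11 * f$dy * 0  # origin-corner distance proxy
    sqrt(sum((f$d0 + 21.5 * f$dx + 10 * f$dy)[1:2]^2))
  }, 0)
  expect_equal(order(radii) - 1L, sensor_admission_order())
  # inter-ASIC gap: a1 origin is exactly (194 + 3) pixels along fast
  s <- find_node(det, c("detector", "q0", "s0"))
  expect_equal(s$children[[2]]$frame$d0[1] - s$children[[1]]$frame$d0[1],
               197 * 0.110)
})
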