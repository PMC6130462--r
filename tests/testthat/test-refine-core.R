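test_that("build_residuals computes the weighted target", {
  obs <- data.frame(image_id = 1, h = 1, k = 2, l = 3, x_obs = 0, y_obs = 0,
                    var_x = 1, var_y = 1)
  pred <- data.frame(image_id = 1, h = 1, k = 2, l = 3, x_calc = 1,
                     y_calc = 2, psi = 0)
  rs <- build_residuals(obs, pred, w_psi = 1)
  expect_equal(rs$L, 5)
  # perfect match
  pred2 <- transform(pred, x_calc = 0, y_calc = 0)
  expect_equal(build_residuals(obs, pred2)$L, 0)
  # doubling the variances halves L
  obs2 <- transform(obs, var_x = 2, var_y = 2)
  expect_equal(build_residuals(obs2, pred, w_psi = 1)$L, 2.5)
  # unmatched observations are excluded
  obs3 <- rbind(obs, transform(obs, h = 9))
  expect_equal(nrow(build_residuals(obs3, pred, w_psi = 1)$matched), 1L)
})

small_system <- function(level = "sensor",
                         dofs = c("distance", "shift1", "shift2", "tau1")) {
  bun <- small_bundle()
  refl <- assigned_refl(bun)
  make_refine_system(bun$work_det, bun$crystals, bun$beams, refl,
                     refine_step(level, dofs))
}

test_that("the chain-rule Jacobian matches central finite differences", {
  sys <- small_system()
  set.seed(2)
  th <- rnorm(sys$n, 0, 1e-4)
  Jf <- sys$jacobian(th, mode = "fd")
  Jc <- sys$jacobian(th, mode = "chain")
  expect_lt(max(abs(Jf - Jc)) / max(abs(Jf)), 1e-5)
})

test_that("Jacobian columns have the ownership sparsity structure", {
  sys <- small_system()
  J <- sys$jacobian(numeric(sys$n))
  par <- sys$pset$par
  m <- sys$m
  # a crystal-owned column has entries only in its own image's rows
  ccol <- par$col[par$type == "cry" & par$owner == sys$imgs[2]][1]
  rows <- which(J[, ccol] != 0)
  rows_m <- unique((rows - 1) %% m + 1)
  expect_true(all(rows_m %in% sys$col_rows[[ccol]]))
  other <- unlist(sys$col_rows[par$col[par$type == "cry" &
                                         par$owner == sys$imgs[1]]][1])
  expect_false(any(rows_m %in% other))
  # shared-distance column touches every reflection
  shcol <- sys$pset$shared_col
  expect_gt(shcol, 0)
  expect_equal(length(sys$col_rows[[shcol]]), m)
})

test_that("curvatures are the Gauss-Newton diagonal and non-negative", {
  sys <- small_system(level = "quadrant", dofs = c("shift1", "shift2"))
  th <- numeric(sys$n)
  J <- sys$jacobian(th)
  cv <- curvature_diag(J, sys$sw^2)
  expect_true(all(cv >= 0))
  # panel translations enter the residuals linearly, so the curvature
  # equals the exact second difference of L for those columns
  pd <- sys$pset$par
  for (cc in pd$col[pd$type == "det" & pd$dof == "shift1"][1:2]) {
    h <- 1e-4
    tp <- th; tp[cc] <- h
    tm <- th; tm[cc] <- -h
    d2 <- (sys$L(tp) - 2 * sys$L(th) + sys$L(tm)) / h^2
    expect_lt(abs(d2 - cv[cc]) / abs(d2), 1e-5)
  }
})

test_that("the structural sparsity pattern bounds the numeric normal matrix", {
  sys <- small_system()
  pat <- sparsity_structure(sys)
  J <- sys$jacobian(numeric(sys$n))
  Jw <- Matrix::Diagonal(x = sys$sw) %*% J
  A <- Matrix::crossprod(Jw)
  nz <- as(as(A, "generalMatrix"), "TsparseMatrix")
  on <- abs(nz@x) > 0
  expect_true(all(pat[cbind(nz@i[on] + 1L, nz@j[on] + 1L)]))
  # two crystals never share an entry
  pd <- sys$pset$par
  c1 <- pd$col[pd$type == "cry" & pd$owner == sys$imgs[1]]
  c2 <- pd$col[pd$type == "cry" & pd$owner == sys$imgs[2]]
  expect_true(all(A[c1, c2] == 0))
  expect_false(any(pat[c1, c2]))
})

test_that("a linear two-parameter system reaches its analytic minimum", {
  bun <- noiseless_bundle()
  refl <- assigned_refl(bun, det = bun$true_det)
  refl <- refl[refl$image_id == 1, ]
  # detector-level in-plane shifts only; crystal fixed: residuals are
  # linear in the two parameters, the normal equations are exact
  step <- refine_step("detector", c("shift1", "shift2"), coplanar = FALSE,
                      crystals_free = FALSE)
  sys <- make_refine_system(bun$true_det, bun$crystals, bun$beams, refl, step)
  res <- engine_levmar_dense(sys)
  J <- sys$jacobian(numeric(2))
  Jw <- Matrix::Diagonal(x = sys$sw) %*% J
  r0 <- sys$sw * sys$residuals(numeric(2))
  th_exact <- as.numeric(solve(as.matrix(Matrix::crossprod(Jw)),
                               -as.numeric(Matrix::crossprod(Jw, r0))))
  expect_close(res$theta, th_exact, 1e-8)
})

test_that("the psi restraint conditions the orientation block", {
  bun <- small_bundle()
  refl <- assigned_refl(bun)
  refl <- refl[refl$image_id == refl$image_id[1], ]
  # restrict to low-angle reflections (inner sensors), where rotations
  # about beam-perpendicular axes barely move the spot positions and the
  # orientation is held almost entirely by the psi restraint
  refl <- refl[stillsgeom:::sensor_within_quadrant(refl$sensor) %in%
                 c(0L, 1L), ]
  step <- refine_step("detector", "shift1", coplanar = FALSE)
  eig_min <- function(w_psi) {
    sys <- make_refine_system(bun$work_det, bun$crystals, bun$beams, refl,
                              step, w_psi = w_psi)
    J <- sys$jacobian(numeric(sys$n))
    Jw <- Matrix::Diagonal(x = sys$sw) %*% J
    A <- as.matrix(Matrix::crossprod(Jw))
    pd <- sys$pset$par
    rot <- pd$col[pd$dof %in% c("rot1", "rot2", "rot3")]
    min(eigen(A[rot, rot], symmetric = TRUE, only.values = TRUE)$values)
  }
  expect_gt(eig_min(1e6) / eig_min(0), 10)
})

test_that("parameter sets honour constraints and masks", {
  det <- cspad_detector()
  crystals <- replicate(4, crystal_model(diag(3), "hexagonal", c(92.9, 130.4)),
                        simplify = FALSE)
  ps <- build_parameter_set(det, crystals, NULL,
                            refine_step("sensor",
                                        c("distance", "shift1", "shift2", "tau1")))
  # 1 shared distance + 64 shifts + 31 tau1 (first fixed) + 4 * 5 crystal
  expect_equal(ps$n, 1L + 64L + 31L + 20L)
  expect_equal(sum(ps$par$dof == "tau1"), 31L)
  expect_equal(ps$shared_col, 1L)
  # idempotent application at theta = 0
  expect_equal(panel_matrix(apply_theta_det(ps, numeric(ps$n))),
               panel_matrix(det))
})
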