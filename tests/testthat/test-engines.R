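engine_fixture <- function() {
  bun <- small_bundle()
  refl <- assigned_refl(bun)
  refl <- refl[refl$image_id <= 3, ]
  make_refine_system(bun$work_det, bun$crystals, bun$beams, refl,
                     refine_step("quadrant",
                                 c("distance", "shift1", "shift2", "tau1")))
}

test_that("dense and sparse LevMar agree per iteration and decrease L", {
  sys <- engine_fixture()
  res <- engine_levmar_sparse(sys, record_deltas = TRUE)
  expect_gt(res$steps, 2)
  expect_true(all(diff(res$L_trajectory) < 0))
  for (d in res$delta_history)
    expect_lt(max(abs(d$delta - d$alt)) / max(abs(d$delta)), 1e-8)
  resd <- engine_levmar_dense(sys)
  expect_lt(abs(res$rmsd_um - resd$rmsd_um), 1e-6)
  expect_false(is.na(res$nnz_A))
  expect_false(is.na(res$nnz_chol))
  expect_lte(res$nnz_chol, res$nnz_A)
})

test_that("LBFGS engines reach the LevMar optimum; curvatures shorten it", {
  sys <- engine_fixture()
  ref <- engine_levmar_sparse(sys)
  rc <- engine_lbfgs_curv(sys, max_steps = 2000, gtol = 1e-5, ltol = 1e-12)
  rp <- engine_lbfgs(sys, max_steps = 6000, gtol = 1e-5, ltol = 1e-12)
  expect_lt(abs(rc$L - ref$L) / ref$L, 1e-4)
  expect_lt(abs(rp$L - ref$L) / ref$L, 1e-4)
  expect_lt(rc$steps, rp$steps)
  # step-count exhaustion is reported, not raised
  rshort <- engine_lbfgs(sys, max_steps = 3)
  expect_false(rshort$converged)
  expect_equal(rshort$steps, 3L)
})

test_that("run_engine dispatches all four engine names", {
  sys <- engine_fixture()
  for (e in c("sparse_levmar", "levmar"))
    expect_s3_class(run_engine(sys, e, max_steps = 2), "refine_result")
  expect_error(run_engine(sys, "nonsense"))
})
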