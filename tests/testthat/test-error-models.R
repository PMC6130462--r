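test_that("the negative-tail estimator recovers the inflation factor", {
  d <- simulate_intensity_set(20000, 5, inflate = 1, noise_only_frac = 0.5,
                              seed = 21)
  expect_lt(abs(fit_ha14(d$I, d$sigma_c) - 1), 0.02)
  d2 <- simulate_intensity_set(20000, 5, inflate = 2, noise_only_frac = 1,
                               seed = 22)
  expect_lt(abs(fit_ha14(d2$I, d2$sigma_c) - 2) / 2, 0.05)
  expect_equal(apply_ha14(c(1, 2), 1.5), c(1.5, 3))
  # too few negatives -> error naming the image
  expect_error(fit_ha14(abs(rnorm(100)) + 1, rep(1, 100), image_id = 7),
               "image 7")
})

test_that("the three-parameter fit recovers generated error structure", {
  # identity limit: sigma_true = sigma_c
  d1 <- simulate_intensity_set(4000, 8, inflate = 1, seed = 31)
  f1 <- fit_ev11(d1$group, d1$I, d1$sigma_c)
  expect_lt(abs(f1$sdfac - 1), 0.05)
  expect_lt(abs(f1$sdb), 0.05)
  expect_lt(abs(f1$sdadd), 0.05)
  expect_true(all(f1$bin_variance > 0.85 & f1$bin_variance < 1.15))
  # applying the identity fit reduces to sigma_c (within the fit error)
  s <- apply_ev11(d1$sigma_c, rep(0, nrow(d1)), f1)
  expect_close(s / d1$sigma_c, f1$sdfac, 1e-9)
  # multiplicity < 2 everywhere is an error
  expect_error(fit_ev11(1:10, rnorm(10), rep(1, 10)), "multiplicity")
})

test_that("Ev11 inflation is monotone in the adopted form", {
  p <- list(sdfac = 1.3, sdb = 0.2, sdadd = 0.05)
  sc <- runif(50, 0.5, 2)
  im <- runif(50, 0, 100)
  s <- apply_ev11(sc, im, p)
  expect_true(all(s >= p$sdfac * sc - 1e-12))
  expect_equal(apply_ev11(sc, 0 * im, p), p$sdfac * sc)
})

test_that("signal summaries scale inversely with sigma", {
  I <- rexp(500, 1 / 50); s <- sqrt(I + 10)
  a <- signal_summary(I, s)
  b <- signal_summary(I, 2 * s)
  expect_equal(a$overall / 2, b$overall)
  inv_d <- runif(500, 0.1, 0.45)
  ab <- signal_summary(I, s, inv_d = inv_d, n_bins = 5)
  expect_equal(nrow(ab$binned), 5L)
  expect_error(signal_summary(numeric(0), numeric(0)), "empty")
})
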