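# Shared fixtures, built lazily and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small noisy bundle on the full-size detector
small_bundle <- function() cached_fixture("small", {
  make_experiment(sim_config(seed = 42, n_images = 6, d_min = 2.6))
})

# noiseless, unperturbed-observation bundle (obs == truth exactly)
noiseless_bundle <- function() cached_fixture("noiseless", {
  make_experiment(sim_config(seed = 43, n_images = 4, d_min = 2.6,
                             centroid_noise_px = 0, outlier_frac = 0))
})

# reduced-panel detector for image-space work
small_panel_args <- function() list(distance = 130, asic_fast = 48L,
                                    asic_slow = 44L, pixel = 0.5)

# index-assigned reflections of a bundle (ground-truth crystal models, as
# produced by indexing, against the working detector)
assigned_refl <- function(bundle, det = bundle$work_det, cutoff = 0.3) {
  ptab <- panel_table(det)
  out <- lapply(sort(unique(bundle$obs$image_id)), function(im) {
    oi <- bundle$obs[bundle$obs$image_id == im,
                     c("image_id", "panel", "sensor", "quadrant",
                       "x_obs", "y_obs", "var_x", "var_y",
                       "x_true", "y_true", "intensity", "sigma_c")]
    ai <- assign_indices(oi, bundle$crystals[[im]], bundle$beams[[im]], det,
                         cutoff = cutoff, ptab = ptab)
    ai[!is.na(ai$h), ]
  })
  do.call(rbind, out)
}

expect_close <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)

with_seed_local <- stillsgeom:::with_seed

# internal helpers exercised directly by the tests
panel_matrix <- stillsgeom:::panel_matrix
find_node <- stillsgeom:::find_node
rotation_about_axis <- stillsgeom:::rotation_about_axis
ptab_matrix <- stillsgeom:::ptab_matrix
project_to_panels <- stillsgeom:::project_to_panels
apply_theta_det <- stillsgeom:::apply_theta_det
apply_theta_crystals <- stillsgeom:::apply_theta_crystals
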