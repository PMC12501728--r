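test_that("basis-function maps agree with the NLLS ROI fit on noise-free data", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  spec <- fixture_two_region_spec()
  ph <- build_pet_phantom(spec, sched, input)
  cortex <- ph$labels == 2L
  roi_fit <- fit_1tcm(extract_tac(ph$dynamic, cortex, sched), input)

  grid50 <- theta_grid_default(50)
  maps <- parametric_maps(ph$dynamic, input, sched, delay = roi_fit$delay,
                          theta_grid = grid50, mask = cortex)
  k2_vox <- unique(maps$k2[cortex])
  expect_length(k2_vox, 1L)            # homogeneous region, one solution
  # within one multiplicative grid step of the NLLS estimate
  step <- grid50[2] / grid50[1]
  expect_lt(abs(log(k2_vox / roi_fit$k2)), log(step) * 1.0001)
  expect_rel_equal(unique(maps$K1[cortex]), roi_fit$K1, 0.05)
  expect_equal(unique(maps$perfusion[cortex]), perfusion_from_k2(k2_vox))
})

test_that("refining the clearance grid never increases any voxel's RSS", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  spec <- fixture_two_region_spec()
  ph <- build_pet_phantom(spec, sched, input, psf_fwhm = 6,
                          noise_scale = 0.3, seed = 4)
  mask <- ph$labels > 0
  g30 <- theta_grid_default(30)
  g100 <- theta_grid_default(100)
  # nested grids: every coarse node has a (near-)match in the fine grid
  fine <- parametric_maps(ph$dynamic, input, sched, delay = 4,
                          theta_grid = sort(unique(c(g30, g100))), mask = mask)
  coarse <- parametric_maps(ph$dynamic, input, sched, delay = 4,
                            theta_grid = g30, mask = mask)
  expect_true(all(fine$rss[mask] <= coarse$rss[mask] + 1e-10))
})

test_that("all-zero voxels get K1 = 0 and the blood-term residual", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  dyn <- array(0, c(2, 2, 1, 26))
  maps <- parametric_maps(dyn, input, sched, delay = 0)
  expect_equal(max(maps$K1), 0)
  # RSS equals the weighted Va-term residual
  mid <- frame_midtimes(sched)
  keep <- which(mid <= 150 + 1e-9)
  sw <- frame_schedule(sched$frame_starts[keep], sched$frame_durations[keep])
  w <- sw$frame_durations / sum(sw$frame_durations)
  ca <- renalperf:::.frame_means(input$values, input$time, sw)
  expect_equal(unique(as.numeric(maps$rss)), sum(w * (0.15 * ca)^2),
               tolerance = 1e-10)
})

test_that("clustered IDIF recovers the aorta exactly on a separable phantom", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  spec <- default_phantom_spec()
  ph <- build_pet_phantom(spec, sched, input)
  box <- array(FALSE, spec$shape)
  box[20:28, 20:28, 3:22] <- TRUE
  id <- extract_idif(ph$dynamic, box, sched, n_clusters = 3, seed = 2)
  expect_equal(id$tac$values, ph$region_tacs$aorta$values, tolerance = 1e-12)
  expect_identical(id$mask, ph$labels == 1L)
  expect_error(extract_idif(ph$dynamic, box, sched, n_clusters = 1), ">= 2")
})

test_that("two-cluster partition of a two-region phantom is pure", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  spec <- fixture_two_region_spec()
  ph <- build_pet_phantom(spec, sched, input)
  region <- ph$labels > 0
  id <- extract_idif(ph$dynamic, region, sched, n_clusters = 2, seed = 3)
  lab <- id$cluster_labels[region]
  truth <- ph$labels[region]
  purity <- max(mean((lab == lab[truth == 1][1]) == (truth == 1)),
                mean((lab != lab[truth == 1][1]) == (truth == 1)))
  expect_equal(purity, 1)
  expect_identical(id$mask, ph$labels == 1L)
})

test_that("IDIF peak survives PSF blur within 15%", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  spec <- default_phantom_spec()
  ph <- build_pet_phantom(spec, sched, input, psf_fwhm = 6, seed = 8)
  box <- array(FALSE, spec$shape)
  box[20:28, 20:28, 3:22] <- TRUE
  id <- extract_idif(ph$dynamic, box, sched, n_clusters = 3,
                     keep_fraction = 0.1, seed = 8)
  true_peak <- max(ph$region_tacs$aorta$values)
  expect_rel_equal(max(id$tac$values), true_peak, 0.15)
})
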