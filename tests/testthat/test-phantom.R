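test_that("gamma-variate input matches its analytic integral and invariants", {
  a <- make_aif(peak_time = 25, peak_amplitude = 40, alpha = 3,
                arrival_time = 10, duration = 2000)
  gp <- attr(a, "gamma_params")
  numeric_int <- sum((a$values[-1] + a$values[-length(a$values)]) / 2) * a$dt
  analytic <- gp[["scale"]] * gp[["beta"]]^(gp[["alpha"]] + 1) *
    gamma(gp[["alpha"]] + 1)
  expect_rel_equal(numeric_int, analytic, 0.001)
  # peak placement and amplitude
  expect_equal(max(a$values), 40, tolerance = 0.01 * 40)
  expect_equal(a$time[which.max(a$values)], 25, tolerance = 0.2)
  # non-negativity, zero start, zero amplitude
  expect_true(min(a$values) >= 0)
  expect_equal(a$values[1], 0)
  expect_equal(max(make_aif(25, 0)$values), 0)
  expect_error(make_aif(25, 40, time_step = -1), "positive")
})

test_that("simulated TACs are frame averages of the forward model", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  # no uptake, no blood -> exact zeros
  z <- simulate_tac(kinetic_params(0, 1, 0), input, sched)
  expect_equal(z$values, rep(0, 26))
  # step input plateau: frames average to (1-Va) K1/k2 + Va
  step <- fixture_step_input()
  late <- frame_schedule(c(0, 500), c(500, 50))
  s <- simulate_tac(kinetic_params(0.5, 2.0, 0.15), step, late)
  expect_equal(s$values[2], 0.3625, tolerance = 1e-4)
  # reproducible noise given (inputs, seed)
  n1 <- simulate_tac(kinetic_params(3, 3.19), input, sched, 0.5, seed = 9)
  n2 <- simulate_tac(kinetic_params(3, 3.19), input, sched, 0.5, seed = 9)
  n3 <- simulate_tac(kinetic_params(3, 3.19), input, sched, 0.5, seed = 10)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_error(simulate_tac(kinetic_params(1, 1), input,
                            frame_schedule(0, 1000)), "span")
})

test_that("phantom regions carry their analytic curves and voxel counts", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  spec <- default_phantom_spec()
  ph <- build_pet_phantom(spec, sched, input, psf_fwhm = 0, noise_scale = 0)
  # construction identity: region-mean TAC equals the analytic curve
  for (r in spec$regions) {
    got <- extract_tac(ph$dynamic, ph$labels == r$label, sched)
    expect_equal(got$values, ph$region_tacs[[r$name]]$values,
                 tolerance = 1e-12)
  }
  # voxel counts match brute-force ellipsoid voxelisation
  for (r in spec$regions) {
    cnt <- 0L
    for (i in seq_len(spec$shape[1])) for (j in seq_len(spec$shape[2]))
      for (k in seq_len(spec$shape[3]))
        if (sum(((c(i, j, k) - r$center) / r$semi_axes)^2) <= 1) cnt <- cnt + 1L
    expect_equal(sum(ph$labels == r$label), cnt)
  }
  # overlap detection
  bad <- spec
  bad$regions[[2]]$center <- bad$regions[[1]]$center
  expect_error(build_pet_phantom(bad, sched, input), "overlap")
})

test_that("PSF blur spills hot aorta signal into adjacent tissue", {
  input <- fixture_input()
  sched <- default_frame_schedule()
  # low-uptake tissue column directly abutting the vessel: at the
  # first-pass peak the vessel is an order of magnitude hotter, so
  # spill-in dominates the column's own edge loss
  regions <- list(
    list(name = "aorta", label = 1L, shape = "ellipsoid",
         center = c(8, 10, 5), semi_axes = c(2, 2, 3), is_blood = TRUE),
    list(name = "cortex", label = 2L, shape = "box",
         center = c(11, 10, 5), semi_axes = c(0.4, 0.4, 1),
         params = kinetic_params(0.3, 0.5, 0.05, 4)))
  spec <- phantom_spec(c(20, 20, 10), 3, regions)
  clean <- build_pet_phantom(spec, sched, input, psf_fwhm = 0)
  blurred <- build_pet_phantom(spec, sched, input, psf_fwhm = 9)
  cortex <- clean$labels == 2L
  peak_frame <- which.max(clean$region_tacs$aorta$values)
  mean_clean <- mean(clean$dynamic[, , , peak_frame][cortex])
  mean_blur <- mean(blurred$dynamic[, , , peak_frame][cortex])
  expect_gt(mean_blur, mean_clean)
})

test_that("agreement simulator honours the design and degenerate variances", {
  des <- agreement_design(n_participants = 10)
  vc0 <- variance_components(c(ASL = 0, PET = 0), 0, c(ASL = 0, PET = 0),
                             c(ASL = 0, PET = 0))
  tab <- simulate_agreement_dataset(des, vc0, seed = 5)
  # 60 single-kidney measurements per modality; scan/day linkage
  expect_equal(sum(tab$modality == "ASL"), 60L)
  expect_equal(sum(tab$modality == "PET"), 60L)
  expect_true(all(tab$day[tab$scan == 3] == 2))
  expect_true(all(tab$day[tab$scan != 3] == 1))
  expect_false(any(duplicated(tab[c("participant", "kidney", "scan",
                                    "modality")])))
  # all SDs zero -> exact fixed-effect cell means
  cell <- des$grand_mean + des$modality_effect[tab$modality] +
    des$scan_effect[tab$scan] +
    des$interaction[cbind(match(tab$modality, names(des$modality_effect)),
                          tab$scan)]
  expect_equal(tab$perfusion_ml_min_100ml, unname(cell))
  # bit-reproducibility
  expect_identical(simulate_agreement_dataset(des, vc0, seed = 5), tab)
})

test_that("participant-mean variance converges to the analytic expectation", {
  vc <- variance_components(c(ASL = 50, PET = 50), 20, c(ASL = 10, PET = 10),
                            c(ASL = 30, PET = 30))
  des <- agreement_design(n_participants = 2000)
  tab <- simulate_agreement_dataset(des, vc, seed = 21)
  asl <- tab[tab$modality == "ASL", ]
  fx <- des$grand_mean + des$modality_effect[asl$modality] +
    des$scan_effect[asl$scan] +
    des$interaction[cbind(match(asl$modality, names(des$modality_effect)),
                          asl$scan)]
  resid <- asl$perfusion_ml_min_100ml - fx
  pm <- tapply(resid, asl$participant, mean)
  # participant mean over 2 kidneys x 3 scans: day1 draws enter twice and
  # day2 once per kidney, so var = sP^2 + sK^2/2 + (5/18) sD^2 + sE^2/6
  expected <- 50^2 + 20^2 / 2 + 5 / 18 * 10^2 + 30^2 / 6
  expect_rel_equal(var(pm), expected, 0.05)
})
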