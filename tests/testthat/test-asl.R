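test_that("pair averaging reduces to the voxelwise mean difference", {
  spat <- c(3, 3, 2)
  ctrl <- array(100, c(2, spat)); lab <- array(100, c(2, spat))
  pd <- array(1000, spat)
  # identical control and label -> zero difference
  avg <- average_pairs(asl_series(ctrl, lab, pd))
  expect_equal(avg$delta_m, array(0, spat))
  expect_equal(avg$m0, pd)
  # two pairs with differences 40 and 44 -> 42
  lab2 <- lab; lab2[1, , , ] <- 100 - 40; lab2[2, , , ] <- 100 - 44
  avg2 <- average_pairs(asl_series(ctrl, lab2, pd))
  expect_equal(avg2$delta_m, array(42, spat))
  expect_error(asl_series(ctrl, lab[1, , , , drop = FALSE], pd), "shape")
})

test_that("FAIR quantification inverts the forward signal exactly", {
  params <- asl_params()
  # zero difference -> zero perfusion
  expect_equal(quantify_perfusion(array(0, c(2, 2)), array(1000, c(2, 2)),
                                  params)$values,
               array(0, c(2, 2)))
  # hand-checked worked value: dM 41.608 at M0 1000 -> 300 mL/min/100 mL
  dm <- 300 * 2 * 0.6375 * 1.5 * 1000 * exp(-1.5 / 1.6) / (6000 * 0.9)
  expect_equal(dm, 41.608, tolerance = 1e-4)
  f <- quantify_perfusion(array(dm, 1), array(1000, 1), params)
  expect_equal(as.numeric(f$values), 300, tolerance = 1e-9)
  # linearity in delta_m, inverse scaling in m0
  f2 <- quantify_perfusion(array(2 * dm, 1), array(1000, 1), params)
  expect_equal(as.numeric(f2$values), 600, tolerance = 1e-6)
  f3 <- quantify_perfusion(array(dm, 1), array(2000, 1), params)
  expect_equal(as.numeric(f3$values), 150, tolerance = 1e-6)
  # invalid voxels flagged where m0 <= 0
  f4 <- quantify_perfusion(array(dm, c(1, 2)), array(c(1000, 0), c(1, 2)), params)
  expect_equal(f4$valid[1, ], c(TRUE, FALSE))
  expect_true(is.na(f4$values[1, 2]))
})

test_that("ASL forward/inverse round trip is exact on noise-free series", {
  f0 <- array(c(100, 200, 300, 450), c(2, 2))
  m0 <- array(1000, c(2, 2))
  series <- build_asl_series(f0, m0, n_pairs = 3, noise_sd = 0)
  avg <- average_pairs(series)
  out <- quantify_perfusion(avg$delta_m, avg$m0)
  expect_rel_equal(out$values, f0, 1e-9)
  # zero flow -> zero difference
  s0 <- build_asl_series(array(0, c(2, 2)), m0, n_pairs = 2, noise_sd = 0)
  expect_equal(max(abs(s0$control - s0$label)), 0)
})

test_that("ROI mean applies the 500 mL/min/100 mL exclusion rule", {
  mk <- function(v) structure(list(values = v, valid = rep(TRUE, length(v))),
                              class = "perfusion_map")
  r <- roi_perfusion(mk(c(300, 400, 600)), c(1, 1, 1))
  expect_equal(r$mean, 350)
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$n_used, 2L)
  r2 <- roi_perfusion(mk(rep(250, 5)), rep(1, 5))
  expect_equal(r2$mean, 250)
  expect_equal(r2$n_excluded, 0L)
  expect_error(roi_perfusion(mk(c(600, 700)), c(1, 1)), "exceed")
  # permutation invariance and threshold monotonicity
  v <- c(480, 120, 300, 510, 90, 505)
  r3 <- roi_perfusion(mk(v), rep(1, 6))
  r4 <- roi_perfusion(mk(sample(v)), rep(1, 6))
  expect_equal(r3$mean, r4$mean)
  loose <- roi_perfusion(mk(v), rep(1, 6), asl_params(exclusion_threshold = 520))
  expect_equal(loose$n_used, 6L)
  expect_equal(loose$mean, mean(v))
})

test_that("slice QC keeps clean slices and drops pure-noise slices", {
  set.seed(42)
  stack <- array(50, c(4, 16, 16))      # 4 clean slices of positive signal
  expect_equal(slice_qc(stack), rep(TRUE, 4))
  stack[2, , ] <- rnorm(256, 0, 10)     # zero-mean noise slice
  qc <- slice_qc(stack)
  expect_equal(qc, c(TRUE, FALSE, TRUE, TRUE))
  # criteria disabled -> pass-through
  expect_equal(slice_qc(stack, NA, NA), rep(TRUE, 4))
})

test_that("mean difference over noisy pairs obeys the standard-error law", {
  f0 <- array(300, c(25, 40)); m0 <- array(1000, c(25, 40))
  n_pairs <- 8; noise_sd <- 5
  series <- build_asl_series(f0, m0, n_pairs = n_pairs, noise_sd = noise_sd,
                             seed = 11)
  avg <- average_pairs(series)
  truth <- 300 * 2 * 0.6375 * 1.5 * 1000 * exp(-1.5 / 1.6) / (6000 * 0.9)
  # voxelwise SD of the mean difference ~ noise_sd * sqrt(2 / n_pairs)
  emp_sd <- sd(avg$delta_m)
  expect_rel_equal(emp_sd, noise_sd * sqrt(2 / n_pairs), 0.10)
  expect_lt(abs(mean(avg$delta_m) - truth), 3 * noise_sd * sqrt(2 / n_pairs) /
              sqrt(length(f0)))
})
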