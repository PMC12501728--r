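# Shared fixtures built in code at test time.

# Smooth arterial input with a mild recirculation tail, spanning the
# default 420-s schedule.
fixture_input <- function() make_aif(peak_time = 30, peak_amplitude = 40,
                                     alpha = 3, arrival_time = 10,
                                     recirc_fraction = 0.1)

# Step input: Ca = 1 for t >= dt, long span for asymptotic checks.
fixture_step_input <- function(span = 600) {
  tgrid <- seq(0, span, by = 0.1)
  aif(tgrid, c(0, rep(1, length(tgrid) - 1L)))
}

# A small two-region phantom spec (one blood vessel next to one tissue
# slab) for spill-over and clustering tests.
fixture_two_region_spec <- function(gap = 3) {
  regions <- list(
    list(name = "aorta", label = 1L, shape = "ellipsoid",
         center = c(8, 10, 5), semi_axes = c(2, 2, 3), is_blood = TRUE),
    list(name = "cortex", label = 2L, shape = "ellipsoid",
         center = c(12 + gap, 10, 5), semi_axes = c(2.5, 4, 3),
         params = kinetic_params(3.0, 3.19, 0.15, 4)))
  phantom_spec(c(20, 20, 10), 3, regions)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), rel_tol)
}
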