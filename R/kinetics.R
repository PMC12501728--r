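#' One-tissue-compartment kinetic parameters
#'
#' Parameters of the standard one-tissue compartment model (1TCM) for a
#' freely diffusible tracer: uptake rate `K1` (mL/min/mL), clearance rate
#' `k2` (1/min), fractional arterial blood volume `Va` (mL/mL) and an
#' arrival time delay of the tissue curve relative to the input function
#' (s).  Tissue tracer concentration follows
#' `dCt/dt = K1 Ca(t - delay) - k2 Ct(t)`.
#'
#' @param K1 Uptake rate constant, mL/min/mL, `>= 0`.
#' @param k2 Clearance rate constant, 1/min, `>= 0`.
#' @param va Arterial blood volume fraction, in `[0, 1)`.  Default 0.15.
#' @param delay Time delay, s.  Default 0.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, va = 0.15, delay = 0) {
  if (K1 < 0 || k2 < 0) stop("K1 and k2 must be non-negative")
  if (va < 0 || va >= 1) stop("va must lie in [0, 1)")
  structure(list(K1 = K1, k2 = k2, va = va, delay = delay),
            class = "kinetic_params")
}

#' Configuration for 1TCM fitting
#'
#' @param fit_window Only frames whose midpoint time is `<=` this value (s)
#'   enter the fit.  Default 150 s.
#' @param partition_coefficient Tissue-blood partition coefficient `p`
#'   (mL/g) used to convert clearance to perfusion.  Default 0.94.
#' @param delay_bounds Search bounds for the time delay (s).  Default
#'   `c(-10, 10)`.
#' @param delay_step Delay grid step (s).  Default 0.5; the grid minimum is
#'   refined parabolically.
#' @param weights Per-frame weight scheme, `"duration"` (default) or
#'   `"uniform"`.
#' @param blood_model Measurement equation: `"mixed"` (default) uses
#'   `C = (1 - Va) Ct + Va Ca`; `"additive"` uses `C = Ct + Va Ca`.
#' @param k2_range Bracket for the clearance search, 1/min.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(fit_window = 150, partition_coefficient = 0.94,
                       delay_bounds = c(-10, 10), delay_step = 0.5,
                       weights = c("duration", "uniform"),
                       blood_model = c("mixed", "additive"),
                       k2_range = c(0.01, 20)) {
  weights <- match.arg(weights)
  blood_model <- match.arg(blood_model)
  if (fit_window <= 0 || partition_coefficient <= 0)
    stop("fit_window and partition_coefficient must be positive")
  structure(list(fit_window = fit_window,
                 partition_coefficient = partition_coefficient,
                 delay_bounds = sort(delay_bounds), delay_step = delay_step,
                 weights = weights, blood_model = blood_model,
                 k2_range = k2_range),
            class = "fit_config")
}

#' Time-activity curve container
#'
#' @param values Frame-mean activity concentrations (kBq/mL), one per frame.
#' @param schedule The [frame_schedule()] the values were measured on.
#' @return Object of class `tac`.
#' @export
tac <- function(values, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != length(schedule$frame_starts))
    stop("values length must match the number of frames")
  structure(list(values = as.numeric(values), schedule = schedule),
            class = "tac")
}

# Causal exponential convolution integral(0..t) x(s) exp(-lambda (t - s)) ds
# on a uniform grid, exact for piecewise-linear x.  The per-interval
# increments feed a first-order recursive filter (C implementation in
# stats::filter), so the cost is linear in grid length.
.conv_exp <- function(x, dt, lambda) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  lh <- lambda * dt
  if (lh < 1e-7) {
    A <- dt * (1 - lh / 2 + lh^2 / 6)
    G <- dt * (0.5 - lh / 3 + lh^2 / 8)   # (1 - e^-lh (1 + lh)) / (lambda^2 h)
  } else {
    e <- exp(-lh)
    A <- (1 - e) / lambda
    G <- (1 - e * (1 + lh)) / (lambda^2 * dt)
  }
  B <- A - G
  u <- x[-n] * (A - B) + x[-1L] * B
  out <- stats::filter(u, exp(-lh), method = "recursive")
  c(0, as.numeric(out))
}

# Cumulative trapezoidal integral on a uniform grid.
.cumtrapz <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1L] + y[-n]) / 2) * dt)
}

# Frame means of a fine-grid curve: differences of the cumulative integral
# at frame boundaries divided by frame durations.
.frame_means <- function(values, time, schedule) {
  cumint <- .cumtrapz(values, time[2] - time[1])
  ends <- schedule$frame_starts + schedule$frame_durations
  ia <- stats::approx(time, cumint, xout = schedule$frame_starts, rule = 2)$y
  ib <- stats::approx(time, cumint, xout = ends, rule = 2)$y
  (ib - ia) / schedule$frame_durations
}

#' Forward 1TCM prediction
#'
#' Computes the modelled tracer concentration
#' `C(t) = (1 - Va) Ct(t) + Va Ca(t - delay)` with
#' `Ct(t) = K1 [Ca(. - delay) * exp(-k2 .)](t)`, evaluated by exact
#' convolution of the piecewise-linear input on its fine grid.  Rate
#' constants are given per minute and converted to per second internally.
#'
#' @param params A [kinetic_params()].
#' @param input An [aif()].
#' @param eval_times Times (s) at which to return the prediction; must lie
#'   within the input's span.
#' @param blood_model `"mixed"` (default) or `"additive"`, see
#'   [fit_config()].
#' @return Numeric vector of concentrations at `eval_times`.
#' @export
predict_curve <- function(params, input, eval_times,
                          blood_model = c("mixed", "additive")) {
  stopifnot(inherits(params, "kinetic_params"), inherits(input, "aif"))
  blood_model <- match.arg(blood_model)
  span <- input$time[length(input$time)]
  if (any(eval_times < 0) || any(eval_times > span + 1e-9))
    stop("eval_times must lie within the input function's span")
  fine <- .predict_on_grid(params, input, blood_model)
  stats::approx(input$time, fine, xout = eval_times, rule = 2)$y
}

# Model curve on the input's own grid.
.predict_on_grid <- function(params, input, blood_model = "mixed") {
  ca_d <- aif_at(input, input$time, delay = params$delay)
  k1s <- params$K1 / 60
  k2s <- params$k2 / 60
  ct <- if (k1s > 0) k1s * .conv_exp(ca_d, input$dt, k2s) else numeric(length(ca_d))
  tisw <- if (blood_model == "mixed") 1 - params$va else 1
  tisw * ct + params$va * ca_d
}

# Frame-averaged model prediction for a schedule.
.predict_frames <- function(params, input, schedule, blood_model = "mixed") {
  fine <- .predict_on_grid(params, input, blood_model)
  .frame_means(fine, input$time, schedule)
}

#' Convert clearance rate to perfusion
#'
#' For a freely diffusible tracer, perfusion equals the clearance rate `k2`
#' multiplied by the tissue-blood partition coefficient `p`; the factor 100
#' converts mL/min/mL to mL/min/100 mL (unit tissue density assumed).
#'
#' @param k2 Clearance rate, 1/min, `>= 0`.
#' @param p Partition coefficient, mL/g.  Default 0.94.
#' @return Perfusion in mL/min/100 mL: `k2 * p * 100`.
#' @examples
#' perfusion_from_k2(1)      # 94
#' perfusion_from_k2(3.19)   # 299.86
#' @export
perfusion_from_k2 <- function(k2, p = 0.94) {
  if (any(k2 < 0)) stop("k2 must be non-negative")
  if (p <= 0) stop("partition coefficient must be positive")
  k2 * p * 100
}

#' Extract a region time-activity curve from a dynamic image
#'
#' @param dynamic 4D array (x, y, z, frame) of activity concentrations.
#' @param mask 3D logical or numeric array; voxels with `mask > 0` define
#'   the region.
#' @param schedule The [frame_schedule()] of the dynamic series.
#' @return A [tac()] of per-frame means over the region.
#' @export
extract_tac <- function(dynamic, mask, schedule) {
  stopifnot(length(dim(dynamic)) == 4L)
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("empty ROI: mask selects no voxels")
  nf <- dim(dynamic)[4]
  if (nf != length(schedule$frame_starts))
    stop("frame count mismatch between image and schedule")
  vox <- matrix(dynamic, ncol = nf)[idx, , drop = FALSE]
  tac(colMeans(vox), schedule)
}

# Weighted profile fit of K1 at fixed (k2, delay); returns list(K1_s, rss).
.profile_k1 <- function(k2_min, ca_d_fine, input_time, dt, schedule_w,
                        y, w, blood_y, tisw) {
  tf <- .frame_means(.conv_exp(ca_d_fine, dt, k2_min / 60), input_time, schedule_w)
  tp <- tisw * tf
  num <- sum(w * tp * blood_y)
  den <- sum(w * tp * tp)
  k1s <- if (den > 0) max(0, num / den) else 0
  resid <- blood_y - k1s * tp
  list(k1s = k1s, rss = sum(w * resid^2))
}

#' Fit the one-tissue compartment model to a region TAC
#'
#' Weighted nonlinear least squares over `(K1, k2)` with a grid-searched,
#' parabolically refined arterial delay and a fixed blood volume fraction.
#' Only frames whose midpoint lies within the configured fit window are
#' used; model values are frame averages of the forward prediction so that
#' fitted and simulated curves live on the same footing.  `K1` is profiled
#' linearly at each `(k2, delay)`, and `k2` is minimised by bracketed 1-D
#' search on the log scale.
#'
#' @param region_tac A [tac()].
#' @param input An [aif()] (measured or image-derived).
#' @param config A [fit_config()].
#' @param va Fixed arterial blood volume fraction.  Default 0.15.
#' @return Object of class `onetcm_fit`: `K1` (mL/min/mL), `k2` (1/min),
#'   `va`, `delay` (s), `perfusion` (mL/min/100 mL, `k2 * p * 100`),
#'   `rss` (weighted), `frames_used`, `converged`.
#' @export
fit_1tcm <- function(region_tac, input, config = fit_config(), va = 0.15) {
  stopifnot(inherits(region_tac, "tac"), inherits(input, "aif"),
            inherits(config, "fit_config"))
  sched <- region_tac$schedule
  mid <- frame_midtimes(sched)
  keep <- which(mid <= config$fit_window + 1e-9)
  if (length(keep) < 4L) stop("insufficient frames within the fit window")
  sched_w <- frame_schedule(sched$frame_starts[keep], sched$frame_durations[keep])
  y <- region_tac$values[keep]
  w <- if (config$weights == "duration") sched_w$frame_durations else
    rep(1, length(keep))
  w <- w / sum(w)
  tisw <- if (config$blood_model == "mixed") 1 - va else 1

  # restrict the fine grid to the fit window plus a delay margin
  span_need <- schedule_span(sched_w) + max(abs(config$delay_bounds)) + 5
  n_keep <- min(length(input$time), ceiling(span_need / input$dt) + 1L)
  tgrid <- input$time[seq_len(n_keep)]
  vals <- input$values[seq_len(n_keep)]

  delays <- seq(config$delay_bounds[1], config$delay_bounds[2],
                by = config$delay_step)
  k2grid <- exp(seq(log(config$k2_range[1]), log(config$k2_range[2]),
                    length.out = 13))

  fit_at_delay <- function(delay) {
    ca_d <- stats::approx(tgrid, vals, xout = tgrid - delay, yleft = 0,
                          yright = vals[length(vals)])$y
    ca_f <- .frame_means(ca_d, tgrid, sched_w)
    blood_y <- y - va * ca_f
    rss_k2 <- function(k2) .profile_k1(k2, ca_d, tgrid, input$dt, sched_w,
                                       y, w, blood_y, tisw)$rss
    rg <- vapply(k2grid, rss_k2, numeric(1))
    j <- which.min(rg)
    lo <- k2grid[max(1L, j - 1L)]; hi <- k2grid[min(length(k2grid), j + 1L)]
    op <- stats::optimize(function(l) rss_k2(exp(l)), c(log(lo), log(hi)),
                          tol = 1e-7)
    k2 <- exp(op$minimum)
    pk <- .profile_k1(k2, ca_d, tgrid, input$dt, sched_w, y, w, blood_y, tisw)
    list(k2 = k2, k1s = pk$k1s, rss = pk$rss)
  }

  fits <- lapply(delays, fit_at_delay)
  rss_d <- vapply(fits, `[[`, numeric(1), "rss")
  j <- which.min(rss_d)
  delay <- delays[j]
  # parabolic refinement through the minimum and its neighbours
  if (j > 1L && j < length(delays)) {
    r1 <- rss_d[j - 1L]; r2 <- rss_d[j]; r3 <- rss_d[j + 1L]
    den <- r1 - 2 * r2 + r3
    if (den > 1e-300) {
      shift <- 0.5 * (r1 - r3) / den * config$delay_step
      if (abs(shift) <= config$delay_step) delay <- delays[j] + shift
    }
  }
  best <- fit_at_delay(delay)
  if (best$rss > rss_d[j]) { delay <- delays[j]; best <- fits[[j]] }

  k2 <- best$k2
  converged <- k2 > config$k2_range[1] * 1.001 && k2 < config$k2_range[2] * 0.999
  if (!converged)
    warning("fit_1tcm: clearance estimate at the search boundary; fit flagged")
  structure(list(K1 = best$k1s * 60, k2 = k2, va = va, delay = delay,
                 perfusion = perfusion_from_k2(k2, config$partition_coefficient),
                 rss = best$rss, frames_used = length(keep),
                 converged = converged),
            class = "onetcm_fit")
}

#' @export
print.onetcm_fit <- function(x, ...) {
  cat(sprintf(paste0("<1TCM fit: K1 = %.3f mL/min/mL, k2 = %.3f /min, ",
                     "delay = %.2f s, perfusion = %.1f mL/min/100 mL, ",
                     "%d frames%s>\n"),
              x$K1, x$k2, x$delay, x$perfusion, x$frames_used,
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}
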