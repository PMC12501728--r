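#' Arterial input function container
#'
#' An arterial input function (AIF) is the tracer concentration in arterial
#' blood sampled on a fine, uniform time grid starting at 0 s.  All kinetic
#' operations in the package interpolate linearly on this grid.
#'
#' @param time Numeric vector of sample times (s), uniformly spaced from 0.
#' @param values Numeric vector of activity concentrations (kBq/mL), finite
#'   and non-negative, with `values[1] == 0`.
#' @return Object of class `aif` with elements `time`, `values` and the
#'   grid step `dt`.
#' @export
aif <- function(time, values) {
  time <- as.numeric(time); values <- as.numeric(values)
  if (length(time) != length(values) || length(time) < 2L)
    stop("time and values must have equal length >= 2")
  dt <- diff(time)
  if (time[1] != 0 || any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time must be uniformly spaced, strictly increasing, starting at 0")
  if (any(!is.finite(values)) || any(values < -1e-12))
    stop("AIF values must be finite and non-negative")
  values[values < 0] <- 0
  structure(list(time = time, values = values, dt = dt[1]), class = "aif")
}

#' Synthetic gamma-variate arterial input function
#'
#' Builds a first-pass bolus as a gamma-variate,
#' `A (t - t0)^alpha exp(-(t - t0)/beta)` for `t > t0`, scaled so that the
#' curve peaks at `peak_amplitude` at `t = peak_time`, with an optional
#' exponential recirculation tail.  The gamma-variate has the closed-form
#' integral `A beta^(alpha+1) Gamma(alpha+1)` over `[t0, Inf)`, which makes
#' the generator easy to validate numerically.
#'
#' @param peak_time Time of the first-pass peak (s), `> arrival_time`.
#' @param peak_amplitude Peak concentration (kBq/mL), `>= 0`.
#' @param alpha Gamma-variate shape parameter (unitless, default 3).
#' @param arrival_time Tracer arrival time `t0` (s, default 10); the curve
#'   is exactly 0 before it.
#' @param recirc_fraction Amplitude of the recirculation tail as a fraction
#'   of the peak (default 0, i.e. pure gamma-variate).
#' @param recirc_tau Time constant of the recirculation decay (s, default 120).
#' @param time_step Grid step (s, default 0.1, must be <= 0.5).
#' @param duration Total grid span (s, default 420).
#' @return An [aif()].  The attribute `"gamma_params"` records
#'   `(scale, alpha, beta, t0)` of the first-pass term.
#' @examples
#' a <- make_aif(peak_time = 25, peak_amplitude = 40)
#' max(a$values)   # 40 (up to grid resolution)
#' @export
make_aif <- function(peak_time, peak_amplitude, alpha = 3, arrival_time = 10,
                     recirc_fraction = 0, recirc_tau = 120,
                     time_step = 0.1, duration = 420) {
  if (duration <= 0 || time_step <= 0) stop("duration and time_step must be positive")
  if (time_step > 0.5) stop("time_step must be <= 0.5 s")
  if (peak_time <= arrival_time) stop("peak_time must exceed arrival_time")
  if (peak_amplitude < 0) stop("peak_amplitude must be non-negative")
  if (alpha <= 0) stop("alpha must be positive")
  time <- seq(0, duration, by = time_step)
  beta <- (peak_time - arrival_time) / alpha
  ts <- pmax(time - arrival_time, 0)
  # raw gamma-variate peaks at alpha*beta with value (alpha*beta)^alpha e^-alpha
  scale <- if (peak_amplitude == 0) 0 else
    peak_amplitude / ((alpha * beta)^alpha * exp(-alpha))
  values <- scale * ts^alpha * exp(-ts / beta)
  if (recirc_fraction > 0 && peak_amplitude > 0) {
    tr <- pmax(time - peak_time, 0)
    values <- values + recirc_fraction * peak_amplitude *
      (1 - exp(-tr / (recirc_tau / 4))) * exp(-tr / recirc_tau)
  }
  out <- aif(time, values)
  attr(out, "gamma_params") <- c(scale = scale, alpha = alpha, beta = beta,
                                 t0 = arrival_time)
  out
}

#' Evaluate an AIF at arbitrary times
#'
#' Linear interpolation on the AIF grid, optionally with a delay shift:
#' returns `Ca(t - delay)`, taking the curve as 0 before its grid start and
#' holding the last sample after its end.
#'
#' @param a An [aif()].
#' @param t Times (s) at which to evaluate.
#' @param delay Delay shift (s, default 0); positive delays move the curve
#'   later in time.
#' @return Numeric vector of concentrations.
#' @export
aif_at <- function(a, t, delay = 0) {
  stopifnot(inherits(a, "aif"))
  stats::approx(a$time, a$values, xout = t - delay, yleft = 0,
                yright = a$values[length(a$values)])$y
}

#' Convert a frame-sampled curve to an AIF on a fine grid
#'
#' Used for image-derived input functions.  The default reconstruction is
#' mean-preserving: a piecewise-linear curve over the frame boundaries is
#' solved so that its average over every frame equals the observed frame
#' value (`v[i] = 2 m[i] - v[i-1]`, anchored at 0), which retains the
#' height of a sharp first-pass peak that plain midtime interpolation
#' flattens.  `"midpoint"` interpolates the frame values at frame midtimes
#' instead (more robust to very noisy curves).  Either way the result is
#' clamped non-negative on a uniform grid from 0.
#'
#' @param values Frame values (kBq/mL).
#' @param schedule The [frame_schedule()] the values were sampled on.
#' @param time_step Target grid step (s, default 0.1).
#' @param method `"mean-preserving"` (default) or `"midpoint"`.
#' @return An [aif()].
#' @export
aif_from_tac <- function(values, schedule, time_step = 0.1,
                         method = c("mean-preserving", "midpoint")) {
  method <- match.arg(method)
  span <- schedule_span(schedule)
  time <- seq(0, span, by = time_step)
  if (method == "mean-preserving") {
    n <- length(values)
    v <- numeric(n + 1L)
    for (i in seq_len(n)) v[i + 1L] <- 2 * values[i] - v[i]
    v <- pmax(v, 0)
    bounds <- c(schedule$frame_starts, span)
    out <- stats::approx(bounds, v, xout = time, rule = 2)$y
  } else {
    out <- stats::approx(c(0, frame_midtimes(schedule)), c(0, values),
                         xout = time, rule = 2)$y
  }
  aif(time, pmax(out, 0))
}
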