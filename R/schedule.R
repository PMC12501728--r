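#' Dynamic PET frame schedule
#'
#' A frame schedule is the ordered list of acquisition frame start times and
#' durations (seconds) that defines the temporal sampling of a dynamic PET
#' series.  Frames must be contiguous: each frame starts where the previous
#' one ends.
#'
#' @param frame_starts Numeric vector of frame start times in seconds.
#' @param frame_durations Numeric vector of frame durations in seconds,
#'   same length as `frame_starts`, all positive.
#' @return An object of class `frame_schedule` with elements
#'   `frame_starts` and `frame_durations`.
#' @examples
#' sched <- default_frame_schedule()
#' length(sched$frame_starts)           # 26 frames
#' sum(sched$frame_durations)           # 420 s total
#' @export
frame_schedule <- function(frame_starts, frame_durations) {
  frame_starts <- as.numeric(frame_starts)
  frame_durations <- as.numeric(frame_durations)
  if (length(frame_starts) != length(frame_durations) || length(frame_starts) == 0L)
    stop("frame_starts and frame_durations must be non-empty and of equal length")
  if (any(frame_durations <= 0)) stop("frame durations must be positive")
  n <- length(frame_starts)
  if (n > 1L) {
    expected <- frame_starts[-n] + frame_durations[-n]
    if (max(abs(frame_starts[-1L] - expected)) > 1e-9)
      stop("frame schedule must be contiguous: start[i+1] = start[i] + duration[i]")
  }
  structure(list(frame_starts = frame_starts, frame_durations = frame_durations),
            class = "frame_schedule")
}

#' Default 26-frame water-PET schedule
#'
#' The standard 7-minute [15O]H2O acquisition framing used throughout this
#' package: 1 x 10, 8 x 5, 4 x 10, 2 x 15, 3 x 20 and 8 x 30 s
#' (26 frames, 420 s in total).
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  durations <- c(10, rep(5, 8), rep(10, 4), rep(15, 2), rep(20, 3), rep(30, 8))
  frame_schedule(cumsum(c(0, durations[-length(durations)])), durations)
}

#' Frame midpoint times
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector: `start + duration / 2` for each frame, in seconds.
#' @export
frame_midtimes <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$frame_starts + schedule$frame_durations / 2
}

#' Total duration of a schedule in seconds
#' @param schedule A [frame_schedule()].
#' @return Scalar end time of the last frame.
#' @export
schedule_span <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  n <- length(schedule$frame_starts)
  schedule$frame_starts[n] + schedule$frame_durations[n]
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.0f s total>\n",
              length(x$frame_starts), schedule_span(x)))
  invisible(x)
}
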