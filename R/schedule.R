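#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is the list of contiguous, non-overlapping time bins the
#' emission data were reconstructed into. All times are minutes post
#' injection.
#'
#' @param frame_start,frame_end Numeric vectors of frame start/end times in
#'   minutes; must be non-overlapping and increasing.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `frame_start`, `frame_end`, `mid`, `dur`.
#' @seealso [default_frame_schedule()] for the 45-frame / 180-min protocol
#'   used throughout the package examples.
#' @export
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) != length(frame_end) || length(frame_start) < 1L)
    stop_petkin("frame_start and frame_end must be equal-length, non-empty vectors")
  if (any(frame_end <= frame_start))
    stop_petkin("every frame_end must exceed its frame_start")
  if (is.unsorted(frame_start, strictly = TRUE) ||
      any(frame_start[-1] < frame_end[-length(frame_end)] - 1e-9))
    stop_petkin("frames must be increasing and non-overlapping")
  out <- data.frame(frame_start = as.numeric(frame_start),
                    frame_end = as.numeric(frame_end))
  out$mid <- (out$frame_start + out$frame_end) / 2
  out$dur <- out$frame_end - out$frame_start
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default 45-frame, 180-minute schedule
#'
#' 6 x 30 s, 3 x 1 min, 2 x 2 min, then 34 x 5 min, spanning 0-180 min —
#' the standard long-scan protocol for slow-kinetic radiotracers on a
#' small-animal scanner.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 34))
  ends <- cumsum(dur)
  frame_schedule(ends - dur, ends)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.4g-%.4g min\n",
              nrow(x), x$frame_start[1], x$frame_end[nrow(x)]))
  invisible(x)
}

#' Regional time-activity curve
#'
#' Frame-averaged activity concentration for one region of interest, with
#' its frame schedule and fitting weights. Default weights are proportional
#' to frame duration; alternatives are uniform weights or duration^2 /
#' activity (an approximation to inverse count variance).
#'
#' @param roi_name Region label.
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector, kBq/cm3, one value per frame.
#' @param weights Optional non-negative weights per frame; defaults to
#'   frame durations.
#' @return Object of class `tac`.
#' @export
tac <- function(roi_name, schedule, activity, weights = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(activity) != nrow(schedule))
    stop_petkin("tac '%s': %d activity values for %d frames",
                roi_name, length(activity), nrow(schedule))
  if (is.null(weights)) weights <- schedule$dur
  if (length(weights) != nrow(schedule) || any(weights < 0))
    stop_petkin("weights must be non-negative, one per frame")
  structure(list(roi_name = as.character(roi_name), schedule = schedule,
                 activity = as.numeric(activity), weights = as.numeric(weights)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> roi '%s': %d frames, %.4g-%.4g min, peak %.3g kBq/cm3\n",
              x$roi_name, nrow(x$schedule), x$schedule$frame_start[1],
              x$schedule$frame_end[nrow(x$schedule)], max(x$activity)))
  invisible(x)
}

## Subset a tac to a logical/integer frame index, keeping weights aligned.
subset_tac <- function(x, keep) {
  sched <- frame_schedule(x$schedule$frame_start[keep], x$schedule$frame_end[keep])
  tac(x$roi_name, sched, x$activity[keep], x$weights[keep])
}
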