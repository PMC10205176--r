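#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule records, in seconds, when each reconstructed frame starts
#' and how long it lasts. Frames must be contiguous (each frame starts where
#' the previous one ends) and non-overlapping.
#'
#' @param start_s numeric vector of frame start times (seconds).
#' @param duration_s numeric vector of frame durations (seconds), all > 0.
#' @return An object of class `frame_schedule`: a data.frame with columns
#'   `start_s` and `duration_s`.
#' @export
#' @examples
#' frame_schedule(c(0, 30), c(30, 30))
frame_schedule <- function(start_s, duration_s) {
  if (length(start_s) != length(duration_s) || length(start_s) < 1L) {
    stop("start_s and duration_s must be equal-length, non-empty vectors")
  }
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s))) {
    stop("frame times must be finite")
  }
  if (any(duration_s <= 0)) stop("frame durations must be positive")
  if (any(diff(start_s) <= 0)) stop("frame starts must be strictly increasing")
  ends <- start_s + duration_s
  if (length(start_s) > 1L &&
      any(abs(start_s[-1L] - ends[-length(ends)]) > 1e-9)) {
    stop("frames must be contiguous and non-overlapping")
  }
  out <- data.frame(start_s = as.numeric(start_s),
                    duration_s = as.numeric(duration_s))
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' The default 60-minute, 22-frame acquisition protocol
#'
#' Builds the frame schedule used throughout the package: 4 frames of 30 s,
#' 4 of 60 s, 4 of 120 s, 4 of 240 s and 6 of 300 s, spanning 60 minutes.
#' Frame k starts at the cumulative sum of the earlier durations.
#'
#' @return A [frame_schedule()] with 22 frames totalling 3600 s.
#' @export
#' @examples
#' sched <- make_frame_schedule()
#' nrow(sched)                    # 22
#' sum(sched$duration_s)          # 3600
make_frame_schedule <- function() {
  dur <- c(rep(30, 4), rep(60, 4), rep(120, 4), rep(240, 4), rep(300, 6))
  frame_schedule(start_s = cumsum(c(0, dur[-length(dur)])), duration_s = dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Dynamic PET frame schedule: %d frames, %.1f min total\n",
              nrow(x), sum(x$duration_s) / 60))
  print.data.frame(x, ...)
  invisible(x)
}

n_frames <- function(schedule) nrow(schedule)

frame_end_s <- function(schedule) schedule$start_s + schedule$duration_s

#' Frame midpoints in minutes
#' @param schedule a [frame_schedule()].
#' @return numeric vector of frame midpoint times (minutes).
#' @export
frame_mid_min <- function(schedule) {
  (schedule$start_s + schedule$duration_s / 2) / 60
}

total_duration_s <- function(schedule) {
  frame_end_s(schedule)[n_frames(schedule)]
}

same_schedule <- function(a, b) {
  nrow(a) == nrow(b) &&
    max(abs(a$start_s - b$start_s), abs(a$duration_s - b$duration_s)) < 1e-6
}

#' Write / read a frame-timing sidecar
#'
#' The sidecar is a plain CSV with columns `start_s,duration_s`, one row per
#' frame, matching the on-disk convention for dynamic NIfTI volumes.
#'
#' @param schedule a [frame_schedule()].
#' @param path file path of the CSV sidecar.
#' @return `write_frame_schedule` returns `path` invisibly;
#'   `read_frame_schedule` returns a [frame_schedule()].
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_schedule
#' @export
read_frame_schedule <- function(path) {
  df <- utils::read.csv(path)
  frame_schedule(df$start_s, df$duration_s)
}
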