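#' Dynamic PET frame schedule
#'
#' A frame schedule records, in seconds, when each frame of a dynamic
#' acquisition starts and how long it lasts. Frames must tile the scan
#' contiguously (no gaps, no overlap) and a usable dynamic study needs at
#' least three frames. Frame mid-times are derived as `start + duration/2`.
#'
#' @param start numeric vector of frame start times (seconds).
#' @param duration numeric vector of frame durations (seconds), same length.
#' @return An object of class `frame_schedule`: a list with elements
#'   `start`, `duration`, `mid` (all seconds), `n_frames` and
#'   `total_duration`.
#' @examples
#' sch <- frame_schedule(c(0, 30, 60), c(30, 30, 30))
#' sch$total_duration
#' @export
frame_schedule <- function(start, duration) {
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) != length(duration))
    stop("frame start and duration vectors differ in length")
  n <- length(start)
  if (n < 3)
    stop("a frame schedule needs at least 3 frames, got ", n)
  if (anyNA(start) || anyNA(duration))
    stop("frame timings contain missing values")
  bad <- which(duration <= 0)
  if (length(bad))
    stop("non-positive duration at frame ", bad[1])
  gap <- which(abs(start[-1] - (start[-n] + duration[-n])) > 1e-6)
  if (length(gap))
    stop("non-contiguous frames: frame ", gap[1] + 1,
         " starts at ", start[gap[1] + 1], " s but frame ", gap[1],
         " ends at ", start[gap[1]] + duration[gap[1]], " s")
  structure(
    list(start = start, duration = duration,
         mid = start + duration / 2,
         n_frames = n,
         total_duration = start[n] + duration[n] - start[1]),
    class = "frame_schedule")
}

#' The 22-frame, 60-minute [11C]-PK11195 acquisition schedule
#'
#' The dynamic acquisition used throughout this package: 4 x 30 s,
#' 4 x 60 s, 4 x 120 s, 4 x 240 s and 6 x 300 s frames, 60 min in total,
#' started at tracer injection.
#'
#' @return A [frame_schedule()].
#' @export
pk11195_frame_schedule <- function() {
  duration <- c(rep(30, 4), rep(60, 4), rep(120, 4), rep(240, 4), rep(300, 6))
  frame_schedule(start = cumsum(c(0, duration[-length(duration)])),
                 duration = duration)
}

#' Read a frame-timing sidecar
#'
#' Reads a JSON sidecar holding frame start times and durations in seconds.
#' Both the BIDS-PET keys (`FrameTimesStart`, `FrameDuration`) and plain
#' `start`/`duration` keys are accepted.
#'
#' @param path path to the JSON sidecar.
#' @return A validated [frame_schedule()].
#' @export
read_frame_schedule <- function(path) {
  if (!file.exists(path)) stop("timing sidecar not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  start <- if (!is.null(j$FrameTimesStart)) j$FrameTimesStart else j$start
  duration <- if (!is.null(j$FrameDuration)) j$FrameDuration else j$duration
  if (is.null(start) || is.null(duration))
    stop("timing sidecar must contain FrameTimesStart/FrameDuration ",
         "(or start/duration) arrays: ", path)
  frame_schedule(start, duration)
}

#' Write a frame-timing sidecar
#'
#' @param schedule a [frame_schedule()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  jsonlite::write_json(
    list(FrameTimesStart = schedule$start, FrameDuration = schedule$duration),
    path, digits = NA)
  invisible(path)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.0f s (%.1f min) total\n",
              x$n_frames, x$total_duration, x$total_duration / 60))
  cat("  durations (s):", paste(rle(x$duration)$lengths, "x",
                                rle(x$duration)$values, collapse = " + "), "\n")
  invisible(x)
}

# frame mid-times in minutes; kinetic code works in minutes
frame_mid_min <- function(schedule) schedule$mid / 60
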