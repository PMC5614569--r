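#' Construct an acquisition schedule
#'
#' @param rates numeric vector of frame rates (frames/second), one per segment.
#' @param durations numeric vector of segment durations (seconds).
#' @param extensionRate fps of the optional prolongation segment.
#' @param extensionDuration seconds of prolongation (0 = none).
#' @return An [AcquisitionSchedule-class] object.
#' @examples
#' AcquisitionSchedule(c(7.5, 4, 3, 2), c(5, 3, 2, 2))
#' @export
AcquisitionSchedule <- function(rates, durations, extensionRate = 2,
                                extensionDuration = 0) {
  new("AcquisitionSchedule", rates = as.numeric(rates),
      durations = as.numeric(durations),
      extensionRate = as.numeric(extensionRate),
      extensionDuration = as.numeric(extensionDuration))
}

#' The clinical default DSA acquisition schedule
#'
#' 7.5 fps for the first 5 s, 4 fps for 3 s, 3 fps for 2 s and 2 fps for the
#' final 2 s: a 12 s base acquisition, optionally prolonged at 2 fps to
#' follow slow venous opacification.
#'
#' @param extensionDuration seconds of 2 fps prolongation (default 0).
#' @return An [AcquisitionSchedule-class].
#' @examples
#' sum(defaultSchedule()@durations)  # 12 s base duration
#' @export
defaultSchedule <- function(extensionDuration = 0) {
  AcquisitionSchedule(c(7.5, 4, 3, 2), c(5, 3, 2, 2),
                      extensionRate = 2, extensionDuration = extensionDuration)
}

#' Total base duration of a schedule, seconds
#' @param schedule an [AcquisitionSchedule-class].
#' @export
scheduleBaseDuration <- function(schedule) sum(schedule@durations)

#' Build the frame time grid of an acquisition schedule
#'
#' Each segment is half-open \code{[start, start + duration)}: within a
#' segment frames are spaced \code{1/rate} apart starting exactly at the
#' segment start, and a frame never lands on the segment end. A 7.5 fps x 5 s
#' segment therefore yields 38 frames (t = 0 ... 37/7.5 s).
#'
#' @param schedule an [AcquisitionSchedule-class].
#' @return numeric vector of frame times (seconds), strictly increasing,
#'   starting at 0.
#' @examples
#' buildTimeGrid(AcquisitionSchedule(2, 2))  # 0.0 0.5 1.0 1.5
#' @export
buildTimeGrid <- function(schedule) {
  stopifnot(is(schedule, "AcquisitionSchedule"))
  validObject(schedule)
  rates <- schedule@rates
  durations <- schedule@durations
  if (schedule@extensionDuration > 0) {
    rates <- c(rates, schedule@extensionRate)
    durations <- c(durations, schedule@extensionDuration)
  }
  starts <- cumsum(c(0, durations[-length(durations)]))
  ts <- unlist(lapply(seq_along(rates), function(i) {
    # frames at start + k/rate strictly inside [start, start + duration)
    n <- ceiling(rates[i] * durations[i] - 1e-9)
    starts[i] + seq(0, n - 1) / rates[i]
  }))
  stopifnot(all(diff(ts) > 0))
  ts
}
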