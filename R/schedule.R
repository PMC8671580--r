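#' Acquisition frame schedules
#'
#' A frame schedule is the ordered set of acquisition frames of a dynamic
#' planar study, each frame a half-open interval `[start_s, start_s +
#' duration_s)` in seconds from tracer injection. Frames must be strictly
#' increasing and non-overlapping; gaps (e.g. between the dynamic scan and
#' later static scans) are allowed and carry no data.
#'
#' @param start_s numeric vector of frame start times (seconds post injection)
#' @param duration_s numeric vector of frame durations (seconds, > 0)
#' @return An object of class `frame_schedule`: a data.frame with columns
#'   `start_s` and `duration_s`.
#' @examples
#' sched <- frame_schedule(c(0, 2, 4), c(2, 2, 2))
#' frame_mid(sched)
#' @export
frame_schedule <- function(start_s, duration_s) {
  if (length(start_s) != length(duration_s)) {
    stop("start_s and duration_s must have equal length")
  }
  if (length(start_s) == 0) stop("schedule must contain at least one frame")
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s))) {
    stop("frame times must be finite")
  }
  if (any(duration_s <= 0)) {
    stop("frame durations must be positive (rows ",
         paste(which(duration_s <= 0), collapse = ", "), ")")
  }
  if (is.unsorted(start_s, strictly = TRUE)) {
    stop("frame start times must be strictly increasing")
  }
  ends <- start_s + duration_s
  bad <- which(utils::head(ends, -1) > utils::tail(start_s, -1) + 1e-9)
  if (length(bad)) {
    stop("overlapping frames at rows ", paste(bad, collapse = ", "))
  }
  structure(data.frame(start_s = as.numeric(start_s),
                       duration_s = as.numeric(duration_s)),
            class = c("frame_schedule", "data.frame"))
}

#' Standard DPS acquisition schedules
#'
#' The dynamic protocol: scan 1 runs 30 x 2 s + 40 x 6 s + 75 x 20 s
#' (145 frames, 30 min) from injection; scans 2 and 3 are 3 x 300 s static
#' acquisitions starting at 90 and 180 min. `"full"` concatenates all three,
#' ending at 195 min (the delayed heart-to-mediastinum window).
#'
#' @param kind one of `"scan1"`, `"scan2"`, `"scan3"`, `"full"`
#' @return a [frame_schedule()]
#' @examples
#' nrow(standard_schedule("scan1"))  # 145
#' @export
standard_schedule <- function(kind = c("scan1", "scan2", "scan3", "full")) {
  kind <- match.arg(kind)
  scan1_dur <- c(rep(2, 30), rep(6, 40), rep(20, 75))
  scan1_start <- cumsum(c(0, utils::head(scan1_dur, -1)))
  mk <- function(s, d) list(start = s, dur = d)
  part <- switch(kind,
    scan1 = mk(scan1_start, scan1_dur),
    scan2 = mk(90 * 60 + 300 * (0:2), rep(300, 3)),
    scan3 = mk(180 * 60 + 300 * (0:2), rep(300, 3)),
    full  = mk(c(scan1_start, 90 * 60 + 300 * (0:2), 180 * 60 + 300 * (0:2)),
               c(scan1_dur, rep(300, 6)))
  )
  frame_schedule(part$start, part$dur)
}

#' Frame midpoints in seconds
#' @param schedule a [frame_schedule()]
#' @export
frame_mid <- function(schedule) schedule$start_s + schedule$duration_s / 2

#' Frame midpoints in minutes
#' @param schedule a [frame_schedule()]
#' @export
frame_mid_min <- function(schedule) frame_mid(schedule) / 60

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g-%g s (total acquisition %g s)\n",
              nrow(x), x$start_s[1], x$start_s[nrow(x)] + x$duration_s[nrow(x)],
              sum(x$duration_s)))
  invisible(x)
}

same_schedule <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    max(abs(a$start_s - b$start_s)) <= tol &&
    max(abs(a$duration_s - b$duration_s)) <= tol
}
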