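#' Acquisition schedule of the imaging rig
#'
#' One imaging window is a burst of frames taken at a fixed interval; bursts
#' repeat with a fixed period. The defaults reproduce the assay's nominal
#' schedule: an image every 0.8 s for 160 s (200 frames per window), one
#' window every 5 min.
#'
#' @param frame_interval_s Seconds between consecutive frames within a window.
#' @param window_duration_s Duration of one imaging window in seconds.
#' @param period_s Seconds from the start of one window to the start of the
#'   next; must be at least `window_duration_s`.
#' @return An `acquisition_schedule` object.
#' @examples
#' sched <- acquisition_schedule()
#' frames_per_window(sched) # 200
#' frame_rate_fps(sched)    # 1.25
#' @export
acquisition_schedule <- function(frame_interval_s = 0.8,
                                 window_duration_s = 160,
                                 period_s = 300) {
  check_scalar_number(frame_interval_s, "frame_interval_s", min = 1e-9)
  check_scalar_number(window_duration_s, "window_duration_s", min = 1e-9)
  check_scalar_number(period_s, "period_s", min = 1e-9)
  f <- round(window_duration_s / frame_interval_s)
  if (f < 2) stop_input("schedule must give at least 2 frames per window")
  if (period_s < window_duration_s) {
    stop_input("period_s must be >= window_duration_s")
  }
  structure(
    list(frame_interval_s = frame_interval_s,
         window_duration_s = window_duration_s,
         period_s = period_s),
    class = "acquisition_schedule"
  )
}

#' @rdname acquisition_schedule
#' @param schedule An `acquisition_schedule`.
#' @export
frames_per_window <- function(schedule) {
  as.integer(round(schedule$window_duration_s / schedule$frame_interval_s))
}

#' @rdname acquisition_schedule
#' @export
frame_rate_fps <- function(schedule) 1 / schedule$frame_interval_s

#' Number of imaging windows covering an experiment duration
#'
#' One window starts every `period_s`; a run of `duration_days` days
#' contains `ceiling(duration_days * 86400 / period_s)` windows, with a
#' minimum of one.
#'
#' @param duration_days Run length in days (> 0).
#' @param schedule An [acquisition_schedule()].
#' @return Integer window count.
#' @examples
#' n_windows(1, acquisition_schedule()) # 288
#' @export
n_windows <- function(duration_days, schedule) {
  check_scalar_number(duration_days, "duration_days", min = 1e-12)
  max(1L, as.integer(ceiling(duration_days * 86400 / schedule$period_s)))
}

#' Window midpoint in days since L4 placement
#'
#' @param window_index 0-based window index (vectorised).
#' @param schedule An [acquisition_schedule()].
#' @export
window_t_mid_days <- function(window_index, schedule) {
  (window_index * schedule$period_s + schedule$window_duration_s / 2) / 86400
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf(
    "acquisition schedule: %g s frame interval, %g s window (%d frames), every %g s\n",
    x$frame_interval_s, x$window_duration_s, frames_per_window(x), x$period_s))
  invisible(x)
}
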