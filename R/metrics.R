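#' Plate configuration
#'
#' Metadata for one Petri dish: its condition, the nominal number of worms
#' plated (the denominator of fraction moving), censoring status, and
#' imaging geometry. Censored plates (quality-control failures such as
#' contamination or burrowing) are excluded from all condition-level
#' statistics downstream.
#'
#' @param plate_id Unique plate identifier.
#' @param condition Condition label.
#' @param n_worms_nominal Worms plated (> 0); default 30 per 6-cm dish.
#' @param censored Logical QC flag.
#' @param censor_reason Free-text reason when censored.
#' @param um_per_px Image scale.
#' @param roi A [roi_mask()] or `NULL`.
#' @export
plate_config <- function(plate_id, condition, n_worms_nominal = 30,
                         censored = FALSE, censor_reason = "",
                         um_per_px = 25, roi = NULL) {
  check_scalar_number(n_worms_nominal, "n_worms_nominal", min = 1)
  structure(
    list(plate_id = plate_id, condition = condition,
         n_worms_nominal = as.integer(n_worms_nominal),
         censored = isTRUE(censored), censor_reason = censor_reason,
         um_per_px = um_per_px, roi = roi),
    class = "plate_config")
}

#' Population metrics of one imaging window
#'
#' Converts the retained moving objects of one window into the assay's
#' three population outputs:
#' \describe{
#'   \item{fraction_moving}{number of moving objects divided by the nominal
#'     plated count. Deliberately never clamped: occasional false positives
#'     can push it above 1, and clamping would hide that known anomaly.}
#'   \item{mean_speed_moving_um_s}{arithmetic mean speed over the moving
#'     objects; `NA` (undefined, never 0) when nothing moved.}
#'   \item{mean_speed_all_um_s}{total object length divided by
#'     (nominal count x window duration), identically equal to
#'     fraction_moving x mean_speed_moving; 0 when nothing moved.}
#' }
#'
#' @param objects Data.frame from [detect_moving_objects()] for one window
#'   of one plate (already speed-filtered).
#' @param plate A [plate_config()].
#' @param schedule An [acquisition_schedule()].
#' @param window_index,t_mid_days Window identity; defaults are taken from
#'   `objects` when it has rows.
#' @return A one-row data.frame: `plate_id`, `condition`, `window_index`,
#'   `t_mid_days`, `n_moving`, `fraction_moving`, `mean_speed_moving_um_s`,
#'   `mean_speed_all_um_s`, `censored`.
#' @export
window_metrics <- function(objects, plate, schedule,
                           window_index = NULL, t_mid_days = NULL) {
  stopifnot(inherits(plate, "plate_config"))
  n_moving <- nrow(objects)
  if (is.null(window_index)) {
    window_index <- if (n_moving) objects$window_index[1] else NA_integer_
  }
  if (is.null(t_mid_days)) {
    t_mid_days <- if (n_moving) objects$t_mid_days[1] else NA_real_
  }
  frac <- n_moving / plate$n_worms_nominal
  msm <- if (n_moving > 0) mean(objects$speed_um_s) else NA_real_
  msa <- if (n_moving > 0) {
    sum(objects$length_um) /
      (plate$n_worms_nominal * schedule$window_duration_s)
  } else 0
  data.frame(
    plate_id = plate$plate_id, condition = plate$condition,
    window_index = as.integer(window_index), t_mid_days = t_mid_days,
    n_moving = as.integer(n_moving), fraction_moving = frac,
    mean_speed_moving_um_s = msm, mean_speed_all_um_s = msa,
    censored = plate$censored, stringsAsFactors = FALSE)
}
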