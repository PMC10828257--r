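#' Per-plate metric time series
#'
#' An ordered series of one population metric for one plate, with explicit
#' support for excluded (censored) imaging windows: excluded windows carry
#' no value and are skipped by smoothing and integration. An `NA` value
#' that is not excluded means the metric is undefined there (for example
#' mean speed of moving worms in a window with zero movers).
#'
#' @param plate_id Plate identifier.
#' @param metric One of `"fraction_moving"`, `"mean_speed_moving"`,
#'   `"mean_speed_all"`.
#' @param t_days Strictly increasing times in days.
#' @param value Metric values (`NA` where undefined).
#' @param window_index Optional 0-based window indices (defaults to
#'   `seq_along(t_days) - 1`).
#' @return A `plate_series` object.
#' @export
plate_series <- function(plate_id, metric, t_days, value,
                         window_index = seq_along(t_days) - 1L) {
  metric <- match.arg(metric, c("fraction_moving", "mean_speed_moving",
                                "mean_speed_all"))
  if (length(t_days) != length(value)) stop_input("t_days/value length mismatch")
  if (any(diff(t_days) <= 0)) stop_input("t_days must be strictly increasing")
  structure(
    list(plate_id = plate_id, metric = metric, t_days = as.numeric(t_days),
         value = as.numeric(value),
         window_index = as.integer(window_index),
         excluded = rep(FALSE, length(t_days))),
    class = "plate_series")
}

#' Mark imaging windows as censored
#'
#' Excluded windows (plate transfers, machine restarts and other
#' disturbances that create spurious movement bumps) carry no value;
#' smoothing and AUC integration skip them. Exclusions outside the series
#' raise a warning and are ignored.
#'
#' @param series A [plate_series()].
#' @param window_index 0-based window indices to exclude.
#' @param time_ranges Optional list of `c(t_start, t_end)` day ranges to
#'   exclude (inclusive).
#' @return The series with the windows marked excluded and values removed.
#' @export
censor_windows <- function(series, window_index = integer(0),
                           time_ranges = NULL) {
  stopifnot(inherits(series, "plate_series"))
  sel <- series$window_index %in% window_index
  unknown <- setdiff(window_index, series$window_index)
  if (length(unknown)) {
    warning("ignoring exclusions outside the series: ",
            paste(unknown, collapse = ", "))
  }
  for (rg in time_ranges %||% list()) {
    sel <- sel | (series$t_days >= rg[1] & series$t_days <= rg[2])
  }
  series$excluded <- series$excluded | sel
  series$value[series$excluded] <- NA_real_
  series
}

#' Smooth a plate series with a centred moving average
#'
#' Averages up to `2 * half_width + 1` consecutive available points around
#' each point. The window truncates at the series edges and does not reach
#' across excluded or undefined points, so censored gaps are never bridged.
#' `half_width = 0` is the identity. The default of 6 spans about one hour
#' at the nominal 5-minute window period.
#'
#' @param series A [plate_series()].
#' @param half_width Non-negative integer half width in windows.
#' @return The smoothed series.
#' @export
smooth_series <- function(series, half_width = 6) {
  stopifnot(inherits(series, "plate_series"), half_width >= 0)
  v <- series$value
  n <- length(v)
  if (half_width == 0 || n == 0) return(series)
  avail <- is.finite(v)
  out <- v
  for (i in which(avail)) {
    lo <- i; hi <- i
    while (lo > 1 && (i - lo) < half_width && avail[lo - 1]) lo <- lo - 1
    while (hi < n && (hi - i) < half_width && avail[hi + 1]) hi <- hi + 1
    out[i] <- mean(v[lo:hi])
  }
  series$value <- out
  series
}

#' Condition-level mean and SEM across plates
#'
#' Aggregates plate series (same metric, identical time grid) into a
#' condition curve: per-time mean and standard error of the mean across
#' dishes. For the mean-speed-of-moving-worms metric the condition value
#' at a time is undefined as soon as any contributing dish has an undefined
#' value there (an entire dish with zero movers removes the condition's
#' speed estimate), and the series is truncated at the first time from
#' which that holds for every later time.
#'
#' @param plates List of at least two non-censored [plate_series()]
#'   objects on a common time grid.
#' @param condition Condition label for the output.
#' @return A `condition_series`: `t_days`, `mean`, `sem`, `n_plates`.
#' @export
condition_series <- function(plates, condition = "condition") {
  if (length(plates) < 2) stop_input("need >= 2 plates for a SEM")
  metric <- plates[[1]]$metric
  t0 <- plates[[1]]$t_days
  for (p in plates) {
    if (!isTRUE(all.equal(p$t_days, t0)) || p$metric != metric) {
      stop_input("plates must share one metric and time grid")
    }
  }
  vals <- do.call(rbind, lapply(plates, function(p) p$value))
  n_ok <- colSums(is.finite(vals))
  mean_t <- ifelse(n_ok >= 2, colMeans(vals, na.rm = TRUE), NA_real_)
  sem_t <- vapply(seq_along(t0), function(i) {
    x <- vals[, i]; x <- x[is.finite(x)]
    if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  if (metric == "mean_speed_moving") {
    undef <- colSums(!is.finite(vals)) > 0
    mean_t[undef] <- NA_real_
    sem_t[undef] <- NA_real_
    # truncate at the first time from which undefined holds persistently
    if (any(undef)) {
      run <- rev(cumprod(rev(undef))) == 1
      if (any(run)) {
        cut <- which(run)[1]
        keep <- seq_len(cut - 1)
        t0 <- t0[keep]; mean_t <- mean_t[keep]
        sem_t <- sem_t[keep]; n_ok <- n_ok[keep]
      }
    }
  }
  structure(
    list(condition = condition, metric = metric, t_days = t0,
         mean = mean_t, sem = sem_t, n_plates = as.integer(n_ok)),
    class = "condition_series")
}

#' Area under a plate series
#'
#' Trapezoidal integral over `[day_start, day_end]`, with boundary values
#' linearly interpolated. Gaps of missing or excluded windows up to
#' `gap_max_days` (default 0.25 day = 6 h) are bridged by the linear
#' interpolation inherent in the trapezoid rule; longer gaps split the
#' integral into separate segments with a warning (the gap contributes
#' nothing). For the fraction-moving metric the result is the average time
#' (days) spent moving over the range; see [auc_mm()] for the distance
#' interpretation of mean speed of all worms.
#'
#' @param series A [plate_series()] (usually smoothed).
#' @param day_start,day_end Integration range in days, `day_start < day_end`.
#' @param gap_max_days Longest gap bridged by interpolation.
#' @return The integral in metric-units x days.
#' @export
auc <- function(series, day_start, day_end, gap_max_days = 0.25) {
  stopifnot(inherits(series, "plate_series"))
  if (!(day_start < day_end)) stop_input("day_start must be < day_end")
  ok <- is.finite(series$value)
  t <- series$t_days[ok]; v <- series$value[ok]
  inr <- t >= day_start - gap_max_days & t <= day_end + gap_max_days
  if (sum(t >= day_start & t <= day_end) == 0) {
    stop_input("series does not cover the integration range")
  }
  t <- t[inr]; v <- v[inr]
  if (length(t) < 2) stop_input("series does not cover the integration range")
  gaps <- which(diff(t) > gap_max_days)
  if (length(gaps)) {
    warning(sprintf(
      "integral split across %d gap(s) longer than %g days", length(gaps),
      gap_max_days))
  }
  seg_start <- c(1, gaps + 1)
  seg_end <- c(gaps, length(t))
  total <- 0
  for (s in seq_along(seg_start)) {
    ti <- t[seg_start[s]:seg_end[s]]
    vi <- v[seg_start[s]:seg_end[s]]
    if (length(ti) < 2) next
    a <- max(day_start, ti[1]); b <- min(day_end, ti[length(ti)])
    if (b <= a) next
    grid <- unique(sort(c(a, b, ti[ti > a & ti < b])))
    gv <- approx(ti, vi, xout = grid)$y
    total <- total + sum(diff(grid) * (head(gv, -1) + tail(gv, -1)) / 2)
  }
  total
}

#' Convert a mean-speed-of-all-worms AUC to millimetres
#'
#' An AUC of mean speed of all worms has units um/s x days; multiplying by
#' 86400 s/day and dividing by 1000 um/mm (x 86.4) gives the average
#' distance moved per plated worm, in millimetres.
#'
#' @param auc_value AUC in um/s x days.
#' @export
auc_mm <- function(auc_value) auc_value * 86.4

#' Percent difference of two AUC endpoints
#'
#' `100 * (treated - control) / control`: the reporting convention for
#' statements such as "the mutant spends x% more time moving".
#'
#' @param auc_treated,auc_control AUC values; `auc_control` must be > 0.
#' @export
percent_difference <- function(auc_treated, auc_control) {
  if (!is.finite(auc_control) || auc_control <= 0) {
    stop_input("auc_control must be positive")
  }
  100 * (auc_treated - auc_control) / auc_control
}
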