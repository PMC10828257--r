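#' Worm allocation arithmetic
#'
#' Total worms per condition per analysis method when a batch of dishes is
#' split equally across methods: `n_dishes * n_worms_per_dish / n_methods`.
#' For example 26 dishes of 30 worms split over an automated and a manual
#' arm gives 390 worms per condition per method.
#'
#' @param n_dishes Dishes prepared per condition.
#' @param n_worms_per_dish Worms per dish.
#' @param n_methods Number of analysis arms sharing the dishes.
#' @export
worms_per_condition_per_method <- function(n_dishes, n_worms_per_dish,
                                           n_methods) {
  check_scalar_number(n_dishes, "n_dishes", min = 1)
  check_scalar_number(n_worms_per_dish, "n_worms_per_dish", min = 1)
  check_scalar_number(n_methods, "n_methods", min = 1)
  n_dishes * n_worms_per_dish / n_methods
}

#' Validate an experiment manifest
#'
#' Report-only checks of the manifest's internal arithmetic: uniqueness of
#' plate ids, schedule consistency (frames per window, period vs window),
#' worm-allocation accounting when a `design` block is present, and the
#' ROI circle fitting inside the field when a field size is declared.
#'
#' @param manifest Manifest list (see [run_pipeline()]).
#' @return A data.frame with columns `check`, `ok`, `detail`; one row per
#'   check performed. Violations have `ok = FALSE`.
#' @export
validate_manifest <- function(manifest) {
  rows <- list()
  add <- function(check, ok, detail) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, ok = ok, detail = detail, stringsAsFactors = FALSE)
  }
  ids <- vapply(manifest$plates %||% list(), `[[`, "", "plate_id")
  add("unique_plate_ids", !anyDuplicated(ids),
      sprintf("%d plates, %d unique", length(ids), length(unique(ids))))
  sc <- manifest$schedule
  if (!is.null(sc)) {
    f <- round(sc$window_duration_s / sc$frame_interval_s)
    add("frames_per_window", f >= 2,
        sprintf("%g s / %g s = %d frames", sc$window_duration_s,
                sc$frame_interval_s, as.integer(f)))
    add("period_covers_window", sc$period_s >= sc$window_duration_s,
        sprintf("period %g s, window %g s", sc$period_s,
                sc$window_duration_s))
  }
  dg <- manifest$design
  if (!is.null(dg)) {
    wpm <- worms_per_condition_per_method(
      dg$n_dishes, dg$n_worms_per_dish, dg$n_methods)
    add("worms_per_condition_per_method", wpm == round(wpm),
        sprintf("%g dishes x %g worms / %g methods = %g", dg$n_dishes,
                dg$n_worms_per_dish, dg$n_methods, wpm))
  }
  for (pl in manifest$plates %||% list()) {
    if (!is.null(pl$field_size_px) && !is.null(pl$roi_radius_px)) {
      cen <- as.numeric(pl$roi_center_px)
      rad <- pl$roi_radius_px
      fits <- cen[1] - rad >= 0.5 && cen[2] - rad >= 0.5 &&
        cen[1] + rad <= pl$field_size_px[1] + 0.5 &&
        cen[2] + rad <= pl$field_size_px[2] + 0.5
      add(paste0("roi_inside_field:", pl$plate_id), fits,
          sprintf("centre (%g, %g), radius %g, field %d x %d", cen[1],
                  cen[2], rad, pl$field_size_px[1], pl$field_size_px[2]))
    }
  }
  do.call(rbind, rows)
}

# assemble per-plate series for one metric from the window_metrics table,
# aligned to the union time grid of the condition's plates
build_plate_series <- function(wm, plate_id, metric) {
  sub <- wm[wm$plate_id == plate_id, , drop = FALSE]
  sub <- sub[order(sub$window_index), , drop = FALSE]
  col <- switch(metric,
                fraction_moving = "fraction_moving",
                mean_speed_moving = "mean_speed_moving_um_s",
                mean_speed_all = "mean_speed_all_um_s")
  plate_series(plate_id, metric, sub$t_mid_days, sub[[col]],
               window_index = sub$window_index)
}

metric_columns <- c(fraction_moving = "fraction_moving",
                    mean_speed_moving = "mean_speed_moving_um_s",
                    mean_speed_all = "mean_speed_all_um_s")

#' Run the full analysis pipeline over a dataset on disk
#'
#' Executes, per non-censored plate and imaging window: image reading,
#' motion detection, object measurement and window metrics; then censors
#' listed windows, smooths per-plate series, aggregates condition curves
#' with SEM, integrates per-plate AUC endpoints over the configured day
#' ranges, and compares every condition against the declared control with
#' Gaussian error statistics.
#'
#' The manifest is a list (read from YAML or JSON by [read_manifest()])
#' with fields `run_id`, `schedule` (frame_interval_s, window_duration_s,
#' period_s), `plates` (each with `plate_id`, `condition`,
#' `n_worms_nominal`, `um_per_px`, `roi_center_px`, `roi_radius_px`,
#' `path`, optional `censored`/`censor_reason`), optional `detection`
#' overrides for [detection_params()], optional `analysis` block
#' (`smooth_half_width`, `auc_ranges` as a list of two-element day ranges,
#' `control_condition`, `direction`, `length_mode`, `metrics`), and an
#' optional `censor` block with per-plate window exclusion lists.
#'
#' @param manifest Manifest list.
#' @param input_dir Directory containing the plate image directories.
#' @param output_dir Output directory for the result tables; created if
#'   missing.
#' @return Invisibly, a list with the result tables (`objects`,
#'   `window_metrics`, `condition_series`, `auc`, `comparisons`, `summary`).
#'   The same tables are written to `output_dir` as CSV plus
#'   `summary.json` and `run_log.txt`.
#' @export
run_pipeline <- function(manifest, input_dir, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- do.call(acquisition_schedule, manifest$schedule)
  det_args <- manifest$detection %||% list()
  ana <- manifest$analysis %||% list()
  half_width <- ana$smooth_half_width %||% 6
  auc_ranges <- ana$auc_ranges %||% list(c(2, 7), c(2, 12))
  # manifests read from JSON may present the ranges as a matrix or a bare
  # pair; normalise to a list of length-2 numeric vectors
  if (is.matrix(auc_ranges)) {
    auc_ranges <- lapply(seq_len(nrow(auc_ranges)),
                         function(i) as.numeric(auc_ranges[i, ]))
  } else if (is.numeric(auc_ranges) && length(auc_ranges) == 2) {
    auc_ranges <- list(auc_ranges)
  }
  direction <- ana$direction %||% "greater"
  length_mode <- ana$length_mode %||% "skeleton"
  metrics <- ana$metrics %||% c("fraction_moving", "mean_speed_all")
  log_lines <- c(sprintf("run_id: %s", manifest$run_id %||% "run"),
                 sprintf("schedule: %g s x %d frames every %g s",
                         sched$frame_interval_s, frames_per_window(sched),
                         sched$period_s),
                 sprintf("length_mode: %s", length_mode))
  plates <- manifest$plates
  censored_now <- character(0)
  obj_list <- list(); wm_list <- list()
  for (pl in plates) {
    if (isTRUE(pl$censored)) {
      log_lines <- c(log_lines, sprintf("plate %s censored: %s",
                                        pl$plate_id,
                                        pl$censor_reason %||% ""))
      next
    }
    pdir <- file.path(input_dir, pl$path %||% pl$plate_id)
    params <- do.call(detection_params,
                      utils::modifyList(det_args,
                                        list(um_per_px = pl$um_per_px)))
    roi <- roi_mask(as.numeric(pl$roi_center_px), pl$roi_radius_px)
    pcfg <- plate_config(pl$plate_id, pl$condition,
                         pl$n_worms_nominal %||% 30,
                         um_per_px = pl$um_per_px, roi = roi)
    files <- sort(dir(pdir, pattern = "^window_\\d+\\.tiff?$",
                      full.names = TRUE))
    res <- tryCatch({
      if (!length(files)) stop_input("no window stacks in ", pdir)
      per_window <- lapply(files, function(f) {
        k <- as.integer(sub("^window_(\\d+)\\..*$", "\\1", basename(f)))
        frames <- read_image_sequence(f, frames_per_window(sched))
        win <- imaging_window(pl$plate_id, k, window_t_mid_days(k, sched),
                              frames)
        obj <- detect_moving_objects(win, roi, params, sched,
                                     length_mode = length_mode)
        list(objects = obj,
             metrics = window_metrics(obj, pcfg, sched, window_index = k,
                                      t_mid_days = win$t_mid_days))
      })
      list(objects = do.call(rbind, lapply(per_window, `[[`, "objects")),
           metrics = do.call(rbind, lapply(per_window, `[[`, "metrics")))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      censored_now <- c(censored_now, pl$plate_id)
      log_lines <- c(log_lines,
                     sprintf("plate %s censored at run time: %s",
                             pl$plate_id, conditionMessage(res)))
      next
    }
    obj_list[[pl$plate_id]] <- res$objects
    wm_list[[pl$plate_id]] <- res$metrics
  }
  active <- vapply(plates, function(pl) {
    !isTRUE(pl$censored) && !(pl$plate_id %in% censored_now)
  }, logical(1))
  conds <- unique(vapply(plates, `[[`, "", "condition"))
  for (cond in conds) {
    alive <- any(vapply(plates[active], function(pl) {
      pl$condition == cond
    }, logical(1)))
    if (!alive) {
      stop_input("condition '", cond, "' has no usable plates ",
                 "(all censored)")
    }
  }
  objects <- do.call(rbind, obj_list); rownames(objects) <- NULL
  wm <- do.call(rbind, wm_list); rownames(wm) <- NULL
  cond_of <- vapply(plates, `[[`, "", "condition")
  names(cond_of) <- vapply(plates, `[[`, "", "plate_id")
  # censoring of listed windows, smoothing, condition curves, AUC
  excl <- manifest$censor$windows %||% list()
  series_rows <- list(); auc_rows <- list()
  per_plate_auc <- list()
  for (metric in metrics) {
    for (cond in conds) {
      pids <- names(cond_of)[cond_of == cond]
      pids <- pids[pids %in% names(wm_list)]
      plist <- lapply(pids, function(pid) {
        s <- build_plate_series(wm, pid, metric)
        ex <- c(excl[[pid]] %||% integer(0), excl[["all"]] %||% integer(0))
        if (length(ex)) s <- censor_windows(s, as.integer(ex))
        smooth_series(s, half_width)
      })
      names(plist) <- pids
      cs <- condition_series(plist, cond)
      series_rows[[paste(metric, cond)]] <- data.frame(
        condition = cond, metric = metric, t_days = cs$t_days,
        mean = cs$mean, sem = cs$sem, n_plates = cs$n_plates,
        stringsAsFactors = FALSE)
      for (rg in auc_ranges) {
        rg <- as.numeric(rg)
        vals <- vapply(plist, function(s) {
          tryCatch(suppressWarnings(auc(s, rg[1], rg[2])),
                   error = function(e) NA_real_)
        }, numeric(1))
        ok <- is.finite(vals)
        auc_rows[[paste(metric, cond, rg[1], rg[2])]] <- data.frame(
          condition = cond, metric = metric, day_start = rg[1],
          day_end = rg[2], plate_id = pids, auc_value = vals,
          stringsAsFactors = FALSE)
        per_plate_auc[[paste(metric, rg[1], rg[2], cond)]] <- vals[ok]
      }
    }
  }
  cond_series_tab <- do.call(rbind, series_rows); rownames(cond_series_tab) <- NULL
  auc_tab <- do.call(rbind, auc_rows); rownames(auc_tab) <- NULL
  # comparisons against the control condition
  control <- ana$control_condition %||% conds[1]
  cmp_rows <- list()
  for (metric in metrics) {
    for (rg in auc_ranges) {
      rg <- as.numeric(rg)
      key_c <- paste(metric, rg[1], rg[2], control)
      vc <- per_plate_auc[[key_c]]
      if (length(vc) < 2) next
      for (cond in setdiff(conds, control)) {
        va <- per_plate_auc[[paste(metric, rg[1], rg[2], cond)]]
        if (length(va) < 2) next
        cr <- compare_groups(mean(va), sem(va), mean(vc), sem(vc),
                             direction = direction)
        cmp_rows[[paste(metric, rg[1], rg[2], cond)]] <- data.frame(
          metric = metric, day_start = rg[1], day_end = rg[2],
          condition_a = cond, condition_b = control,
          mean_a = mean(va), sem_a = sem(va),
          mean_b = mean(vc), sem_b = sem(vc),
          diff = cr$mean_diff, se_diff = cr$se_diff, z = cr$z,
          p_one_sided = cr$p_one_sided, stars = cr$stars,
          percent_difference = percent_difference(mean(va), mean(vc)),
          stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- if (length(cmp_rows)) {
    out <- do.call(rbind, cmp_rows); rownames(out) <- NULL; out
  } else NULL
  summary <- list(
    run_id = manifest$run_id %||% "run",
    control_condition = control,
    auc = lapply(split(auc_tab, paste(auc_tab$metric, auc_tab$day_start,
                                      auc_tab$day_end, auc_tab$condition)),
                 function(d) list(
                   metric = d$metric[1], day_start = d$day_start[1],
                   day_end = d$day_end[1], condition = d$condition[1],
                   mean = mean(d$auc_value[is.finite(d$auc_value)]),
                   sem = if (sum(is.finite(d$auc_value)) >= 2)
                     sem(d$auc_value[is.finite(d$auc_value)]) else NA,
                   n_plates = sum(is.finite(d$auc_value)))),
    comparisons = comparisons)
  write.csv(objects, file.path(output_dir, "objects.csv"),
            row.names = FALSE, na = "")
  write.csv(wm, file.path(output_dir, "window_metrics.csv"),
            row.names = FALSE, na = "")
  write.csv(cond_series_tab, file.path(output_dir, "condition_series.csv"),
            row.names = FALSE, na = "")
  write.csv(auc_tab, file.path(output_dir, "auc.csv"),
            row.names = FALSE, na = "")
  if (!is.null(comparisons)) {
    write.csv(comparisons, file.path(output_dir, "comparisons.csv"),
              row.names = FALSE, na = "")
  }
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(list(objects = objects, window_metrics = wm,
                 condition_series = cond_series_tab, auc = auc_tab,
                 comparisons = comparisons, summary = summary))
}
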