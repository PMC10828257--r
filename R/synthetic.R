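#' Simulation parameters for a synthetic plate
#'
#' Describes one virtual agar dish of worms: population size, imaging
#' geometry, locomotion, the age-dependent behavioural decline, and the
#' camera model. Defaults emulate 30 animals on a 6-cm dish whose moving
#' fraction peaks early in adulthood and then declines, with crawl speeds
#' typical of on-food dwelling behaviour (well above the 10 um/s detection
#' threshold but far below roaming speeds).
#'
#' The moving-state probability follows a logistic decline
#' `p_move(t) = p_move_start * plogis(p_move_steepness * (p_move_midpoint_day - t))`
#' and crawl speed decays exponentially,
#' `v(t) = baseline_speed_um_s * exp(-speed_decay_per_day * t)`. Death times
#' are logistic with the given midpoint and scale; dead worms never move
#' again. `death_midpoint_day = Inf` disables death, `-Inf` makes every
#' worm dead from day 0.
#'
#' @param n_worms Worms per plate (>= 0).
#' @param field_size_px Image size as (rows, cols).
#' @param um_per_px Micrometres per pixel (isotropic).
#' @param worm_length_um Body length along the midline.
#' @param worm_width_px Rendered stroke width in pixels.
#' @param baseline_speed_um_s Mean crawl speed of a moving worm at day 0.
#' @param heading_diffusion Angular standard deviation of the persistent
#'   random walk, radians per square-root second.
#' @param p_move_start,p_move_midpoint_day,p_move_steepness Logistic
#'   moving-probability decline: early-life level, day of half-decline,
#'   steepness per day.
#' @param speed_decay_per_day Exponential speed decline rate with age.
#' @param death_midpoint_day,death_scale_days Logistic death-time
#'   distribution (days).
#' @param lawn_contrast Amplitude of the low-frequency bacterial-lawn
#'   texture, gray levels.
#' @param trail_amplitude Intensity change left per pass along a worm's
#'   path (gray levels); 0 disables trails.
#' @param noise_sigma Per-pixel Gaussian read-noise standard deviation,
#'   gray levels.
#' @param worm_contrast How many gray levels darker a worm body is than the
#'   background.
#' @param roi_center_px,roi_radius_px Detection circle; defaults are the
#'   field centre and `min(field)/2 - 8`.
#' @param seed Integer root seed; identical parameters (including the seed)
#'   give bit-identical simulations.
#' @return A `sim_params` object.
#' @export
sim_params <- function(n_worms = 30,
                       field_size_px = c(512, 512),
                       um_per_px = 25,
                       worm_length_um = 1000,
                       worm_width_px = 3,
                       baseline_speed_um_s = 20,
                       heading_diffusion = 0.15,
                       p_move_start = 0.6,
                       p_move_midpoint_day = 5,
                       p_move_steepness = 0.6,
                       speed_decay_per_day = 0.12,
                       death_midpoint_day = 14,
                       death_scale_days = 3,
                       lawn_contrast = 10,
                       trail_amplitude = 0,
                       noise_sigma = 3,
                       worm_contrast = 70,
                       roi_center_px = NULL,
                       roi_radius_px = NULL,
                       seed = 1) {
  if (length(n_worms) != 1L || is.na(n_worms) || n_worms < 0 ||
      n_worms != round(n_worms)) {
    stop_input("invalid value for 'n_worms'")
  }
  if (length(field_size_px) != 2L || any(field_size_px < 8)) {
    stop_input("invalid value for 'field_size_px'")
  }
  check_scalar_number(um_per_px, "um_per_px", min = 1e-9)
  check_scalar_number(worm_length_um, "worm_length_um", min = 1e-9)
  check_scalar_number(worm_width_px, "worm_width_px", min = 1)
  check_scalar_number(baseline_speed_um_s, "baseline_speed_um_s", min = 0)
  check_scalar_number(heading_diffusion, "heading_diffusion", min = 0)
  check_scalar_number(p_move_start, "p_move_start", min = 0, max = 1)
  check_scalar_number(p_move_midpoint_day, "p_move_midpoint_day",
                      allow_inf = TRUE)
  check_scalar_number(p_move_steepness, "p_move_steepness", min = 0)
  check_scalar_number(speed_decay_per_day, "speed_decay_per_day", min = 0)
  check_scalar_number(death_midpoint_day, "death_midpoint_day",
                      allow_inf = TRUE)
  check_scalar_number(death_scale_days, "death_scale_days", min = 1e-9)
  check_scalar_number(lawn_contrast, "lawn_contrast", min = 0)
  check_scalar_number(trail_amplitude, "trail_amplitude", min = 0)
  check_scalar_number(noise_sigma, "noise_sigma", min = 0)
  check_scalar_number(worm_contrast, "worm_contrast", min = 0, max = 255)
  check_scalar_number(seed, "seed", min = 0)
  p <- list(
    n_worms = as.integer(n_worms), field_size_px = as.integer(field_size_px),
    um_per_px = um_per_px, worm_length_um = worm_length_um,
    worm_width_px = worm_width_px,
    baseline_speed_um_s = baseline_speed_um_s,
    heading_diffusion = heading_diffusion,
    p_move_start = p_move_start, p_move_midpoint_day = p_move_midpoint_day,
    p_move_steepness = p_move_steepness,
    speed_decay_per_day = speed_decay_per_day,
    death_midpoint_day = death_midpoint_day,
    death_scale_days = death_scale_days,
    lawn_contrast = lawn_contrast, trail_amplitude = trail_amplitude,
    noise_sigma = noise_sigma, worm_contrast = worm_contrast,
    roi_center_px = roi_center_px %||% (as.integer(field_size_px) + 1) / 2,
    roi_radius_px = roi_radius_px %||% (min(field_size_px) / 2 - 8),
    seed = as.integer(seed))
  structure(p, class = "sim_params")
}

#' Age-dependent moving probability and crawl speed
#'
#' @param t_days Age in days since L4 placement (vectorised).
#' @param params A [sim_params()] object.
#' @return Probability (for `p_move`) or speed in um/s (for `crawl_speed`).
#' @export
p_move <- function(t_days, params) {
  params$p_move_start *
    plogis(params$p_move_steepness * (params$p_move_midpoint_day - t_days))
}

#' @rdname p_move
#' @export
crawl_speed <- function(t_days, params) {
  params$baseline_speed_um_s * exp(-params$speed_decay_per_day * t_days)
}

#' @rdname p_move
#' @export
p_dead <- function(t_days, params) {
  plogis((t_days - params$death_midpoint_day) / params$death_scale_days)
}

# reflect a position (um, origin at ROI centre) back inside the ROI circle,
# adjusting the heading as a specular bounce off the circle
reflect_into_roi <- function(x, y, heading, r_max_um) {
  r <- sqrt(x^2 + y^2)
  if (r <= r_max_um || r == 0) {
    return(list(x = x, y = y, heading = heading))
  }
  ex <- x / r; ey <- y / r
  vx <- cos(heading); vy <- sin(heading)
  dot <- vx * ex + vy * ey
  vx <- vx - 2 * dot * ex
  vy <- vy - 2 * dot * ey
  rr <- max(2 * r_max_um - r, 0)
  list(x = ex * rr, y = ey * rr, heading = atan2(vy, vx))
}

#' Simulate worm trajectories for every imaging window of a run
#'
#' Each worm owns an independent random substream derived from the plate
#' seed (see [substream_seed()]), so enlarging the population never
#' perturbs existing worms. Per window a worm is dead (if past its drawn
#' death time), moving (with probability `p_move(t)`), or paused. Moving
#' worms follow a persistent random walk at the age-dependent crawl speed,
#' sampled at frame times, with a reflective boundary at the ROI circle;
#' they keep walking (coarsely stepped) through the gap to the next window.
#' Paused and dead worms hold a fixed pose.
#'
#' @param params A [sim_params()].
#' @param duration_days Run length in days (> 0).
#' @param schedule An [acquisition_schedule()].
#' @return A `worm_trajectory_set`: window times plus, per worm, the state,
#'   true centroid path length (um) and true speed (um/s) for every window,
#'   and the pose track (x um, y um, heading, undulation phase; one row per
#'   frame while moving, a single static row otherwise). Positions are in
#'   micrometres with the origin at the ROI centre.
#' @export
simulate_worms <- function(params, duration_days,
                           schedule = acquisition_schedule()) {
  stopifnot(inherits(params, "sim_params"))
  nw <- n_windows(duration_days, schedule)
  t_mid <- window_t_mid_days(seq_len(nw) - 1, schedule)
  fpw <- frames_per_window(schedule)
  dt <- schedule$frame_interval_s
  gap_s <- schedule$period_s - schedule$window_duration_s
  r_max <- params$roi_radius_px * params$um_per_px * 0.98
  lambda <- params$worm_length_um / 1.5 # undulation wavelength
  worms <- vector("list", params$n_worms)
  for (w in seq_len(params$n_worms)) {
    set.seed(substream_seed(params$seed, c(17L, w)))
    r0 <- r_max * 0.9 * sqrt(runif(1))
    a0 <- runif(1, 0, 2 * pi)
    x <- r0 * cos(a0); y <- r0 * sin(a0)
    heading <- runif(1, 0, 2 * pi)
    phase <- runif(1, 0, 2 * pi)
    u_death <- runif(1)
    death_day <- params$death_midpoint_day +
      params$death_scale_days * qlogis(u_death)
    state <- character(nw)
    path_um <- numeric(nw)
    speed <- numeric(nw)
    poses <- vector("list", nw)
    for (k in seq_len(nw)) {
      t_k <- t_mid[k]
      if (t_k >= death_day) {
        state[k] <- "dead"
      } else {
        state[k] <- if (runif(1) < p_move(t_k, params)) "moving" else "paused"
      }
      if (state[k] == "moving") {
        v <- crawl_speed(t_k, params)
        pose <- matrix(NA_real_, fpw, 4)
        pose[1, ] <- c(x, y, heading, phase)
        for (f in 2:fpw) {
          heading <- heading + rnorm(1, 0, params$heading_diffusion * sqrt(dt))
          x <- x + v * dt * cos(heading)
          y <- y + v * dt * sin(heading)
          phase <- phase + v * dt * 2 * pi / lambda
          rf <- reflect_into_roi(x, y, heading, r_max)
          x <- rf$x; y <- rf$y; heading <- rf$heading
          pose[f, ] <- c(x, y, heading, phase)
        }
        poses[[k]] <- pose
        path_um[k] <- v * schedule$window_duration_s
        speed[k] <- v
        # coarse advance through the inter-window gap
        if (gap_s > 0) {
          ngs <- 5L
          dtg <- gap_s / ngs
          for (g in seq_len(ngs)) {
            heading <- heading +
              rnorm(1, 0, params$heading_diffusion * sqrt(dtg))
            x <- x + v * dtg * cos(heading)
            y <- y + v * dtg * sin(heading)
            phase <- phase + v * dtg * 2 * pi / lambda
            rf <- reflect_into_roi(x, y, heading, r_max)
            x <- rf$x; y <- rf$y; heading <- rf$heading
          }
        }
      } else {
        poses[[k]] <- matrix(c(x, y, heading, phase), 1)
      }
    }
    worms[[w]] <- list(worm_id = w, death_day = death_day, state = state,
                       true_path_length_um = path_um, true_speed_um_s = speed,
                       poses = poses)
  }
  structure(
    list(params = params, schedule = schedule, duration_days = duration_days,
         n_windows = nw, t_mid_days = t_mid, worms = worms),
    class = "worm_trajectory_set")
}

#' Ground-truth table of a trajectory set
#'
#' One row per worm per window with the simulated state, true centroid path
#' length, true speed and the `true_moving` call at the detection speed
#' threshold.
#'
#' @param traj A [simulate_worms()] result.
#' @param plate_id Plate label for the output rows.
#' @param v_min_um_s Speed threshold defining `true_moving`.
#' @return A data.frame.
#' @export
ground_truth_table <- function(traj, plate_id = "plate1", v_min_um_s = 10) {
  if (!length(traj$worms)) {
    return(data.frame(plate_id = character(0), window_index = integer(0),
                      worm_id = integer(0), state = character(0),
                      true_path_length_um = numeric(0),
                      true_speed_um_s = numeric(0),
                      true_moving = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(traj$worms, function(w) {
    data.frame(plate_id = plate_id,
               window_index = seq_len(traj$n_windows) - 1L,
               worm_id = w$worm_id, state = w$state,
               true_path_length_um = w$true_path_length_um,
               true_speed_um_s = w$true_speed_um_s,
               true_moving = w$true_speed_um_s >= v_min_um_s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$window_index, out$worm_id), , drop = FALSE]
}

# pixel linear indices covered by one worm body at one pose
worm_body_pixels <- function(pose, params) {
  L <- params$worm_length_um
  lambda <- L / 1.5
  amp <- L / 10
  s <- seq(-L / 2, L / 2, by = params$um_per_px / 2)
  ux <- cos(pose[3]); uy <- sin(pose[3])
  nx <- -uy; ny <- ux
  off <- amp * sin(2 * pi * s / lambda + pose[4])
  px_x <- pose[1] + ux * s + nx * off
  px_y <- pose[2] + uy * s + ny * off
  r0 <- params$roi_center_px[1]
  c0 <- params$roi_center_px[2]
  rr <- round(r0 + px_y / params$um_per_px)
  cc <- round(c0 + px_x / params$um_per_px)
  half <- floor((params$worm_width_px - 1) / 2)
  if (half > 0) {
    offs <- expand.grid(dr = -half:half, dc = -half:half)
    rr <- rep(rr, nrow(offs)) + rep(offs$dr, each = length(px_x))
    cc <- rep(cc, nrow(offs)) + rep(offs$dc, each = length(px_x))
  }
  nr <- params$field_size_px[1]; ncl <- params$field_size_px[2]
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncl
  unique((cc[ok] - 1) * nr + rr[ok])
}

# static lawn texture for a plate: coarse uniform grid, bilinearly
# interpolated to the field, scaled by lawn_contrast
lawn_background <- function(params, base_level = 200) {
  nr <- params$field_size_px[1]; ncl <- params$field_size_px[2]
  bg <- matrix(base_level, nr, ncl)
  if (params$lawn_contrast > 0) {
    set.seed(substream_seed(params$seed, c(101L)))
    g <- 9L
    coarse <- matrix(runif(g * g, -1, 1), g, g)
    ri <- seq(1, g, length.out = nr)
    ci <- seq(1, g, length.out = ncl)
    r0 <- pmin(floor(ri), g - 1L); c0 <- pmin(floor(ci), g - 1L)
    fr <- ri - r0; fc <- ci - c0
    m <- coarse[r0, c0] * outer(1 - fr, 1 - fc) +
      coarse[r0 + 1, c0] * outer(fr, 1 - fc) +
      coarse[r0, c0 + 1] * outer(1 - fr, fc) +
      coarse[r0 + 1, c0 + 1] * outer(fr, fc)
    bg <- bg + params$lawn_contrast * m
  }
  bg
}

# cumulative trail darkening from all windows before `upto_window`
trail_field <- function(traj, upto_window, params) {
  nr <- params$field_size_px[1]; ncl <- params$field_size_px[2]
  tf <- matrix(0, nr, ncl)
  if (params$trail_amplitude <= 0 || upto_window < 1) return(tf)
  for (k in seq_len(upto_window)) {
    for (w in traj$worms) {
      pose <- w$poses[[k]]
      steps <- seq(1, nrow(pose), by = 2L)
      for (f in steps) {
        idx <- worm_body_pixels(pose[f, ], params)
        tf[idx] <- tf[idx] + params$trail_amplitude
      }
    }
  }
  pmin(tf, 40)
}

#' Render the image stack of one imaging window
#'
#' Produces the 8-bit grayscale frames a camera would record: a light lawn
#' background with low-frequency texture, dark worm bodies drawn as
#' sinusoidally undulating polylines at each frame's pose (the undulation
#' phase advances with travel, so paused worms are perfectly static),
#' optional accumulated trail darkening from earlier windows, and Gaussian
#' read noise, clipped to [0, 255] and rounded to whole gray levels.
#'
#' @param traj A [simulate_worms()] result.
#' @param plate_id Plate label.
#' @param window_index 0-based window to render; must be covered by `traj`.
#' @param schedule The schedule used for the simulation.
#' @param params Simulation parameters; defaults to those in `traj`.
#' @return An [imaging_window()].
#' @export
render_window <- function(traj, plate_id, window_index,
                          schedule = traj$schedule, params = traj$params) {
  k <- window_index + 1L
  if (k < 1L || k > traj$n_windows) stop_input("window_index not in schedule")
  fpw <- frames_per_window(schedule)
  bg <- lawn_background(params) - trail_field(traj, window_index, params)
  frames <- vector("list", fpw)
  set.seed(substream_seed(params$seed, c(211L, window_index)))
  for (f in seq_len(fpw)) {
    img <- bg
    for (w in traj$worms) {
      pose <- w$poses[[k]]
      prow <- pose[min(f, nrow(pose)), ]
      if (any(!is.finite(prow))) stop_input("worm pose non-finite")
      idx <- worm_body_pixels(prow, params)
      if (length(idx)) img[idx] <- bg[idx] - params$worm_contrast
    }
    if (params$noise_sigma > 0) {
      img <- img + rnorm(length(img), 0, params$noise_sigma)
    }
    frames[[f]] <- matrix(clip01(round(img)), nrow(bg), ncol(bg))
  }
  imaging_window(plate_id, window_index,
                 window_t_mid_days(window_index, schedule), frames)
}

#' Generate a synthetic experiment on disk
#'
#' Simulates and renders every plate of a multi-condition experiment and
#' writes the directory tree
#' `<out_dir>/<condition>/<plate>/window_<k>.tiff` together with
#' `manifest.json` (plate metadata and schedule) and `ground_truth.csv`.
#' Plate seeds are derived per (condition, plate) with [substream_seed()],
#' so adding conditions or plates leaves existing ones bit-identical.
#'
#' @param config A list with `conditions` (named list; each entry a list of
#'   [sim_params()] overrides for that condition), `plates_per_condition`,
#'   `duration_days`, optional `schedule` (an [acquisition_schedule()] or a
#'   list of its fields), optional shared `base_params` overrides, `seed`,
#'   and optional `run_id` / `t0`.
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest as an R list.
#' @export
generate_experiment <- function(config, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0 &&
      !overwrite) {
    stop_input("output directory exists and is not empty; ",
               "set overwrite = TRUE to replace it")
  }
  sched <- config$schedule %||% acquisition_schedule()
  if (!inherits(sched, "acquisition_schedule")) {
    sched <- do.call(acquisition_schedule, sched)
  }
  stopifnot(length(config$conditions) >= 1, !is.null(config$plates_per_condition))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  base <- config$base_params %||% list()
  plates <- list()
  gt <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- names(config$conditions)[ci]
    over <- config$conditions[[ci]] %||% list()
    for (pj in seq_len(config$plates_per_condition)) {
      plate_id <- sprintf("%s_p%02d", cond, pj)
      args <- utils::modifyList(base, over)
      args$seed <- substream_seed(seed, c(ci, pj))
      params <- do.call(sim_params, args)
      traj <- simulate_worms(params, config$duration_days, sched)
      pdir <- file.path(out_dir, cond, plate_id)
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(traj$n_windows) - 1L) {
        win <- render_window(traj, plate_id, k, sched, params)
        write_window_tiff(win, file.path(pdir, sprintf("window_%04d.tiff", k)))
      }
      gt[[plate_id]] <- ground_truth_table(traj, plate_id)
      plates[[length(plates) + 1]] <- list(
        plate_id = plate_id, condition = cond,
        n_worms_nominal = params$n_worms, um_per_px = params$um_per_px,
        roi_center_px = as.numeric(params$roi_center_px),
        roi_radius_px = params$roi_radius_px,
        path = file.path(cond, plate_id))
    }
  }
  manifest <- list(
    run_id = config$run_id %||% "synthetic_run",
    t0 = config$t0 %||% "2026-01-01T00:00:00Z",
    schedule = list(frame_interval_s = sched$frame_interval_s,
                    window_duration_s = sched$window_duration_s,
                    period_s = sched$period_s),
    n_windows = n_windows(config$duration_days, sched),
    seed = seed,
    plates = plates)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(do.call(rbind, gt), file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Write one imaging window as a multi-page 8-bit TIFF
#'
#' Page order is frame order. Values are rounded to whole gray levels
#' before writing, so a written-then-read stack is bit-identical.
#'
#' @param window An [imaging_window()].
#' @param path Output file path.
#' @export
write_window_tiff <- function(window, path) {
  pages <- lapply(window$frames, function(f) clip01(round(f)) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}
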