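test_that("simulation handles degenerate populations", {
  sched <- fast_schedule()
  # empty population
  p0 <- dish_params(n_worms = 0, seed = 2)
  traj0 <- simulate_worms(p0, 0.1, sched)
  expect_length(traj0$worms, 0)
  expect_equal(nrow(ground_truth_table(traj0)), 0)
  # everyone dead from day 0: no window ever has movement
  pd <- dish_params(n_worms = 6, death_midpoint_day = -Inf, seed = 3)
  trajd <- simulate_worms(pd, 0.2, sched)
  gtd <- ground_truth_table(trajd)
  expect_true(all(gtd$state == "dead"))
  expect_true(all(gtd$true_speed_um_s == 0))
  expect_false(any(gtd$true_moving))
})

test_that("identical parameters and seed give identical simulations", {
  sched <- fast_schedule()
  p <- dish_params(n_worms = 5, seed = 99)
  t1 <- simulate_worms(p, 0.1, sched)
  t2 <- simulate_worms(p, 0.1, sched)
  expect_identical(t1, t2)
  w1 <- render_window(t1, "p", 0, sched, p)
  w2 <- render_window(t2, "p", 0, sched, p)
  expect_identical(w1$frames, w2$frames)
})

test_that("ground truth is self-consistent", {
  sched <- fast_schedule()
  p <- dish_params(n_worms = 20, seed = 12)
  traj <- simulate_worms(p, 0.3, sched)
  gt <- ground_truth_table(traj, "plateX")
  # one row per worm per window
  expect_equal(nrow(gt), 20 * traj$n_windows)
  # true speed = true path length / window duration
  expect_equal(gt$true_speed_um_s,
               gt$true_path_length_um / sched$window_duration_s)
  # moving call consistent with the threshold
  expect_equal(gt$true_moving, gt$true_speed_um_s >= 10)
  # dead is absorbing: once dead, dead in every later window
  for (w in unique(gt$worm_id)) {
    st <- gt$state[gt$worm_id == w][order(gt$window_index[gt$worm_id == w])]
    dead_idx <- which(st == "dead")
    if (length(dead_idx)) {
      expect_true(all(st[seq(min(dead_idx), length(st))] == "dead"))
    }
  }
})

test_that("static scenes render bit-identical frames", {
  sched <- acquisition_schedule(16, 160, 3600)
  p <- dish_params(n_worms = 8, noise_sigma = 0, p_move_start = 0,
                   seed = 21)
  traj <- simulate_worms(p, 0.05, sched)
  win <- render_window(traj, "p", 0, sched, p)
  for (f in win$frames[-1]) expect_identical(f, win$frames[[1]])
})

test_that("a worm outside the field leaves pure background", {
  sched <- acquisition_schedule(16, 160, 3600)
  # huge ROI so the walk is unconstrained; start the worm far off-field by
  # using a tiny field with the ROI centred far away
  p <- sim_params(n_worms = 1, field_size_px = c(64, 64), um_per_px = 25,
                  roi_center_px = c(2000, 2000), roi_radius_px = 100,
                  noise_sigma = 0, p_move_start = 1,
                  p_move_midpoint_day = 50, seed = 4)
  traj <- simulate_worms(p, 0.05, sched)
  win <- render_window(traj, "p", 0, sched, p)
  bg_only <- render_window(
    simulate_worms(sim_params(n_worms = 0, field_size_px = c(64, 64),
                              um_per_px = 25,
                              roi_center_px = c(2000, 2000),
                              roi_radius_px = 100, noise_sigma = 0,
                              seed = 4), 0.05, sched), "p", 0, sched)
  expect_identical(win$frames, bg_only$frames)
})

test_that("frame differences are exactly the worm footprint changes", {
  # with zero noise and no trails, two frames differ exactly where the
  # union of worm bodies differs between the two times
  sched <- acquisition_schedule(16, 160, 3600)
  p <- dish_params(n_worms = 3, noise_sigma = 0, lawn_contrast = 5,
                   p_move_start = 1, p_move_midpoint_day = 50, seed = 31)
  traj <- simulate_worms(p, 0.05, sched)
  win <- render_window(traj, "p", 0, sched, p)
  fp <- function(f_idx) {
    idx <- unlist(lapply(traj$worms, function(w) {
      pose <- w$poses[[1]]
      plategazer:::worm_body_pixels(pose[min(f_idx, nrow(pose)), ], p)
    }))
    unique(idx)
  }
  for (pair in list(c(1, 2), c(1, 10), c(5, 9))) {
    diffpix <- which(win$frames[[pair[1]]] != win$frames[[pair[2]]])
    sym <- union(setdiff(fp(pair[1]), fp(pair[2])),
                 setdiff(fp(pair[2]), fp(pair[1])))
    expect_setequal(diffpix, sym)
  }
})

test_that("a straight run smears over speed x duration / scale pixels", {
  sched <- acquisition_schedule(8, 160, 3600)
  p <- sim_params(n_worms = 1, field_size_px = c(512, 512), um_per_px = 25,
                  baseline_speed_um_s = 50, heading_diffusion = 0,
                  p_move_start = 1, p_move_midpoint_day = 50,
                  noise_sigma = 0, seed = 8)
  traj <- simulate_worms(p, 0.05, sched)
  win <- render_window(traj, "p", 0, sched, p)
  mask <- motion_mask(win$frames, detection_params())
  px <- which(mask, arr.ind = TRUE)
  extent <- sqrt(diff(range(px[, 1]))^2 + diff(range(px[, 2]))^2)
  expected <- 50 * 160 / 25 # 320 px of pure travel
  # frames span (F-1)/F of the window, and the body adds up to one
  # (undulating) body extent ~ 36 px to the smear
  expect_gt(extent, expected * (19 / 20) * 0.95)
  expect_lt(extent, expected + 45)
})

test_that("generate_experiment writes the documented tree and is reproducible", {
  cfg <- tiny_sim_config()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  man <- generate_experiment(cfg, out1, overwrite = TRUE)
  generate_experiment(cfg, out2, overwrite = TRUE)
  expect_equal(length(man$plates), 4) # 2 conditions x 2 plates
  files <- sort(list.files(out1, recursive = TRUE))
  expect_true("manifest.json" %in% files)
  expect_true("ground_truth.csv" %in% files)
  tiffs <- grep("window_\\d{4}\\.tiff$", files, value = TRUE)
  expect_length(tiffs, 4 * n_windows(cfg$duration_days, cfg$schedule))
  # byte-identical rerun
  for (f in files) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e7),
                     readBin(file.path(out2, f), "raw", 1e7),
                     info = f)
  }
  # refusal to overwrite silently
  expect_error(generate_experiment(cfg, out1), "overwrite")
  # frame count in each stack follows the schedule
  frames <- read_image_sequence(file.path(out1, tiffs[1]))
  expect_length(frames, frames_per_window(cfg$schedule))
})

test_that("window counts follow the ceiling rule and the 5-min period", {
  expect_equal(n_windows(1, acquisition_schedule()), 288L) # 86400 / 300
  expect_equal(n_windows(0.01, acquisition_schedule(8, 160, 3600)), 1L)
  expect_equal(n_windows(2, acquisition_schedule()), 576L)
})

test_that("substream seeds are insensitive to sibling additions", {
  s1 <- substream_seed(5, c(1, 3))
  expect_identical(s1, substream_seed(5, c(1, 3)))
  expect_false(s1 == substream_seed(5, c(1, 4)))
  expect_false(s1 == substream_seed(5, c(2, 3)))
  # worm streams are per-worm: adding a worm leaves earlier worms alone
  sched <- fast_schedule()
  p5 <- dish_params(n_worms = 5, seed = 7)
  p6 <- dish_params(n_worms = 6, seed = 7)
  t5 <- simulate_worms(p5, 0.1, sched)
  t6 <- simulate_worms(p6, 0.1, sched)
  expect_identical(t5$worms[[3]], t6$worms[[3]])
})
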