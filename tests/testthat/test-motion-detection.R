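test_that("schedule arithmetic matches the acquisition design", {
  sched <- acquisition_schedule()
  expect_identical(frames_per_window(sched), 200L)
  expect_equal(frame_rate_fps(sched), 1.25)
  expect_equal(window_t_mid_days(0, sched), 80 / 86400)
  expect_error(acquisition_schedule(period_s = 100), "period_s")
  expect_error(acquisition_schedule(frame_interval_s = 200,
                                    window_duration_s = 160,
                                    period_s = 200),
               "at least 2 frames")
})

test_that("mean_frame averages per pixel in floating precision", {
  a <- matrix(7, 4, 4)
  expect_equal(mean_frame(list(a, a, a)), a)
  f1 <- matrix(0, 3, 3); f2 <- matrix(255, 3, 3)
  expect_equal(mean_frame(list(f1, f2))[2, 2], 127.5)
  expect_equal(mean_frame(const_stack(42, n = 5)), matrix(42, 5, 5))
  expect_error(mean_frame(list(matrix(0, 2, 2))), "2 frames")
  expect_error(mean_frame(list(matrix(0, 2, 2), matrix(0, 3, 3))), "shape")
})

test_that("motion mask flags exactly the pixels that change past threshold", {
  params <- detection_params()
  # identical frames: nothing moves
  expect_false(any(motion_mask(const_stack(100, 4), params)))
  # one pixel alternating 0/255
  st <- const_stack(0, 4)
  for (i in c(2, 4)) st[[i]][3, 3] <- 255
  m <- motion_mask(st, params)
  expect_true(m[3, 3])
  expect_equal(sum(m), 1)
  # sub-threshold bump stays dark
  st2 <- const_stack(100, 5)
  st2[[3]][2, 2] <- 110 # mean 102, max deviation 8 < 15
  expect_false(any(motion_mask(st2, params)))
})

test_that("motion mask agrees with brute-force evaluation on random stacks", {
  set.seed(42)
  params <- detection_params()
  for (rep in 1:300) {
    nf <- sample(2:6, 1)
    st <- replicate(nf, matrix(sample(0:255, 25, replace = TRUE), 5, 5),
                    simplify = FALSE)
    expect_identical(motion_mask(st, params),
                     brute_motion_mask(st, 15))
  }
})

test_that("raising the threshold never adds mask pixels", {
  set.seed(7)
  st <- replicate(5, matrix(sample(0:255, 100, replace = TRUE), 10, 10),
                  simplify = FALSE)
  prev <- Inf
  for (thr in c(5, 15, 40, 90)) {
    n <- sum(motion_mask(st, detection_params(diff_threshold = thr)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("label_objects applies 8-connectivity, area and ROI rules", {
  params <- detection_params(min_area_px = 3)
  roi <- full_roi(c(9, 9))
  expect_length(label_objects(matrix(FALSE, 9, 9), roi, params), 0)
  # two 3-px blobs, well separated
  m <- matrix(FALSE, 9, 9)
  m[2, 2:4] <- TRUE
  m[7, 6:8] <- TRUE
  obs <- label_objects(m, roi, params)
  expect_length(obs, 2)
  expect_equal(vapply(obs, `[[`, 0L, "area_px"), c(3L, 3L))
  # diagonal touching merges under 8-connectivity
  d <- matrix(FALSE, 9, 9)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE; d[4, 4] <- TRUE
  expect_length(label_objects(d, roi, detection_params(min_area_px = 1)), 1)
  # area filter
  expect_length(label_objects(d, roi, detection_params(min_area_px = 4)), 0)
  # centroid outside the ROI circle drops the blob
  big <- matrix(FALSE, 20, 20)
  big[2:6, 2:11] <- TRUE # 50 px, centroid (4, 6.5)
  away <- roi_mask(c(15, 15), 5)
  expect_length(label_objects(big, away, detection_params()), 0)
  inside <- roi_mask(c(4, 6), 6)
  expect_length(label_objects(big, inside, detection_params()), 1)
})

test_that("translation moves objects without changing count, area or length", {
  set.seed(19)
  m <- matrix(FALSE, 40, 40)
  m[10:12, 5:25] <- TRUE # bar
  m[25 + (0:6), 25 + (0:6)] <- TRUE # diagonal line
  roi <- roi_mask(c(18, 18), 30)
  params <- detection_params(min_area_px = 3)
  base <- label_objects(m, roi, params)
  shifted <- matrix(FALSE, 40, 40)
  shifted[which(m, arr.ind = TRUE) + matrix(c(4, 6), sum(m), 2, byrow = TRUE)] <- TRUE
  roi2 <- roi_mask(c(22, 24), 30)
  moved <- label_objects(shifted, roi2, params)
  expect_length(moved, length(base))
  expect_equal(vapply(moved, `[[`, 0L, "area_px"),
               vapply(base, `[[`, 0L, "area_px"))
  for (i in seq_along(base)) {
    sub <- function(ob) {
      px <- ob$pixels
      mm <- matrix(FALSE, diff(range(px[, 1])) + 1, diff(range(px[, 2])) + 1)
      mm[cbind(px[, 1] - min(px[, 1]) + 1, px[, 2] - min(px[, 2]) + 1)] <- TRUE
      mm
    }
    expect_equal(object_path_length(sub(moved[[i]]), 25),
                 object_path_length(sub(base[[i]]), 25))
  }
})

test_that("skeleton path length matches hand-countable geometry", {
  # 41-px bar, 3 px thick: full midline survives, 40 axial steps
  bar <- matrix(FALSE, 7, 45)
  bar[3:5, 3:43] <- TRUE
  expect_equal(object_path_length(bar, 25), 1000)
  # single pixel skeleton has zero length
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(object_path_length(one, 25), 0)
  expect_error(object_path_length(matrix(FALSE, 3, 3), 25), "empty")
  # L-shaped 1-px path, arms of 21 px sharing the corner pixel: 40 steps
  L <- matrix(FALSE, 30, 30)
  L[5:25, 5] <- TRUE
  L[25, 5:25] <- TRUE
  expect_equal(object_path_length(L, 25) / 25, 40, tolerance = 2 / 40)
})

test_that("skeleton length of digital straight segments tracks Euclidean length", {
  for (slope in c(0, 0.2, 0.25, 0.5, 0.75, 1)) {
    for (dc in c(60, 120)) {
      seg <- digital_segment(20, 10, dc, slope)
      eu <- sqrt(dc^2 + round(dc * slope)^2)
      got <- object_path_length(seg, 1)
      expect_lt(abs(got - eu) / eu, 0.08)
    }
  }
})

test_that("detect_moving_objects filters by the 10 um/s speed threshold", {
  sched <- acquisition_schedule()
  # length 3200 um in 160 s -> 20 um/s, retained; 1440 um -> 9 um/s, dropped
  expect_equal(3200 / sched$window_duration_s, 20)
  expect_lt(1440 / sched$window_duration_s, 10)
  # a static stack yields nothing
  win <- imaging_window("p", 0L, 0, const_stack(128, 4, c(16, 16)))
  out <- detect_moving_objects(win, full_roi(c(16, 16)),
                               detection_params(), sched)
  expect_equal(nrow(out), 0)
  # synthetic bars: one fast (41 px at 25 um/px = 1000 um -> 6.25 um/s,
  # dropped), one long diagonal streak fast enough to keep
  sched2 <- acquisition_schedule(8, 80, 300) # 10 frames, 80 s window
  f0 <- matrix(0, 80, 80)
  st <- replicate(10, f0, simplify = FALSE)
  # paint a 65-px streak into half the frames so it shows in the mask
  streak <- cbind(40, 8:72)
  for (i in seq(2, 10, by = 2)) st[[i]][streak] <- 255
  win2 <- imaging_window("p", 0L, 0, st)
  out2 <- detect_moving_objects(win2, full_roi(c(80, 80)),
                                detection_params(um_per_px = 25), sched2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$length_um, 64 * 25)
  expect_equal(out2$speed_um_s, 64 * 25 / 80) # = 20 um/s >= 10
})

test_that("read/write of window stacks round-trips bit-exactly", {
  set.seed(5)
  frames <- replicate(4, matrix(sample(0:255, 64, replace = TRUE), 8, 8),
                      simplify = FALSE)
  win <- imaging_window("p", 0L, 0.5, frames)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_window_tiff(win, path)
  back <- read_image_sequence(path, expected_frames = 4)
  expect_equal(back, frames)
  expect_error(read_image_sequence(path, expected_frames = 200), "expects")
})
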