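# small in-code fixtures shared across test files

# a stack of constant frames
const_stack <- function(value, n = 3, dim = c(5, 5)) {
  replicate(n, matrix(value, dim[1], dim[2]), simplify = FALSE)
}

# brute-force oracle for the motion-mask definition: literal evaluation of
# "some frame deviates from the per-pixel mean by at least the threshold",
# written with explicit loops so it shares nothing with the implementation
brute_motion_mask <- function(frames, threshold) {
  d <- dim(frames[[1]])
  mask <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      vals <- vapply(frames, function(f) f[r, c], numeric(1))
      m <- sum(vals) / length(vals)
      mask[r, c] <- any(abs(vals - m) >= threshold)
    }
  }
  mask
}

# 1-px-wide digital straight segment from (r0, c0) with the given column
# extent and slope, drawn by rounding (the mask IS the segment)
digital_segment <- function(r0, c0, dc, slope, dim = c(160, 160)) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (k in 0:dc) {
    m[r0 + round(k * slope), c0 + k] <- TRUE
  }
  m
}

# permissive roi covering a whole field
full_roi <- function(dim = c(5, 5)) {
  roi_mask(c(dim[1] / 2, dim[2] / 2), max(dim) * 2)
}

# a fast dish-scale simulation configuration: whole 6-cm dish imaged at
# 0.1 mm/px, 20 frames spanning the 160 s window, one window per hour
dish_params <- function(...) {
  sim_params(field_size_px = c(512, 512), um_per_px = 100,
             roi_radius_px = 240, ...)
}

fast_schedule <- function() {
  acquisition_schedule(frame_interval_s = 8, window_duration_s = 160,
                       period_s = 3600)
}

# tiny rendering setup used by interface tests: small field, few worms
tiny_sim_config <- function(seed = 11) {
  list(
    run_id = "tiny",
    seed = seed,
    duration_days = 4 / 24, # 4 windows at 1/h
    schedule = acquisition_schedule(16, 160, 3600),
    plates_per_condition = 2,
    base_params = list(field_size_px = c(128, 128), um_per_px = 100,
                       n_worms = 4, worm_length_um = 800,
                       baseline_speed_um_s = 30, noise_sigma = 2,
                       p_move_midpoint_day = 30, p_move_start = 0.9),
    conditions = list(ctrl = list(), slow = list(p_move_start = 0.4)))
}
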