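#' Detection parameters for motion analysis
#'
#' @param diff_threshold Minimum absolute deviation from the window-mean
#'   image (8-bit gray levels) for a pixel to count as changed. The default
#'   of 15 suppresses cameras with read-noise sigma up to ~3 gray levels at
#'   a false-pixel rate below 1e-6 per pixel-frame.
#' @param min_area_px Connected components smaller than this many pixels are
#'   discarded as salt-and-pepper residue.
#' @param v_min_um_s Speed threshold in micrometres per second; objects
#'   slower than this are not counted as moving. Default 10.
#' @param um_per_px Image scale, micrometres per pixel (isotropic).
#' @param adaptive If `TRUE`, the per-window threshold is raised to
#'   `max(diff_threshold, 5 * sigma_hat)` where `sigma_hat` is a robust
#'   (MAD-based) noise estimate from the difference images.
#' @param bridge_occlusions A worm that crawls across a motionless worm
#'   leaves no pixel change where the static body occludes it, which cuts
#'   its motion smear in two. When `TRUE` (default), constantly-dark
#'   pixels (static bodies) may *connect* smear fragments during
#'   labelling, while never contributing pixels to any object.
#' @return A `detection_params` object.
#' @export
detection_params <- function(diff_threshold = 15, min_area_px = 5,
                             v_min_um_s = 10, um_per_px = 25,
                             adaptive = FALSE, bridge_occlusions = TRUE) {
  check_scalar_number(diff_threshold, "diff_threshold", min = 1e-9)
  check_scalar_number(min_area_px, "min_area_px", min = 0)
  check_scalar_number(v_min_um_s, "v_min_um_s", min = 0)
  check_scalar_number(um_per_px, "um_per_px", min = 1e-12)
  structure(
    list(diff_threshold = diff_threshold, min_area_px = min_area_px,
         v_min_um_s = v_min_um_s, um_per_px = um_per_px,
         adaptive = isTRUE(adaptive),
         bridge_occlusions = isTRUE(bridge_occlusions)),
    class = "detection_params"
  )
}

#' Circular region of interest
#'
#' Only objects whose centroid falls strictly inside this circle are kept,
#' mirroring the ring-shaped area limit for worm detection on the imaging
#' rig. The circle need not fit inside the frame.
#'
#' @param center_px Numeric length-2, circle centre as (row, col) in pixels.
#' @param radius_px Circle radius in pixels (> 0).
#' @export
roi_mask <- function(center_px, radius_px) {
  if (length(center_px) != 2L || !all(is.finite(center_px))) {
    stop_input("center_px must be two finite numbers (row, col)")
  }
  check_scalar_number(radius_px, "radius_px", min = 1e-9)
  structure(list(center_px = as.numeric(center_px),
                 radius_px = radius_px),
            class = "roi_mask")
}

#' One plate's frame stack for a single imaging window
#'
#' @param plate_id Plate identifier.
#' @param window_index 0-based index of the window in the run.
#' @param t_mid_days Window midpoint in days since L4 placement (>= 0).
#' @param frames List of equal-shaped numeric matrices with values on the
#'   8-bit scale (0-255).
#' @export
imaging_window <- function(plate_id, window_index, t_mid_days, frames) {
  validate_frames(frames)
  check_scalar_number(t_mid_days, "t_mid_days", min = 0)
  structure(
    list(plate_id = plate_id, window_index = as.integer(window_index),
         t_mid_days = t_mid_days, frames = frames),
    class = "imaging_window"
  )
}

validate_frames <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_input("frames must be a non-empty list of matrices")
  }
  d <- dim(frames[[1]])
  if (is.null(d)) stop_input("frames must be matrices")
  same <- vapply(frames, function(f) {
    is.matrix(f) && identical(dim(f), d)
  }, logical(1))
  if (!all(same)) stop_input("all frames must have identical shape")
  invisible(d)
}

#' Per-pixel mean of a frame stack
#'
#' The temporal background estimate: the arithmetic mean of all frames in
#' the window, kept in floating precision (not re-quantised to 8 bits).
#'
#' @param frames List of at least two equal-shaped numeric matrices.
#' @return A numeric matrix of the same shape.
#' @export
mean_frame <- function(frames) {
  validate_frames(frames)
  if (length(frames) < 2L) stop_input("need at least 2 frames")
  Reduce(`+`, frames) / length(frames)
}

#' Motion mask of an imaging window
#'
#' Subtracts the window-mean image from every frame and accumulates, by
#' logical OR, the pixels whose absolute deviation reaches the threshold in
#' at least one frame. Pixels that changed during the window (because a worm
#' transited them) come out `TRUE`; the static background stays `FALSE`.
#'
#' @param frames List of frames (see [mean_frame()]).
#' @param params A [detection_params()] object.
#' @return A logical matrix.
#' @export
motion_mask <- function(frames, params) {
  mf <- mean_frame(frames)
  thr <- params$diff_threshold
  if (params$adaptive) {
    sig <- median(vapply(frames, function(f) mad(f - mf), numeric(1)))
    thr <- max(thr, 5 * sig)
  }
  mask <- matrix(FALSE, nrow(mf), ncol(mf))
  for (f in frames) {
    mask <- mask | (abs(f - mf) >= thr)
  }
  mask
}

# 8-connected component labelling of a sparse binary mask.
# Vectorised label propagation with pointer jumping: each true pixel starts
# as its own label (its compact index); labels are repeatedly replaced by
# the minimum over the 8-neighbourhood, with path-halving to speed
# convergence. Returns NULL for an empty mask, otherwise a list with the
# pixel coordinates (in row-major scan order) and an integer component id
# per pixel (ids are 1..n_components, numbered by first pixel in raster
# order).
label_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(NULL)
  nr <- nrow(mask); ncl <- ncol(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  # row-major order so that component ids follow raster order of first pixel
  o <- order(r, c)
  r <- r[o]; c <- c[o]
  n <- length(r)
  key <- (r - 1) * (ncl + 2) + c # collision-free linear key with margin
  pos <- seq_len(n)
  nb_off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                  c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  nbr <- matrix(NA_integer_, n, 8)
  for (k in 1:8) {
    nbr[, k] <- match(key + nb_off[k, 1] * (ncl + 2) + nb_off[k, 2], key)
  }
  lab <- pos
  repeat {
    old <- lab
    for (k in 1:8) {
      nk <- nbr[, k]
      ok <- !is.na(nk)
      lab[ok] <- pmin(lab[ok], lab[nk[ok]])
    }
    lab <- pmin(lab, lab[lab]) # path halving
    lab <- lab[lab]
    if (identical(lab, old)) break
  }
  comp <- match(lab, sort(unique(lab)))
  list(row = r, col = c, component = comp, n = max(comp))
}

#' Extract candidate motion objects from a binary mask
#'
#' Finds 8-connected components of the mask, discards those smaller than
#' `min_area_px`, and keeps a component only if its centroid lies strictly
#' inside the ROI circle (components straddling the ring are kept when the
#' centroid is inside). Geometry only: speeds are attached later by
#' [detect_moving_objects()].
#'
#' @param mask Logical matrix from [motion_mask()].
#' @param roi A [roi_mask()].
#' @param params A [detection_params()].
#' @param bridge Optional logical matrix of connector pixels (static dark
#'   bodies occluding a smear): they join fragments during labelling but
#'   are never part of any object's pixels, area or centroid.
#' @return A list of objects, each a list with `object_id`, `area_px`,
#'   `centroid_px` (row, col) and `pixels` (2-column matrix of row, col).
#'   Objects are ordered by the raster position of their first pixel.
#' @export
label_objects <- function(mask, roi, params, bridge = NULL) {
  aug <- if (is.null(bridge)) mask else (mask | bridge)
  lc <- label_components(aug)
  if (is.null(lc)) return(list())
  out <- list()
  oid <- 0L
  for (ci in seq_len(lc$n)) {
    sel <- lc$component == ci
    pr <- lc$row[sel]; pc <- lc$col[sel]
    if (!is.null(bridge)) {
      core <- mask[cbind(pr, pc)]
      pr <- pr[core]; pc <- pc[core]
    }
    if (length(pr) < params$min_area_px) next
    cen <- c(mean(pr), mean(pc))
    d2 <- (cen[1] - roi$center_px[1])^2 + (cen[2] - roi$center_px[2])^2
    if (d2 >= roi$radius_px^2) next # strict interior
    oid <- oid + 1L
    out[[oid]] <- list(object_id = oid, area_px = length(pr),
                       centroid_px = cen,
                       pixels = cbind(row = pr, col = pc))
  }
  out
}

#' Morphological skeleton of a binary mask
#'
#' Iterative thinning: in each iteration the north, south, east and west
#' boundary pixels (determined from a snapshot at the start of each
#' directional subcycle) are deleted in sequence when they are 8-simple
#' (Yokoi connectivity number 1, so deletion cannot break or create
#' components) and are not line endpoints (at least two foreground
#' neighbours). Endpoint preservation keeps the full extent of elongated
#' blobs, so a 3-pixel-thick straight bar thins to its complete midline.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same shape containing the skeleton.
#' @export
skeletonize <- function(mask) {
  nr <- nrow(mask); ncl <- ncol(mask)
  p <- matrix(FALSE, nr + 2, ncl + 2)
  p[2:(nr + 1), 2:(ncl + 1)] <- mask
  # neighbour order x1=E, x2=NE, x3=N, x4=NW, x5=W, x6=SW, x7=S, x8=SE
  dro <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dco <- c(1, 1, 0, -1, -1, -1, 0, 1)
  dirs <- list(c(-1, 0), c(1, 0), c(0, 1), c(0, -1))
  np <- nrow(p)
  repeat {
    changed <- FALSE
    for (d in dirs) {
      idx <- which(p)
      if (!length(idx)) break
      rr <- ((idx - 1L) %% np) + 1L
      cc <- ((idx - 1L) %/% np) + 1L
      bnd <- !p[cbind(rr + d[1], cc + d[2])]
      rr <- rr[bnd]; cc <- cc[bnd]
      for (k in seq_along(rr)) {
        r <- rr[k]; c <- cc[k]
        if (!p[r, c]) next
        x <- p[cbind(r + dro, c + dco)]
        if (sum(x) < 2) next # endpoints and isolated pixels survive
        xb <- !x
        nc8 <- 0L
        for (j in c(1L, 3L, 5L, 7L)) {
          j1 <- if (j == 7L) 8L else j + 1L
          j2 <- if (j >= 7L) j - 6L else j + 2L
          nc8 <- nc8 + (xb[j] - (xb[j] && xb[j1] && xb[j2]))
        }
        if (nc8 == 1L) { p[r, c] <- FALSE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  p[2:(nr + 1), 2:(ncl + 1), drop = FALSE]
}

# chain length of a skeleton: each pair of 8-adjacent skeleton pixels
# contributes one step (1 per axial step, sqrt(2) per diagonal), counted
# once; a diagonal step is dropped when the two pixels already share an
# axial neighbour (corner-cut rule, avoids double counting at bends).
chain_length_steps <- function(sk) {
  px <- which(sk, arr.ind = TRUE)
  if (nrow(px) < 2) return(0)
  # pad by one on all sides so neighbour lookups never leave the matrix
  on <- matrix(FALSE, max(px[, 1]) + 2, max(px[, 2]) + 2)
  on[px + 1L] <- TRUE
  r <- px[, 1] + 1L; c <- px[, 2] + 1L
  ax <- sum(on[cbind(r, c + 1L)]) + sum(on[cbind(r + 1L, c)])
  dse <- on[cbind(r + 1L, c + 1L)] &
    !(on[cbind(r, c + 1L)] | on[cbind(r + 1L, c)])
  dsw <- on[cbind(r + 1L, c - 1L)] &
    !(on[cbind(r, c - 1L)] | on[cbind(r + 1L, c)])
  ax + (sum(dse) + sum(dsw)) * sqrt(2)
}

#' Path length of one motion object
#'
#' Operationalises the "length of the object" measurement: the motion smear
#' accumulated over a window is reduced to its morphological skeleton
#' ([skeletonize()]) and the skeleton's chain length is summed (1 per axial
#' step, sqrt(2) per diagonal step) and scaled to micrometres. A
#' single-pixel skeleton has length 0.
#'
#' @param component_mask Logical matrix holding a single connected
#'   component (it may be a cropped bounding box).
#' @param um_per_px Micrometres per pixel.
#' @return Length in micrometres.
#' @examples
#' bar <- matrix(FALSE, 7, 45); bar[3:5, 3:43] <- TRUE
#' object_path_length(bar, 25) # 1000
#' @export
object_path_length <- function(component_mask, um_per_px) {
  if (!any(component_mask)) stop_input("empty component")
  chain_length_steps(skeletonize(component_mask)) * um_per_px
}

# per-frame centre-of-mass tracking length for one component: in each
# frame, the deviation-weighted centroid of the component's pixels at or
# above the threshold (weighting suppresses the faint "ghost" residue of
# the depressed mean along the path, which would otherwise drag the
# centroid); the path is the summed distance between consecutive
# available centroids.
centroid_track_length <- function(frames, mf, pixels, params) {
  thr <- params$diff_threshold
  lin <- (pixels[, 2] - 1L) * nrow(mf) + pixels[, 1]
  prev <- NULL
  total <- 0
  for (f in frames) {
    dev <- abs(f[lin] - mf[lin])
    # the body deviates by about the full worm contrast while the path
    # residue stays near the mean-depression level; keeping only pixels
    # above half the frame's peak deviation isolates the body
    hot <- dev >= pmax(thr, 0.5 * max(dev))
    if (!any(hot)) next
    w <- dev[hot]
    cen <- c(sum(pixels[hot, 1] * w), sum(pixels[hot, 2] * w)) / sum(w)
    if (!is.null(prev)) {
      total <- total + sqrt(sum((cen - prev)^2))
    }
    prev <- cen
  }
  total * params$um_per_px
}

#' Detect moving objects in one imaging window
#'
#' The per-window analysis chain: [motion_mask()] then [label_objects()],
#' a path-length measurement per object, speed = length / window duration,
#' and finally the minimum-speed filter (`v_min_um_s`, default 10 um/s)
#' that separates moving worms from trails and other slow intensity drift.
#'
#' Two length measurements are available. `"skeleton"` (default) measures
#' the geodesic length of the smear skeleton; note that a smear spans the
#' worm's path plus one body extent, so skeleton speeds carry a positive
#' bias of roughly body_length / (speed x window). `"centroid"` follows the
#' changed pixels' centre of mass frame by frame, which is unbiased for
#' worms that displace clearly between frames.
#'
#' @param window An [imaging_window()].
#' @param roi A [roi_mask()].
#' @param params A [detection_params()].
#' @param schedule An [acquisition_schedule()].
#' @param length_mode `"skeleton"` or `"centroid"`.
#' @return A data.frame with one row per retained object: `plate_id`,
#'   `window_index`, `t_mid_days`, `object_id`, `area_px`, `length_um`,
#'   `speed_um_s`, `centroid_row`, `centroid_col`. Zero rows when nothing
#'   moves.
#' @export
detect_moving_objects <- function(window, roi, params, schedule,
                                  length_mode = c("skeleton", "centroid")) {
  length_mode <- match.arg(length_mode)
  stopifnot(inherits(window, "imaging_window"))
  mask <- motion_mask(window$frames, params)
  mf <- if (params$bridge_occlusions %||% FALSE || length_mode == "centroid") {
    mean_frame(window$frames)
  }
  bridge <- if (params$bridge_occlusions %||% FALSE) {
    # constantly-dark pixels: well below the background level and not
    # themselves part of the motion mask
    (mf < median(mf) - 2 * params$diff_threshold) & !mask
  }
  objs <- label_objects(mask, roi, params, bridge = bridge)
  empty <- data.frame(
    plate_id = character(0), window_index = integer(0),
    t_mid_days = numeric(0), object_id = integer(0), area_px = integer(0),
    length_um = numeric(0), speed_um_s = numeric(0),
    centroid_row = numeric(0), centroid_col = numeric(0),
    stringsAsFactors = FALSE)
  if (!length(objs)) return(empty)
  rows <- lapply(objs, function(ob) {
    if (length_mode == "skeleton") {
      rmin <- min(ob$pixels[, 1]); cmin <- min(ob$pixels[, 2])
      sub <- matrix(FALSE, max(ob$pixels[, 1]) - rmin + 1,
                    max(ob$pixels[, 2]) - cmin + 1)
      sub[cbind(ob$pixels[, 1] - rmin + 1L, ob$pixels[, 2] - cmin + 1L)] <- TRUE
      len <- object_path_length(sub, params$um_per_px)
    } else {
      len <- centroid_track_length(window$frames, mf, ob$pixels, params)
    }
    data.frame(
      plate_id = window$plate_id, window_index = window$window_index,
      t_mid_days = window$t_mid_days, object_id = ob$object_id,
      area_px = ob$area_px, length_um = len,
      speed_um_s = len / schedule$window_duration_s,
      centroid_row = ob$centroid_px[1], centroid_col = ob$centroid_px[2],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$speed_um_s >= params$v_min_um_s, , drop = FALSE]
  if (nrow(out)) {
    out$object_id <- seq_len(nrow(out)) # renumber after the speed filter
    rownames(out) <- NULL
  } else {
    out <- empty
  }
  out
}
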