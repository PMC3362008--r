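#' Tracker configuration
#'
#' Parameters of the frame-to-frame normalized cross-correlation tracker and
#' the key-point smoothing filter.
#'
#' @param rolling_average_window frames averaged before correlation
#'   (default 2) to damp frame noise.
#' @param coarse_range,coarse_step coarse rotation sweep half-range and step
#'   in degrees about the predicted rotation.
#' @param fine_range,fine_step fine rotation sweep about the coarse optimum.
#' @param shift_radius translation search half-width in pixels about the
#'   velocity-extrapolated position.
#' @param coarse_stride,fine_stride template-point subsampling strides for
#'   the coarse and fine sweeps (strides are relaxed automatically for small
#'   templates so at least 200 support points remain).
#' @param peak_threshold minimum acceptable correlation peak; below it the
#'   frame is flagged `low_peak` and the previous pose propagated.
#' @param subpixel `"parabolic"` (3-point parabolic interpolation of the
#'   correlation peak over shift and rotation) or `"none"`.
#' @param butterworth_order,butterworth_cutoff order and cutoff (Hz) of the
#'   zero-phase low-pass used by [smooth_keypoints()].  The trunk sweep
#'   fundamental is about 0.05-0.12 Hz under the consensus protocol, so the
#'   1 Hz default preserves motion while removing frame noise.
#' @param template_update `"none"` keeps the frame-0 template throughout
#'   (incremental search only); `"every_frame"` re-samples the template
#'   appearance from each newly tracked frame.
#' @return An object of class `qf_tracker_config`.
#' @export
tracker_config <- function(rolling_average_window = 2L,
                           coarse_range = 2, coarse_step = 0.25,
                           fine_range = 0.15, fine_step = 0.05,
                           shift_radius = 2L, coarse_stride = 4L,
                           fine_stride = 2L,
                           peak_threshold = 0.5,
                           subpixel = c("parabolic", "none"),
                           butterworth_order = 4L, butterworth_cutoff = 1.0,
                           template_update = c("none", "every_frame")) {
  stopifnot(coarse_step > 0, fine_step > 0, shift_radius >= 1,
            peak_threshold > 0, peak_threshold < 1,
            rolling_average_window >= 1)
  structure(
    list(rolling_average_window = as.integer(rolling_average_window),
         coarse_range = coarse_range, coarse_step = coarse_step,
         fine_range = fine_range, fine_step = fine_step,
         shift_radius = as.integer(shift_radius),
         coarse_stride = as.integer(coarse_stride),
         fine_stride = as.integer(fine_stride),
         peak_threshold = peak_threshold,
         subpixel = match.arg(subpixel),
         butterworth_order = as.integer(butterworth_order),
         butterworth_cutoff = butterworth_cutoff,
         template_update = match.arg(template_update)),
    class = "qf_tracker_config"
  )
}

#' Build a tracking template from an image and polygon
#'
#' Samples the grey values of all integer pixel positions inside the
#' tracking polygon; these values and coordinates form the rigid template
#' correlated against later frames.
#'
#' @param image grayscale image matrix (frame 0, usually rolling-averaged).
#' @param polygon n x 2 matrix of polygon vertices.
#' @param metal optional list of polygons whose interiors are excluded from
#'   the correlation support (implant masking).
#' @param pivot rotation pivot; defaults to the support centroid.
#' @return An object of class `qf_template` with fields `x`, `y` (integer
#'   pixel coordinates), `values`, `weights`, `pivot`, `polygon`,
#'   `support_fraction`.
#' @export
qf_template <- function(image, polygon, metal = list(), pivot = NULL) {
  polygon <- as.matrix(polygon)
  xr <- max(0, floor(min(polygon[, 1]))):min(ncol(image) - 1, ceiling(max(polygon[, 1])))
  yr <- max(0, floor(min(polygon[, 2]))):min(nrow(image) - 1, ceiling(max(polygon[, 2])))
  px <- rep(xr, each = length(yr)); py <- rep(yr, times = length(xr))
  inside <- points_in_polygon(px, py, polygon)
  px <- px[inside]; py <- py[inside]
  if (length(px) < 16) stop("tracking polygon encloses too few pixels", call. = FALSE)
  tpl <- structure(
    list(x = as.integer(px), y = as.integer(py),
         values = image[cbind(py + 1, px + 1)],
         weights = rep(1, length(px)),
         pivot = pivot %||% c(mean(px), mean(py)),
         polygon = polygon, support_fraction = 1),
    class = "qf_template")
  if (length(metal)) tpl <- mask_metal(tpl, metal)
  tpl
}

#' Exclude implant regions from a template's correlation support
#'
#' Pixels inside the given polygons get zero weight in the normalized
#' cross-correlation, removing implanted metal from the registration.
#'
#' @param template a [qf_template()].
#' @param polygons list of n x 2 polygon matrices (image coordinates).
#' @return The template with updated `weights` and `support_fraction`.
#' @export
mask_metal <- function(template, polygons) {
  stopifnot(inherits(template, "qf_template"))
  if (length(polygons) == 0) return(template)
  w <- template$weights
  for (poly in polygons) {
    w[points_in_polygon(template$x, template$y, as.matrix(poly))] <- 0
  }
  frac <- sum(w) / length(w)
  if (frac < 0.25) {
    stop("metal masking leaves only ", round(100 * frac), "% of the template ",
         "support; at least 25% is required", call. = FALSE)
  }
  template$weights <- w
  template$support_fraction <- frac
  template
}

# One registration of a template against an image: coarse rotation sweep on
# a strided support, fine sweep on the full support, parabolic sub-pixel and
# sub-step refinement.  pred = list(rot, shift).  Returns rot (cumulative
# degrees), shift (2-vector), peak, oob (logical).
# symmetric candidate grid about a predicted value (seq(-r, r) alone drops
# the end point when 2r is not a multiple of the step)
sym_grid <- function(center, range, step) {
  d <- seq(0, range, by = step)
  center + sort(unique(c(-d, d)))
}

stride_indices <- function(n, stride, floor_n = 200L) {
  while (stride > 1 && n %/% stride < floor_n) stride <- stride - 1L
  seq(1L, n, by = stride)
}

register_template <- function(img, tpl, pred, cfg,
                              coarse_range = cfg$coarse_range,
                              radius = cfg$shift_radius) {
  np <- length(tpl$x)
  stride_idx <- stride_indices(np, cfg$coarse_stride)
  fine_idx <- stride_indices(np, cfg$fine_stride)
  coarse_rots <- sym_grid(pred$rot, coarse_range, cfg$coarse_step)
  sw <- ncc_sweep_cpp(img, tpl$x[stride_idx], tpl$y[stride_idx],
                      tpl$values[stride_idx], tpl$weights[stride_idx],
                      tpl$pivot[1], tpl$pivot[2], coarse_rots,
                      pred$shift[1], pred$shift[2], radius)
  idx <- arrayInd(which.max(sw$ncc), dim(sw$ncc))
  best_rot <- coarse_rots[idx[3]]
  R <- rot_mat(best_rot)
  coarse_shift <- pred$shift +
    as.numeric(R %*% c(idx[1] - 1 - radius, idx[2] - 1 - radius))

  fine_rots <- sym_grid(best_rot, cfg$fine_range, cfg$fine_step)
  sw2 <- ncc_sweep_cpp(img, tpl$x[fine_idx], tpl$y[fine_idx],
                       tpl$values[fine_idx], tpl$weights[fine_idx],
                       tpl$pivot[1], tpl$pivot[2], fine_rots,
                       coarse_shift[1], coarse_shift[2], 1L)
  a <- sw2$ncc  # dims 3 x 3 x nrot
  idx2 <- arrayInd(which.max(a), dim(a))
  k <- idx2[1]; l <- idx2[2]; j <- idx2[3]
  peak <- a[k, l, j]
  dk <- dl <- dj <- 0
  if (cfg$subpixel == "parabolic") {
    para <- function(m, c0, p) {
      den <- m - 2 * c0 + p
      if (is.finite(den) && den < -1e-12) {
        max(-0.5, min(0.5, 0.5 * (m - p) / den))
      } else 0
    }
    if (k == 2) dk <- para(a[1, l, j], a[2, l, j], a[3, l, j])
    if (l == 2) dl <- para(a[k, 1, j], a[k, 2, j], a[k, 3, j])
    if (j > 1 && j < length(fine_rots)) {
      dj <- para(a[k, l, j - 1], a[k, l, j], a[k, l, j + 1])
    }
  }
  rot <- fine_rots[j] + dj * cfg$fine_step
  Rf <- rot_mat(rot)
  shift <- coarse_shift + as.numeric(Rf %*% c(k - 2 + dk, l - 2 + dl))
  list(rot = rot, shift = shift, peak = peak,
       oob = sw2$oob_frac[j] > 0 || peak < -1)
}

#' Track vertebral templates through an image sequence
#'
#' Registers every vertebral tracking template from frame to frame through
#' the sequence by masked normalized cross-correlation: each frame is
#' rolling-averaged with its predecessors, the template is resampled at
#' candidate cumulative rotations in a coarse-to-fine sweep about the
#' velocity-extrapolated pose, and the global correlation maximum over
#' rotation and shift is refined to sub-pixel/sub-step by parabolic peak
#' interpolation.  Frames whose peak falls below `peak_threshold` are
#' flagged `low_peak` and carry the previous pose forward; templates
#' touching the field edge are flagged `edge_of_field`.
#'
#' @param seq a [qf_sequence()].
#' @param landmarks landmark tibble (see [phantom_landmarks()] or
#'   [read_landmarks()]) defined on frame 0.
#' @param cfg a [tracker_config()].
#' @return A `qf_pose_series`: tibble with columns `vertebra`, `marking_id`,
#'   `frame`, `rot_deg`, `dx_px`, `dy_px`, `peak`, `flag`.  Poses are
#'   cumulative from frame 0 (frame 0 is the identity).  Attributes carry
#'   the frame rate, the landmark table and the per-template pivots.
#' @export
track_sequence <- function(seq, landmarks, cfg = tracker_config()) {
  stopifnot(inherits(seq, "qf_sequence"))
  nf <- n_frames(seq)
  base0 <- rolled_frame(seq, 1L, cfg$rolling_average_window)
  keys <- dplyr::distinct(landmarks, .data$vertebra, .data$marking_id)
  nk <- nrow(keys)
  tpls <- vector("list", nk)
  for (ki in seq_len(nk)) {
    lm <- landmarks[landmarks$vertebra == keys$vertebra[ki] &
                      landmarks$marking_id == keys$marking_id[ki], ]
    ply <- lm[lm$point_role == "polygon", ]
    poly <- as.matrix(ply[order(ply$point_index), c("x_px", "y_px")])
    tpls[[ki]] <- qf_template(base0, poly, metal = split_metal_polygons(lm))
  }
  pivots <- lapply(tpls, `[[`, "pivot")
  rot <- matrix(0, nf, nk); dx <- matrix(0, nf, nk); dy <- matrix(0, nf, nk)
  resid <- rep(Inf, nk)
  peak <- matrix(1, nf, nk)
  flag <- matrix("ok", nf, nk)
  for (t in 2:nf) {
    img <- rolled_frame(seq, t, cfg$rolling_average_window)
    for (ki in seq_len(nk)) {
      tpl <- tpls[[ki]]
      # velocity extrapolation of the previous pose; once a velocity prior
      # exists the coarse rotation sweep narrows to the predicted
      # neighbourhood (the per-frame increment is far below the full range)
      if (t > 2) {
        dr <- rot[t - 1, ki] - rot[t - 2, ki]
        pr <- rot[t - 1, ki] + max(-1, min(1, dr))
        ps <- c(dx[t - 1, ki], dy[t - 1, ki]) +
          pmax(-3, pmin(3, c(dx[t - 1, ki] - dx[t - 2, ki],
                             dy[t - 1, ki] - dy[t - 2, ki])))
        crange <- min(cfg$coarse_range, 0.5 + 2 * abs(dr))
        # shrink the shift search when recent predictions have been accurate
        rad <- if (resid[ki] < 0.4) 1L else cfg$shift_radius
      } else {
        pr <- rot[t - 1, ki]; ps <- c(dx[t - 1, ki], dy[t - 1, ki])
        crange <- cfg$coarse_range
        rad <- max(cfg$shift_radius, 4L)  # no velocity prior yet
      }
      reg <- register_template(img, tpl, list(rot = pr, shift = ps), cfg,
                               coarse_range = crange, radius = rad)
      resid[ki] <- sqrt(sum((reg$shift - ps)^2))
      if (reg$oob) {
        rot[t, ki] <- rot[t - 1, ki]; dx[t, ki] <- dx[t - 1, ki]
        dy[t, ki] <- dy[t - 1, ki]
        peak[t, ki] <- max(reg$peak, 0); flag[t, ki] <- "edge_of_field"
      } else if (reg$peak < cfg$peak_threshold) {
        rot[t, ki] <- rot[t - 1, ki]; dx[t, ki] <- dx[t - 1, ki]
        dy[t, ki] <- dy[t - 1, ki]
        peak[t, ki] <- reg$peak; flag[t, ki] <- "low_peak"
      } else {
        rot[t, ki] <- reg$rot; dx[t, ki] <- reg$shift[1]
        dy[t, ki] <- reg$shift[2]
        peak[t, ki] <- min(reg$peak, 1); flag[t, ki] <- "ok"
        if (cfg$template_update == "every_frame") {
          pts <- apply_pose(cbind(tpl$x, tpl$y), reg$rot, tpl$pivot, reg$shift)
          v <- bilinear_sample_cpp(img, pts[, 1], pts[, 2])
          ok <- !is.na(v)
          tpls[[ki]]$values[ok] <- v[ok]
        }
      }
    }
  }
  res <- dplyr::bind_rows(lapply(seq_len(nk), function(ki) {
    tibble::tibble(
      vertebra = keys$vertebra[ki], marking_id = keys$marking_id[ki],
      frame = seq_len(nf) - 1L, rot_deg = rot[, ki], dx_px = dx[, ki],
      dy_px = dy[, ki], peak = peak[, ki], flag = flag[, ki])
  }))
  if (all(res$flag[res$frame > 0] != "ok")) {
    stop("tracking failure: every frame of every template was flagged",
         call. = FALSE)
  }
  names(pivots) <- paste(keys$vertebra, keys$marking_id, sep = "/")
  structure(res, class = c("qf_pose_series", class(res)),
            frame_rate = seq$frame_rate, landmarks = landmarks,
            pivots = pivots, pixel_spacing = seq$pixel_spacing)
}

#' Construct a pose series from per-frame rigid poses
#'
#' Builds the `qf_pose_series` container from a table of cumulative rigid
#' poses (for example, poses obtained from an external tracker).  Each pose
#' maps frame-0 points p to `R(rot_deg) (p - pivot) + pivot + (dx, dy)`.
#'
#' @param df tibble with columns `vertebra`, `marking_id`, `frame`,
#'   `rot_deg`, `dx_px`, `dy_px` (and optionally `peak`, `flag`).
#' @param frame_rate frames per second.
#' @param landmarks optional landmark tibble (needed for corner
#'   propagation).
#' @param pivots named list of rotation pivots (`"vertebra/marking"`); by
#'   default the centroid of each marking's corner landmarks.
#' @param pixel_spacing mm per pixel.
#' @return A `qf_pose_series`.
#' @export
qf_pose_series <- function(df, frame_rate = NA_real_, landmarks = NULL,
                           pivots = NULL, pixel_spacing = NA_real_) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("vertebra", "marking_id", "frame", "rot_deg",
                  "dx_px", "dy_px") %in% names(df)))
  if (!"peak" %in% names(df)) df$peak <- 1
  if (!"flag" %in% names(df)) df$flag <- "ok"
  if (is.null(pivots) && !is.null(landmarks)) {
    keys <- dplyr::distinct(df, .data$vertebra, .data$marking_id)
    pivots <- lapply(seq_len(nrow(keys)), function(ki) {
      lm <- landmarks[landmarks$vertebra == keys$vertebra[ki] &
                        landmarks$marking_id == keys$marking_id[ki] &
                        grepl("^corner_", landmarks$point_role), ]
      c(mean(lm$x_px), mean(lm$y_px))
    })
    names(pivots) <- paste(keys$vertebra, keys$marking_id, sep = "/")
  }
  structure(df, class = c("qf_pose_series", class(df)),
            frame_rate = frame_rate, landmarks = landmarks,
            pivots = pivots, pixel_spacing = pixel_spacing)
}

split_metal_polygons <- function(lm) {
  mm <- lm[lm$point_role == "metal", ]
  if (nrow(mm) == 0) return(list())
  lapply(split(mm, mm$region_id), function(g) {
    as.matrix(g[order(g$point_index), c("x_px", "y_px")])
  })
}

# Zero-phase Butterworth low-pass of one channel with odd-reflection padding.
butter_smooth <- function(x, fs, cutoff, order) {
  n <- length(x)
  if (n <= 3 * order) {
    stop("series too short for the requested filter order", call. = FALSE)
  }
  bf <- signal::butter(order, min(0.99, cutoff / (fs / 2)), type = "low")
  p <- min(n - 1, max(6 * order, ceiling(3 * fs / cutoff)))
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  # remove the mean so the filter's zero initial state causes no transient
  m <- mean(xp)
  y <- signal::filtfilt(bf, xp - m) + m
  y[(p + 1):(p + n)]
}

#' Zero-phase Butterworth smoothing of tracked key points
#'
#' Applies a forward-backward (zero-phase) low-pass Butterworth filter to
#' every coordinate and angle channel of a pose series, or to a plain
#' numeric vector.  End points are handled by odd reflection padding.
#'
#' @param x a `qf_pose_series` or numeric vector.
#' @param cfg a [tracker_config()] supplying the filter order and cutoff.
#' @param frame_rate frames per second; taken from the series attribute when
#'   available.  Required (the cutoff is in Hz).
#' @return The smoothed object, same type as `x`.
#' @export
smooth_keypoints <- function(x, cfg = tracker_config(), frame_rate = NULL) {
  fs <- frame_rate %||% attr(x, "frame_rate")
  if (is.null(fs) || is.na(fs)) {
    stop("frame rate unknown: a time-based cutoff cannot be applied",
         call. = FALSE)
  }
  if (is.numeric(x) && is.null(dim(x))) {
    return(butter_smooth(x, fs, cfg$butterworth_cutoff, cfg$butterworth_order))
  }
  stopifnot(inherits(x, "qf_pose_series"))
  at <- attributes(x)
  sm <- x |>
    dplyr::group_by(.data$vertebra, .data$marking_id) |>
    dplyr::mutate(
      rot_deg = butter_smooth(.data$rot_deg, fs, cfg$butterworth_cutoff,
                              cfg$butterworth_order),
      dx_px = butter_smooth(.data$dx_px, fs, cfg$butterworth_cutoff,
                            cfg$butterworth_order),
      dy_px = butter_smooth(.data$dy_px, fs, cfg$butterworth_cutoff,
                            cfg$butterworth_order)) |>
    dplyr::ungroup()
  attributes(sm) <- modifyList(attributes(sm),
                               at[c("class", "frame_rate", "landmarks",
                                    "pivots", "pixel_spacing")])
  sm
}

#' Report on tracking quality
#'
#' Summarises, per vertebra, the fraction of flagged frames, the spread of
#' the rotation estimate across the independent markings and the number of
#' direction reversals of the median rotation curve, and issues a
#' pass/warn/fail verdict.
#'
#' @param poses a `qf_pose_series`.
#' @param flag_warn,flag_fail flagged-frame fractions above which the
#'   verdict degrades.
#' @param spread_warn per-frame across-marking rotation SD (degrees) above
#'   which the verdict degrades to warn.
#' @param deadband rotation deadband (degrees) for counting reversals.
#' @return A tibble with one row per vertebra (`frac_flagged`,
#'   `spread_max_deg`, `spread_median_deg`, `n_reversals`, `verdict`) with
#'   attribute `overall` (pass/warn/fail).
#' @export
verify_tracking <- function(poses, flag_warn = 0.05, flag_fail = 0.25,
                            spread_warn = 0.5, deadband = 0.05) {
  if (is.null(poses) || nrow(poses) == 0) {
    out <- tibble::tibble(vertebra = character(), frac_flagged = numeric(),
                          spread_max_deg = numeric(),
                          spread_median_deg = numeric(),
                          n_reversals = integer(), verdict = character())
    attr(out, "overall") <- "fail"
    return(out)
  }
  rep <- poses |>
    dplyr::group_by(.data$vertebra) |>
    dplyr::group_modify(function(g, key) {
      spread <- g |>
        dplyr::group_by(.data$frame) |>
        dplyr::summarise(s = if (dplyr::n() > 1) sd(.data$rot_deg) else 0,
                         .groups = "drop")
      med <- g |>
        dplyr::group_by(.data$frame) |>
        dplyr::summarise(m = median(.data$rot_deg), .groups = "drop")
      dm <- diff(med$m)
      sgn <- sign(dm[abs(dm) > deadband])
      nrev <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0L
      tibble::tibble(
        frac_flagged = mean(g$flag[g$frame > 0] != "ok"),
        spread_max_deg = max(spread$s),
        spread_median_deg = median(spread$s),
        n_reversals = as.integer(nrev))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(verdict = dplyr::case_when(
      .data$frac_flagged > flag_fail ~ "fail",
      .data$frac_flagged > flag_warn | .data$spread_max_deg > spread_warn ~ "warn",
      TRUE ~ "pass"))
  attr(rep, "overall") <-
    if (any(rep$verdict == "fail")) "fail"
    else if (any(rep$verdict == "warn")) "warn" else "pass"
  rep
}
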