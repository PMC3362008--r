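# Anatomical ordering of vertebra names (L1..L5 then S1).
order_vertebrae <- function(v) {
  v <- unique(v)
  key <- function(x) {
    num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", x)))
    base <- ifelse(grepl("^L", x), 0L, ifelse(grepl("^S", x), 100L, 200L))
    base + ifelse(is.na(num), 0L, num)
  }
  v[order(key(v))]
}

#' Intervertebral rotation curves from a tracked pose series
#'
#' Differences the cumulative rotation of every marking of each vertebra
#' from every marking of the adjacent vertebra, giving (with five markings
#' per vertebra) twenty-five intervertebral angle curves per adjacent pair,
#' plus their per-frame mean and median.  The median is the default central
#' estimate, being robust to a single poor marking.
#'
#' @param poses a `qf_pose_series` from [track_sequence()] (usually after
#'   [smooth_keypoints()]).
#' @param trunk optional trunk (global) angle series, one value per frame.
#' @return A `qf_kinematics` object: list with `curves` (level,
#'   marking_upper, marking_lower, frame, iv_rot_deg), `rotation` (level,
#'   frame, mean, median, min, max), `levels`, `trunk`, `frame_rate`.
#' @export
intervertebral_series <- function(poses, trunk = NULL) {
  stopifnot(inherits(poses, "qf_pose_series"))
  verts <- order_vertebrae(poses$vertebra)
  if (length(verts) < 2) stop("need at least two vertebrae", call. = FALSE)
  nf <- max(poses$frame) + 1L
  curves <- vector("list", length(verts) - 1)
  for (j in seq_len(length(verts) - 1)) {
    up <- poses[poses$vertebra == verts[j], ]
    lo <- poses[poses$vertebra == verts[j + 1], ]
    mu <- sort(unique(up$marking_id)); ml <- sort(unique(lo$marking_id))
    combos <- expand.grid(m_up = mu, m_lo = ml)
    cc <- lapply(seq_len(nrow(combos)), function(ci) {
      ru <- up$rot_deg[up$marking_id == combos$m_up[ci]][order(up$frame[up$marking_id == combos$m_up[ci]])]
      rl <- lo$rot_deg[lo$marking_id == combos$m_lo[ci]][order(lo$frame[lo$marking_id == combos$m_lo[ci]])]
      tibble::tibble(
        level = paste0(verts[j], "-", verts[j + 1]),
        marking_upper = combos$m_up[ci], marking_lower = combos$m_lo[ci],
        frame = seq_len(nf) - 1L, iv_rot_deg = ru - rl)
    })
    curves[[j]] <- dplyr::bind_rows(cc)
  }
  curves <- dplyr::bind_rows(curves)
  rotation <- curves |>
    dplyr::group_by(.data$level, .data$frame) |>
    dplyr::summarise(mean = mean(.data$iv_rot_deg),
                     median = median(.data$iv_rot_deg),
                     min = min(.data$iv_rot_deg),
                     max = max(.data$iv_rot_deg), .groups = "drop")
  structure(
    list(curves = curves, rotation = rotation,
         levels = paste0(verts[-length(verts)], "-", verts[-1]),
         vertebrae = verts, trunk = trunk,
         frame_rate = attr(poses, "frame_rate"),
         pixel_spacing = attr(poses, "pixel_spacing"),
         poses = poses),
    class = "qf_kinematics")
}

#' @export
print.qf_kinematics <- function(x, ...) {
  cat(sprintf("<qf_kinematics> %d levels (%s), %d frames\n",
              length(x$levels), paste(x$levels, collapse = ", "),
              max(x$rotation$frame) + 1L))
  if (!is.null(x$indices)) {
    cat("  indices computed; see tidy()\n")
  }
  invisible(x)
}

# Propagate the reference-template corners of every vertebra/marking through
# the pose series.  Returns a nested list corners[[vertebra]][[marking]] of
# 4 x 2 x nframe arrays, plus the across-marking mean array per vertebra.
propagate_corners <- function(poses) {
  lmk <- attr(poses, "landmarks")
  pivots <- attr(poses, "pivots")
  if (is.null(lmk)) stop("pose series carries no landmark table", call. = FALSE)
  nf <- max(poses$frame) + 1L
  roles <- c("corner_as", "corner_ps", "corner_pi", "corner_ai")
  out <- list(); mean_out <- list()
  for (v in unique(poses$vertebra)) {
    ms <- sort(unique(poses$marking_id[poses$vertebra == v]))
    per <- list()
    for (m in ms) {
      lm <- lmk[lmk$vertebra == v & lmk$marking_id == m, ]
      c0 <- as.matrix(lm[match(roles, lm$point_role), c("x_px", "y_px")])
      pv <- pivots[[paste(v, m, sep = "/")]]
      g <- poses[poses$vertebra == v & poses$marking_id == m, ]
      g <- g[order(g$frame), ]
      th <- deg2rad(g$rot_deg)
      arr <- array(NA_real_, c(4, 2, nf))
      for (ci in 1:4) {
        rx <- c0[ci, 1] - pv[1]; ry <- c0[ci, 2] - pv[2]
        arr[ci, 1, ] <- cos(th) * rx + sin(th) * ry + pv[1] + g$dx_px
        arr[ci, 2, ] <- -sin(th) * rx + cos(th) * ry + pv[2] + g$dy_px
      }
      per[[as.character(m)]] <- arr
    }
    out[[v]] <- per
    mean_out[[v]] <- Reduce(`+`, per) / length(per)
  }
  list(per_marking = out, mean = mean_out)
}

#' Continuous intervertebral translation and disc height
#'
#' Propagates the four-corner reference templates through the tracked poses
#' and computes, per frame and per adjacent pair, the corner-based
#' intervertebral pose: bisectrix-referenced translation (as change from the
#' neutral frame, percent of mean body depth) and disc height.  All marking
#' combinations are evaluated; the median and the across-marking envelope
#' are returned.
#'
#' @param kin a `qf_kinematics` from [intervertebral_series()], or a
#'   `qf_pose_series`.
#' @return The `qf_kinematics` object with a `translation` element: tibble
#'   with per-level, per-frame `trans_median_pct`, `trans_mean_pct`,
#'   `trans_min_pct`, `trans_max_pct`, `disc_median_pct`, and `trans_median_mm`
#'   when the pixel spacing is known.
#' @export
continuous_translation <- function(kin) {
  if (inherits(kin, "qf_pose_series")) kin <- intervertebral_series(kin)
  poses <- kin$poses
  pc <- propagate_corners(poses)
  verts <- kin$vertebrae
  rows <- list()
  for (j in seq_along(kin$levels)) {
    up <- pc$per_marking[[verts[j]]]
    lo <- pc$per_marking[[verts[j + 1]]]
    for (mu in names(up)) {
      fu <- frobin_series(up[[mu]])
      for (ml in names(lo)) {
        fl <- frobin_series(lo[[ml]])
        s <- iv_pose_series(fu, fl)
        rows[[length(rows) + 1]] <- tibble::tibble(
          level = kin$levels[j], marking_upper = as.integer(mu),
          marking_lower = as.integer(ml), frame = s$frame,
          trans_pct = s$iv_trans_raw_pct - s$iv_trans_raw_pct[1],
          disc_pct = s$disc_height_pct,
          depth_px = s$mean_depth_px)
      }
    }
  }
  all <- dplyr::bind_rows(rows)
  trans <- all |>
    dplyr::group_by(.data$level, .data$frame) |>
    dplyr::summarise(
      trans_median_pct = median(.data$trans_pct),
      trans_mean_pct = mean(.data$trans_pct),
      trans_min_pct = min(.data$trans_pct),
      trans_max_pct = max(.data$trans_pct),
      disc_median_pct = median(.data$disc_pct),
      depth_px = mean(.data$depth_px), .groups = "drop")
  sp <- kin$pixel_spacing
  if (!is.null(sp) && !is.na(sp)) {
    trans$trans_median_mm <- trans$trans_median_pct / 100 * trans$depth_px * sp
  }
  kin$translation <- trans
  kin$translation_curves <- all
  kin$corners <- pc
  kin
}

#' Neutral zone laxity from intervertebral and trunk motion
#'
#' Fits least-squares lines to the intervertebral and global (trunk) angle
#' series over the outward frames within the first 10 degrees of trunk
#' motion from neutral, and reports the ratio of their slopes.  A higher
#' ratio means less passive restraint near the neutral position.
#'
#' @param iv intervertebral angle series (numeric, one per frame) or a
#'   `qf_kinematics` (then every level's median curve is used).
#' @param trunk trunk angle series (required when `iv` is numeric; taken
#'   from the kinematics object otherwise).
#' @param window_deg trunk window from neutral, degrees (default 10).
#' @return A tibble with `slope_iv`, `slope_global` (degrees/frame),
#'   `ratio`, `window_start`, `window_end` (frame indices), `fit_r2`; one
#'   row per level for a kinematics input (class `qf_laxity`).
#' @export
neutral_zone_laxity <- function(iv, trunk = NULL, window_deg = 10) {
  if (inherits(iv, "qf_kinematics")) {
    kin <- iv
    trunk <- trunk %||% kin$trunk
    if (is.null(trunk)) stop("no trunk angle series available", call. = FALSE)
    out <- dplyr::bind_rows(lapply(kin$levels, function(lv) {
      med <- kin$rotation$median[kin$rotation$level == lv]
      cbind(tibble::tibble(level = lv),
            neutral_zone_laxity(med, trunk, window_deg))
    }))
    class(out) <- c("qf_laxity", class(out))
    return(out)
  }
  stopifnot(is.numeric(iv), is.numeric(trunk), length(iv) == length(trunk))
  if (abs(trunk[1]) > 1) {
    stop("trunk series does not start at neutral", call. = FALSE)
  }
  beyond <- which(abs(trunk) > window_deg)
  end <- if (length(beyond)) beyond[1] - 1L else
    stop("trunk motion never leaves the first ", window_deg,
         " degrees; laxity window undefined", call. = FALSE)
  if (end < 5) {
    stop("fewer than 5 frames inside the neutral-zone window; ",
         "acquisition too fast for laxity estimation", call. = FALSE)
  }
  idx <- seq_len(end)
  fg <- lm(trunk[idx] ~ idx)
  fi <- lm(iv[idx] ~ idx)
  slope_global <- coef(fg)[2]
  if (abs(slope_global) < 1e-9) {
    stop("global motion slope is zero; laxity undefined", call. = FALSE)
  }
  ss_tot <- sum((iv[idx] - mean(iv[idx]))^2)
  r2 <- if (ss_tot < 1e-12) 1 else 1 - sum(residuals(fi)^2) / ss_tot
  tibble::tibble(
    slope_iv = unname(coef(fi)[2]), slope_global = unname(slope_global),
    ratio = unname(coef(fi)[2] / slope_global),
    window_start = 0L, window_end = end - 1L, fit_r2 = r2)
}

#' Instantaneous axis of rotation by geometric construction
#'
#' Expresses the upper vertebra's motion in the lower vertebra's reference
#' frame between two positions, then locates the IAR as the intersection of
#' the perpendicular bisectors of the displacement segments of the anterior
#' and posterior body midpoints (the classical graphical construction for a
#' finite rotation of a rigid body).
#'
#' @param upper_t0,upper_t1 4x2 corner matrices (canonical order) of the
#'   upper vertebra at the two positions.
#' @param lower_t0,lower_t1 corner matrices of the lower vertebra.
#' @param min_angle smallest relative rotation (degrees) for which the IAR
#'   is considered stable (default 5).
#' @param pixel_spacing mm per pixel, for the millimetre offsets (optional).
#' @return An object of class `qf_iar`: list with `location` (x, y in the
#'   t0 image frame), `valid`, `rotation_deg`, `ref_offset_px` and
#'   `ref_offset_mm` (offsets from the posterior-inferior corner of the
#'   lower vertebra at t0).
#' @export
iar <- function(upper_t0, upper_t1, lower_t0, lower_t1,
                min_angle = 5, pixel_spacing = NA_real_) {
  fu0 <- frobin_frame(upper_t0); fu1 <- frobin_frame(upper_t1)
  fl0 <- frobin_frame(lower_t0); fl1 <- frobin_frame(lower_t1)
  # undo the lower vertebra's motion so the construction is relative
  lam <- signed_angle(fl0$axis, fl1$axis)
  Rl <- rot_mat(lam)
  tl <- fl1$center - as.numeric(Rl %*% fl0$center)
  # inverse of p -> Rl p + tl is p -> Rl^T (p - tl); row-vector form below
  u1 <- sweep(as.matrix(upper_t1), 2, tl) %*% Rl
  fu1r <- frobin_frame(u1)
  theta <- signed_angle(fu0$axis, fu1r$axis)
  res <- list(location = c(NA_real_, NA_real_), valid = FALSE,
              rotation_deg = theta,
              ref_offset_px = c(NA_real_, NA_real_),
              ref_offset_mm = c(NA_real_, NA_real_))
  class(res) <- "qf_iar"
  if (abs(theta) < min_angle) return(res)
  a0 <- fu0$anterior_mid; a1 <- fu1r$anterior_mid
  p0 <- fu0$posterior_mid; p1 <- fu1r$posterior_mid
  bis <- function(q0, q1) {
    d <- q1 - q0
    list(p = (q0 + q1) / 2, d = unitize(c(-d[2], d[1])))
  }
  if (vnorm(a1 - a0) < 1e-9 || vnorm(p1 - p0) < 1e-9) return(res)
  ba <- bis(a0, a1); bp <- bis(p0, p1)
  A <- cbind(ba$d, -bp$d)
  if (abs(det(A)) < 1e-9) {
    stop("degenerate IAR: displacement bisectors are parallel", call. = FALSE)
  }
  tt <- solve(A, bp$p - ba$p)
  loc <- ba$p + tt[1] * ba$d
  ref <- as.matrix(lower_t0)[3, ]  # posterior-inferior corner of lower body
  res$location <- loc
  res$valid <- TRUE
  res$ref_offset_px <- loc - ref
  if (!is.na(pixel_spacing)) res$ref_offset_mm <- (loc - ref) * pixel_spacing
  res
}

#' @export
print.qf_iar <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<qf_iar> (%.2f, %.2f) px; rotation %.2f deg; offset from PI corner (%.2f, %.2f) px\n",
                x$location[1], x$location[2], x$rotation_deg,
                x$ref_offset_px[1], x$ref_offset_px[2]))
  } else {
    cat(sprintf("<qf_iar> invalid (rotation %.2f deg below minimum)\n",
                x$rotation_deg))
  }
  invisible(x)
}

#' Summary motion indices for every intervertebral level
#'
#' Derives the per-level summary indices from the continuous curves:
#' maximum rotation and translation ranges (wherever attained during trunk
#' motion), neutral-zone laxity ratio, directional coherence, motion
#' commencement order, phase lag, motion sharing, disc height and the IAR
#' between the neutral and end-of-range positions.
#'
#' Coherence, commencement and phase lag are operational definitions of
#' this package (the consensus names the indices without formulas):
#' coherence is the fraction of frame steps in which the level moves in the
#' same direction as the trunk (steps within the `deadband` excluded);
#' commencement is the trunk angle at which the level first exceeds
#' `commence_frac` of its own range, levels ranked ascending; phase lag is
#' the trunk angle at the level's maximum minus the trunk angle at the
#' global maximum.
#'
#' @param kin a `qf_kinematics` with translation computed (see
#'   [continuous_translation()]); trunk series required.
#' @param deadband step deadband in degrees for coherence.
#' @param commence_frac fraction of a level's range defining commencement.
#' @param iar_min_angle minimum rotation for a valid IAR (degrees).
#' @return The `qf_kinematics` with an `indices` tibble (one row per level)
#'   and a `laxity` tibble attached.
#' @export
motion_indices <- function(kin, deadband = 0.05, commence_frac = 0.10,
                           iar_min_angle = 5) {
  stopifnot(inherits(kin, "qf_kinematics"))
  if (is.null(kin$trunk)) stop("trunk angle series required", call. = FALSE)
  if (is.null(kin$translation)) kin <- continuous_translation(kin)
  trunk <- kin$trunk
  gmax_i <- which.max(abs(trunk))
  lax <- neutral_zone_laxity(kin)
  rows <- lapply(seq_along(kin$levels), function(j) {
    lv <- kin$levels[j]
    r <- kin$rotation$median[kin$rotation$level == lv]
    tr <- kin$translation[kin$translation$level == lv, ]
    rng <- max(r) - min(r)
    lmax_i <- which.max(abs(r - r[1]))
    dr <- diff(r); dt <- diff(trunk)
    act <- abs(dr) > deadband & abs(dt) > deadband
    coher <- if (any(act)) mean(sign(dr[act]) == sign(dt[act])) else NA_real_
    exceed <- which(abs(r - r[1]) > commence_frac * rng)
    comm_trunk <- if (length(exceed)) abs(trunk[exceed[1]]) else NA_real_
    ia <- level_iar(kin, j, gmax_i, iar_min_angle)
    tibble::tibble(
      level = lv,
      max_rotation_range_deg = rng,
      max_translation_range_pct = max(tr$trans_median_pct) - min(tr$trans_median_pct),
      max_translation_range_mm = if ("trans_median_mm" %in% names(tr))
        max(tr$trans_median_mm) - min(tr$trans_median_mm) else NA_real_,
      laxity_ratio = lax$ratio[lax$level == lv],
      coherence = coher,
      commencement_trunk_deg = comm_trunk,
      phase_lag_deg = trunk[lmax_i] - trunk[gmax_i],
      disc_height_mean_pct = mean(tr$disc_median_pct),
      iar_x_px = ia$location[1], iar_y_px = ia$location[2],
      iar_valid = ia$valid)
  })
  idx <- dplyr::bind_rows(rows)
  idx$motion_share <- idx$max_rotation_range_deg / sum(idx$max_rotation_range_deg)
  idx$commencement_rank <- as.integer(rank(idx$commencement_trunk_deg,
                                           ties.method = "first"))
  kin$indices <- idx
  kin$laxity <- lax
  kin
}

# IAR for level j between frame 0 and the end-of-range frame, using the
# across-marking mean reference corners.
level_iar <- function(kin, j, t1_index, min_angle) {
  if (is.null(kin$corners)) {
    return(list(location = c(NA_real_, NA_real_), valid = FALSE))
  }
  vu <- kin$vertebrae[j]; vl <- kin$vertebrae[j + 1]
  cu <- kin$corners$mean[[vu]]; cl <- kin$corners$mean[[vl]]
  iar(cu[, , 1], cu[, , t1_index], cl[, , 1], cl[, , t1_index],
      min_angle = min_angle,
      pixel_spacing = kin$pixel_spacing %||% NA_real_)
}

#' Full kinematic analysis of a tracked sequence
#'
#' Convenience pipeline: smooths the pose series, builds the intervertebral
#' rotation curves, the translation and disc-height curves, the laxity
#' table and the summary indices.
#'
#' @param poses a `qf_pose_series` from [track_sequence()].
#' @param trunk trunk angle series, one value per frame.
#' @param cfg a [tracker_config()] (for the smoothing filter).
#' @param smooth apply [smooth_keypoints()] first (default `TRUE`).
#' @return A `qf_kinematics` with `rotation`, `curves`, `translation`,
#'   `laxity` and `indices` populated.
#' @export
analyze_kinematics <- function(poses, trunk, cfg = tracker_config(),
                               smooth = TRUE) {
  if (smooth) {
    poses <- smooth_keypoints(poses, cfg)
    # filter the trunk channel identically so slope ratios (laxity) compare
    # like with like
    fs <- attr(poses, "frame_rate")
    if (!is.null(fs) && !is.na(fs)) {
      trunk <- butter_smooth(trunk, fs, cfg$butterworth_cutoff,
                             cfg$butterworth_order)
    }
  }
  kin <- intervertebral_series(poses, trunk = trunk)
  kin <- continuous_translation(kin)
  motion_indices(kin)
}
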