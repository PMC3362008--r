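#' Build a protocol-conformant trunk motion program
#'
#' Generates the trunk (global) angle series for one motion direction under
#' the consensus acquisition protocol: the trunk starts at neutral, sweeps at
#' constant angular velocity to the outward range, reverses, and returns to
#' neutral, with raised-cosine velocity ramps at the start, at motion
#' reversal and at the end.  Ramp intervals are additional to the cruise
#' (sweep) time, so the total duration is `2 * sweep_duration +
#' 3 * ramp_interval`.
#'
#' @param direction one of `"flexion"`, `"extension"`, `"left_bend"`,
#'   `"right_bend"`.  Flexion and right bend are positive angles; extension
#'   and left bend negative.
#' @param outward_range unsigned outward range in degrees (0-60).
#' @param sweep_duration cruise time per direction in seconds; the consensus
#'   protocol requires 8-12 s.
#' @param ramp_interval ramp-up / reversal / ramp-down interval in seconds;
#'   the protocol requires 0.5-1 s.
#' @param frame_rate acquisition rate in frames per second (>= 12.5).
#' @return An object of class `qf_motion_program`: list with the inputs plus
#'   `time_s`, `trunk_angle_series` (degrees, one per frame, signed) and
#'   `plateau_velocity` (degrees/s, unsigned).
#' @examples
#' prog <- make_motion_program("flexion", 40, 10, 0.5, 15)
#' length(prog$trunk_angle_series)  # 300 cruise frames plus ramp frames
#' max(prog$trunk_angle_series)     # 40 degrees
#' @export
make_motion_program <- function(direction = c("flexion", "extension",
                                              "left_bend", "right_bend"),
                                outward_range = 40, sweep_duration = 10,
                                ramp_interval = 0.5, frame_rate = 15) {
  direction <- match.arg(direction)
  if (sweep_duration < 8 || sweep_duration > 12) {
    stop("protocol violation: sweep_duration ", sweep_duration,
         " s is outside the consensus 8-12 s motion-direction window",
         call. = FALSE)
  }
  if (ramp_interval < 0.5 || ramp_interval > 1) {
    stop("protocol violation: ramp_interval ", ramp_interval,
         " s is outside the consensus 0.5-1 s ramp/reversal window",
         call. = FALSE)
  }
  if (frame_rate < 12.5) {
    stop("protocol violation: frame_rate ", frame_rate,
         " fps is below the consensus 12.5 fps minimum", call. = FALSE)
  }
  if (outward_range < 0 || outward_range > 60) {
    stop("protocol violation: outward_range must be within 0-60 degrees",
         call. = FALSE)
  }
  S <- sweep_duration; r <- ramp_interval
  total <- 2 * S + 3 * r
  # plateau velocity: the ramp-up contributes v*r/2 and the half-reversal
  # v*r/pi to the peak angle, so peak = v * (S + r/2 + r/pi)
  v <- outward_range / (S + r / 2 + r / pi)
  tt <- seq(0, total, by = 1 / frame_rate)
  a <- numeric(length(tt))
  t1 <- r; t2 <- r + S; t3 <- 2 * r + S; t4 <- 2 * r + 2 * S
  for (i in seq_along(tt)) {
    t <- tt[i]
    a[i] <- if (t <= t1) {
      v / 2 * (t - (r / pi) * sin(pi * t / r))
    } else if (t <= t2) {
      v * r / 2 + v * (t - t1)
    } else if (t <= t3) {
      v * r / 2 + v * S + v * (r / pi) * sin(pi * (t - t2) / r)
    } else if (t <= t4) {
      v * r / 2 + v * S - v * (t - t3)
    } else {
      v * r / 2 - v / 2 * ((t - t4) + (r / pi) * sin(pi * (t - t4) / r))
    }
  }
  a[length(a)] <- 0  # exact neutral finish (guards rounding in the last step)
  sgn <- if (direction %in% c("flexion", "right_bend")) 1 else -1
  structure(
    list(direction = direction, outward_range = outward_range,
         sweep_duration = sweep_duration, ramp_interval = ramp_interval,
         frame_rate = frame_rate, time_s = tt,
         trunk_angle_series = sgn * a, plateau_velocity = v),
    class = "qf_motion_program"
  )
}

#' @export
print.qf_motion_program <- function(x, ...) {
  cat(sprintf(
    "<qf_motion_program> %s, %.1f deg outward, %.1f s sweep + %.2f s ramps, %.1f fps (%d frames)\n",
    x$direction, x$outward_range, x$sweep_duration, x$ramp_interval,
    x$frame_rate, length(x$trunk_angle_series)))
  invisible(x)
}

#' Specify a synthetic spine phantom
#'
#' Parameters of the rigid vertebra-shaped objects, their programmed motion
#' distribution, and the image degradation model used by [render_sequence()]
#' and [apply_degradations()].  The sacrum (last vertebra) is rendered
#' static; each intervertebral level rotates by its `motion_sharing`
#' fraction of the trunk angle about a centre in the posterior half of the
#' disc space, with a coupled translation along the endplate.
#'
#' @param n_vertebrae number of vertebrae (default 6: L1-S1).
#' @param body_depth_px,body_height_px vertebral body size in pixels.
#' @param disc_gap_px disc space height in pixels.
#' @param motion_sharing fractions of trunk motion taken by each
#'   intervertebral level, cranial to caudal (`n_vertebrae - 1` values
#'   summing to 1).
#' @param translation_mm_per_deg coupled translation per degree of
#'   intervertebral rotation at each level (mm/degree; recycled).
#' @param image_size image width and height in pixels (>= 512 each, per the
#'   consensus minimum).
#' @param bit_depth stored bits per pixel (>= 8).
#' @param pixel_spacing millimetres per pixel.
#' @param noise_model list with `gaussian_sd` (grey levels), `poisson_scale`
#'   (variance per grey level), `flare_amplitude` (fractional radial gain)
#'   and `tissue_amplitude` (grey levels of the low-frequency soft-tissue
#'   field).
#' @param out_of_plane_deg out-of-plane tilt applied by
#'   [apply_degradations()] (degrees).
#' @param blur motion-blur kernel scale (kernel length = `blur` times the
#'   inter-frame displacement).
#' @param corner_rounding corner rounding radius as a fraction of the
#'   shortest body side.
#' @param rim_width cortical rim width in pixels.
#' @return An object of class `qf_phantom_spec`.
#' @export
phantom_spec <- function(n_vertebrae = 6, body_depth_px = 70,
                         body_height_px = 44, disc_gap_px = 12,
                         motion_sharing = c(0.25, 0.25, 0.2, 0.15, 0.15),
                         translation_mm_per_deg = 0.15,
                         image_size = c(512, 512), bit_depth = 8,
                         pixel_spacing = 0.5,
                         noise_model = list(), out_of_plane_deg = 0,
                         blur = 1, corner_rounding = 0.1, rim_width = 2) {
  if (any(image_size < 512)) {
    stop("image_size must be at least 512 x 512 (consensus minimum)",
         call. = FALSE)
  }
  if (bit_depth < 8) {
    stop("bit_depth must be at least 8 (consensus minimum)", call. = FALSE)
  }
  if (length(motion_sharing) != n_vertebrae - 1) {
    stop("motion_sharing must have one fraction per intervertebral level (",
         n_vertebrae - 1, ")", call. = FALSE)
  }
  if (any(motion_sharing < 0) || abs(sum(motion_sharing) - 1) > 1e-9) {
    stop("motion_sharing fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  noise <- modifyList(
    list(gaussian_sd = 2, poisson_scale = 0.05, flare_amplitude = 0.10,
         tissue_amplitude = 10),
    noise_model)
  structure(
    list(n_vertebrae = as.integer(n_vertebrae), body_depth_px = body_depth_px,
         body_height_px = body_height_px, disc_gap_px = disc_gap_px,
         motion_sharing = motion_sharing,
         translation_mm_per_deg = rep_len(translation_mm_per_deg,
                                          n_vertebrae - 1),
         image_size = as.integer(image_size), bit_depth = as.integer(bit_depth),
         pixel_spacing = pixel_spacing, noise_model = noise,
         out_of_plane_deg = out_of_plane_deg, blur = blur,
         corner_rounding = corner_rounding, rim_width = rim_width),
    class = "qf_phantom_spec"
  )
}

vertebra_names <- function(n) {
  if (n <= 6) c(paste0("L", seq_len(n - 1) + (6 - n)), "S1")
  else c(paste0("V", seq_len(n - 1)), "S1")
}

# Neutral-configuration geometry: corner matrices (canonical role order,
# anterior = +x), body centres and per-level disc rotation centres.
phantom_neutral_geometry <- function(spec) {
  n <- spec$n_vertebrae
  W <- spec$image_size[1]; H <- spec$image_size[2]
  bh <- spec$body_height_px; gap <- spec$disc_gap_px; d <- spec$body_depth_px
  col_h <- n * bh + (n - 1) * gap
  cy <- (H - col_h) / 2 + bh / 2 + (seq_len(n) - 1) * (bh + gap)
  cx <- W / 2
  wedge <- 0.04 * bh  # mild trapezoid: posterior edge slightly shorter
  corners <- lapply(seq_len(n), function(i) {
    rbind(
      c(cx + d / 2, cy[i] - bh / 2),          # anterior-superior
      c(cx - d / 2, cy[i] - bh / 2 + wedge),  # posterior-superior
      c(cx - d / 2, cy[i] + bh / 2 - wedge),  # posterior-inferior
      c(cx + d / 2, cy[i] + bh / 2)           # anterior-inferior
    )
  })
  # level j couples vertebra j (upper) to j+1 (lower); rotation centre in the
  # posterior half of the disc space
  iar <- lapply(seq_len(n - 1), function(j) {
    c(cx - 0.15 * d, (cy[j] + bh / 2 + cy[j + 1] - bh / 2) / 2)
  })
  list(corners = corners, centers = cbind(cx, cy), iar = iar)
}

compose_rigid <- function(A, B) {
  list(R = A$R %*% B$R, t = as.numeric(A$R %*% B$t) + A$t)
}

apply_rigid <- function(Tf, pts) {
  sweep(pts %*% t(Tf$R), 2, Tf$t, `+`)
}

# Global rigid transforms of every vertebra at one trunk angle.  Levels are
# numbered cranial to caudal; the most caudal vertebra (sacrum) is static.
phantom_transforms <- function(spec, geom, trunk_deg) {
  n <- spec$n_vertebrae
  tf <- vector("list", n)
  tf[[n]] <- list(R = diag(2), t = c(0, 0))
  for (j in (n - 1):1) {
    phi <- spec$motion_sharing[j] * trunk_deg
    tau_px <- spec$translation_mm_per_deg[j] * phi / spec$pixel_spacing
    p <- geom$iar[[j]]
    R <- rot_mat(phi)
    M <- list(R = R, t = as.numeric(p - R %*% p) + c(tau_px, 0))
    tf[[j]] <- compose_rigid(tf[[j + 1]], M)
  }
  tf
}

# Rasterize one rigid vertebra (C++ core); NULL signals a field-of-view
# breach.  img is modified in place and returned for clarity.
draw_vertebra <- function(img, corners, spec, scale) {
  sides <- sqrt(rowSums((corners[c(2, 3, 4, 1), ] - corners)^2))
  rho <- spec$corner_rounding * min(sides)
  ok <- draw_vertebra_cpp(img, corners, rho, spec$rim_width, scale)
  if (!ok) return(NULL)
  img
}

#' Render a ground-truthed synthetic fluoroscopy sequence
#'
#' Draws the phantom spine at every frame of a motion program and emits the
#' exact ground-truth channel alongside.  Rendering is deterministic; the
#' seed is recorded in the metadata and governs any degradations applied
#' afterwards with [apply_degradations()].
#'
#' @param spec a [phantom_spec()].
#' @param program a [make_motion_program()] program.
#' @param seed integer seed recorded in the sequence metadata.
#' @param plane image plane label for the metadata.
#' @return A list with `sequence` (a [qf_sequence()]) and `truth`
#'   (a `qf_truth` object, see Details).
#' @details The truth channel is exact pre-noise, pre-distortion geometry:
#'   `truth$poses` holds per frame and vertebra the rigid pose angle, centre
#'   and corner coordinates; `truth$levels` the per-frame intervertebral
#'   rotation (degrees), translation (percent body depth and mm, referenced
#'   to frame 0) and disc height obtained by applying the corner-based pose
#'   definitions to the exact corners, plus the programmed level rotation;
#'   `truth$level_info` the per-level motion share (which is also the exact
#'   neutral-zone laxity slope ratio), coupled translation rate and true
#'   rotation centre.
#' @export
render_sequence <- function(spec, program, seed = 1L, plane = NULL) {
  stopifnot(inherits(spec, "qf_phantom_spec"),
            inherits(program, "qf_motion_program"))
  geom <- phantom_neutral_geometry(spec)
  n <- spec$n_vertebrae
  nv <- vertebra_names(n)
  W <- spec$image_size[1]; H <- spec$image_size[2]
  scale <- (2^spec$bit_depth - 1) / 255
  bg <- 60 * scale
  angles <- program$trunk_angle_series
  nf <- length(angles)
  frames <- vector("list", nf)
  pose_rows <- vector("list", nf)
  corner_arrs <- array(NA_real_, c(4, 2, nf, n))
  prev_centers <- NULL
  frame_disp <- numeric(nf)
  for (t in seq_len(nf)) {
    tfs <- phantom_transforms(spec, geom, angles[t])
    img <- matrix(bg, H, W)
    centers <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      cc <- apply_rigid(tfs[[i]], geom$corners[[i]])
      corner_arrs[, , t, i] <- cc
      centers[i, ] <- colMeans(cc)
      img2 <- draw_vertebra(img, cc, spec, scale)
      if (is.null(img2)) {
        stop("vertebra ", nv[i], " leaves the field of view at frame ",
             t - 1L, call. = FALSE)
      }
      img <- img2
    }
    frame_disp[t] <- if (is.null(prev_centers)) 0 else
      max(sqrt(rowSums((centers - prev_centers)^2)))
    prev_centers <- centers
    ang <- vapply(seq_len(n), function(i)
      rad2deg(atan2(tfs[[i]]$R[1, 2], tfs[[i]]$R[1, 1])), numeric(1))
    pose_rows[[t]] <- tibble::tibble(
      frame = t - 1L, vertebra = nv, angle_deg = ang,
      cx_px = centers[, 1], cy_px = centers[, 2])
    frames[[t]] <- img
  }
  poses <- dplyr::bind_rows(pose_rows)
  corner_tbl <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      frame = rep(seq_len(nf) - 1L, each = 4),
      vertebra = nv[i],
      corner = rep(c("as", "ps", "pi", "ai"), nf),
      x_px = as.numeric(corner_arrs[, 1, , i]),
      y_px = as.numeric(corner_arrs[, 2, , i]))
  }))
  # per-level truth via the corner-based pose definitions on exact corners
  lvl <- dplyr::bind_rows(lapply(seq_len(n - 1), function(j) {
    up <- frobin_series(corner_arrs[, , , j])
    lo <- frobin_series(corner_arrs[, , , j + 1])
    s <- iv_pose_series(up, lo)
    depth_mm <- s$mean_depth_px[1] * spec$pixel_spacing
    tibble::tibble(
      level = paste0(nv[j], "-", nv[j + 1]),
      frame = s$frame,
      trunk_deg = angles,
      iv_rot_deg = s$iv_rot_deg - s$iv_rot_deg[1],
      iv_trans_pct = s$iv_trans_raw_pct - s$iv_trans_raw_pct[1],
      iv_trans_mm = (s$iv_trans_raw_pct - s$iv_trans_raw_pct[1]) / 100 * depth_mm,
      disc_height_pct = s$disc_height_pct,
      programmed_rot_deg = spec$motion_sharing[j] * angles)
  }))
  level_info <- tibble::tibble(
    level = paste0(nv[-n], "-", nv[-1]),
    motion_share = spec$motion_sharing,
    laxity_ratio = spec$motion_sharing,
    translation_mm_per_deg = spec$translation_mm_per_deg,
    iar_x_px = vapply(geom$iar, `[`, numeric(1), 1),
    iar_y_px = vapply(geom$iar, `[`, numeric(1), 2))
  truth <- structure(
    list(poses = poses, corners = corner_tbl, levels = lvl,
         level_info = level_info, program = program, spec = spec),
    class = "qf_truth")
  seqn <- qf_sequence(
    frames,
    frame_rate = program$frame_rate, bit_depth = spec$bit_depth,
    pixel_spacing = spec$pixel_spacing,
    plane = plane %||%
      ifelse(program$direction %in% c("flexion", "extension"),
             "sagittal", "coronal"),
    orientation_config = "recumbent_passive",
    direction = program$direction,
    meta = list(seed = seed, trunk_angle_series = angles,
                frame_disp_px = frame_disp, phantom = TRUE))
  list(sequence = seqn, truth = truth)
}

#' @export
print.qf_truth <- function(x, ...) {
  cat(sprintf("<qf_truth> %d frames, %d vertebrae, %d levels\n",
              max(x$poses$frame) + 1L, length(unique(x$poses$vertebra)),
              nrow(x$level_info)))
  invisible(x)
}

# Forward out-of-plane homography (source -> distorted) and its inverse.
foreshortening_homography <- function(spec) {
  theta <- deg2rad(spec$out_of_plane_deg)
  s <- cos(theta)
  H <- spec$image_size[2]
  eta <- 0.05 * sin(theta) / sin(deg2rad(10)) / H  # 5% keystone at 10 deg
  cx <- spec$image_size[1] / 2; cy <- H / 2
  Tc <- rbind(c(1, 0, cx), c(0, 1, cy), c(0, 0, 1))
  Tm <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1))
  K <- rbind(c(s, 0, 0), c(0, 1, 0), c(0, eta, 1))
  Ki <- rbind(c(1 / s, 0, 0), c(0, 1, 0), c(0, -eta, 1))
  list(forward = Tc %*% K %*% Tm, inverse = Tc %*% Ki %*% Tm)
}

#' Map points through a homography
#'
#' @param H 3x3 homography matrix.
#' @param pts n x 2 point matrix.
#' @return n x 2 matrix of mapped points.
#' @export
map_points_homography <- function(H, pts) {
  pts <- as.matrix(pts)
  ph <- cbind(pts, 1) %*% t(H)
  ph[, 1:2] / ph[, 3]
}

#' Degrade a rendered sequence towards calibration-study realism
#'
#' Applies, in order: out-of-plane foreshortening (anisotropic projective
#' scale `cos(theta)` plus first-order keystone), a static low-frequency
#' soft-tissue intensity field, motion blur proportional to the inter-frame
#' displacement, Poisson plus Gaussian noise, and a radial intensifier-flare
#' gain, clipping to the bit-depth range.  The truth channel of the phantom
#' is untouched; the forward distortion homography is stored in
#' `meta$distortion_h` so that initial landmarks can be placed in the
#' distorted geometry that an observer would mark.
#'
#' @param seq a [qf_sequence()].
#' @param spec the [phantom_spec()] holding the degradation parameters.
#' @param seed integer seed; identical inputs and seed give identical output.
#' @return The degraded `qf_sequence`.
#' @export
apply_degradations <- function(seq, spec, seed = 1L) {
  stopifnot(inherits(seq, "qf_sequence"), inherits(spec, "qf_phantom_spec"))
  W <- ncol(seq$frames[[1]]); H <- nrow(seq$frames[[1]])
  top <- 2^seq$bit_depth - 1
  nm <- spec$noise_model
  scale <- top / 255
  hgs <- NULL
  if (spec$out_of_plane_deg != 0) {
    hgs <- foreshortening_homography(spec)
  }
  with_seed(seed, {
    # static soft-tissue field: a few broad oriented cosines
    tissue <- NULL
    if (nm$tissue_amplitude > 0) {
      xg <- matrix(rep(0:(W - 1), each = H), H, W)
      yg <- matrix(rep(0:(H - 1), W), H, W)
      tissue <- matrix(0, H, W)
      for (k in 1:3) {
        th <- runif(1, 0, pi); wl <- runif(1, 150, 400); ph <- runif(1, 0, 2 * pi)
        tissue <- tissue +
          cos(2 * pi * (cos(th) * xg + sin(th) * yg) / wl + ph)
      }
      tissue <- nm$tissue_amplitude * scale * tissue / 3
    }
    flare <- NULL
    if (nm$flare_amplitude > 0) {
      xg <- matrix(rep(0:(W - 1), each = H), H, W)
      yg <- matrix(rep(0:(H - 1), W), H, W)
      r2 <- ((xg - W / 2)^2 + (yg - H / 2)^2) / ((W / 2)^2 + (H / 2)^2)
      flare <- 1 + nm$flare_amplitude * (0.5 - r2)
    }
    disp <- seq$meta$frame_disp_px %||% rep(0, n_frames(seq))
    frames <- vector("list", n_frames(seq))
    for (t in seq_len(n_frames(seq))) {
      img <- seq$frames[[t]]
      if (!is.null(hgs)) img <- warp_homography_cpp(img, hgs$inverse, 60 * scale)
      if (!is.null(tissue)) img <- img + tissue
      L <- spec$blur * disp[t]
      if (L >= 0.6) {
        k <- motion_blur_kernel(L)
        img <- convolve2d_cpp(img, k)
      }
      if (nm$poisson_scale > 0) {
        # photon noise: exact Poisson at low counts; at the high counts
        # typical of these grey levels its normal approximation is folded
        # into a single draw together with the Gaussian read noise
        lam <- pmax(img, 0) / nm$poisson_scale
        lo <- lam <= 50
        nz <- img
        if (any(lo)) nz[lo] <- rpois(sum(lo), lam[lo]) * nm$poisson_scale +
            rnorm(sum(lo), sd = nm$gaussian_sd * scale)
        if (any(!lo)) nz[!lo] <- img[!lo] +
            sqrt(nm$poisson_scale * img[!lo] + (nm$gaussian_sd * scale)^2) *
              rnorm(sum(!lo))
        img <- matrix(nz, H, W)
      } else if (nm$gaussian_sd > 0) {
        img <- img + matrix(rnorm(W * H, sd = nm$gaussian_sd * scale), H, W)
      }
      if (!is.null(flare)) img <- img * flare
      frames[[t]] <- matrix(pmin(pmax(img, 0), top), H, W)
    }
    seq$frames <- frames
  })
  seq$meta$degradations <- list(
    out_of_plane_deg = spec$out_of_plane_deg, noise_model = nm,
    blur = spec$blur, seed = seed)
  if (!is.null(hgs)) seq$meta$distortion_h <- hgs$forward
  seq
}

# Unit-sum line kernel of length L pixels along direction (dx, dy).
motion_blur_kernel <- function(L, dir = c(1, 0)) {
  half <- ceiling(L / 2)
  size <- 2 * half + 1
  k <- matrix(0, size, size)
  ts <- seq(-L / 2, L / 2, length.out = max(3, ceiling(L * 4)))
  d <- unitize(dir)
  for (t in ts) {
    x <- half + 1 + t * d[1]; y <- half + 1 + t * d[2]
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    for (oo in list(c(0, 0, (1 - fx) * (1 - fy)), c(1, 0, fx * (1 - fy)),
                    c(0, 1, (1 - fx) * fy), c(1, 1, fx * fy))) {
      xi <- x0 + oo[1]; yi <- y0 + oo[2]
      if (xi >= 1 && xi <= size && yi >= 1 && yi <= size) {
        k[yi, xi] <- k[yi, xi] + oo[3]
      }
    }
  }
  k / sum(k)
}

#' Generate initial landmark markings for a phantom sequence
#'
#' Produces the landmark table an observer would create on frame 0: the four
#' body corners per vertebra (taken from the truth channel, mapped through
#' the out-of-plane distortion when the sequence was degraded, and jittered
#' by a Gaussian placement error per marking) plus a tracking polygon
#' enclosing the body rim.
#'
#' @param truth the `qf_truth` of the rendered sequence.
#' @param seq the (possibly degraded) `qf_sequence`; supplies the distortion
#'   mapping if present.
#' @param n_markings number of independent markings per vertebra (default 5).
#' @param jitter_sd Gaussian corner placement error in pixels.
#' @param seed integer seed for the placement jitter.
#' @return A landmark tibble with columns `vertebra`, `marking_id`,
#'   `point_role` (`corner_as`, `corner_ps`, `corner_pi`, `corner_ai`,
#'   `polygon`), `region_id`, `point_index`, `x_px`, `y_px`.
#' @export
phantom_landmarks <- function(truth, seq = NULL, n_markings = 5,
                              jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "qf_truth"))
  hfwd <- seq$meta$distortion_h
  f0 <- truth$corners[truth$corners$frame == 0L, ]
  verts <- unique(f0$vertebra)
  with_seed(seed, {
    rows <- list()
    for (v in verts) {
      cc <- as.matrix(f0[f0$vertebra == v, c("x_px", "y_px")])
      if (!is.null(hfwd)) cc <- map_points_homography(hfwd, cc)
      ctr <- colMeans(cc)
      for (m in seq_len(n_markings)) {
        cj <- cc + matrix(rnorm(8, sd = jitter_sd), 4, 2)
        # tracking polygon: corners pushed outward past the rim, plus edge
        # midpoints, so the template support straddles the cortical edge
        poly <- sweep(sweep(cj, 2, ctr) * 1.18, 2, ctr, `+`)
        poly8 <- matrix(NA_real_, 8, 2)
        poly8[c(1, 3, 5, 7), ] <- poly
        poly8[c(2, 4, 6, 8), ] <- (poly + poly[c(2, 3, 4, 1), ]) / 2
        rows[[length(rows) + 1]] <- tibble::tibble(
          vertebra = v, marking_id = m,
          point_role = c("corner_as", "corner_ps", "corner_pi", "corner_ai",
                         rep("polygon", 8)),
          region_id = 1L,
          point_index = c(1:4, 1:8),
          x_px = c(cj[, 1], poly8[, 1]),
          y_px = c(cj[, 2], poly8[, 2]))
      }
    }
    dplyr::bind_rows(rows)
  })
}
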