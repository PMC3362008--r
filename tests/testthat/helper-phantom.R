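# Shared fixtures, generated in code and cached across test files.

qf_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = qf_test_cache)) {
    assign(key, force(expr), envir = qf_test_cache)
  }
  get(key, envir = qf_test_cache)
}

# Compact phantom: three vertebrae (two levels), protocol-conformant program
# at the protocol minima so the frame count stays small.
small_spec <- function(...) {
  phantom_spec(n_vertebrae = 4, motion_sharing = c(0.35, 0.35, 0.30),
               disc_gap_px = 16,
               noise_model = list(gaussian_sd = 0, poisson_scale = 0,
                                  flare_amplitude = 0, tissue_amplitude = 0),
               blur = 0, ...)
}

small_shares <- c("L3-L4" = 0.35, "L4-L5" = 0.35, "L5-S1" = 0.30)

small_program <- function(direction = "flexion", range = 40) {
  make_motion_program(direction, range, 8, 0.5, 12.5)
}

clean_phantom <- function() {
  cached("clean_phantom", render_sequence(small_spec(), small_program(),
                                          seed = 42))
}

# The clean phantom tracked with 5 markings and analysed end to end.
tracked_phantom <- function() {
  cached("tracked_phantom", {
    rs <- clean_phantom()
    lmk <- phantom_landmarks(rs$truth, rs$sequence, n_markings = 5,
                             jitter_sd = 0.3, seed = 9)
    poses <- track_sequence(rs$sequence, lmk, tracker_config())
    kin <- analyze_kinematics(poses, rs$sequence$meta$trunk_angle_series)
    list(rs = rs, landmarks = lmk, poses = poses, kin = kin)
  })
}

# A synthetic pose series built from exact analytic poses (no tracking),
# with matching landmarks, for pure-math kinematics tests.  A `global` rigid
# transform, when given, is applied to the whole scene (landmarks and every
# frame's geometry alike), as a global image distortion would.
analytic_pose_series <- function(spec = small_spec(), program = small_program(),
                                 global = NULL) {
  geom <- qfkin:::phantom_neutral_geometry(spec)
  nv <- qfkin:::vertebra_names(spec$n_vertebrae)
  angles <- program$trunk_angle_series
  nf <- length(angles)
  roles <- c("corner_as", "corner_ps", "corner_pi", "corner_ai")
  G <- if (is.null(global)) list(R = diag(2), t = c(0, 0)) else global
  Ginv <- list(R = t(G$R), t = as.numeric(-t(G$R) %*% G$t))
  lmk <- dplyr::bind_rows(lapply(seq_len(spec$n_vertebrae), function(i) {
    cc <- qfkin:::apply_rigid(G, geom$corners[[i]])
    tibble::tibble(vertebra = nv[i], marking_id = 1L, point_role = roles,
                   region_id = 1L, point_index = 1:4,
                   x_px = cc[, 1], y_px = cc[, 2])
  }))
  rows <- lapply(seq_len(spec$n_vertebrae), function(i) {
    piv <- colMeans(qfkin:::apply_rigid(G, geom$corners[[i]]))
    rot <- numeric(nf); dx <- numeric(nf); dy <- numeric(nf)
    for (t in seq_len(nf)) {
      tf <- qfkin:::phantom_transforms(spec, geom, angles[t])[[i]]
      tf <- qfkin:::compose_rigid(G, qfkin:::compose_rigid(tf, Ginv))
      rot[t] <- qfkin:::rad2deg(atan2(tf$R[1, 2], tf$R[1, 1]))
      # pose convention: p' = R (p - piv) + piv + shift
      shift <- as.numeric(tf$R %*% piv) + tf$t - piv
      dx[t] <- shift[1]; dy[t] <- shift[2]
    }
    tibble::tibble(vertebra = nv[i], marking_id = 1L, frame = seq_len(nf) - 1L,
                   rot_deg = rot, dx_px = dx, dy_px = dy)
  })
  qf_pose_series(dplyr::bind_rows(rows), frame_rate = program$frame_rate,
                 landmarks = lmk, pixel_spacing = spec$pixel_spacing)
}

rms <- function(x) sqrt(mean(x^2))

range_of <- function(x) max(x) - min(x)

# Synthetic pose series with hand-set rotations for combinatorial checks.
toy_pose_series <- function(n_markings = 5, nf = 20) {
  mk <- seq_len(n_markings)
  df <- tidyr::expand_grid(vertebra = c("L4", "L5"), marking_id = mk,
                           frame = 0:(nf - 1))
  df$rot_deg <- ifelse(df$vertebra == "L4", 0.2, 0.05) * df$frame +
    0.01 * df$marking_id
  df$dx_px <- 0; df$dy_px <- 0
  qf_pose_series(df, frame_rate = 15)
}

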