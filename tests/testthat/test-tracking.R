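# A tiny static sequence built from one phantom frame.
static_sequence <- function(n = 5) {
  rs <- clean_phantom()
  qf_sequence(rep(rs$sequence$frames[1], n), frame_rate = 15, bit_depth = 8,
              pixel_spacing = 0.5)
}

first_landmarks <- function(n_markings = 1, jitter = 0) {
  rs <- clean_phantom()
  phantom_landmarks(rs$truth, rs$sequence, n_markings = n_markings,
                    jitter_sd = jitter, seed = 4)
}

test_that("identical frames track to the identity pose with peak near 1", {
  seqn <- static_sequence()
  poses <- track_sequence(seqn, first_landmarks(), tracker_config())
  expect_true(all(abs(poses$rot_deg) < 0.02))
  expect_true(all(abs(poses$dx_px) < 0.02))
  expect_true(all(abs(poses$dy_px) < 0.02))
  expect_true(all(poses$peak > 0.99))
  expect_true(all(poses$flag == "ok"))
})

test_that("integer frame shifts are recovered exactly (shift equivariance)", {
  rs <- clean_phantom()
  f0 <- rs$sequence$frames[[1]]
  shift_im <- function(img, dx) {
    out <- img * 0 + 60  # background fill
    out[, (1 + dx):ncol(img)] <- img[, 1:(ncol(img) - dx)]
    out
  }
  frames <- list(f0, shift_im(f0, 3), shift_im(f0, 6), shift_im(f0, 9))
  seqn <- qf_sequence(frames, frame_rate = 15, bit_depth = 8)
  # rolling window 1 so each frame is registered as-is
  poses <- track_sequence(seqn, first_landmarks(),
                          tracker_config(rolling_average_window = 1))
  for (t in 1:3) {
    at <- poses[poses$frame == t, ]
    expect_equal(at$dx_px, rep(3 * t, nrow(at)), tolerance = 0.05)
    expect_equal(at$dy_px, rep(0, nrow(at)), tolerance = 0.05)
    expect_equal(at$rot_deg, rep(0, nrow(at)), tolerance = 0.02)
  }
})

test_that("cumulative rotation stays within 0.1 degree of truth at the sweep extremes", {
  # mid-sweep estimates carry the half-frame lag of the 2-frame rolling
  # average (~ half the per-frame trunk increment); at the motion reversal
  # and at the neutral finish the velocity is zero and the lag vanishes, so
  # cumulative error there is pure tracking error
  tp <- tracked_phantom()
  truth <- tp$rs$truth$poses
  poses <- tp$poses
  trunk <- tp$rs$sequence$meta$trunk_angle_series
  peak <- which.max(abs(trunk))
  nf <- length(trunk)
  for (m in unique(poses$marking_id)) {
    est <- poses[poses$vertebra == "L3" & poses$marking_id == m, ]
    est <- est[order(est$frame), ]
    tru <- truth[truth$vertebra == "L3", ]
    tru <- tru[order(tru$frame), ]
    err <- est$rot_deg - tru$angle_deg
    expect_lt(abs(err[peak]), 0.1)       # end of outward sweep (~40 deg)
    expect_lt(abs(err[nf]), 0.1)         # back at neutral
    expect_lt(max(abs(err)), 0.4)        # bounded everywhere mid-sweep
  }
})

test_that("independent markings of one vertebra agree to 0.1 degree RMS", {
  tp <- tracked_phantom()
  poses <- tp$poses
  for (v in c("L3", "L5")) {
    g <- poses[poses$vertebra == v, ]
    w <- tidyr::pivot_wider(g[, c("frame", "marking_id", "rot_deg")],
                            names_from = "marking_id", values_from = "rot_deg")
    m <- as.matrix(w[, -1])
    spread <- apply(m, 1, function(r) sqrt(mean((r - mean(r))^2)))
    expect_lt(sqrt(mean(spread^2)), 0.1)
  }
})

test_that("lowering the peak threshold never increases flagged frames", {
  rs <- clean_phantom()
  spec_n <- phantom_spec(n_vertebrae = 4, motion_sharing = c(0.35, 0.35, 0.3),
                         disc_gap_px = 16)
  short <- rs$sequence
  short$frames <- short$frames[1:30]
  short$meta$frame_disp_px <- short$meta$frame_disp_px[1:30]
  noisy <- apply_degradations(short, spec_n, seed = 3)
  lmk <- first_landmarks()
  n_flagged <- function(th) {
    p <- track_sequence(noisy, lmk, tracker_config(peak_threshold = th))
    sum(p$flag == "low_peak")
  }
  expect_gte(n_flagged(0.95), n_flagged(0.6))
  expect_gte(n_flagged(0.6), n_flagged(0.2))
})

test_that("metal masking removes implant pixels from the correlation support", {
  rs <- clean_phantom()
  img <- rs$sequence$frames[[1]]
  poly <- rbind(c(200, 200), c(260, 200), c(260, 240), c(200, 240))
  tpl <- qf_template(img, poly)
  expect_identical(mask_metal(tpl, list()), tpl)
  half <- rbind(c(200, 200), c(230, 200), c(230, 240), c(200, 240))
  tpl2 <- mask_metal(tpl, list(half))
  expect_equal(tpl2$support_fraction, 0.5, tolerance = 0.05)
  big <- rbind(c(195, 195), c(255, 195), c(255, 245), c(195, 245))
  expect_error(mask_metal(tpl, list(big)), "25%")
})

test_that("a masked implant does not perturb tracking", {
  rs <- clean_phantom()
  tr <- rs$truth
  # screw: a bright rectangle riding rigidly inside L4, drawn per frame
  nfr <- 40
  seq_a <- rs$sequence; seq_a$frames <- seq_a$frames[1:nfr]
  seq_b <- seq_a
  f0 <- tr$poses[tr$poses$frame == 0 & tr$poses$vertebra == "L4", ]
  base <- rbind(c(-18, -6), c(12, -2), c(12, 2), c(-18, 2)) +
    matrix(rep(c(f0$cx_px, f0$cy_px), each = 4), 4, 2)
  for (t in seq_len(nfr)) {
    p <- tr$poses[tr$poses$frame == t - 1 & tr$poses$vertebra == "L4", ]
    p0 <- c(f0$cx_px, f0$cy_px)
    R <- qfkin:::rot_mat(p$angle_deg)
    scr <- sweep(sweep(base, 2, p0) %*% t(R), 2, c(p$cx_px, p$cy_px), `+`)
    xr <- floor(min(scr[, 1])):ceiling(max(scr[, 1]))
    yr <- floor(min(scr[, 2])):ceiling(max(scr[, 2]))
    px <- rep(xr, each = length(yr)); py <- rep(yr, times = length(xr))
    inside <- qfkin:::points_in_polygon(px, py, scr)
    img <- seq_b$frames[[t]]
    img[cbind(py[inside] + 1, px[inside] + 1)] <- 255
    seq_b$frames[[t]] <- img
  }
  lmk <- first_landmarks()
  # metal polygon around the screw's frame-0 footprint, on the L4 marking
  metal <- tibble::tibble(
    vertebra = "L4", marking_id = 1L, point_role = "metal", region_id = 1L,
    point_index = 1:4,
    x_px = base[, 1] + c(-3, 3, 3, -3), y_px = base[, 2] + c(-3, -3, 3, 3))
  pa <- track_sequence(seq_a, lmk, tracker_config())
  pb <- track_sequence(seq_b, dplyr::bind_rows(lmk, metal), tracker_config())
  ra <- pa[pa$vertebra == "L4", ]; rb <- pb[pb$vertebra == "L4", ]
  expect_lt(max(abs(ra$rot_deg - rb$rot_deg)), 0.1)
})

test_that("tracking verification summarises flags, spread and reversals", {
  tp <- tracked_phantom()
  rep <- verify_tracking(tp$poses)
  expect_true(attr(rep, "overall") %in% c("pass", "warn"))
  expect_true(all(rep$frac_flagged == 0))
  # perturb one marking grossly: its spread must be flagged
  bad <- tp$poses
  sel <- bad$vertebra == "L4" & bad$marking_id == 3 & bad$frame > 10
  bad$rot_deg[sel] <- bad$rot_deg[sel] + 5
  rep2 <- verify_tracking(bad)
  expect_gt(rep2$spread_max_deg[rep2$vertebra == "L4"], 0.5)
  expect_equal(rep2$verdict[rep2$vertebra == "L4"], "warn")
  # empty series fails
  expect_identical(attr(verify_tracking(tp$poses[0, ]), "overall"), "fail")
})

test_that("zero-phase Butterworth smoothing matches its analytic response", {
  fs <- 15; fc <- 1; ord <- 4
  cfg <- tracker_config(butterworth_cutoff = fc, butterworth_order = ord)
  n <- 300
  tt <- (0:(n - 1)) / fs
  # digital Butterworth magnitude via the bilinear transform, squared for
  # the forward-backward pass
  gain2 <- function(f) {
    w <- tan(pi * f / fs) / tan(pi * fc / fs)
    (1 / sqrt(1 + w^(2 * ord)))^2
  }
  # constant series is unchanged
  expect_equal(smooth_keypoints(rep(3.2, n), cfg, frame_rate = fs),
               rep(3.2, n))
  # 0.1 Hz motion band: amplitude preserved within 1%
  x <- sin(2 * pi * 0.1 * tt)
  y <- smooth_keypoints(x, cfg, frame_rate = fs)
  mid <- 50:250
  amp <- max(abs(y[mid])) / max(abs(x[mid]))
  expect_equal(amp, gain2(0.1), tolerance = 0.01)
  expect_gt(amp, 0.99)
  # 6 Hz jitter attenuated by more than 95%
  j <- sin(2 * pi * 6 * tt)
  yj <- smooth_keypoints(j, cfg, frame_rate = fs)
  att <- max(abs(yj[mid]))
  expect_lt(att, 0.05)
  expect_equal(att, gain2(6), tolerance = 0.01)
  # refusal without a frame rate or with too short a series
  expect_error(smooth_keypoints(x, cfg), "frame rate")
  expect_error(smooth_keypoints(x[1:10], cfg, frame_rate = fs), "too short")
})
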