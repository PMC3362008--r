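test_that("five markings per vertebra give 25 intervertebral curves", {
  kin <- intervertebral_series(toy_pose_series(5))
  combos <- dplyr::distinct(kin$curves, marking_upper, marking_lower)
  expect_identical(nrow(combos), 25L)
  expect_identical(unique(kin$curves$level), "L4-L5")
  # mean and median lie within the 25-curve envelope
  expect_true(all(kin$rotation$mean >= kin$rotation$min - 1e-12 &
                    kin$rotation$mean <= kin$rotation$max + 1e-12))
  expect_true(all(kin$rotation$median >= kin$rotation$min - 1e-12 &
                    kin$rotation$median <= kin$rotation$max + 1e-12))
})

test_that("a single marking gives one curve with mean equal to median", {
  kin <- intervertebral_series(toy_pose_series(1))
  expect_identical(nrow(dplyr::distinct(kin$curves, marking_upper,
                                        marking_lower)), 1L)
  expect_equal(kin$rotation$mean, kin$rotation$median)
})

test_that("median intervertebral curves recover phantom truth within 0.2 deg RMS", {
  tp <- tracked_phantom()
  kin <- tp$kin
  tr <- tp$rs$truth$levels
  for (lv in kin$levels) {
    med <- kin$rotation$median[kin$rotation$level == lv]
    tru <- tr$iv_rot_deg[tr$level == lv]
    expect_lt(rms(med - tru), 0.2)
    # mean and median of the 25 curves are near-identical on clean phantoms
    mn <- kin$rotation$mean[kin$rotation$level == lv]
    expect_lt(rms(med - mn), 0.2)
  }
})

test_that("translation curves: static input is zero; rigid distortion changes nothing", {
  # static: zero-range program
  ps0 <- analytic_pose_series(program = make_motion_program("flexion", 0, 8, 0.5, 12.5))
  kin0 <- continuous_translation(intervertebral_series(ps0))
  expect_true(all(abs(kin0$translation$trans_median_pct) < 1e-9))
  # the same motion seen through a global rigid distortion gives the same
  # translation and disc height curves (corner-based compensation)
  ps <- analytic_pose_series()
  kin <- continuous_translation(intervertebral_series(ps))
  G <- list(R = qfkin:::rot_mat(8), t = c(12, -7))
  psg <- analytic_pose_series(global = G)
  king <- continuous_translation(intervertebral_series(psg))
  expect_equal(king$translation$trans_median_pct,
               kin$translation$trans_median_pct, tolerance = 1e-6)
  expect_equal(king$translation$disc_median_pct,
               kin$translation$disc_median_pct, tolerance = 1e-6)
  expect_equal(king$rotation$median, kin$rotation$median, tolerance = 1e-6)
})

test_that("programmed translation is recovered from the images", {
  # couple 2 mm of translation into the L4-L5 level over the sweep
  spec <- small_spec(translation_mm_per_deg = c(2 / (0.35 * 40), 0, 0))
  prog <- small_program()
  rs <- render_sequence(spec, prog, seed = 21)
  lmk <- phantom_landmarks(rs$truth, rs$sequence, n_markings = 2,
                           jitter_sd = 0.3, seed = 5)
  poses <- smooth_keypoints(track_sequence(rs$sequence, lmk, tracker_config()))
  kin <- continuous_translation(intervertebral_series(poses))
  tr <- rs$truth$levels
  for (lv in kin$levels) {
    meas <- range_of(kin$translation$trans_median_pct[kin$translation$level == lv])
    tru <- range_of(tr$iv_trans_pct[tr$level == lv])
    expect_lt(abs(meas - tru), 0.5)
  }
  # the truth channel carries the programmed translation coupling
  expect_gt(range_of(tr$iv_trans_mm[tr$level == "L3-L4"]), 1.5)
})

test_that("laxity ratio is the slope ratio in the first 10 degrees", {
  trunk <- c(seq(0, 15, by = 0.5), seq(15, 0, by = -0.5))
  expect_equal(neutral_zone_laxity(0.3 * trunk, trunk)$ratio, 0.3,
               tolerance = 1e-9)
  expect_equal(neutral_zone_laxity(trunk, trunk)$ratio, 1.0, tolerance = 1e-9)
  # window covers exactly the frames within 10 degrees on the outward sweep
  lx <- neutral_zone_laxity(0.3 * trunk, trunk)
  expect_identical(lx$window_end, max(which(abs(trunk) <= 10 &
                                              seq_along(trunk) <= 21)) - 1L)
  # degenerate inputs
  expect_error(neutral_zone_laxity(trunk, trunk * 0), "never leaves")
  fast <- c(0, 4, 8, 12, 16, 20)
  expect_error(neutral_zone_laxity(fast, fast), "fewer than 5")
  expect_error(neutral_zone_laxity(trunk, trunk + 5), "neutral")
})

test_that("laxity per level matches the programmed motion sharing", {
  tp <- tracked_phantom()
  lax <- neutral_zone_laxity(tp$kin)
  share <- small_shares
  for (lv in names(share)) {
    expect_lt(abs(lax$ratio[lax$level == lv] - share[lv]), 0.02)
  }
})

test_that("IAR recovers a known rotation centre and flags pure translation", {
  up <- rbind(c(300, 200), c(230, 200), c(230, 244), c(300, 244))
  lo <- up; lo[, 2] <- lo[, 2] + 56
  P <- c(255, 250)
  R <- qfkin:::rot_mat(10)
  up2 <- sweep(sweep(up, 2, P) %*% t(R), 2, P, `+`)
  res <- iar(up, up2, lo, lo, min_angle = 5)
  expect_true(res$valid)
  expect_equal(res$rotation_deg, 10, tolerance = 1e-9)
  expect_lt(sqrt(sum((res$location - P)^2)), 0.1)
  # offsets are reported from the posterior-inferior corner of the lower body
  expect_equal(res$ref_offset_px, P - lo[3, ], tolerance = 0.1)
  # pure translation has no finite IAR
  res2 <- iar(up, sweep(up, 2, c(-8, 0)), lo, lo)
  expect_false(res2$valid)
  # below the minimum angle the location is not reported
  small <- sweep(sweep(up, 2, P) %*% t(qfkin:::rot_mat(2)), 2, P, `+`)
  expect_false(iar(up, small, lo, lo, min_angle = 5)$valid)
})

test_that("IAR agrees with a least-squares rigid-fit oracle and is equivariant", {
  # oracle: 2D Kabsch fit of the upper body's motion in the lower frame,
  # then the fixed point p = (I - R)^{-1} t
  kabsch_fixed_point <- function(a, b) {
    ca <- colMeans(a); cb <- colMeans(b)
    H <- t(sweep(a, 2, ca)) %*% sweep(b, 2, cb)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    tt <- cb - as.numeric(R %*% ca)
    as.numeric(solve(diag(2) - R, tt))
  }
  set.seed(11)
  up <- rbind(c(300, 200), c(230, 204), c(232, 246), c(301, 242))
  lo <- up; lo[, 2] <- lo[, 2] + 56
  for (k in 1:5) {
    P <- c(runif(1, 220, 300), runif(1, 240, 270))
    ang <- runif(1, 6, 15) * sample(c(-1, 1), 1)
    R <- qfkin:::rot_mat(ang)
    shift <- c(runif(1, -3, 3), runif(1, -3, 3))
    up2 <- sweep(sweep(up, 2, P) %*% t(R), 2, P - shift, `+`)
    res <- iar(up, up2, lo, lo, min_angle = 5)
    expect_true(res$valid)
    oracle <- kabsch_fixed_point(up, up2)
    expect_lt(sqrt(sum((res$location - oracle)^2)), 0.5)
    # equivariance: a global rigid transform moves the IAR identically
    G <- qfkin:::rot_mat(7); gt <- c(5, -11)
    mv <- function(m) sweep(m %*% t(G), 2, gt, `+`)
    resg <- iar(mv(up), mv(up2), mv(lo), mv(lo), min_angle = 5)
    expect_lt(sqrt(sum((resg$location -
                          (as.numeric(G %*% res$location) + gt))^2)), 1e-6)
  }
})

test_that("summary indices behave on proportional and inverted motion", {
  ps <- analytic_pose_series()
  trunk <- small_program()$trunk_angle_series
  kin <- motion_indices(continuous_translation(intervertebral_series(ps, trunk)))
  idx <- kin$indices
  # both levels move proportionally to the trunk
  expect_true(all(idx$coherence > 0.99))
  expect_true(all(abs(idx$phase_lag_deg) < 0.5))
  expect_equal(idx$motion_share, unname(small_shares), tolerance = 0.01)
  expect_equal(idx$max_rotation_range_deg, unname(small_shares) * 40,
               tolerance = 0.05)
  # commencement ties are broken in anatomical order
  expect_identical(idx$commencement_rank, seq_along(small_shares))
  # inverting one level's motion destroys its directional coherence
  ps2 <- ps
  sel <- ps2$vertebra == "L3"
  l4 <- ps2[ps2$vertebra == "L4", ]
  ps2$rot_deg[sel] <- 2 * l4$rot_deg[match(ps2$frame[sel], l4$frame)] -
    ps2$rot_deg[sel]
  kin2 <- motion_indices(continuous_translation(intervertebral_series(ps2, trunk)))
  expect_lt(kin2$indices$coherence[kin2$indices$level == "L3-L4"], 0.05)
})

test_that("motion sharing is recovered from tracked images within 0.02", {
  tp <- tracked_phantom()
  idx <- tidy(tp$kin)
  expect_lt(max(abs(idx$motion_share - small_shares)), 0.02)
  expect_true(all(idx$iar_valid))
  # the IAR equals the fixed point of the programmed relative motion:
  # rotation about the disc centre plus the coupled endplate translation
  info <- tp$rs$truth$level_info
  trunk <- tp$rs$sequence$meta$trunk_angle_series
  th_trunk <- trunk[which.max(abs(trunk))]
  for (lv in idx$level) {
    est <- c(idx$iar_x_px[idx$level == lv], idx$iar_y_px[idx$level == lv])
    p <- c(info$iar_x_px[info$level == lv], info$iar_y_px[info$level == lv])
    th <- info$motion_share[info$level == lv] * th_trunk
    tau <- info$translation_mm_per_deg[info$level == lv] * th / 0.5
    R <- qfkin:::rot_mat(th)
    expected <- p + solve(diag(2) - R, tau * c(1, 0))
    expect_lt(sqrt(sum((est - expected)^2)), 2)
  }
})
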