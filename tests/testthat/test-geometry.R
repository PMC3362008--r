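test_that("corner registration of a unit square", {
  # anterior side at x = 0: roles as, ps, pi, ai
  fr <- frobin_frame(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(fr$center, c(0.5, 0.5))
  expect_equal(fr$body_depth, 1)
  expect_equal(fr$axis, c(-1, 0))
})

test_that("corner frame is rigidly equivariant", {
  set.seed(1)
  cc <- rbind(c(10, 2), c(0, 0), c(0.5, 8), c(9, 9.5))
  fr <- frobin_frame(cc)
  expect_equal(fr$center, colMeans(cc))  # brute-force centroid
  R <- qfkin:::rot_mat(17)
  cc2 <- sweep(sweep(cc, 2, c(5, 5)) %*% t(R), 2, c(5, 5), `+`)
  fr2 <- frobin_frame(cc2)
  expect_equal(qfkin:::signed_angle(fr$axis, fr2$axis), 17, tolerance = 1e-9)
  expect_equal(fr2$body_depth, fr$body_depth)
})

test_that("degenerate and self-intersecting corner sets are rejected", {
  expect_error(frobin_frame(rbind(c(0, 0), c(0, 0), c(0, 1), c(0, 1))),
               "depth|self-intersect")
  expect_error(frobin_frame(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))),
               "self-intersecting")
})

stack_pair <- function() {
  up <- rbind(c(80, 10), c(10, 10), c(10, 50), c(80, 50))
  lo <- up; lo[, 2] <- lo[, 2] + 55
  list(up = up, lo = lo)
}

test_that("intervertebral pose of an unmoved pair is zero", {
  p <- stack_pair()
  n0 <- iv_pose(frobin_frame(p$up), frobin_frame(p$lo))
  p1 <- iv_pose(frobin_frame(p$up), frobin_frame(p$lo), neutral = n0)
  expect_equal(p1$rotation_deg, 0)
  expect_equal(p1$translation_pct, 0)
})

test_that("rotation about the disc centre reads 5 degrees with little translation", {
  p <- stack_pair()
  disc <- c(45, 57.5)  # midpoint of the two body centres
  n0 <- iv_pose(frobin_frame(p$up), frobin_frame(p$lo))
  R <- qfkin:::rot_mat(5)
  up2 <- sweep(sweep(p$up, 2, disc) %*% t(R), 2, disc, `+`)
  pose <- iv_pose(frobin_frame(up2), frobin_frame(p$lo), neutral = n0)
  expect_equal(pose$rotation_deg, 5, tolerance = 1e-9)
  expect_lt(abs(pose$translation_pct), 0.2)
})

test_that("0.91 mm of shift on a 35 mm body reads 2.60% depth", {
  p <- stack_pair()  # depth 70 px; at 0.5 mm/px that is a 35 mm body
  n0 <- iv_pose(frobin_frame(p$up), frobin_frame(p$lo))
  bis <- n0$bisectrix
  shift_px <- 0.91 / 0.5  # 0.91 mm at 0.5 mm/px
  up2 <- sweep(p$up, 2, -shift_px * bis)
  pose <- iv_pose(frobin_frame(up2), frobin_frame(p$lo), neutral = n0)
  expect_equal(abs(pose$translation_pct), 2.60, tolerance = 1e-6)
  expect_equal(translation_pct_to_mm(abs(pose$translation_pct), 35), 0.91,
               tolerance = 1e-6)
})

test_that("percent-depth to millimetre conversion", {
  expect_equal(translation_pct_to_mm(2.60, 35), 0.91)
  expect_equal(translation_pct_to_mm(0, 1234), 0)
  expect_equal(translation_pct_to_mm(100, 42), 42)
})

test_that("intervertebral measures are invariant to global rigid distortion", {
  set.seed(7)
  p <- stack_pair()
  R5 <- qfkin:::rot_mat(3)
  up2 <- sweep(sweep(p$up, 2, c(45, 52)) %*% t(R5), 2, c(45, 52), `+`)
  up2 <- sweep(up2, 2, c(1.5, -2.0), `+`)  # some intervertebral motion
  base <- iv_pose(frobin_frame(up2), frobin_frame(p$lo))
  for (ang in c(-10, -3, 5, 10)) {
    G <- qfkin:::rot_mat(ang)
    ctr <- c(runif(1, 0, 200), runif(1, 0, 200))
    tr <- c(runif(1, -40, 40), runif(1, -40, 40))
    move <- function(m) sweep(sweep(m, 2, ctr) %*% t(G), 2, ctr + tr, `+`)
    pose <- iv_pose(frobin_frame(move(up2)), frobin_frame(move(p$lo)))
    expect_equal(pose$rotation_deg, base$rotation_deg, tolerance = 1e-6)
    expect_equal(pose$translation_raw_pct, base$translation_raw_pct,
                 tolerance = 1e-6)
    expect_equal(pose$disc_height_pct, base$disc_height_pct, tolerance = 1e-6)
  }
  # scale invariance of the normalized measures
  pose2 <- iv_pose(frobin_frame(up2 * 2), frobin_frame(p$lo * 2))
  expect_equal(pose2$translation_raw_pct, base$translation_raw_pct,
               tolerance = 1e-9)
  expect_equal(pose2$disc_height_pct, base$disc_height_pct, tolerance = 1e-9)
  # antisymmetry of rotation under vertebra swap
  swap <- iv_pose(frobin_frame(p$lo), frobin_frame(up2))
  expect_equal(swap$rotation_deg, -base$rotation_deg, tolerance = 1e-12)
})

test_that("corner refinement recovers true corners on the phantom", {
  rs <- clean_phantom()
  img <- rs$sequence$frames[[1]]
  f0 <- rs$truth$corners[rs$truth$corners$frame == 0 &
                           rs$truth$corners$vertebra == "L5", ]
  truth <- as.matrix(f0[, c("x_px", "y_px")])
  set.seed(3)
  off <- truth + matrix(rnorm(8, sd = 2 / sqrt(2)), 4, 2)
  ref <- refine_corners(img, off, n_iterations = 4)
  expect_true(all(sqrt(rowSums((ref$corners - truth)^2)) <= 0.5))
  # fixed point: corners already on truth barely move
  ref2 <- refine_corners(img, truth, n_iterations = 1)
  expect_true(all(sqrt(rowSums((ref2$corners - truth)^2)) <= 0.25))
  # flat image: unchanged and flagged
  flat <- matrix(100, 64, 64)
  ref3 <- refine_corners(flat, rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30)))
  expect_equal(ref3$corners,
               rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30)))
  expect_true(all(ref3$flagged))
})

test_that("contour snapping locks a polygon onto the body edge", {
  rs <- clean_phantom()
  img <- rs$sequence$frames[[1]]
  f0 <- rs$truth$corners[rs$truth$corners$frame == 0 &
                           rs$truth$corners$vertebra == "L5", ]
  truth <- as.matrix(f0[, c("x_px", "y_px")])
  ctr <- colMeans(truth)
  # vertices on the straight edge segments (clear of the rounded corners)
  poly <- do.call(rbind, lapply(1:4, function(e) {
    a <- truth[e, ]; b <- truth[e %% 4 + 1, ]
    rbind(a + 0.3 * (b - a), a + 0.5 * (b - a), a + 0.7 * (b - a))
  }))
  snapped <- snap_contour(img, poly)
  expect_lt(max(sqrt(rowSums((snapped - poly)^2))), 0.75)
  # a polygon pushed 2.5 px off the rim is pulled back onto it
  outward <- t(apply(poly, 1, function(p) qfkin:::unitize(p - ctr)))
  dil <- poly + 2.5 * outward
  rec <- snap_contour(img, dil)
  d_before <- sqrt(rowSums((dil - poly)^2))
  d_after <- sqrt(rowSums((rec - poly)^2))
  expect_lt(max(d_after), 1.5)
  expect_lt(mean(d_after), mean(d_before) / 2)
  # flat image: unchanged
  flat <- matrix(7, 64, 64)
  sq <- rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30))
  expect_equal(snap_contour(flat, sq), sq)
})
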