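# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring caller state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Rotation matrix for an angle positive-anticlockwise on screen (y down).
rot_mat <- function(deg) {
  th <- deg2rad(deg)
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
}

# Apply rigid pose (rotation about pivot, then translation) to an n x 2
# point matrix.
apply_pose <- function(pts, rot_deg, pivot, shift) {
  R <- rot_mat(rot_deg)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot + shift, `+`)
}

vnorm <- function(v) sqrt(sum(v^2))
unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# Signed area of a polygon (positive when wound anticlockwise in a y-down
# frame is negative; sign is only used for consistency checks).
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Does the closed polygon self-intersect?  Checks all non-adjacent edge pairs.
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  seg <- function(i) list(a = pts[i, ], b = pts[i %% n + 1, ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p, q) {
    d1 <- cross2(q$a, q$b, p$a); d2 <- cross2(q$a, q$b, p$b)
    d3 <- cross2(p$a, p$b, q$a); d4 <- cross2(p$a, p$b, q$b)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Gradient magnitude at arbitrary sub-pixel locations via central differences
# of bilinear samples (Scharr-like isotropic weighting is unnecessary at the
# sub-pixel scale used here).
gradient_magnitude_at <- function(image, x, y, h = 0.5) {
  gx <- (bilinear_sample_cpp(image, x + h, y) -
           bilinear_sample_cpp(image, x - h, y)) / (2 * h)
  gy <- (bilinear_sample_cpp(image, x, y + h) -
           bilinear_sample_cpp(image, x, y - h)) / (2 * h)
  sqrt(gx^2 + gy^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
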