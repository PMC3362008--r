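#' Register a vertebral body from its four corners
#'
#' Builds the corner-based description of vertebral position used throughout
#' the package: anterior and posterior edge midpoints, body centre, central
#' axis and body depth.  Because every derived quantity is constructed from
#' the corner geometry alone, intervertebral measures computed from two such
#' frames are invariant to any rigid transform applied to the whole image —
#' the distortion-compensation property that motivates corner-based
#' registration for translation and disc height.
#'
#' @param corners 4x2 numeric matrix of corner coordinates in canonical role
#'   order: anterior-superior, posterior-superior, posterior-inferior,
#'   anterior-inferior (pixel units, x rightward, y downward).
#' @return An object of class `qf_vertebra_frame`: a list with elements
#'   `corners`, `anterior_mid`, `posterior_mid`, `center`, `axis` (unit
#'   vector pointing anteriorly), `body_depth` and `body_height` (pixels).
#' @examples
#' fr <- frobin_frame(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' fr$center      # centroid of the corners
#' fr$body_depth  # anterior-posterior midpoint separation
#' @export
frobin_frame <- function(corners) {
  corners <- as.matrix(corners)
  if (!is.numeric(corners) || nrow(corners) != 4 || ncol(corners) != 2) {
    stop("`corners` must be a 4x2 numeric matrix", call. = FALSE)
  }
  if (polygon_self_intersects(corners)) {
    stop("corner quadrilateral is self-intersecting", call. = FALSE)
  }
  am <- (corners[1, ] + corners[4, ]) / 2  # anterior edge midpoint
  pm <- (corners[2, ] + corners[3, ]) / 2  # posterior edge midpoint
  sm <- (corners[1, ] + corners[2, ]) / 2  # superior edge midpoint
  im <- (corners[3, ] + corners[4, ]) / 2  # inferior edge midpoint
  depth <- vnorm(am - pm)
  if (depth < .Machine$double.eps^0.5) {
    stop("degenerate vertebra: zero body depth", call. = FALSE)
  }
  structure(
    list(
      corners = corners,
      anterior_mid = am,
      posterior_mid = pm,
      center = colMeans(corners),
      axis = unitize(am - pm),
      body_depth = depth,
      body_height = vnorm(sm - im)
    ),
    class = "qf_vertebra_frame"
  )
}

# Signed angle (degrees) rotating direction `from` onto `to`, positive
# anticlockwise on screen.
signed_angle <- function(from, to) {
  rad2deg(atan2(-(from[1] * to[2] - from[2] * to[1]),
                from[1] * to[1] + from[2] * to[2]))
}

#' Intervertebral pose from two registered vertebrae
#'
#' Computes the relative rotation, bisectrix-referenced translation and disc
#' height of an adjacent vertebral pair from their corner-based frames.
#' Translation is the component of the centre-to-centre vector along the
#' bisectrix of the two central axes, expressed as a percentage of the mean
#' body depth; disc height is the perpendicular component corrected for the
#' two half body heights.  When a `neutral` pose is supplied, `translation_pct`
#' is reported as the change from that neutral value (the convention used for
#' continuous motion curves); otherwise the raw value is returned.
#'
#' @param upper,lower `qf_vertebra_frame` objects for the upper and lower
#'   vertebra of the pair.
#' @param neutral optional `qf_iv_pose` of the same pair in the neutral
#'   (first) frame, used as the translation reference.
#' @return An object of class `qf_iv_pose`: list with `rotation_deg`,
#'   `translation_pct`, `translation_raw_pct`, `disc_height_pct`,
#'   `bisectrix`, `mean_depth_px`.
#' @export
iv_pose <- function(upper, lower, neutral = NULL) {
  stopifnot(inherits(upper, "qf_vertebra_frame"),
            inherits(lower, "qf_vertebra_frame"))
  rot <- signed_angle(lower$axis, upper$axis)
  if (abs(abs(rot) - 180) < 1) {
    stop("antiparallel vertebral axes: intervertebral rotation near 180 degrees",
         call. = FALSE)
  }
  bis <- unitize(upper$axis + lower$axis)
  perp <- c(-bis[2], bis[1])
  d <- upper$center - lower$center
  if (sum(d * perp) < 0) perp <- -perp  # point from lower towards upper
  mean_depth <- (upper$body_depth + lower$body_depth) / 2
  trans_raw <- 100 * sum(d * bis) / mean_depth
  sep <- sum(d * perp)
  disc <- 100 * (sep - (upper$body_height + lower$body_height) / 2) / mean_depth
  structure(
    list(
      rotation_deg = rot,
      translation_pct = trans_raw - (neutral$translation_raw_pct %||% 0),
      translation_raw_pct = trans_raw,
      disc_height_pct = disc,
      bisectrix = bis,
      mean_depth_px = mean_depth
    ),
    class = "qf_iv_pose"
  )
}

#' Convert a translation in percent body depth to millimetres
#'
#' @param pct translation as a percentage of vertebral body depth.
#' @param depth_mm vertebral body depth in millimetres.
#' @return Translation in millimetres.
#' @examples
#' translation_pct_to_mm(2.60, 35)  # 0.91 mm
#' @export
translation_pct_to_mm <- function(pct, depth_mm) {
  pct / 100 * depth_mm
}

# Vectorized corner-frame quantities for a 4 x 2 x nframe corner array.
# Returns a list of nframe-length vectors / nframe x 2 matrices.
frobin_series <- function(corners_arr) {
  am <- (corners_arr[1, , ] + corners_arr[4, , ]) / 2  # 2 x nf
  pm <- (corners_arr[2, , ] + corners_arr[3, , ]) / 2
  sm <- (corners_arr[1, , ] + corners_arr[2, , ]) / 2
  im <- (corners_arr[3, , ] + corners_arr[4, , ]) / 2
  ax <- am - pm
  depth <- sqrt(colSums(ax^2))
  list(
    center = (corners_arr[1, , ] + corners_arr[2, , ] +
                corners_arr[3, , ] + corners_arr[4, , ]) / 4,
    axis = sweep(ax, 2, depth, `/`),
    depth = depth,
    height = sqrt(colSums((sm - im)^2))
  )
}

# Vectorized intervertebral pose over frames; upper/lower are frobin_series
# lists.  Returns tibble with per-frame rotation, raw translation %, disc %.
iv_pose_series <- function(upper, lower) {
  cross <- lower$axis[1, ] * upper$axis[2, ] - lower$axis[2, ] * upper$axis[1, ]
  dot <- colSums(lower$axis * upper$axis)
  rot <- rad2deg(atan2(-cross, dot))
  bis <- upper$axis + lower$axis
  bis <- sweep(bis, 2, sqrt(colSums(bis^2)), `/`)
  perp <- rbind(-bis[2, ], bis[1, ])
  d <- upper$center - lower$center
  sgn <- ifelse(colSums(d * perp) < 0, -1, 1)
  mean_depth <- (upper$depth + lower$depth) / 2
  trans_raw <- 100 * colSums(d * bis) / mean_depth
  sep <- sgn * colSums(d * perp)
  disc <- 100 * (sep - (upper$height + lower$height) / 2) / mean_depth
  tibble::tibble(
    frame = seq_along(rot) - 1L,
    iv_rot_deg = rot,
    iv_trans_raw_pct = trans_raw,
    disc_height_pct = disc,
    mean_depth_px = mean_depth
  )
}

# Snap a point to the strongest gradient along direction `normal` within
# +/- radius, with quarter-pixel sampling and parabolic refinement.
snap_to_gradient <- function(image, pt, normal, radius = 3, step = 0.25) {
  ts <- seq(-radius, radius, by = step)
  xs <- pt[1] + ts * normal[1]
  ys <- pt[2] + ts * normal[2]
  g <- gradient_magnitude_at(image, xs, ys)
  g[is.na(g)] <- -Inf
  i <- which.max(g)
  if (!is.finite(g[i]) || g[i] < .Machine$double.eps) {
    return(list(pt = pt, found = FALSE))
  }
  # a linear-ramp edge gives a flat-topped gradient profile: centre on the
  # contiguous plateau around the maximum rather than its first sample
  lo <- i; hi <- i
  thr <- g[i] - max(1e-9, 0.02 * g[i])
  while (lo > 1 && is.finite(g[lo - 1]) && g[lo - 1] >= thr) lo <- lo - 1
  while (hi < length(ts) && is.finite(g[hi + 1]) && g[hi + 1] >= thr) hi <- hi + 1
  t_best <- mean(ts[lo:hi])
  if (lo == hi && i > 1 && i < length(ts) &&
      is.finite(g[i - 1]) && is.finite(g[i + 1])) {
    den <- g[i - 1] - 2 * g[i] + g[i + 1]
    if (den < -1e-12) {
      t_best <- t_best + step * 0.5 * (g[i - 1] - g[i + 1]) / den
    }
  }
  list(pt = pt + t_best * normal, found = TRUE)
}

#' Verify and refine vertebral corner locations against image edges
#'
#' Refines a marked corner set so that corners sit on the intersection of the
#' vertebral body's edge lines.  Points along the two body edges adjacent to
#' each corner are snapped to the local intensity-gradient ridge (searching
#' along each edge normal within a small window), a line is fitted through
#' the snapped points of each edge, and the corner is moved to the lines'
#' intersection.  The process is iterated; per-iteration displacement is
#' bounded by the search-window radius.  Where no edge response is found
#' (flat image) the corner is left unchanged and flagged.
#'
#' @param image grayscale image matrix (rows = y, cols = x, 0-based coords).
#' @param corners 4x2 corner matrix in canonical role order.
#' @param n_iterations number of refinement passes (default 4).
#' @param window_radius half-width in pixels of the gradient search window.
#' @return A list with `corners` (refined 4x2 matrix) and `flagged` (logical
#'   vector, `TRUE` where no edge response was found).
#' @export
refine_corners <- function(image, corners, n_iterations = 4, window_radius = 3) {
  stopifnot(n_iterations >= 1)
  corners <- as.matrix(corners)
  flagged <- rep(FALSE, 4)
  # sample most of each edge (clear of the rounded corners) so the fitted
  # line needs little extrapolation back to the corner
  edge_fracs <- seq(0.18, 0.82, by = 0.08)
  for (iter in seq_len(n_iterations)) {
    new_corners <- corners
    for (ci in 1:4) {
      # the two edges adjacent to corner ci (to previous and next corner)
      nb <- c(ifelse(ci == 1, 4, ci - 1), ifelse(ci == 4, 1, ci + 1))
      lines <- vector("list", 2)
      ok <- TRUE
      for (ei in 1:2) {
        other <- corners[nb[ei], ]
        dir <- unitize(other - corners[ci, ])
        nrm <- c(-dir[2], dir[1])
        pts <- matrix(NA_real_, length(edge_fracs), 2)
        found_any <- FALSE
        for (k in seq_along(edge_fracs)) {
          p0 <- corners[ci, ] + edge_fracs[k] * (other - corners[ci, ])
          sn <- snap_to_gradient(image, p0, nrm, radius = window_radius)
          pts[k, ] <- sn$pt
          found_any <- found_any || sn$found
        }
        if (!found_any) { ok <- FALSE; break }
        # total-least-squares line through snapped points
        ctr <- colMeans(pts)
        sv <- svd(sweep(pts, 2, ctr))
        lines[[ei]] <- list(p = ctr, d = sv$v[, 1])
      }
      if (!ok) { flagged[ci] <- TRUE; next }
      # intersect the two edge lines
      A <- cbind(lines[[1]]$d, -lines[[2]]$d)
      if (abs(det(A)) < 1e-9) { flagged[ci] <- TRUE; next }
      t12 <- solve(A, lines[[2]]$p - lines[[1]]$p)
      cand <- lines[[1]]$p + t12[1] * lines[[1]]$d
      move <- cand - corners[ci, ]
      mn <- vnorm(move)
      if (mn > window_radius) move <- move * window_radius / mn
      new_corners[ci, ] <- corners[ci, ] + move
      flagged[ci] <- FALSE
    }
    corners <- new_corners
  }
  list(corners = corners, flagged = flagged)
}

#' Snap a tracking polygon to nearby image edges
#'
#' A simplified edge-refinement in the spirit of active-contour template
#' fitting: each polygon vertex is moved along its local outward normal to
#' the strongest intensity gradient within a search band, and smoothness is
#' enforced by bounding the difference between the displacements of
#' neighbouring vertices.
#'
#' @param image grayscale image matrix.
#' @param polygon n x 2 matrix of polygon vertices (closed implicitly).
#' @param band half-width of the normal search band in pixels.
#' @param max_kink maximum allowed difference between adjacent vertex
#'   displacements (pixels); larger differences are relaxed towards the
#'   neighbour average.
#' @return The refined polygon (n x 2 matrix).
#' @export
snap_contour <- function(image, polygon, band = 3, max_kink = 1) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  disp <- numeric(n)
  normals <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    prv <- polygon[ifelse(i == 1, n, i - 1), ]
    nxt <- polygon[i %% n + 1, ]
    tang <- unitize(nxt - prv)
    normals[i, ] <- c(-tang[2], tang[1])
    sn <- snap_to_gradient(image, polygon[i, ], normals[i, ], radius = band)
    disp[i] <- if (sn$found) sum((sn$pt - polygon[i, ]) * normals[i, ]) else 0
  }
  # bounded-difference smoothing of displacements
  for (pass in 1:3) {
    avg <- (disp[c(n, seq_len(n - 1))] + disp[c(seq_len(n)[-1], 1)]) / 2
    kink <- disp - avg
    disp <- avg + pmax(pmin(kink, max_kink), -max_kink)
  }
  polygon + disp * normals
}
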