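#' Construct a fluoroscopic image sequence
#'
#' Container for an ordered grayscale frame stack with acquisition metadata.
#' Frames are numeric matrices (rows = y, columns = x) holding grey levels in
#' `[0, 2^bit_depth - 1]`.
#'
#' @param frames list of numeric matrices, all the same dimensions.
#' @param frame_rate frames per second (`NA` if unknown; time-based
#'   operations will refuse to run).
#' @param bit_depth stored bits per pixel (8, 10, 12 or 16).
#' @param pixel_spacing millimetres per pixel, or `NA` if unknown (then
#'   translations are reported only in percent body depth).
#' @param plane `"sagittal"` or `"coronal"`.
#' @param orientation_config `"recumbent_passive"` or `"weightbearing_active"`.
#' @param direction motion direction label (`"flexion"`, `"extension"`,
#'   `"left_bend"`, `"right_bend"`).
#' @param meta free-form metadata list (trunk angle series, degradation
#'   settings, seeds, ...).
#' @return An object of class `qf_sequence`.
#' @export
qf_sequence <- function(frames, frame_rate = NA_real_, bit_depth = 8L,
                        pixel_spacing = NA_real_, plane = "sagittal",
                        orientation_config = "recumbent_passive",
                        direction = "flexion", meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 10L, 12L, 16L)) {
    stop("bit_depth must be one of 8, 10, 12, 16", call. = FALSE)
  }
  if (!is.na(frame_rate) && frame_rate <= 0) {
    stop("frame_rate must be positive", call. = FALSE)
  }
  plane <- match.arg(plane, c("sagittal", "coronal"))
  orientation_config <- match.arg(orientation_config,
                                  c("recumbent_passive", "weightbearing_active"))
  structure(
    list(frames = frames, frame_rate = frame_rate, bit_depth = as.integer(bit_depth),
         pixel_spacing = pixel_spacing, plane = plane,
         orientation_config = orientation_config, direction = direction,
         meta = meta),
    class = "qf_sequence"
  )
}

#' @export
print.qf_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<qf_sequence> %d frames of %dx%d, %d-bit, %s fps, %s plane, %s, %s\n",
    length(x$frames), d[2], d[1], x$bit_depth,
    ifelse(is.na(x$frame_rate), "unknown", format(x$frame_rate)),
    x$plane, x$orientation_config, x$direction))
  cat(sprintf("  pixel spacing: %s mm/px\n",
              ifelse(is.na(x$pixel_spacing), "unknown", format(x$pixel_spacing))))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a `qf_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$frames)

# Rolling average of the window ending at frame i (1-based), used to damp
# frame noise before correlation.
rolled_frame <- function(seq, i, window = 2L) {
  lo <- max(1L, i - window + 1L)
  if (lo == i) return(seq$frames[[i]])
  Reduce(`+`, seq$frames[lo:i]) / (i - lo + 1L)
}
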