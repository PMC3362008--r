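#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot continuous intervertebral and trunk motion
#'
#' Reproduces the standard continuous-motion display: the median
#' intervertebral angle of every level against frame, with the
#' across-marking envelope shaded and the trunk angle overlaid (rescaled to
#' the intervertebral axis).
#'
#' @param object a `qf_kinematics`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.qf_kinematics <- function(object, ...) {
  rot <- object$rotation
  p <- ggplot2::ggplot(rot, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.4) +
    ggplot2::facet_wrap(~level, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "intervertebral rotation (deg)",
                  title = "Continuous intervertebral rotation",
                  subtitle = "median of marking combinations; envelope shaded") +
    ggplot2::theme_minimal()
  if (!is.null(object$trunk)) {
    sc <- max(abs(rot$median), 1e-6) / max(abs(object$trunk), 1e-6)
    tr <- tibble::tibble(frame = seq_along(object$trunk) - 1L,
                         trunk = object$trunk * sc)
    p <- p + ggplot2::geom_line(data = tr,
                                ggplot2::aes(y = .data$trunk),
                                colour = "steelblue", linetype = 2)
  }
  p
}

#' Plot the translational motion path of one level
#'
#' Translation (percent body depth, referenced to the neutral frame)
#' against frame with the all-marking envelope shaded, in the style of the
#' standard translational motion-path display.
#'
#' @param kin a `qf_kinematics` with translation computed.
#' @param level level label (default: the most caudal level).
#' @return A ggplot object.
#' @export
plot_translation_path <- function(kin, level = NULL) {
  stopifnot(inherits(kin, "qf_kinematics"))
  if (is.null(kin$translation)) kin <- continuous_translation(kin)
  level <- level %||% utils::tail(kin$levels, 1)
  tr <- kin$translation[kin$translation$level == level, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$trans_min_pct,
                                      ymax = .data$trans_max_pct),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$trans_median_pct),
                       linewidth = 0.4) +
    ggplot2::labs(x = "frame", y = "translation (% body depth)",
                  title = paste("Translational motion path at", level)) +
    ggplot2::theme_minimal()
}

#' Plot laxity fits: intervertebral versus trunk motion near neutral
#'
#' @param object a `qf_laxity` tibble from [neutral_zone_laxity()].
#' @param ... unused.
#' @return A ggplot object (slope ratio per level).
#' @export
autoplot.qf_laxity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "laxity slope ratio (IV / global)",
                  title = "Neutral zone laxity") +
    ggplot2::theme_minimal()
}

#' Plot an accuracy study
#'
#' @param object a `qf_accuracy`.
#' @param ... unused.
#' @return A ggplot of RMS errors per motion direction.
#' @export
autoplot.qf_accuracy <- function(object, ...) {
  d <- tidyr::pivot_longer(object$by_direction,
                           cols = c("rms_rotation_deg", "rms_translation_pct"),
                           names_to = "measure", values_to = "rms")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$direction, y = .data$rms)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "RMS error",
                  title = "Synthetic calibration accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a trunk motion program
#'
#' @param object a `qf_motion_program`.
#' @param ... unused.
#' @return A ggplot of the trunk angle series against time.
#' @export
autoplot.qf_motion_program <- function(object, ...) {
  d <- tibble::tibble(time_s = object$time_s,
                      angle = object$trunk_angle_series)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "trunk angle (deg)",
                  title = sprintf("%s program, %g deg outward",
                                  object$direction, object$outward_range)) +
    ggplot2::theme_minimal()
}
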