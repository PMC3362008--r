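#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-level summary indices of a kinematic analysis
#'
#' @param x a `qf_kinematics` (indices are computed on the fly if missing
#'   and a trunk series is available).
#' @param ... unused.
#' @return A tibble with one row per intervertebral level.
#' @export
tidy.qf_kinematics <- function(x, ...) {
  if (is.null(x$indices) && !is.null(x$trunk)) x <- motion_indices(x)
  if (is.null(x$indices)) stop("no indices available; run motion_indices()",
                               call. = FALSE)
  x$indices
}

#' @rdname tidy.qf_kinematics
#' @export
glance.qf_kinematics <- function(x, ...) {
  tibble::tibble(
    n_levels = length(x$levels),
    n_frames = max(x$rotation$frame) + 1L,
    n_curves_per_level = nrow(dplyr::distinct(
      x$curves, .data$marking_upper, .data$marking_lower)),
    frame_rate = x$frame_rate %||% NA_real_,
    total_rotation_range_deg = sum(tapply(
      x$rotation$median, x$rotation$level, function(v) max(v) - min(v))))
}

#' Tidy an accuracy report
#' @param x a `qf_accuracy`.
#' @param ... unused.
#' @return Per-direction RMS errors as a tibble.
#' @export
tidy.qf_accuracy <- function(x, ...) x$by_direction

#' @rdname tidy.qf_accuracy
#' @export
glance.qf_accuracy <- function(x, ...) {
  tibble::tibble(
    n_sequences = x$settings$n,
    rms_rotation_deg = x$overall$rms_rotation_deg,
    rms_translation_pct = x$overall$rms_translation_pct,
    out_of_plane_deg = x$settings$out_of_plane_deg,
    seed = x$settings$seed)
}

#' Tidy a repeatability report
#' @param x a `qf_repeatability`.
#' @param ... unused.
#' @return Per-run per-level ranges as a tibble.
#' @export
tidy.qf_repeatability <- function(x, ...) x$per_run

#' @rdname tidy.qf_repeatability
#' @export
glance.qf_repeatability <- function(x, ...) {
  tibble::tibble(
    n_sequences = x$settings$n_sequences,
    n_runs = x$settings$n_runs,
    marking_perturbation_sd = x$settings$marking_perturbation_sd,
    inter_rms_rotation_deg = x$inter$rms_rotation_deg,
    inter_rms_translation_pct = x$inter$rms_translation_pct,
    intra_rms_rotation_deg = x$intra$rms_rotation_deg,
    intra_rms_translation_pct = x$intra$rms_translation_pct)
}

#' Tidy a protocol report
#' @param x a `qf_protocol_report`.
#' @param ... unused.
#' @return The checks tibble (rule, value, bound, pass).
#' @export
tidy.qf_protocol_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.qf_protocol_report
#' @export
glance.qf_protocol_report <- function(x, ...) {
  tibble::tibble(n_checks = nrow(x), n_failed = sum(!x$pass),
                 overall_pass = attr(x, "overall"))
}
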