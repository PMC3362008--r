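#' Validate acquisition metadata against the consensus protocol
#'
#' Checks an image sequence (and optionally its motion program) against the
#' consensus acquisition minima: at least 12.5 fps, 8-bit depth and 512x512
#' pixels; 8-12 s motion-direction sweeps with 0.5-1 s ramps starting from
#' neutral; and the standardised ranges (40 degrees recumbent in every
#' direction; 60 degrees flexion / 20 degrees extension / 40 degrees bends
#' when weight bearing).
#'
#' @param seq a [qf_sequence()].
#' @param program optional [make_motion_program()] used for the acquisition.
#' @return A `qf_protocol_report`: tibble of checks (`rule`, `value`,
#'   `bound`, `pass`) with attribute `overall` (`TRUE` only if every check
#'   passes).
#' @export
validate_protocol <- function(seq, program = NULL) {
  stopifnot(inherits(seq, "qf_sequence"))
  d <- dim(seq$frames[[1]])
  checks <- list(
    list(rule = "frame_rate >= 12.5 fps", value = seq$frame_rate, bound = 12.5,
         pass = !is.na(seq$frame_rate) && seq$frame_rate >= 12.5),
    list(rule = "bit_depth >= 8", value = seq$bit_depth, bound = 8,
         pass = seq$bit_depth >= 8),
    list(rule = "image width >= 512 px", value = d[2], bound = 512,
         pass = d[2] >= 512),
    list(rule = "image height >= 512 px", value = d[1], bound = 512,
         pass = d[1] >= 512))
  if (!is.null(program)) {
    expected_range <- if (seq$orientation_config == "weightbearing_active") {
      switch(program$direction, flexion = 60, extension = 20, 40)
    } else 40
    checks <- c(checks, list(
      list(rule = "sweep_duration within 8-12 s",
           value = program$sweep_duration, bound = NA_real_,
           pass = program$sweep_duration >= 8 && program$sweep_duration <= 12),
      list(rule = "ramp_interval within 0.5-1 s",
           value = program$ramp_interval, bound = NA_real_,
           pass = program$ramp_interval >= 0.5 && program$ramp_interval <= 1),
      list(rule = "acquisition starts at neutral",
           value = program$trunk_angle_series[1], bound = 0.5,
           pass = abs(program$trunk_angle_series[1]) <= 0.5),
      list(rule = sprintf("outward range is the standardised %g degrees (%s, %s)",
                          expected_range, seq$orientation_config,
                          program$direction),
           value = program$outward_range, bound = expected_range,
           pass = abs(program$outward_range - expected_range) <= 0.5)))
  }
  rep <- dplyr::bind_rows(lapply(checks, tibble::as_tibble))
  attr(rep, "overall") <- all(rep$pass)
  class(rep) <- c("qf_protocol_report", class(rep))
  rep
}

# Run the full measurement pipeline on one phantom sequence and return the
# per-level measured ranges next to truth.
measure_phantom <- function(seqn, truth, landmarks, cfg) {
  poses <- track_sequence(seqn, landmarks, cfg)
  poses <- smooth_keypoints(poses, cfg)
  kin <- intervertebral_series(poses, trunk = seqn$meta$trunk_angle_series)
  kin <- continuous_translation(kin)
  meas <- kin$rotation |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(rot_range = max(.data$median) - min(.data$median),
                     .groups = "drop") |>
    dplyr::left_join(
      kin$translation |>
        dplyr::group_by(.data$level) |>
        dplyr::summarise(
          trans_range = max(.data$trans_median_pct) - min(.data$trans_median_pct),
          .groups = "drop"),
      by = "level")
  tru <- truth$levels |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(rot_range_true = max(.data$iv_rot_deg) - min(.data$iv_rot_deg),
                     trans_range_true = max(.data$iv_trans_pct) - min(.data$iv_trans_pct),
                     .groups = "drop")
  dplyr::left_join(meas, tru, by = "level")
}

#' Synthetic calibration accuracy study
#'
#' Generates `n` protocol-conformant degraded phantom sequences (every
#' second one additionally foreshortened by the out-of-plane tilt), runs
#' the full tracking and kinematics pipeline on each, and reports the RMS
#' error of the measured per-level maximum intervertebral rotation and
#' translation ranges against the exact ground truth, per motion direction
#' and pooled.
#'
#' @param n number of sequences (default 20).
#' @param spec a [phantom_spec()]; its noise model is used as-is.
#' @param cfg a [tracker_config()].
#' @param seed master seed; every render, degradation and marking derives a
#'   sub-seed from it, so the study is fully reproducible.
#' @param directions motion directions cycled over the sequences.
#' @param out_of_plane_deg tilt applied to every second sequence (degrees).
#' @param sweep_duration,frame_rate program parameters (protocol-conformant
#'   defaults: 8 s sweeps at 15 fps, 40 degree recumbent range).
#' @param marking_jitter_sd Gaussian corner/template placement error per
#'   marking in pixels.
#' @param n_markings markings per vertebra (default 5).
#' @return A `qf_accuracy` object: list with `per_level` (sequence,
#'   direction, distorted, level, measured and true ranges, errors),
#'   `by_direction` (RMS errors per direction), `overall` (pooled RMS
#'   rotation error in degrees and translation error in percent body depth,
#'   translation pooled over flexion/extension), and `settings`.
#' @export
accuracy_study <- function(n = 20, spec = phantom_spec(),
                           cfg = tracker_config(), seed = 42,
                           directions = c("flexion", "extension",
                                          "left_bend", "right_bend"),
                           out_of_plane_deg = 10,
                           sweep_duration = 8, frame_rate = 15,
                           marking_jitter_sd = 0.5, n_markings = 5) {
  if (n < 1) stop("accuracy study needs at least one sequence", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dir <- directions[(i - 1) %% length(directions) + 1]
    distorted <- i %% 2 == 0
    spec_i <- spec
    spec_i$out_of_plane_deg <- if (distorted) out_of_plane_deg else 0
    prog <- make_motion_program(dir, 40, sweep_duration, 0.5, frame_rate)
    rs <- render_sequence(spec_i, prog, seed = sub_seed(seed, i))
    seqn <- apply_degradations(rs$sequence, spec_i,
                               seed = sub_seed(seed, 1000 + i))
    lmk <- phantom_landmarks(rs$truth, seqn, n_markings = n_markings,
                             jitter_sd = marking_jitter_sd,
                             seed = sub_seed(seed, 2000 + i))
    m <- measure_phantom(seqn, rs$truth, lmk, cfg)
    rows[[i]] <- dplyr::mutate(m, sequence = i, direction = dir,
                               distorted = distorted,
                               rot_err = .data$rot_range - .data$rot_range_true,
                               trans_err = .data$trans_range - .data$trans_range_true)
  }
  per_level <- dplyr::bind_rows(rows)
  rms <- function(x) sqrt(mean(x^2))
  by_direction <- per_level |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      n_sequences = dplyr::n_distinct(.data$sequence),
      rms_rotation_deg = rms(.data$rot_err),
      rms_translation_pct = rms(.data$trans_err), .groups = "drop")
  sag <- per_level$direction %in% c("flexion", "extension")
  overall <- list(
    rms_rotation_deg = rms(per_level$rot_err),
    rms_translation_pct = if (any(sag)) rms(per_level$trans_err[sag]) else NA_real_)
  structure(
    list(per_level = per_level, by_direction = by_direction,
         overall = overall,
         settings = list(n = n, seed = seed,
                         out_of_plane_deg = out_of_plane_deg,
                         noise_model = spec$noise_model,
                         sweep_duration = sweep_duration,
                         frame_rate = frame_rate,
                         marking_jitter_sd = marking_jitter_sd,
                         n_markings = n_markings)),
    class = "qf_accuracy")
}

#' @export
print.qf_accuracy <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<qf_accuracy> %d synthetic sequences (tilt %g deg on half; gaussian_sd %g, poisson %g, marking jitter %g px)\n",
    s$n, s$out_of_plane_deg, s$noise_model$gaussian_sd,
    s$noise_model$poisson_scale, s$marking_jitter_sd))
  cat(sprintf("  RMS rotation error:    %.3f deg\n", x$overall$rms_rotation_deg))
  cat(sprintf("  RMS translation error: %.3f %% body depth (flexion/extension)\n",
              x$overall$rms_translation_pct))
  cat("  (phantom motion magnitudes and tissue model are synthetic stand-ins)\n")
  invisible(x)
}

#' Simulated re-marking repeatability study
#'
#' Emulates repeated observer markings by independently perturbing the
#' initial landmark placements with Gaussian noise of the stated SD,
#' re-running the tracking pipeline for each run, and pooling the inter-run
#' RMS differences of the per-level rotation and translation ranges.  This
#' quantifies robustness to initialization; it is not a claim of
#' equivalence to human observers.
#'
#' @param n_sequences phantom sequences (default 10).
#' @param n_runs independent re-markings per sequence (default 3).
#' @param marking_perturbation_sd corner perturbation SD in pixels.
#' @param spec,cfg phantom and tracker configuration.
#' @param seed master seed.
#' @param directions directions cycled over sequences.
#' @param sweep_duration,frame_rate program parameters.
#' @param n_markings markings per vertebra per run.
#' @return A `qf_repeatability` object: list with `per_run` (sequence, run,
#'   level, ranges), `inter` (mean pairwise inter-run RMS difference of
#'   rotation, degrees, and translation, percent depth), `intra` (mean RMS
#'   pairwise difference among the individual marking-combination curves
#'   within a run) and `settings`.
#' @export
repeatability_study <- function(n_sequences = 10, n_runs = 3,
                                marking_perturbation_sd = 1.5,
                                spec = phantom_spec(), cfg = tracker_config(),
                                seed = 7,
                                directions = c("flexion", "extension"),
                                sweep_duration = 8, frame_rate = 15,
                                n_markings = 5) {
  if (n_sequences < 1) stop("need at least one sequence", call. = FALSE)
  if (n_runs < 1) stop("need at least one run", call. = FALSE)
  if (n_runs == 1) {
    warning("a single run defines intra-run repeatability only; ",
            "inter-run RMS is undefined")
  }
  per_run <- list(); intra_vals_rot <- c(); intra_vals_tr <- c()
  for (s in seq_len(n_sequences)) {
    dir <- directions[(s - 1) %% length(directions) + 1]
    prog <- make_motion_program(dir, 40, sweep_duration, 0.5, frame_rate)
    rs <- render_sequence(spec, prog, seed = sub_seed(seed, s))
    seqn <- apply_degradations(rs$sequence, spec,
                               seed = sub_seed(seed, 1000 + s))
    for (r in seq_len(n_runs)) {
      lmk <- phantom_landmarks(rs$truth, seqn, n_markings = n_markings,
                               jitter_sd = marking_perturbation_sd,
                               seed = sub_seed(seed, 10000 + 100 * s + r))
      poses <- track_sequence(seqn, lmk, cfg)
      poses <- smooth_keypoints(poses, cfg)
      kin <- intervertebral_series(poses,
                                   trunk = seqn$meta$trunk_angle_series)
      kin <- continuous_translation(kin)
      med <- kin$rotation |>
        dplyr::group_by(.data$level) |>
        dplyr::summarise(rot_range = max(.data$median) - min(.data$median),
                         .groups = "drop") |>
        dplyr::left_join(
          kin$translation |>
            dplyr::group_by(.data$level) |>
            dplyr::summarise(
              trans_range = max(.data$trans_median_pct) -
                min(.data$trans_median_pct), .groups = "drop"),
          by = "level")
      per_run[[length(per_run) + 1]] <-
        dplyr::mutate(med, sequence = s, run = r, direction = dir)
      # intra-run: spread among individual marking-combination curves
      comb_rot <- kin$curves |>
        dplyr::group_by(.data$level, .data$marking_upper, .data$marking_lower) |>
        dplyr::summarise(rng = max(.data$iv_rot_deg) - min(.data$iv_rot_deg),
                         .groups = "drop")
      comb_tr <- kin$translation_curves |>
        dplyr::group_by(.data$level, .data$marking_upper, .data$marking_lower) |>
        dplyr::summarise(rng = max(.data$trans_pct) - min(.data$trans_pct),
                         .groups = "drop")
      intra_vals_rot <- c(intra_vals_rot, vapply(
        split(comb_rot$rng, comb_rot$level), pairwise_rms, numeric(1)))
      intra_vals_tr <- c(intra_vals_tr, vapply(
        split(comb_tr$rng, comb_tr$level), pairwise_rms, numeric(1)))
    }
  }
  per_run <- dplyr::bind_rows(per_run)
  inter <- list(rms_rotation_deg = NA_real_, rms_translation_pct = NA_real_)
  if (n_runs >= 2) {
    pairs <- utils::combn(n_runs, 2)
    dif <- function(col) {
      vals <- apply(pairs, 2, function(p) {
        a <- per_run[per_run$run == p[1], ]
        b <- per_run[per_run$run == p[2], ]
        key <- paste(a$sequence, a$level)
        m <- match(key, paste(b$sequence, b$level))
        sqrt(mean((a[[col]] - b[[col]][m])^2))
      })
      mean(vals)
    }
    inter <- list(rms_rotation_deg = dif("rot_range"),
                  rms_translation_pct = dif("trans_range"))
  }
  structure(
    list(per_run = per_run, inter = inter,
         intra = list(rms_rotation_deg = mean(intra_vals_rot),
                      rms_translation_pct = mean(intra_vals_tr)),
         settings = list(n_sequences = n_sequences, n_runs = n_runs,
                         marking_perturbation_sd = marking_perturbation_sd,
                         seed = seed, noise_model = spec$noise_model,
                         sweep_duration = sweep_duration,
                         frame_rate = frame_rate, n_markings = n_markings)),
    class = "qf_repeatability")
}

pairwise_rms <- function(x) {
  if (length(x) < 2) return(0)
  d <- outer(x, x, `-`)
  sqrt(mean(d[upper.tri(d)]^2))
}

#' @export
print.qf_repeatability <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<qf_repeatability> %d sequences x %d runs, marking perturbation SD %.2f px\n",
    s$n_sequences, s$n_runs, s$marking_perturbation_sd))
  cat(sprintf("  inter-run mean RMS rotation:    %.3f deg\n",
              x$inter$rms_rotation_deg))
  cat(sprintf("  inter-run mean RMS translation: %.3f %% body depth\n",
              x$inter$rms_translation_pct))
  cat(sprintf("  intra-run mean RMS rotation:    %.3f deg\n",
              x$intra$rms_rotation_deg))
  cat("  (phantom motion magnitudes and tissue model are synthetic stand-ins)\n")
  invisible(x)
}
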