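#' Synthetic annulus motion parameters
#'
#' Bundles everything the synthetic detection-stream generator needs: the
#' true longitudinal excursion of each of the six annular walls, the
#' amplitude of transverse and rotational annular motion, acquisition timing
#' (heart rate, volume rate, number of cardiac cycles), and the artifact
#' model (isotropic detection noise, per-point dropout, displaced outliers).
#'
#' Defaults emulate single-beat full-volume 3D transesophageal acquisition
#' in sedated postoperative patients: about 19 volumes per second, 10
#' cardiac cycles per recording, and per-wall excursions matching typical
#' postoperative values where septal walls move less than lateral walls.
#'
#' @param per_wall_excursion named numeric vector of true longitudinal
#'   excursion in mm for the six walls `anterior`, `inferior`,
#'   `anterolateral`, `inferoseptal`, `anteroseptal`, `inferolateral`.
#' @param transverse_amplitude mm of annular motion perpendicular to the
#'   long axis.
#' @param rotation_amplitude_deg rigid in-plane rotation of the detected
#'   landmark pattern about the long axis, per cycle (degrees).
#' @param heart_rate beats per minute.
#' @param volume_rate volumes per second (temporal resolution).
#' @param n_cycles number of cardiac cycles in the recording.
#' @param noise_sd mm isotropic Gaussian detection noise per candidate point.
#' @param dropout_prob per-point probability that a candidate detection is
#'   missing.
#' @param outlier_prob per-point probability that a candidate detection is
#'   displaced by an artifact.
#' @param outlier_magnitude mm displacement of artifact points; keep above
#'   the 5 mm filter thresholds so artifacts are filterable.
#' @param lax_angle_deg azimuth of the long-axis (LAX) view plane.
#' @param annulus_radius_mm radius of the annular ring.
#' @param tilt_deg tilt of the annular ring plane relative to the plane
#'   orthogonal to the long axis (kept small; the annulus is near-planar).
#' @param points_per_arc number of candidate detections emitted inside each
#'   wall arc per volume.
#' @param seed integer seed; all randomness in the generator derives from it.
#'
#' @return An object of class `annulus_motion_params`.
#' @seealso [simulate_recording()]
#' @export
annulus_motion_params <- function(per_wall_excursion = c(
                                    anterior = 4.9, inferior = 5.6,
                                    anterolateral = 6.1, inferoseptal = 5.4,
                                    anteroseptal = 4.6, inferolateral = 6.2),
                                  transverse_amplitude = 2,
                                  rotation_amplitude_deg = 5,
                                  heart_rate = 75,
                                  volume_rate = 19,
                                  n_cycles = 10,
                                  noise_sd = 0.3,
                                  dropout_prob = 0.05,
                                  outlier_prob = 0.02,
                                  outlier_magnitude = 12,
                                  lax_angle_deg = 0,
                                  annulus_radius_mm = 15,
                                  tilt_deg = 5,
                                  points_per_arc = 3,
                                  seed = 1L) {
  if (!is.numeric(per_wall_excursion) ||
      !setequal(names(per_wall_excursion), WALLS))
    stop_param(
      "`per_wall_excursion` must be a numeric vector named with the 6 walls: %s",
      paste(WALLS, collapse = ", "))
  per_wall_excursion <- per_wall_excursion[WALLS]
  if (any(!is.finite(per_wall_excursion)) || any(per_wall_excursion < 0))
    stop_param("wall excursions must be finite and >= 0")
  check_number(transverse_amplitude, "transverse_amplitude", lower = 0)
  check_number(rotation_amplitude_deg, "rotation_amplitude_deg", lower = 0)
  check_number(heart_rate, "heart_rate", lower = 0, strict_lower = TRUE)
  check_number(volume_rate, "volume_rate", lower = 0, strict_lower = TRUE)
  check_number(n_cycles, "n_cycles", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(dropout_prob, "dropout_prob", lower = 0, upper = 1)
  check_number(outlier_prob, "outlier_prob", lower = 0, upper = 1)
  check_number(outlier_magnitude, "outlier_magnitude", lower = 0)
  check_number(lax_angle_deg, "lax_angle_deg")
  check_number(annulus_radius_mm, "annulus_radius_mm", lower = 0,
               strict_lower = TRUE)
  check_number(tilt_deg, "tilt_deg", lower = 0, upper = 10)
  check_number(points_per_arc, "points_per_arc", lower = 1)
  check_number(seed, "seed")
  structure(list(
    per_wall_excursion = per_wall_excursion,
    transverse_amplitude = transverse_amplitude,
    rotation_amplitude_deg = rotation_amplitude_deg,
    heart_rate = heart_rate,
    volume_rate = volume_rate,
    n_cycles = as.integer(n_cycles),
    noise_sd = noise_sd,
    dropout_prob = dropout_prob,
    outlier_prob = outlier_prob,
    outlier_magnitude = outlier_magnitude,
    lax_angle_deg = lax_angle_deg,
    annulus_radius_mm = annulus_radius_mm,
    tilt_deg = tilt_deg,
    points_per_arc = as.integer(points_per_arc),
    seed = as.integer(seed)
  ), class = "annulus_motion_params")
}

#' Test-retest simulation parameters
#'
#' Parameters for simulating a linked-replicates method-comparison table:
#' each subject is measured several times in rapid succession by two
#' methods, with replicate r of method A and replicate r of method B taken
#' under the same conditions.  Values are generated as
#' subject effect + shared replicate effect + method bias + method-specific
#' residual.
#'
#' Defaults match a postoperative test-retest protocol: triplicate
#' recordings, population MAPSE around 6.6 +/- 2.0 mm, and per-method
#' residual SDs consistent with least significant changes of about 0.9 mm
#' (reference method A) and 1.6 mm (automatic method B) for a single
#' measurement.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param true_mapse_mean,true_mapse_sd population mean and SD of the
#'   subject-level true MAPSE (mm).
#' @param within_subject_sd SD of the replicate-to-replicate effect shared
#'   by both methods within a replicate occasion (mm).
#' @param method_bias systematic offset of method B relative to method A
#'   (mm); negative means B reads lower.
#' @param method_sd_a,method_sd_b residual measurement SD of each method
#'   (mm).
#' @param replicates_per_subject replicates per subject and method (>= 2).
#' @param seed integer seed.
#'
#' @return An object of class `test_retest_params`.
#' @seealso [simulate_test_retest()], [fit_linked_replicates()]
#' @export
test_retest_params <- function(n_subjects = 50,
                               true_mapse_mean = 6.6,
                               true_mapse_sd = 2.0,
                               within_subject_sd = 0.5,
                               method_bias = -1.4,
                               method_sd_a = 0.23,
                               method_sd_b = 0.41,
                               replicates_per_subject = 3,
                               seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 2)
  check_number(true_mapse_mean, "true_mapse_mean")
  check_number(true_mapse_sd, "true_mapse_sd", lower = 0)
  check_number(within_subject_sd, "within_subject_sd", lower = 0)
  check_number(method_bias, "method_bias")
  check_number(method_sd_a, "method_sd_a", lower = 0)
  check_number(method_sd_b, "method_sd_b", lower = 0)
  check_number(replicates_per_subject, "replicates_per_subject", lower = 2)
  check_number(seed, "seed")
  structure(list(
    n_subjects = as.integer(n_subjects),
    true_mapse_mean = true_mapse_mean,
    true_mapse_sd = true_mapse_sd,
    within_subject_sd = within_subject_sd,
    method_bias = method_bias,
    method_sd_a = method_sd_a,
    method_sd_b = method_sd_b,
    replicates_per_subject = as.integer(replicates_per_subject),
    seed = as.integer(seed)
  ), class = "test_retest_params")
}

#' Artifact filter configuration
#'
#' Thresholds of the per-volume and per-cycle artifact filters.  A wall
#' point is excluded when it moved more than `max_jump_mm` from its most
#' recent valid position in a preceding volume, or when it lies more than
#' `max_neighbour_dist_mm` from its closest neighbours; a cardiac cycle is
#' discarded when the annulus was detected in less than
#' `min_cycle_detection_frac` of the volumes of that cycle.
#'
#' Boundary conventions: exclusion thresholds are strict (a jump of exactly
#' `max_jump_mm` is retained); the cycle detection fraction is inclusive (a
#' cycle at exactly `min_cycle_detection_frac` is retained).
#'
#' @param max_jump_mm maximum allowed 3D displacement from the preceding
#'   valid sample of the same wall (mm).
#' @param max_neighbour_dist_mm maximum allowed distance to the closest
#'   neighbouring detection (mm).  Applied at two levels: candidate points
#'   within the same wall arc (3D distance) and wall points against the
#'   azimuthally nearest concurrently detected wall (axis-projected
#'   distance; the in-plane separation of walls is annulus geometry, not an
#'   artifact signal).
#' @param min_cycle_detection_frac minimum fraction of volumes within a
#'   cycle in which the wall must be validly detected (in (0, 1]).
#' @param neighbour_mode `"spatial"` compares against concurrently detected
#'   neighbouring walls within the same volume (default); `"temporal"`
#'   compares against the same wall in adjacent volumes (3D distance).
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_jump_mm = 5,
                          max_neighbour_dist_mm = 5,
                          min_cycle_detection_frac = 0.60,
                          neighbour_mode = c("spatial", "temporal")) {
  check_number(max_jump_mm, "max_jump_mm", lower = 0, strict_lower = TRUE)
  check_number(max_neighbour_dist_mm, "max_neighbour_dist_mm", lower = 0,
               strict_lower = TRUE)
  check_number(min_cycle_detection_frac, "min_cycle_detection_frac",
               lower = 0, upper = 1, strict_lower = TRUE)
  neighbour_mode <- match.arg(neighbour_mode)
  structure(list(
    max_jump_mm = max_jump_mm,
    max_neighbour_dist_mm = max_neighbour_dist_mm,
    min_cycle_detection_frac = min_cycle_detection_frac,
    neighbour_mode = neighbour_mode
  ), class = "filter_config")
}

#' Left-ventricular long axis
#'
#' A directed line in 3D along which annular excursion is measured, with
#' positive direction from apex toward base so that systolic descent of the
#' annulus decreases the longitudinal coordinate.
#'
#' @param origin numeric length-3 point (mm) on the axis.
#' @param direction numeric length-3 direction; normalized internally.
#'
#' @return An object of class `long_axis`.
#' @export
long_axis <- function(origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  if (!is.numeric(origin) || length(origin) != 3L || any(!is.finite(origin)))
    stop_param("`origin` must be a finite numeric length-3 vector")
  if (!is.numeric(direction) || length(direction) != 3L ||
      any(!is.finite(direction)))
    stop_param("`direction` must be a finite numeric length-3 vector")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12)
    stop_param("`direction` must be non-zero")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm),
            class = "long_axis")
}

#' @export
print.annulus_motion_params <- function(x, ...) {
  cat("Annulus motion parameters\n")
  cat(sprintf("  excursions (mm): %s\n",
              paste(sprintf("%s=%.1f", names(x$per_wall_excursion),
                            x$per_wall_excursion), collapse = ", ")))
  cat(sprintf("  HR %g bpm, %g vol/s, %d cycles; noise %.2g mm, dropout %.2g, outliers %.2g x %.3g mm\n",
              x$heart_rate, x$volume_rate, x$n_cycles, x$noise_sd,
              x$dropout_prob, x$outlier_prob, x$outlier_magnitude))
  invisible(x)
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(
    "Filter config: jump > %g mm, neighbour > %g mm (%s), cycle detection >= %g%%\n",
    x$max_jump_mm, x$max_neighbour_dist_mm, x$neighbour_mode,
    100 * x$min_cycle_detection_frac))
  invisible(x)
}

#' @export
print.long_axis <- function(x, ...) {
  cat(sprintf("Long axis: origin (%.2f, %.2f, %.2f) mm, direction (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}
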