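#' Simulate a 3D annulus detection stream with known ground truth
#'
#' Generates the candidate mitral-annulus detections a landmark detector
#' would emit on a single-beat full-volume 3D recording.  The annulus is
#' modelled as a near-planar ring translating along the left-ventricular
#' long axis with a raised-cosine waveform (end-diastole at each R wave,
#' excursion extremum at mid-cycle), with superimposed transverse
#' translation and in-plane rotation, per-point Gaussian detection noise,
#' Bernoulli dropout, and displaced outlier artifacts.
#'
#' Each wall is represented by `points_per_arc` candidate detections spread
#' over +/- 10 degrees around the wall azimuth, inside the 15 degree
#' aggregation arc used downstream.  The longitudinal excursion of every
#' candidate of a wall equals that wall's true excursion, so the arc centre
#' of mass inherits it exactly and the ground truth stays analytic.
#'
#' @param params an [annulus_motion_params()] object.
#' @return An object of class `simulated_recording`: a list with
#'   \describe{
#'     \item{stream}{a [detection_stream()] ready for [run_pipeline()].}
#'     \item{truth}{ground truth for validation: the true long axis, the
#'       per-wall excursions, wall azimuths, per-point artifact labels and
#'       noise-free coordinates, the number of dropped points, and the
#'       generating parameters.}
#'   }
#' @examples
#' rec <- simulate_recording(annulus_motion_params(noise_sd = 0, seed = 7))
#' rec$stream
#' @export
simulate_recording <- function(params) {
  if (!inherits(params, "annulus_motion_params"))
    stop_param("`params` must be created by annulus_motion_params()")
  p <- params
  period <- 60 / p$heart_rate
  vols_per_cycle <- ceiling(p$volume_rate * period)
  n_vol <- p$n_cycles * vols_per_cycle
  times <- (seq_len(n_vol) - 1L) / p$volume_rate
  r_times <- (0:p$n_cycles) * period

  views <- slice_views(p$lax_angle_deg)
  wall_az <- views$wall_azimuths

  k <- p$points_per_arc
  spread <- if (k == 1L) 0 else seq(-10, 10, length.out = k)

  # full emission grid: volume x wall x candidate
  grid <- expand.grid(cand = seq_len(k), wall = WALLS, volume = seq_len(n_vol),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("volume", "wall", "cand")]
  grid$t <- times[grid$volume]
  grid$azimuth_deg <- (wall_az[grid$wall] + spread[grid$cand]) %% 360

  phase <- (grid$t %% period) / period
  h <- (1 - cos(2 * pi * phase)) / 2
  az_rad <- grid$azimuth_deg * pi / 180
  rot <- p$rotation_amplitude_deg * sin(2 * pi * phase) * pi / 180
  tilt <- p$tilt_deg * pi / 180
  psi <- pi / 6  # fixed direction of transverse annular translation

  excursion <- p$per_wall_excursion[grid$wall]
  x_true <- p$transverse_amplitude * sin(2 * pi * phase) * cos(psi) +
    p$annulus_radius_mm * cos(az_rad + rot)
  y_true <- p$transverse_amplitude * sin(2 * pi * phase) * sin(psi) +
    p$annulus_radius_mm * sin(az_rad + rot)
  z_true <- p$annulus_radius_mm * tan(tilt) * cos(az_rad) - excursion * h

  n_pts <- nrow(grid)
  withr::with_seed(derive_seed(p$seed, "recording"), {
    keep <- runif(n_pts) >= p$dropout_prob
    is_outlier <- runif(n_pts) < p$outlier_prob
    # isotropic unit displacement directions for outliers
    u <- matrix(rnorm(3 * n_pts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    noise <- matrix(rnorm(3 * n_pts, sd = p$noise_sd), ncol = 3)
    confidence <- runif(n_pts, 0.5, 1)
  })
  confidence[is_outlier] <- confidence[is_outlier] * 0.8

  disp <- p$outlier_magnitude * u * is_outlier
  x <- x_true + disp[, 1] + noise[, 1]
  y <- y_true + disp[, 2] + noise[, 2]
  z <- z_true + disp[, 3] + noise[, 3]

  points <- data.frame(
    volume = grid$volume,
    azimuth_deg = grid$azimuth_deg,
    x = x, y = y, z = z,
    confidence = confidence
  )[keep, , drop = FALSE]

  truth_points <- data.frame(
    volume = grid$volume,
    azimuth_deg = grid$azimuth_deg,
    wall = grid$wall,
    is_outlier = is_outlier,
    x_true = x_true, y_true = y_true, z_true = z_true
  )[keep, , drop = FALSE]
  rownames(points) <- rownames(truth_points) <- NULL

  stream <- detection_stream(
    points = points,
    times = times,
    r_times = r_times,
    volume_rate = p$volume_rate,
    metadata = list(
      source = "mapse3d synthetic generator",
      lax_angle_deg = p$lax_angle_deg,
      heart_rate = p$heart_rate,
      seed = p$seed
    )
  )
  truth <- list(
    axis = long_axis(origin = c(0, 0, 0), direction = c(0, 0, 1)),
    per_wall_excursion = p$per_wall_excursion,
    wall_azimuths = wall_az,
    lax_angle_deg = p$lax_angle_deg,
    volumes_per_cycle = vols_per_cycle,
    points = truth_points,
    n_dropped = sum(!keep),
    params = p
  )
  structure(list(stream = stream, truth = truth),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  print(x$stream)
  cat(sprintf("  ground truth: mean excursion %.2f mm, %d outlier points, %d dropped\n",
              mean(x$truth$per_wall_excursion),
              sum(x$truth$points$is_outlier), x$truth$n_dropped))
  invisible(x)
}

#' Simulate a linked-replicates test-retest table
#'
#' Generates a balanced subject x method x replicate table of MAPSE values
#' under the linked-replicates model: value = subject effect + replicate
#' effect (shared between methods within a replicate occasion) + method
#' bias + method-specific residual.  Method `"A"` is the reference; method
#' `"B"` carries the systematic bias.
#'
#' @param params a [test_retest_params()] object.
#' @return A `replicate_table` data.frame with columns `subject`, `method`
#'   (factor with levels `A`, `B`), `replicate`, `value`, and a `truth`
#'   attribute holding the generated subject and replicate effects plus the
#'   parameters, for parameter-recovery tests.
#' @seealso [fit_linked_replicates()]
#' @export
simulate_test_retest <- function(params) {
  if (!inherits(params, "test_retest_params"))
    stop_param("`params` must be created by test_retest_params()")
  p <- params
  if (p$n_subjects < 2L)
    stop_param("n_subjects must be >= 2: variance components are unidentifiable")
  I <- p$n_subjects
  R <- p$replicates_per_subject
  withr::with_seed(derive_seed(p$seed, "test_retest"), {
    mu <- rnorm(I, p$true_mapse_mean, p$true_mapse_sd)
    a <- matrix(rnorm(I * R, 0, p$within_subject_sd), nrow = I)
    e_a <- matrix(rnorm(I * R, 0, p$method_sd_a), nrow = I)
    e_b <- matrix(rnorm(I * R, 0, p$method_sd_b), nrow = I)
  })
  base <- mu + a  # I x R matrix of occasion-level true values
  tab <- rbind(
    data.frame(subject = rep(seq_len(I), R),
               method = "A",
               replicate = rep(seq_len(R), each = I),
               value = as.vector(base + e_a)),
    data.frame(subject = rep(seq_len(I), R),
               method = "B",
               replicate = rep(seq_len(R), each = I),
               value = as.vector(base + p$method_bias + e_b))
  )
  tab$method <- factor(tab$method, levels = c("A", "B"))
  tab <- tab[order(tab$subject, tab$replicate, tab$method), ]
  rownames(tab) <- NULL
  structure(tab,
            truth = list(subject_effects = mu, replicate_effects = a,
                         params = p),
            class = c("replicate_table", "data.frame"))
}

#' Simulate a monitoring series of repeated MAPSE measurements
#'
#' Emulates semi-continuous monitoring in which a measurement is obtained
#' at a fixed interval over a monitoring period, following a piecewise
#' linear trend with additive Gaussian noise.
#'
#' @param trend either a single number (constant trend, mm) or a data.frame
#'   with columns `time_min` and `value_mm` giving knots of a piecewise
#'   linear profile; values beyond the last knot are held constant.
#' @param interval_min minutes between measurements, > 0.
#' @param duration_min total monitored minutes, > 0.
#' @param noise_sd mm measurement noise SD.
#' @param seed integer seed.
#' @return A `monitoring_series` data.frame with columns `time_min` and
#'   `value_mm`.
#' @seealso [time_weighted_average()]
#' @examples
#' simulate_monitoring_series(5, interval_min = 5, duration_min = 120)
#' @export
simulate_monitoring_series <- function(trend, interval_min = 5,
                                       duration_min = 120, noise_sd = 0,
                                       seed = 1L) {
  check_number(interval_min, "interval_min", lower = 0, strict_lower = TRUE)
  check_number(duration_min, "duration_min", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (is.numeric(trend) && length(trend) == 1L && is.finite(trend)) {
    trend <- data.frame(time_min = c(0, duration_min),
                        value_mm = c(trend, trend))
  }
  if (!is.data.frame(trend) || nrow(trend) == 0L ||
      !all(c("time_min", "value_mm") %in% names(trend)))
    stop_param("`trend` must be a constant or a non-empty data.frame with columns time_min, value_mm")
  tt <- seq(0, duration_min, by = interval_min)
  if (nrow(trend) == 1L) {
    vals <- rep(trend$value_mm, length(tt))
  } else {
    vals <- approx(trend$time_min, trend$value_mm, xout = tt, rule = 2)$y
  }
  if (noise_sd > 0) {
    withr::with_seed(derive_seed(seed, "monitoring"), {
      vals <- vals + rnorm(length(tt), 0, noise_sd)
    })
  }
  monitoring_series(tt, vals)
}

#' Monitoring series container
#'
#' @param time_min numeric timestamps in minutes, strictly increasing.
#' @param value_mm numeric measurement values in mm.
#' @return A `monitoring_series` data.frame.
#' @export
monitoring_series <- function(time_min, value_mm) {
  if (length(time_min) != length(value_mm))
    stop_param("`time_min` and `value_mm` must have equal length")
  if (any(!is.finite(time_min)))
    stop_param("timestamps must be finite")
  if (any(diff(time_min) <= 0))
    stop_param("timestamps must be strictly increasing")
  structure(data.frame(time_min = as.numeric(time_min),
                       value_mm = as.numeric(value_mm)),
            class = c("monitoring_series", "data.frame"))
}

#' @importFrom stats approx
NULL
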