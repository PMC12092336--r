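#' Detection stream: per-volume 3D mitral annulus candidate points
#'
#' The contract between an upstream landmark detector (or the synthetic
#' generator) and the measurement pipeline.  A stream holds one timestamp
#' per acquired 3D volume, the candidate annulus detections of each volume
#' as rows of a long-format table, the ECG R-wave times delimiting cardiac
#' cycles, and the acquisition volume rate.
#'
#' @param points data.frame with one row per candidate detection and
#'   columns `volume` (1-based volume index), `azimuth_deg` in `[0, 360)`,
#'   `x`, `y`, `z` in mm, and optionally `confidence` in `[0, 1]`.
#' @param times numeric vector of volume timestamps in seconds, strictly
#'   increasing; its length defines the number of volumes.  Volumes without
#'   detections simply have no rows in `points`.
#' @param r_times numeric vector of ECG R-wave timestamps in seconds,
#'   strictly increasing, spanning at least one full cardiac cycle.  Cycle
#'   i is the half-open interval `[r_times[i], r_times[i+1])`.
#' @param volume_rate volumes per second, > 0.
#' @param metadata free-form named list stored with the stream.
#'
#' @return An object of class `detection_stream`.
#' @seealso [simulate_recording()], [run_pipeline()], [read_stream()]
#' @export
detection_stream <- function(points, times, r_times, volume_rate,
                             metadata = list()) {
  if (!is.data.frame(points))
    stop_param("`points` must be a data.frame")
  needed <- c("volume", "azimuth_deg", "x", "y", "z")
  missing_cols <- setdiff(needed, names(points))
  if (length(missing_cols))
    stop_param("`points` is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop_param("`times` must be a non-empty finite numeric vector")
  if (any(diff(times) <= 0))
    stop_param("volume timestamps must be strictly increasing")
  if (!is.numeric(r_times) || length(r_times) < 2L ||
      any(!is.finite(r_times)))
    stop_param("`r_times` must contain at least 2 finite R-wave times (one full cycle)")
  if (any(diff(r_times) <= 0))
    stop_param("`r_times` must be strictly increasing")
  check_number(volume_rate, "volume_rate", lower = 0, strict_lower = TRUE)
  if (nrow(points)) {
    if (any(points$volume < 1 | points$volume > length(times)))
      stop_param("`points$volume` indices must lie in 1..%d", length(times))
    if (any(!is.finite(points$x) | !is.finite(points$y) |
            !is.finite(points$z)))
      stop_param("point coordinates must be finite")
    points$azimuth_deg <- points$azimuth_deg %% 360
  }
  if (is.null(points$confidence))
    points$confidence <- rep(NA_real_, nrow(points))
  rownames(points) <- NULL
  structure(list(
    points = points[, c("volume", "azimuth_deg", "x", "y", "z", "confidence")],
    times = as.numeric(times),
    r_times = as.numeric(r_times),
    volume_rate = as.numeric(volume_rate),
    metadata = metadata
  ), class = "detection_stream")
}

#' @export
print.detection_stream <- function(x, ...) {
  cat(sprintf(
    "Detection stream: %d volumes at %.1f vol/s, %d complete cycles, %d candidate points\n",
    length(x$times), x$volume_rate, length(x$r_times) - 1L, nrow(x$points)))
  invisible(x)
}

n_volumes <- function(stream) length(stream$times)
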