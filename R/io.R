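STREAM_SCHEMA <- "mapse3d-stream"
STREAM_VERSION <- "1.0"

#' Write a detection stream to JSON or CSV
#'
#' JSON is the canonical interchange format (nested, versioned,
#' self-describing); CSV is a long-format alternative for spreadsheet
#' audit, carrying the stream-level fields in `#`-prefixed header lines.
#' Both round-trip losslessly through [read_stream()], including volumes
#' without detections.
#'
#' @param stream a [detection_stream()].
#' @param path output file; format chosen by extension (`.json` / `.csv`)
#'   unless `format` is given.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, format = c("auto", "json", "csv")) {
  if (!inherits(stream, "detection_stream"))
    stop_param("`stream` must be a detection_stream")
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    doc <- list(
      schema = STREAM_SCHEMA,
      version = STREAM_VERSION,
      volume_rate = stream$volume_rate,
      times = stream$times,
      r_times = stream$r_times,
      metadata = stream$metadata,
      points = stream$points
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# %s %s", STREAM_SCHEMA, STREAM_VERSION),
      sprintf("# volume_rate=%s", format(stream$volume_rate, digits = 17)),
      sprintf("# times=%s",
              paste(format(stream$times, digits = 17, trim = TRUE),
                    collapse = ",")),
      sprintf("# r_times=%s",
              paste(format(stream$r_times, digits = 17, trim = TRUE),
                    collapse = ","))
    ), con)
    pts <- stream$points
    for (cc in c("azimuth_deg", "x", "y", "z", "confidence"))
      pts[[cc]] <- format(pts[[cc]], digits = 17, trim = TRUE)
    utils::write.table(pts, con, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a detection stream written by [write_stream()]
#'
#' @param path a `.json` or `.csv` stream file.
#' @return A [detection_stream()].
#' @export
read_stream <- function(path) {
  if (!file.exists(path))
    stop_param("stream file not found: %s", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    hdr <- readLines(path, n = 10)
    hdr <- hdr[startsWith(hdr, "#")]
    if (!length(hdr) || !grepl(STREAM_SCHEMA, hdr[1]))
      stop_param("%s: missing '%s' header line", path, STREAM_SCHEMA)
    version <- sub(sprintf(".*%s ", STREAM_SCHEMA), "", hdr[1])
    if (version != STREAM_VERSION)
      stop_param("%s: schema version '%s' not supported (expected %s)",
                 path, version, STREAM_VERSION)
    get_field <- function(name) {
      line <- grep(sprintf("^# %s=", name), hdr, value = TRUE)
      if (!length(line))
        stop_param("%s: missing required header field '%s'", path, name)
      as.numeric(strsplit(sub(sprintf("^# %s=", name), "", line[1]),
                          ",")[[1]])
    }
    volume_rate <- get_field("volume_rate")
    times <- get_field("times")
    r_times <- get_field("r_times")
    points <- read.csv(path, comment.char = "#")
    metadata <- list()
  } else {
    doc <- tryCatch(
      jsonlite::read_json(path, simplifyVector = TRUE),
      error = function(e)
        stop_param("%s: not a %s file (unparseable JSON: %s)", path,
                   STREAM_SCHEMA, conditionMessage(e)))
    if (is.null(doc$schema) || doc$schema != STREAM_SCHEMA)
      stop_param("%s: not a %s file", path, STREAM_SCHEMA)
    if (is.null(doc$version))
      stop_param("%s: missing required field 'version'", path)
    if (doc$version != STREAM_VERSION)
      stop_param("%s: schema version '%s' not supported (expected %s)",
                 path, doc$version, STREAM_VERSION)
    for (f in c("volume_rate", "times", "r_times"))
      if (is.null(doc[[f]]))
        stop_param("%s: missing required field '%s'", path, f)
    points <- doc$points
    if (length(points) == 0L)
      points <- data.frame(volume = integer(), azimuth_deg = numeric(),
                           x = numeric(), y = numeric(), z = numeric(),
                           confidence = numeric())
    volume_rate <- doc$volume_rate
    times <- doc$times
    r_times <- doc$r_times
    metadata <- as.list(doc$metadata)
  }
  detection_stream(points = points, times = times, r_times = r_times,
                   volume_rate = volume_rate, metadata = metadata)
}

#' Write a simulated recording: stream plus ground-truth sidecar
#'
#' Writes the detection stream to `path` and the ground truth to a sidecar
#' JSON with the same basename and suffix `_truth.json`.
#'
#' @param rec a `simulated_recording` from [simulate_recording()].
#' @param path stream output path (`.json` or `.csv`).
#' @return Named character vector with the `stream` and `truth` paths,
#'   invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "simulated_recording"))
    stop_param("`rec` must come from simulate_recording()")
  write_stream(rec$stream, path)
  truth_path <- paste0(sub("\\.(json|csv)$", "", path, ignore.case = TRUE),
                       "_truth.json")
  tr <- rec$truth
  doc <- list(
    schema = "mapse3d-truth",
    version = STREAM_VERSION,
    seed = tr$params$seed,
    config_hash = config_hash(unclass(tr$params)),
    axis = list(origin = tr$axis$origin, direction = tr$axis$direction),
    per_wall_excursion = as.list(tr$per_wall_excursion),
    wall_azimuths = as.list(tr$wall_azimuths),
    lax_angle_deg = tr$lax_angle_deg,
    volumes_per_cycle = tr$volumes_per_cycle,
    n_dropped = tr$n_dropped,
    n_outliers = sum(tr$points$is_outlier),
    params = unclass(tr$params)
  )
  jsonlite::write_json(doc, truth_path, auto_unbox = TRUE, digits = I(17))
  invisible(c(stream = path, truth = truth_path))
}

#' Write a recording measurement as JSON and a per-wall CSV
#'
#' The JSON carries the recording-level MAPSE, feasibility and filtering
#' counts together with the configuration fingerprint; the optional CSV is
#' the per-wall table (wall, feasibility %, MAPSE mm).
#'
#' @param meas a `recording_measurement` from [run_pipeline()].
#' @param path output JSON path.
#' @param csv_path optional per-wall CSV path.
#' @param seed seed recorded in the output header (NA when unknown).
#' @return `path`, invisibly.
#' @export
write_measurement <- function(meas, path, csv_path = NULL, seed = NA) {
  if (!inherits(meas, "recording_measurement"))
    stop_param("`meas` must be a recording_measurement")
  dg <- meas$diagnostics
  doc <- list(
    schema = "mapse3d-measurement",
    version = STREAM_VERSION,
    seed = seed,
    config_hash = if (!is.null(dg)) config_hash(unclass(dg$config)) else NA,
    feasible = meas$feasible,
    mapse_mm = meas$mapse_mm,
    n_sub_measurements = meas$n_sub_measurements,
    n_walls_contributing = meas$n_walls_contributing,
    n_cycles_contributing = meas$n_cycles_contributing,
    filtering = if (!is.null(dg)) list(
      n_candidates_in = dg$n_candidates_in,
      n_candidates_screened = dg$n_candidates_screened,
      n_samples_detected = dg$n_samples_detected,
      n_samples_invalidated = dg$n_samples_invalidated,
      n_wall_cycles_discarded = dg$n_wall_cycles_discarded
    ),
    per_wall = if (!is.null(dg)) dg$per_wall,
    sub_measurements = meas$sub_measurements
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  if (!is.null(csv_path) && !is.null(dg))
    write.csv(dg$per_wall, csv_path, row.names = FALSE)
  invisible(path)
}

#' Write an agreement result as JSON
#'
#' @param result an `agreement_result`.
#' @param path output JSON path.
#' @param seed seed recorded in the output header (NA when unknown).
#' @return `path`, invisibly.
#' @export
write_agreement <- function(result, path, seed = NA) {
  if (!inherits(result, "agreement_result"))
    stop_param("`result` must be an agreement_result")
  doc <- c(list(schema = "mapse3d-agreement", version = STREAM_VERSION,
                seed = seed),
           unclass(result))
  doc$components <- as.list(doc$components)
  doc$residual_sd <- as.list(doc$residual_sd)
  doc$lsc1 <- as.list(doc$lsc1)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' Read / write a replicate measurement table as CSV
#'
#' Columns: `subject`, `method`, `replicate`, `value` (mm).
#'
#' @param path CSV path.
#' @return [read_replicates()] returns a `replicate_table` data.frame.
#' @export
read_replicates <- function(path) {
  tab <- read.csv(path, comment.char = "#")
  req <- c("subject", "method", "replicate", "value")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop_param("%s: missing column(s) %s", path,
               paste(missing_cols, collapse = ", "))
  tab$method <- factor(tab$method)
  structure(tab, class = c("replicate_table", "data.frame"))
}

#' @param table a `replicate_table` data.frame.
#' @rdname read_replicates
#' @export
write_replicates <- function(table, path) {
  write.csv(as.data.frame(table)[, c("subject", "method", "replicate",
                                     "value")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write a monitoring series as CSV
#'
#' Columns: `time_min`, `value_mm`.
#'
#' @param path CSV path.
#' @return [read_monitoring()] returns a `monitoring_series`.
#' @export
read_monitoring <- function(path) {
  tab <- read.csv(path, comment.char = "#")
  if (!all(c("time_min", "value_mm") %in% names(tab)))
    stop_param("%s: needs columns time_min, value_mm", path)
  monitoring_series(tab$time_min, tab$value_mm)
}

#' @param series a `monitoring_series`.
#' @rdname read_monitoring
#' @export
write_monitoring <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
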