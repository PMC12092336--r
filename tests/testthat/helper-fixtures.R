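# Shared fixture builders.  Everything is generated in code; no binary
# fixtures.

# Noise-free, artifact-free generator settings with equal sampling defaults
clean_params <- function(...) {
  annulus_motion_params(noise_sd = 0, dropout_prob = 0, outlier_prob = 0,
                        ...)
}

# A hand-built two-wall stream: walls at azimuth 0 and 60, one candidate
# point each, positions supplied as a function of volume index so filter
# behaviour can be scripted exactly.  Longitudinal motion is along z.
hand_stream <- function(z0, z60, volume_rate = 10, heart_rate = 60) {
  n <- length(z0)
  times <- (seq_len(n) - 1) / volume_rate
  pts <- rbind(
    data.frame(volume = seq_len(n), azimuth_deg = 0, x = 15, y = 0, z = z0),
    data.frame(volume = seq_len(n), azimuth_deg = 60, x = 7.5,
               y = 15 * sin(pi / 3), z = z60)
  )
  pts <- pts[!is.na(pts$z), ]
  detection_stream(points = pts, times = times,
                   r_times = c(0, 60 / heart_rate),
                   volume_rate = volume_rate,
                   metadata = list(lax_angle_deg = 0))
}

expect_cli_ok <- function(args) {
  code <- suppressMessages(mapse_cli(args))
  expect_identical(code, 0L)
}
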