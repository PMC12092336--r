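test_that("parameter constructors validate their invariants", {
  expect_error(annulus_motion_params(volume_rate = 0), "volume_rate")
  expect_error(annulus_motion_params(heart_rate = -10), "heart_rate")
  expect_error(annulus_motion_params(dropout_prob = 1.2), "dropout_prob")
  expect_error(annulus_motion_params(per_wall_excursion = c(anterior = 5)),
               "6 walls")
  bad <- c(anterior = 5, inferior = 5, anterolateral = 5,
           inferoseptal = 5, anteroseptal = -1, inferolateral = 5)
  expect_error(annulus_motion_params(per_wall_excursion = bad), ">= 0")
  expect_error(test_retest_params(n_subjects = 1), "n_subjects")
  expect_error(test_retest_params(replicates_per_subject = 1),
               "replicates_per_subject")
  expect_error(test_retest_params(method_sd_a = -0.1), "method_sd_a")
})

test_that("recordings are deterministic given a seed and differ across seeds", {
  p <- annulus_motion_params(seed = 99)
  r1 <- simulate_recording(p)
  r2 <- simulate_recording(p)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  r3 <- simulate_recording(annulus_motion_params(seed = 100))
  expect_false(identical(r1$stream$points, r3$stream$points))
})

test_that("stream layout matches the acquisition geometry", {
  p <- clean_params(heart_rate = 75, volume_rate = 19, n_cycles = 10,
                    seed = 5)
  rec <- simulate_recording(p)
  vols_per_cycle <- ceiling(19 * 60 / 75)
  expect_length(rec$stream$times, 10 * vols_per_cycle)
  expect_length(rec$stream$r_times, 11)
  expect_equal(diff(rec$stream$r_times), rep(60 / 75, 10))
  # every wall arc is populated with points_per_arc candidates per volume
  expect_equal(nrow(rec$stream$points),
               10 * vols_per_cycle * 6 * p$points_per_arc)
  expect_true(all(rec$stream$points$azimuth_deg >= 0 &
                    rec$stream$points$azimuth_deg < 360))
})

test_that("injected outliers are displaced beyond the labelled magnitude", {
  p <- annulus_motion_params(noise_sd = 0.3, outlier_prob = 0.1,
                             outlier_magnitude = 12, dropout_prob = 0,
                             seed = 21)
  rec <- simulate_recording(p)
  tp <- rec$truth$points
  sp <- rec$stream$points
  disp <- sqrt((sp$x - tp$x_true)^2 + (sp$y - tp$y_true)^2 +
                 (sp$z - tp$z_true)^2)
  # noise envelope: 5 sigma of the 3D noise vector around the 12 mm shell
  expect_true(all(disp[tp$is_outlier] > 12 - 5 * sqrt(3) * 0.3))
  expect_true(all(disp[!tp$is_outlier] < 5 * sqrt(3) * 0.3))
  expect_gt(sum(tp$is_outlier), 0)
})

test_that("dropout thins candidate points at the requested rate", {
  p <- annulus_motion_params(dropout_prob = 0.5, n_cycles = 10, seed = 8)
  rec <- simulate_recording(p)
  n_emitted <- nrow(rec$stream$points) + rec$truth$n_dropped
  frac <- rec$truth$n_dropped / n_emitted
  se <- sqrt(0.25 / n_emitted)
  expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("test-retest generator recovers its stated moments", {
  p <- test_retest_params(n_subjects = 2000, seed = 31)
  tab <- simulate_test_retest(p)
  expect_s3_class(tab, "replicate_table")
  expect_equal(nrow(tab), 2000 * 3 * 2)
  # balanced and linked
  expect_true(all(table(tab$subject, tab$method) == 3))
  # law of large numbers on the bias
  dbar <- with(tab, tapply(value[method == "B"],
                           subject[method == "B"], mean) -
                    tapply(value[method == "A"],
                           subject[method == "A"], mean))
  se <- sd(dbar) / sqrt(length(dbar))
  expect_lt(abs(mean(dbar) - p$method_bias), 3 * se)
  # marginal SD of one method's values: sqrt(subject^2 + occasion^2 + resid^2)
  expected_sd <- sqrt(p$true_mapse_sd^2 + p$within_subject_sd^2 +
                        p$method_sd_b^2)
  vals <- tab$value[tab$method == "B"]
  # replicates share subject effects, so the effective sample size for the
  # SD is the number of subjects, not the number of rows
  mc_se <- expected_sd / sqrt(2 * (p$n_subjects - 1))
  expect_lt(abs(sd(vals) - expected_sd), 3 * mc_se)
})

test_that("degenerate test-retest settings collapse as stated", {
  p <- test_retest_params(n_subjects = 20, within_subject_sd = 0,
                          method_bias = 0, method_sd_a = 0,
                          method_sd_b = 0, seed = 3)
  tab <- simulate_test_retest(p)
  va <- tab$value[tab$method == "A"]
  vb <- tab$value[tab$method == "B"]
  expect_identical(va, vb)
  # replicates within a subject are identical when the occasion SD is 0
  expect_true(all(tapply(va, tab$subject[tab$method == "A"],
                         function(v) max(v) - min(v)) == 0))
})

test_that("monitoring series cover the protocol grid and trend", {
  s <- simulate_monitoring_series(5, interval_min = 5, duration_min = 120)
  expect_equal(nrow(s), 25)
  expect_true(all(s$value_mm == 5))
  trend <- data.frame(time_min = c(0, 120), value_mm = c(9.1, 2.9))
  s2 <- simulate_monitoring_series(trend, 5, 120, noise_sd = 0, seed = 2)
  expect_equal(s2$value_mm[1], 9.1)
  expect_equal(s2$value_mm[25], 2.9)
  twa <- time_weighted_average(s2)
  expect_gt(twa, 2.9)
  expect_lt(twa, 9.1)
  expect_error(simulate_monitoring_series(data.frame()), "trend")
  expect_error(simulate_monitoring_series(5, interval_min = 0), "interval")
})
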