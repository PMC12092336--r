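test_that("LSC follows the 2 x 1.96 x SD / sqrt(n) formula", {
  expect_equal(lsc(0.5, 1), 2 * 1.96 * 0.5)
  expect_equal(lsc(0, 7), 0)
  # sqrt(n) scaling: lsc(sd, 4) = lsc(sd, 1) / 2, and lsc * sqrt(n) constant
  expect_equal(lsc(0.8, 4), lsc(0.8, 1) / 2)
  prods <- vapply(1:10, function(n) lsc(0.37, n) * sqrt(n), numeric(1))
  expect_equal(prods, rep(prods[1], 10))
  expect_error(lsc(0.5, 0), "n")
  expect_error(lsc(-1, 2), "sd")
  # inversion round-trip
  expect_equal(lsc(lsc_invert(1.6, 1), 1), 1.6)
  tab <- lsc_table(lsc_invert(1.6), n_max = 5)
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$lsc_mm) < 0))
})

test_that("linked-replicates fit matches brute-force moment estimates", {
  # tiny balanced fixture: 3 subjects x 2 replicates x 2 methods
  yA <- matrix(c(5.0, 5.4, 6.2, 6.0, 7.1, 7.5), nrow = 3, byrow = TRUE)
  yB <- matrix(c(4.1, 4.9, 5.0, 5.6, 6.3, 6.5), nrow = 3, byrow = TRUE)
  tab <- rbind(
    data.frame(subject = rep(1:3, 2), method = "A",
               replicate = rep(1:2, each = 3), value = as.vector(yA)),
    data.frame(subject = rep(1:3, 2), method = "B",
               replicate = rep(1:2, each = 3), value = as.vector(yB)))
  fit <- fit_linked_replicates(tab)
  # independent brute-force method-of-moments on the same layout
  devA <- yA - rowMeans(yA)
  devB <- yB - rowMeans(yB)
  dfw <- 3 * (2 - 1)
  cross <- sum(devA * devB) / dfw
  sig2A <- max(0, sum(devA^2) / dfw - cross)
  sig2B <- max(0, sum(devB^2) / dfw - cross)
  d <- yB - yA
  tau2 <- max(0, var(rowMeans(d)) - (sig2A + sig2B) / 2)
  expect_equal(fit$bias, mean(d))
  expect_equal(unname(fit$residual_sd), sqrt(c(sig2A, sig2B)))
  expect_equal(unname(fit$components["replicate"]), max(0, cross))
  expect_equal(unname(fit$components["interaction"]), tau2)
  expect_equal(fit$sd_diff, sqrt(2 * tau2 + sig2A + sig2B))
  # frozen values from the same arithmetic done by hand
  expect_equal(fit$bias, -0.8)
  expect_equal(fit$sd_diff, 0.3741657, tolerance = 1e-6)
})

test_that("linked-replicates fit recovers simulator ground truth", {
  p <- test_retest_params(n_subjects = 2000, method_bias = -1.4, seed = 77)
  fit <- fit_linked_replicates(simulate_test_retest(p))
  # 3 Monte-Carlo standard errors of the estimated bias
  expect_lt(abs(fit$bias - (-1.4)), 3 * fit$bias_se)
  expect_lt(abs(unname(fit$residual_sd["A"]) - p$method_sd_a), 0.05)
  expect_lt(abs(unname(fit$residual_sd["B"]) - p$method_sd_b), 0.05)
  expect_lt(abs(sqrt(unname(fit$components["replicate"])) -
                  p$within_subject_sd), 0.05)
  # zero-noise table: everything collapses
  p0 <- test_retest_params(n_subjects = 10, within_subject_sd = 0,
                           method_bias = 0, method_sd_a = 0,
                           method_sd_b = 0, seed = 1)
  f0 <- fit_linked_replicates(simulate_test_retest(p0))
  expect_equal(f0$bias, 0)
  expect_equal(f0$sd_diff, 0)
  expect_equal(f0$loa_low, 0)
  expect_equal(f0$loa_high, 0)
})

test_that("linked-replicates fit rejects broken designs", {
  tab <- simulate_test_retest(test_retest_params(n_subjects = 5, seed = 2))
  # unlinked: a replicate present for one method only
  broken <- tab[-which(tab$method == "A" & tab$subject == 1 &
                         tab$replicate == 1)[1], ]
  expect_error(fit_linked_replicates(broken), "unlinked")
  single <- tab[tab$replicate == 1, ]
  expect_error(fit_linked_replicates(single), "single-replicate")
  three <- rbind(tab, transform(tab, method = "C"))
  expect_error(fit_linked_replicates(three), "2 methods")
})

test_that("fit agrees with conventional Bland-Altman when effects vanish", {
  p <- test_retest_params(n_subjects = 500, within_subject_sd = 0,
                          seed = 10)
  tab <- simulate_test_retest(p)
  fit <- fit_linked_replicates(tab)
  am <- tapply(tab$value[tab$method == "A"],
               tab$subject[tab$method == "A"], mean)
  bm <- tapply(tab$value[tab$method == "B"],
               tab$subject[tab$method == "B"], mean)
  ba <- bland_altman(bm, am)
  expect_equal(fit$bias, ba$bias, tolerance = 1e-9)
  expect_lt(abs(fit$sd_diff - sqrt(3) * ba$sd_diff), 0.05)
})

test_that("conventional Bland-Altman matches hand-computed values", {
  a <- c(5.2, 6.1, 4.8, 7.0, 5.5)
  b <- c(6.0, 7.2, 5.1, 8.3, 6.2)
  res <- bland_altman(a, b)
  expect_equal(res$bias, -0.84)
  expect_equal(res$sd_diff, 0.3847077, tolerance = 1e-6)
  expect_equal(res$loa_low, -1.594027, tolerance = 1e-6)
  expect_equal(res$loa_high, -0.0859729, tolerance = 1e-6)
  # identical columns and constant offset
  same <- bland_altman(a, a)
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
  off <- bland_altman(a, a + 1)
  expect_equal(off$bias, -1)
  expect_equal(off$sd_diff, 0)
  expect_error(bland_altman(1, 2), "pairs")
})

test_that("limits of agreement are always symmetric about the bias", {
  for (seed in 1:20) {
    tab <- simulate_test_retest(test_retest_params(n_subjects = 20,
                                                   seed = seed))
    fit <- fit_linked_replicates(tab)
    expect_equal((fit$loa_low + fit$loa_high) / 2, fit$bias)
    expect_true(all(fit$components >= 0))
  }
})

test_that("time-weighted average integrates the trapezoid correctly", {
  expect_equal(time_weighted_average(
    monitoring_series(c(0, 50, 120), c(5, 5, 5))), 5)
  # linear ramp: midpoint
  expect_equal(time_weighted_average(
    monitoring_series(c(0, 60, 120), c(2, 5, 8))), 5)
  # piecewise profile, hand-computed: (10*5 + 20*6 + 30*4) / 60
  s <- monitoring_series(c(0, 10, 30, 60), c(4, 6, 6, 2))
  expect_equal(time_weighted_average(s), 290 / 60)
  # bounded by the series range
  for (seed in 1:10) {
    sim <- simulate_monitoring_series(
      data.frame(time_min = c(0, 60, 120), value_mm = c(9.1, 4, 2.9)),
      noise_sd = 0.5, seed = seed)
    twa <- time_weighted_average(sim)
    expect_gte(twa, min(sim$value_mm))
    expect_lte(twa, max(sim$value_mm))
  }
  expect_error(time_weighted_average(monitoring_series(0, 5)), ">= 2")
  expect_error(monitoring_series(c(0, 0, 10), c(1, 2, 3)),
               "strictly increasing")
})

test_that("spearman correlation handles monotone, tied and short inputs", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  # tie fixture against brute-force mid-rank Pearson
  y <- c(2, 2, 3, 5, 4, 6)
  res <- spearman_rho(1:6, y)
  ry <- rank(y)
  rx <- rank(1:6)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, brute)
  expect_equal(res$rho, 0.9276337, tolerance = 1e-6)
  expect_identical(res$method, "exact")
  # exact p agrees with the permutation-null definition and cor.test rho
  expect_equal(res$rho, unname(suppressWarnings(
    cor.test(1:6, y, method = "spearman"))$estimate))
  # incomplete pairs dropped
  res2 <- spearman_rho(c(x, NA), c(exp(x), 1))
  expect_equal(res2$n, 6)
  large <- spearman_rho(1:30, (1:30) + rnorm(30, sd = 5))
  expect_identical(large$method, "t-approximation")
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "tied")
  expect_error(spearman_rho(1:2, 2:3), ">= 3")
})

test_that("correlation comparison orders by magnitude and flags ties", {
  out <- compare_correlations(c(continuous = -0.37, lvef = -0.31,
                                co = 0.38))
  expect_equal(out$label, c("co", "continuous", "lvef"))
  expect_equal(out$rank, c(1L, 2L, 3L))
  expect_false(any(out$tied))
  tied <- compare_correlations(c(a = 0.5, b = -0.5, c = 0.1))
  expect_true(all(tied$tied[1:2]))
  expect_equal(tied$rank[1:2], c(1L, 1L))
  expect_error(compare_correlations(c(a = 0.5)), ">= 2")
  expect_error(compare_correlations(c(0.5, 0.3)), "labelled")
})

test_that("derived hemodynamics reproduce the stated formulas", {
  h <- hemo_inputs(sbp = 120, dbp = 70, map = 90.2, hr = 70, sv = 71.4,
                   lvef = 0.55, pre_ejection_time = 0.08,
                   total_ejection_time = 0.30)
  out <- derived_hemodynamics(h)
  expect_equal(out$co_l_min, 70 * 71.4 / 1000)
  expect_equal(out$cpo_w, out$co_l_min * 90.2 / 451)
  expect_equal(out$cpo_w, 1, tolerance = 0.001)
  expect_equal(out$tnd, 0.08 / 0.38)
  # Ea = 0.9 sbp / sv, and halves when sv doubles
  h2 <- hemo_inputs(120, 70, 90.2, 70, 60, 0.55, 0.08, 0.30)
  expect_equal(derived_hemodynamics(h2)$ea, 1.8)
  h3 <- hemo_inputs(120, 70, 90.2, 70, 120, 0.55, 0.08, 0.30)
  expect_equal(derived_hemodynamics(h3)$ea,
               derived_hemodynamics(h2)$ea / 2)
  # single-beat Ees is physiologic at typical inputs and scales with SV
  expect_true(out$valid)
  expect_gt(out$ees, 0.5)
  expect_lt(out$ees, 5)
  expect_equal(out$ea_ees, out$ea / out$ees)
  expect_error(hemo_inputs(120, 70, 90, 70, 0, 0.55, 0.08, 0.3), "sv")
  expect_error(hemo_inputs(120, 70, 90, 70, 60, 1.2, 0.08, 0.3), "lvef")
})

test_that("the normalized-elastance transcription behaves physiologically", {
  # the polynomial is smooth and within (0, 1) over the physiologic range
  # of pre-ejection fractions, and the elastance estimate decreases with
  # higher ejection fraction at fixed pressures
  tnds <- seq(0.15, 0.45, by = 0.01)
  vals <- vapply(tnds, mapse3d:::chen_end_avg, numeric(1))
  expect_true(all(vals > 0 & vals < 1))
  ef <- seq(0.2, 0.7, by = 0.05)
  ends <- vapply(ef, mapse3d:::chen_end_est, numeric(1),
                 dbp = 70, sbp = 120, tnd = 0.21)
  expect_true(all(diff(ends) < 0))
  ees <- vapply(ef, function(e) {
    h <- hemo_inputs(120, 70, 90, 70, 70, e, 0.08, 0.30)
    derived_hemodynamics(h)$ees
  }, numeric(1))
  expect_true(all(diff(ees) > 0))
})
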