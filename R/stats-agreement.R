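#' Least significant change
#'
#' The smallest change distinguishable from measurement error when the
#' reported value is the mean of `n` repeated measurements with residual
#' standard deviation `sd`:
#' `LSC = 2 x 1.96 x sd / sqrt(n)`.
#'
#' @param sd residual standard deviation of a single measurement (mm).
#' @param n number of measurements averaged (>= 1).
#' @return LSC in the units of `sd`.
#' @examples
#' lsc(0.41, 1)
#' lsc(0.41, 3)
#' @export
lsc <- function(sd, n) {
  check_number(sd, "sd", lower = 0)
  check_number(n, "n", lower = 1)
  2 * 1.96 * sd / sqrt(n)
}

#' Invert the LSC formula to recover the residual SD
#'
#' @param lsc_value an LSC (mm).
#' @param n the number of measurements it refers to.
#' @return The residual SD implied by `lsc_value`.
#' @examples
#' lsc_invert(1.6)            # residual SD behind a single-measurement LSC
#' lsc(lsc_invert(1.6), 3)    # LSC for the mean of three
#' @export
lsc_invert <- function(lsc_value, n = 1) {
  check_number(lsc_value, "lsc_value", lower = 0)
  check_number(n, "n", lower = 1)
  lsc_value * sqrt(n) / (2 * 1.96)
}

#' LSC ladder over the number of averaged measurements
#'
#' @param sd residual SD of a single measurement (mm).
#' @param n_max largest number of averaged measurements tabulated.
#' @return data.frame with columns `n` and `lsc_mm`.
#' @export
lsc_table <- function(sd, n_max = 10) {
  check_number(n_max, "n_max", lower = 1)
  n <- seq_len(n_max)
  data.frame(n = n, lsc_mm = vapply(n, function(k) lsc(sd, k), numeric(1)))
}

new_agreement_result <- function(bias, sd_diff, label_a, label_b,
                                 n_subjects, n_pairs,
                                 components = NULL, residual_sd = NULL,
                                 lsc1 = NULL, bias_se = NA_real_,
                                 model = "conventional") {
  structure(list(
    bias = bias,
    sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff,
    loa_high = bias + 1.96 * sd_diff,
    bias_se = bias_se,
    bias_ci = bias + c(-1.96, 1.96) * bias_se,
    method_a = label_a,
    method_b = label_b,
    n_subjects = n_subjects,
    n_pairs = n_pairs,
    components = components,
    residual_sd = residual_sd,
    lsc1 = lsc1,
    model = model
  ), class = "agreement_result")
}

#' Linked-replicates method-comparison model
#'
#' Fits the replicated method-comparison model for a linked design, in
#' which replicate r of method A and replicate r of method B are obtained
#' under the same conditions:
#' \deqn{y_{mir} = \alpha_m + \mu_i + a_{ir} + c_{mi} + e_{mir}}
#' with a subject effect, a replicate (occasion) effect shared between
#' methods, a method-by-subject interaction, and method-specific residuals.
#' Because the replicate effect is linked it cancels from within-occasion
#' differences, so the Bland-Altman bias and limits of agreement are
#' adjusted for the repeated measurements.
#'
#' Estimation is by closed-form method of moments on the balanced layout:
#' the shared occasion variance is the within-subject cross-method
#' covariance of replicate deviations; each method's residual variance is
#' its within-subject variance minus that covariance; the interaction
#' variance comes from the between-subject dispersion of the subject-mean
#' differences.  Negative moment estimates are truncated at zero.  The
#' limits of agreement describe a difference between single measurements
#' by the two methods on the same occasion:
#' `sd_diff^2 = 2 x interaction variance + residual_A^2 + residual_B^2`.
#'
#' @param table a `replicate_table` data.frame with columns `subject`,
#'   `method` (exactly two levels; the first is the reference A), and
#'   `replicate`, `value`.
#' @return An `agreement_result` with the bias (method B minus method A),
#'   limits of agreement, variance components (`subject`, `replicate`,
#'   `interaction`), per-method residual SDs, and the per-method
#'   single-measurement LSC derived from them.
#' @references Carstensen B. Comparing Clinical Measurement Methods. Wiley,
#'   2010.
#' @seealso [simulate_test_retest()], [lsc()], [bland_altman()]
#' @export
fit_linked_replicates <- function(table) {
  req <- c("subject", "method", "replicate", "value")
  if (!is.data.frame(table) || !all(req %in% names(table)))
    stop_param("`table` must have columns %s", paste(req, collapse = ", "))
  table$method <- factor(table$method)
  methods <- levels(table$method)
  if (length(methods) != 2L)
    stop_param("linked-replicates model requires exactly 2 methods (got %d)",
               length(methods))
  # reshape to subject x replicate matrices per method, enforcing the link
  a_rows <- table[table$method == methods[1], ]
  b_rows <- table[table$method == methods[2], ]
  if (nrow(a_rows) != nrow(b_rows) ||
      !setequal(paste(a_rows$subject, a_rows$replicate),
                paste(b_rows$subject, b_rows$replicate)))
    stop_param(paste0(
      "unlinked design: every (subject, replicate) occasion must be ",
      "measured by both methods"))
  b_rows <- b_rows[match(paste(a_rows$subject, a_rows$replicate),
                         paste(b_rows$subject, b_rows$replicate)), ]
  subjects <- unique(a_rows$subject)
  I <- length(subjects)
  if (I < 2L)
    stop_param("need >= 2 subjects to estimate variance components")
  reps_per_subj <- table(a_rows$subject)
  if (any(reps_per_subj < 2L))
    stop_param(paste0(
      "single-replicate input: every subject needs >= 2 linked replicates ",
      "for the replicate effect to be identifiable"))

  ya <- a_rows$value
  yb <- b_rows$value
  subj <- a_rows$subject
  d <- yb - ya

  # within-subject replicate deviations
  dev_a <- ya - ave(ya, subj)
  dev_b <- yb - ave(yb, subj)
  df_within <- sum(reps_per_subj - 1L)
  ms_a <- sum(dev_a^2) / df_within          # omega^2 + sigma_A^2
  ms_b <- sum(dev_b^2) / df_within          # omega^2 + sigma_B^2
  cross <- sum(dev_a * dev_b) / df_within   # omega^2 (shared occasion)
  omega2 <- max(0, cross)
  sigma2_a <- max(0, ms_a - cross)
  sigma2_b <- max(0, ms_b - cross)

  # between-subject dispersion of the mean differences:
  # var(dbar_i) = 2 tau^2 + (sigma_A^2 + sigma_B^2) / R_i  (balanced: R)
  dbar <- tapply(d, subj, mean)
  Rbar <- mean(reps_per_subj)
  tau2 <- max(0, var(dbar) - (sigma2_a + sigma2_b) / Rbar)

  # subject variance from subject means across both methods
  m_i <- tapply((ya + yb) / 2, subj, mean)
  subj_var <- max(0, var(m_i) - omega2 / Rbar - tau2 / 2 -
                    (sigma2_a + sigma2_b) / (4 * Rbar))

  bias <- mean(d)
  sd_diff <- sqrt(2 * tau2 + sigma2_a + sigma2_b)
  bias_se <- sd(dbar) / sqrt(I)

  residual_sd <- setNames(c(sqrt(sigma2_a), sqrt(sigma2_b)), methods)
  new_agreement_result(
    bias = bias, sd_diff = sd_diff,
    label_a = methods[1], label_b = methods[2],
    n_subjects = I, n_pairs = length(d),
    components = c(subject = subj_var, replicate = omega2,
                   interaction = tau2),
    residual_sd = residual_sd,
    lsc1 = setNames(vapply(residual_sd, lsc, numeric(1), n = 1), methods),
    bias_se = bias_se,
    model = "linked_replicates"
  )
}

#' Conventional Bland-Altman analysis
#'
#' Bias and 95% limits of agreement for paired single measurements:
#' bias = mean(a - b), LOA = bias +/- 1.96 x SD(a - b).
#'
#' @param a,b numeric vectors of paired measurements (equal length >= 2).
#' @param labels character length-2 labels for the two measurement sources.
#' @return An `agreement_result`.
#' @export
bland_altman <- function(a, b, labels = c("a", "b")) {
  if (length(a) != length(b))
    stop_param("`a` and `b` must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L)
    stop_param("need >= 2 complete pairs")
  d <- a - b
  new_agreement_result(
    bias = mean(d), sd_diff = sd(d),
    label_a = labels[2], label_b = labels[1],
    n_subjects = length(d), n_pairs = length(d),
    bias_se = sd(d) / sqrt(length(d)),
    model = "conventional"
  )
}

#' @export
print.agreement_result <- function(x, digits = 1, ...) {
  cat(sprintf("%s Bland-Altman analysis (%s - %s), n = %d pairs\n",
              if (x$model == "linked_replicates") "Linked-replicates"
              else "Conventional",
              x$method_b, x$method_a, x$n_pairs))
  cat(sprintf("  bias %.*f mm, LOA %.*f to %.*f mm\n",
              digits, x$bias, digits, x$loa_low, digits, x$loa_high))
  if (!is.null(x$components)) {
    cat(sprintf("  variance components (SD, mm): subject %.2f, replicate %.2f, method x subject %.2f\n",
                sqrt(x$components["subject"]), sqrt(x$components["replicate"]),
                sqrt(x$components["interaction"])))
    cat(sprintf("  residual SD: %s\n",
                paste(sprintf("%s %.2f", names(x$residual_sd),
                              x$residual_sd), collapse = ", ")))
    cat(sprintf("  LSC (n = 1): %s\n",
                paste(sprintf("%s %.1f", names(x$lsc1), x$lsc1),
                      collapse = ", ")))
  }
  invisible(x)
}
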