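#' Time-weighted average of a monitoring series
#'
#' Integrates the monitored values over time (trapezoidal rule) and divides
#' by the total minutes monitored, so that unevenly spaced measurements are
#' weighted by the time they represent.
#'
#' @param series a [monitoring_series()] or a data.frame with columns
#'   `time_min` and `value_mm`.
#' @return The time-weighted average in mm.
#' @examples
#' s <- monitoring_series(c(0, 60, 120), c(2, 5, 8))
#' time_weighted_average(s)  # 5: midpoint of a linear ramp
#' @export
time_weighted_average <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("time_min", "value_mm") %in% names(series)))
    stop_param("`series` must have columns time_min and value_mm")
  t <- series$time_min
  v <- series$value_mm
  if (length(t) < 2L)
    stop_param("need >= 2 points to integrate over time")
  if (any(diff(t) <= 0))
    stop_param("timestamps must be strictly increasing (no duplicates)")
  pracma::trapz(t, v) / (t[length(t)] - t[1])
}

#' Spearman rank correlation with tie-corrected ranks
#'
#' Rank correlation computed as the Pearson correlation of mid-ranks
#' (average ranks for ties).  Incomplete pairs are dropped
#' (pairwise-complete deletion; missing data are not replaced).  The
#' two-sided p-value uses full permutation enumeration for n <= 8 and the
#' t approximation with n - 2 degrees of freedom above that.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n` (complete pairs used), and
#'   `method` ("exact" or "t-approximation").
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_param("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop_param("need >= 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_param("rho is undefined when all values of a variable are tied")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations(n)
    stats_null <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(stats_null) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p_value, n = n, method = method)
}

# all permutations of 1..n as an n! x n matrix (n kept small by caller)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Rank labelled correlation coefficients by strength
#'
#' Descriptive comparison of labelled correlation coefficients: orders them
#' by absolute magnitude and flags ties.  No inferential test is performed
#' on the differences.
#'
#' @param rho_list named numeric vector or named list of correlation
#'   coefficients (length >= 2).
#' @return data.frame ordered by decreasing `|rho|` with columns `label`,
#'   `rho`, `abs_rho`, `rank` (ties share a rank), `tied`.
#' @examples
#' compare_correlations(c(continuous = -0.37, lvef = -0.31))
#' @export
compare_correlations <- function(rho_list) {
  rho <- unlist(rho_list)
  if (length(rho) < 2L)
    stop_param("need >= 2 labelled coefficients to compare")
  if (is.null(names(rho)) || any(!nzchar(names(rho))))
    stop_param("coefficients must be labelled")
  out <- data.frame(label = names(rho), rho = as.numeric(rho))
  out$abs_rho <- abs(out$rho)
  out <- out[order(-out$abs_rho, out$label), ]
  out$rank <- rank(-out$abs_rho, ties.method = "min")
  out$tied <- duplicated(out$abs_rho) | duplicated(out$abs_rho,
                                                   fromLast = TRUE)
  rownames(out) <- NULL
  out
}

#' Hemodynamic inputs for derived indices
#'
#' @param sbp,dbp,map systolic, diastolic and mean arterial pressure
#'   (mmHg).
#' @param hr heart rate (beats/min).
#' @param sv stroke volume (mL).
#' @param lvef left-ventricular ejection fraction, in (0, 1).
#' @param pre_ejection_time seconds from the R wave to the onset of
#'   ejection.
#' @param total_ejection_time seconds of ejection (flow) time.
#' @return An object of class `hemo_inputs`.
#' @export
hemo_inputs <- function(sbp, dbp, map, hr, sv, lvef,
                        pre_ejection_time, total_ejection_time) {
  check_number(sbp, "sbp", lower = 0, strict_lower = TRUE)
  check_number(dbp, "dbp", lower = 0, strict_lower = TRUE)
  check_number(map, "map", lower = 0, strict_lower = TRUE)
  check_number(hr, "hr", lower = 0, strict_lower = TRUE)
  check_number(sv, "sv", lower = 0, strict_lower = TRUE)
  check_number(lvef, "lvef", lower = 0, upper = 1, strict_lower = TRUE)
  if (lvef >= 1) stop_param("`lvef` must be < 1 (a fraction)")
  check_number(pre_ejection_time, "pre_ejection_time", lower = 0,
               strict_lower = TRUE)
  check_number(total_ejection_time, "total_ejection_time", lower = 0,
               strict_lower = TRUE)
  structure(list(sbp = sbp, dbp = dbp, map = map, hr = hr, sv = sv,
                 lvef = lvef, pre_ejection_time = pre_ejection_time,
                 total_ejection_time = total_ejection_time),
            class = "hemo_inputs")
}

# Normalized-elastance polynomial of the single-beat Ees method of
# Chen et al. (2001): ENd(avg) as a 7th-degree polynomial in tNd, the
# ratio of the pre-ejection period to total systolic period, and the
# regression for ENd(est).
chen_end_coefficients <- c(0.35695, -7.2266, 74.249, -307.39,
                           684.54, -856.92, 571.95, -159.1)

chen_end_avg <- function(tnd) {
  sum(chen_end_coefficients * tnd^(0:7))
}

chen_end_est <- function(lvef, dbp, sbp, tnd) {
  0.0275 - 0.165 * lvef + 0.3656 * (dbp / (0.9 * sbp)) +
    0.515 * chen_end_avg(tnd)
}

#' Derived hemodynamic indices
#'
#' Computes from routine noninvasive measurements:
#' \describe{
#'   \item{Ea}{effective arterial elastance, `0.9 x sbp / sv` (mmHg/mL).}
#'   \item{Ees}{end-systolic elastance by the single-beat method of Chen
#'     et al. (2001), using the normalized elastance at ejection onset
#'     estimated from LVEF, the diastolic-to-end-systolic pressure ratio,
#'     and the pre-ejection fraction of systole.}
#'   \item{ea_ees}{ventriculoarterial coupling ratio Ea/Ees.}
#'   \item{co}{cardiac output, `hr x sv / 1000` (L/min).}
#'   \item{cpo}{cardiac power output, `co x map / 451` (W).}
#' }
#'
#' @param h a [hemo_inputs()] object.
#' @return list with `ea`, `ees`, `ea_ees`, `co_l_min`, `cpo_w`, `tnd`,
#'   and `valid` (FALSE when an intermediate renders Ees non-positive).
#' @references Chen CH et al. Noninvasive single-beat determination of
#'   left ventricular end-systolic elastance in humans.
#'   J Am Coll Cardiol 2001;38:2028-34.
#' @examples
#' h <- hemo_inputs(sbp = 120, dbp = 70, map = 90.2, hr = 70, sv = 71.4,
#'                  lvef = 0.55, pre_ejection_time = 0.08,
#'                  total_ejection_time = 0.30)
#' derived_hemodynamics(h)
#' @export
derived_hemodynamics <- function(h) {
  if (!inherits(h, "hemo_inputs"))
    stop_param("`h` must be created by hemo_inputs()")
  ea <- 0.9 * h$sbp / h$sv
  co <- h$hr * h$sv / 1000
  cpo <- co * h$map / 451
  tnd <- h$pre_ejection_time /
    (h$pre_ejection_time + h$total_ejection_time)
  end_est <- chen_end_est(h$lvef, h$dbp, h$sbp, tnd)
  ees <- (h$dbp - end_est * 0.9 * h$sbp) / (end_est * h$sv)
  valid <- is.finite(ees) && ees > 0 && end_est > 0
  list(
    ea = ea,
    ees = if (valid) ees else NA_real_,
    ea_ees = if (valid) ea / ees else NA_real_,
    co_l_min = co,
    cpo_w = cpo,
    tnd = tnd,
    valid = valid
  )
}
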