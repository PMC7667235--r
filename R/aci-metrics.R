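curveSteps <- function(curve) {
  if (is(curve, "AciCurve")) aciSteps(curve) else as.data.frame(curve)
}

#' Initial slope of the A/Ci response
#'
#' Ordinary least squares of A on Ci over the steps with Ci below the cutoff.
#' With A in umol m-2 s-1 and Ci in umol mol-1 the slope comes out directly in
#' mol m-2 s-1 — the carboxylation efficiency.
#'
#' @param curve An [AciCurve-class] (or data.frame with `ci` and `a`).
#' @param ci_cutoff Only steps with `ci < ci_cutoff` enter the fit
#'   (default 100 umol mol-1).
#' @return Named list: `slope` (mol m-2 s-1), `intercept` (umol m-2 s-1),
#'   `n_points`.
#' @examples
#' crv <- simulateAciCurve(slope = 0.25, gamma = 4.5, noise_sd = 0)
#' fitInitialSlope(crv)$slope
#' @export
fitInitialSlope <- function(curve, ci_cutoff = 100) {
  st <- curveSteps(curve)
  low <- st[st$ci < ci_cutoff, , drop = FALSE]
  if (nrow(low) < 2L) {
    stop("need at least 2 steps with ci < ", ci_cutoff, "; have ", nrow(low))
  }
  fit <- lm(a ~ ci, data = low)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_points = nrow(low))
}

#' CO2 compensation point from the low-Ci regression
#'
#' Gamma is the x-intercept of the initial-slope fit, `-intercept / slope`,
#' floored at zero (an extrapolated positive A at Ci = 0 yields Gamma = 0 with
#' `floored = TRUE`).
#'
#' @inheritParams fitInitialSlope
#' @return Named list: `gamma` (umol mol-1), `floored` (logical).
#' @export
estimateGamma <- function(curve, ci_cutoff = 100) {
  fit <- fitInitialSlope(curve, ci_cutoff)
  if (fit$slope <= 0) stop("initial slope must be positive to estimate gamma")
  raw <- -fit$intercept / fit$slope
  list(gamma = max(0, raw), floored = raw < 0)
}

#' Derived point statistics of an A/Ci curve
#'
#' Reads A and gs at the 400 and 1200 umol mol-1 ambient-CO2 steps (nearest
#' step within `tol`) and derives: `a_ratio = a400/a1200`; the initial slope
#' and the normalized carboxylation efficiency `norm_ce = slope / a1200`
#' (correcting the slope for photosynthetic capacity); the CO2 compensation
#' point; intrinsic water-use efficiency `wue = a400/gs400` (umol CO2 per mol
#' H2O, conventionally reported as mmol mol-1); and the `ci/ca` ratio at the
#' 400 step.
#'
#' @param curve An [AciCurve-class].
#' @param ci_cutoff Passed to [fitInitialSlope()].
#' @param tol Maximum |ca - target| for locating the 400 and 1200 steps
#'   (default 25 umol mol-1).
#' @return Named list: `a400`, `a1200`, `a_ratio`, `initial_slope`, `norm_ce`,
#'   `gamma`, `wue`, `ci_ca`.
#' @export
pointMetrics <- function(curve, ci_cutoff = 100, tol = 25) {
  st <- curveSteps(curve)
  locate <- function(target) {
    d <- abs(st$ca - target)
    i <- which.min(d)
    if (d[i] > tol) {
      stop("no step with ca within ", tol, " of ", target, " umol mol-1")
    }
    i
  }
  i400 <- locate(400)
  i1200 <- locate(1200)
  fit <- fitInitialSlope(st, ci_cutoff)
  a400 <- st$a[i400]
  a1200 <- st$a[i1200]
  list(a400 = a400, a1200 = a1200, a_ratio = a400 / a1200,
       initial_slope = fit$slope, norm_ce = fit$slope / a1200,
       gamma = estimateGamma(st, ci_cutoff)$gamma,
       wue = a400 / st$gs[i400],
       ci_ca = st$ci[i400] / st$ca[i400])
}
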