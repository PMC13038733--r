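#' Mean direction and resultant length of angular data
#'
#' Sums (optionally weighted) unit vectors at the given angles and returns
#' the direction and normalized length of the resultant. The mean vector
#' length r ranges from 0 (uniform or fully cancelling) to 1 (all mass at
#' one angle) and serves as a response-amplitude measure for spike-angle
#' distributions.
#'
#' @param angles numeric vector of angles in degrees.
#' @param weights optional non-negative weights (e.g. per-bin firing
#'   rates); must not be all zero.
#' @return list with `mean_direction` (degrees in \[0, 360), `NA` when the
#'   resultant is zero) and `r` (in \[0, 1\]).
#' @export
#' @examples
#' circ_resultant(c(0, 90)) # 45 degrees, r = sqrt(2)/2
circ_resultant <- function(angles, weights = NULL) {
  angles <- as.numeric(angles)
  if (!length(angles)) {
    skytuner_error("skytuner_undefined_statistic",
                   "cannot compute a mean direction of zero angles")
  }
  if (is.null(weights)) weights <- rep(1, length(angles))
  stopifnot(length(weights) == length(angles), all(weights >= 0))
  w <- sum(weights)
  if (w == 0) {
    skytuner_error("skytuner_undefined_statistic", "weights are all zero")
  }
  rad <- angles * pi / 180
  C <- sum(weights * cos(rad)) / w
  S <- sum(weights * sin(rad)) / w
  r <- sqrt(C^2 + S^2)
  mu <- if (r < 1e-12) NA_real_ else (atan2(S, C) * 180 / pi) %% 360
  list(mean_direction = mu, r = min(r, 1))
}

#' Angle doubling and halving for axial (180-degree periodic) data
#'
#' The angle of polarization is defined only modulo 180 degrees. Axial
#' samples are analyzed by doubling all angles modulo 360, applying
#' ordinary circular statistics, and halving the resulting direction,
#' which maps each axial class `{a, a+180}` to a single point.
#'
#' @param angles angles in degrees.
#' @return `axial_double()`: doubled angles in \[0, 360).
#' @export
#' @examples
#' axial_double(c(10, 190)) # both 20
axial_double <- function(angles) (2 * as.numeric(angles)) %% 360

#' @rdname axial_double
#' @param direction a direction in doubled-angle space, degrees.
#' @return `axial_halve()`: direction / 2 reduced to \[0, 180).
#' @export
axial_halve <- function(direction) ((as.numeric(direction) %% 360) / 2) %% 180

#' Preferred stimulus angle (Phi_max)
#'
#' The stimulus angle eliciting maximal excitation, estimated as the mean
#' direction of spike angles (each spike one unit vector) or of weighted
#' bin centers. For axial stimuli (periodicity 180) the computation runs
#' on doubled angles and the result is halved at the last step.
#'
#' @inheritParams circ_resultant
#' @param periodicity 360 for azimuthal stimuli, 180 for the polarizer.
#' @return list with `phi_max` (degrees in \[0, periodicity)) and `r`.
#'   A vanishing resultant raises a typed "no preferred angle" error which
#'   callers report as a non-significant outcome.
#' @export
phi_max <- function(angles, periodicity = 360, weights = NULL) {
  stopifnot(periodicity %in% c(180, 360))
  angles <- as.numeric(angles)
  if (length(angles) < 2L) {
    skytuner_error("skytuner_undefined_statistic",
                   "need at least 2 angles for a preferred direction")
  }
  a <- if (periodicity == 180) axial_double(angles) else angles %% 360
  res <- circ_resultant(a, weights)
  if (is.na(res$mean_direction) || res$r < 1e-12) {
    skytuner_error("skytuner_no_preferred_angle",
                   "resultant vector vanishes: no preferred angle")
  }
  phi <- if (periodicity == 180) axial_halve(res$mean_direction) else res$mean_direction
  list(phi_max = phi, r = res$r)
}

#' Circular standard deviation from the mean vector length
#'
#' Mean angular deviation `(180/pi) * sqrt(2 (1 - r))` (Batschelet
#' convention), monotone decreasing in r, 0 when r = 1 and about 81.03
#' degrees when r = 0. The alternative circular standard deviation
#' `(180/pi) * sqrt(-2 log r)` is available via `convention`.
#'
#' @param r mean vector length in \[0, 1\].
#' @param convention `"angular_deviation"` (default) or `"circular_sd"`.
#' @return dispersion in degrees.
#' @export
circ_sd_from_r <- function(r, convention = c("angular_deviation", "circular_sd")) {
  convention <- match.arg(convention)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
    skytuner_error("skytuner_domain_error", "r must lie in [0, 1]")
  }
  if (convention == "angular_deviation") {
    (180 / pi) * sqrt(2 * (1 - r))
  } else {
    ifelse(r == 0, Inf, (180 / pi) * sqrt(-2 * log(r)))
  }
}

#' 95% confidence arc for a mean direction
#'
#' Analytic two-regime confidence interval for the mean direction of a
#' circular sample (Zar's formulation, chi-square quantile 3.841 with
#' 1 df): with `R = n r`, for `r <= 0.9` the half-arc is
#' `d = acos(sqrt(2 n (2 R^2 - n chi^2) / (4 n - chi^2)) / R)` and for
#' `r > 0.9` `d = acos(sqrt(n^2 - (n^2 - R^2) exp(chi^2 / n)) / R)`.
#' For axial data the arc is computed in doubled-angle space and halved.
#' Samples too dispersed for the formula (arccos argument outside
#' \[-1, 1\]) yield `NA`: the confidence arc is undefined.
#'
#' @param n number of observations (>= 2).
#' @param r mean vector length of the (doubled, if axial) sample.
#' @param periodicity 360 or 180.
#' @return half-arc in degrees (on the reported-angle scale), or `NA` when
#'   undefined.
#' @export
ci95_mean_direction <- function(n, r, periodicity = 360) {
  stopifnot(periodicity %in% c(180, 360))
  if (!is.numeric(n) || n < 2) {
    skytuner_error("skytuner_domain_error", "need n >= 2 for a confidence arc")
  }
  if (!is.finite(r) || r < 0 || r > 1) {
    skytuner_error("skytuner_domain_error", "r must lie in [0, 1]")
  }
  chi2 <- stats::qchisq(0.95, df = 1) # 3.841459
  R <- n * r
  if (R == 0) return(NA_real_)
  arg <- if (r <= 0.9) {
    inner <- 2 * n * (2 * R^2 - n * chi2) / (4 * n - chi2)
    if (inner < 0) return(NA_real_)
    sqrt(inner) / R
  } else {
    inner <- n^2 - (n^2 - R^2) * exp(chi2 / n)
    if (inner < 0) return(NA_real_)
    sqrt(inner) / R
  }
  if (arg > 1) arg <- min(arg, 1 + 1e-12) # numerical grace at r -> 1
  if (arg > 1 || arg < -1) return(NA_real_)
  d <- acos(min(arg, 1)) * 180 / pi
  if (periodicity == 180) d / 2 else d
}

#' Bootstrap confidence arc for a mean direction
#'
#' Percentile bootstrap alternative to the analytic arc of
#' [ci95_mean_direction()]: resamples the angles with replacement,
#' recomputes the (axially doubled, if requested) mean direction, and
#' reports the 95% half-arc of the signed angular deviations from the
#' full-sample direction.
#'
#' @param angles sample of angles in degrees (raw scale, not doubled).
#' @param periodicity 360 or 180.
#' @param B number of bootstrap resamples.
#' @return half-arc in degrees on the reported-angle scale.
#' @export
circ_ci_bootstrap <- function(angles, periodicity = 360, B = 2000) {
  stopifnot(periodicity %in% c(180, 360), length(angles) >= 2)
  est <- phi_max(angles, periodicity)$phi_max
  n <- length(angles)
  dev <- vapply(seq_len(B), function(b) {
    res <- tryCatch(phi_max(angles[sample.int(n, n, replace = TRUE)], periodicity)$phi_max,
                    skytuner_no_preferred_angle = function(e) NA_real_)
    if (is.na(res)) return(NA_real_)
    d <- (res - est) %% periodicity
    if (d > periodicity / 2) d <- d - periodicity
    abs(d)
  }, numeric(1))
  stats::quantile(dev, 0.95, na.rm = TRUE, names = FALSE)
}

#' Linear-circular correlation of a rate with a stimulus angle
#'
#' Correlates a linear variable x (firing rate per bin) with an angle phi
#' through its sine and cosine components: with `r_xc = cor(x, cos phi)`,
#' `r_xs = cor(x, sin phi)`, `r_cs = cor(cos phi, sin phi)`,
#' `R^2 = (r_xc^2 + r_xs^2 - 2 r_xc r_xs r_cs) / (1 - r_cs^2)`.
#' Under the null of no association, `n R^2` is chi-square distributed
#' with 2 degrees of freedom. For axial stimuli the angles are doubled
#' before correlating. R^2 is the proportion of spiking-rate variability
#' explained by the stimulus angle.
#'
#' @param values numeric vector of linear observations (rates), length
#'   >= 4, not all equal.
#' @param angles matching angles in degrees.
#' @param periodicity 360 or 180.
#' @return list with `R2` (clipped to \[0, 1\]), `p` (upper chi-square tail
#'   of the unclipped statistic) and `n`.
#' @export
linear_circular_corr <- function(values, angles, periodicity = 360) {
  stopifnot(periodicity %in% c(180, 360))
  values <- as.numeric(values)
  angles <- as.numeric(angles)
  n <- length(values)
  if (n < 4L || length(angles) != n) {
    skytuner_error("skytuner_domain_error",
                   "need >= 4 paired observations for linear-circular correlation")
  }
  if (stats::sd(values) == 0) {
    skytuner_error("skytuner_undefined_statistic",
                   "correlation undefined for constant values")
  }
  phi <- (if (periodicity == 180) axial_double(angles) else angles) * pi / 180
  cx <- cos(phi); sx <- sin(phi)
  if (stats::sd(cx) == 0 || stats::sd(sx) == 0) {
    skytuner_error("skytuner_undefined_statistic",
                   "angles have no variation in a circular component")
  }
  r_xc <- stats::cor(values, cx)
  r_xs <- stats::cor(values, sx)
  r_cs <- stats::cor(cx, sx)
  R2 <- (r_xc^2 + r_xs^2 - 2 * r_xc * r_xs * r_cs) / (1 - r_cs^2)
  p <- stats::pchisq(n * R2, df = 2, lower.tail = FALSE)
  list(R2 = min(max(R2, 0), 1), p = p, n = n)
}

#' Rayleigh test of circular uniformity
#'
#' Auxiliary uniformity check (the pipeline's significance gate is the
#' linear-circular correlation): `z = n r^2` with the standard series
#' approximation for the p-value. Axial data are doubled first.
#'
#' @param angles angles in degrees (n >= 5).
#' @param periodicity 360 or 180.
#' @return list with `z` and `p`.
#' @export
rayleigh_test <- function(angles, periodicity = 360) {
  stopifnot(periodicity %in% c(180, 360))
  angles <- as.numeric(angles)
  n <- length(angles)
  if (n < 5L) {
    skytuner_error("skytuner_domain_error", "Rayleigh test needs n >= 5")
  }
  a <- if (periodicity == 180) axial_double(angles) else angles
  r <- circ_resultant(a)$r
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(z = z, p = min(max(p, 0), 1))
}

#' Smallest angular distance under a periodicity
#'
#' @param a,b angles in degrees.
#' @param periodicity 360 for azimuths, 180 for axial polarization angles.
#' @return distance in degrees in \[0, periodicity / 2\].
#' @export
#' @examples
#' angular_distance(5, 175, 180) # 10, wrapping through 0/180
angular_distance <- function(a, b, periodicity = 360) {
  d <- (a - b) %% periodicity
  pmin(d, periodicity - d)
}
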