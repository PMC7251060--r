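#' Generate a synthetic calibration step tablet
#'
#' Emulates a film step tablet of known, graded optical densities imaged by
#' an 8-bit camera. Known ODs are evenly spaced over `od_range`; gray
#' levels are obtained by inverting the logarithmic camera model
#' `OD = alpha + beta * log10(256 / (gray + 1))` and adding bounded uniform
#' noise that is clipped so the gray levels stay strictly decreasing.
#' When the requested range fits inside the 8-bit OD range (max OD <=
#' log10(256) ~ 2.408) the uncalibrated reference model `alpha = 0, beta =
#' 1` is used, so with `gray_noise = 0` gray levels are exactly
#' `256 / 10^OD - 1`. Denser tablets (the default density range 0.06-3.05
#' exceeds what 8 bits can span at unit slope) use the same family with
#' `beta` scaled so the full range maps onto gray `[0, 255]`.
#'
#' @param n_steps Number of tablet steps (>= 4).
#' @param od_range Increasing pair of optical densities within `(0, 4]`;
#'   default `c(0.06, 3.05)`.
#' @param gray_noise Half-width of the uniform gray-level noise (default 1
#'   gray level; clipped near neighbours to preserve monotonicity).
#' @param seed Integer seed; all randomness is local to this call.
#' @return A data frame with columns `gray_level` (strictly decreasing,
#'   in `[0, 255]`) and `known_od` (strictly increasing), plus attributes
#'   `alpha` and `beta` recording the generating model.
#' @examples
#' tab <- generate_step_tablet(21, c(0.06, 3.05), seed = 1)
#' range(tab$known_od)
#' @export
generate_step_tablet <- function(n_steps, od_range = c(0.06, 3.05),
                                 gray_noise = 1, seed = NULL) {
  if (n_steps < 4) stop("insufficient calibration points (need >= 4 steps)")
  if (length(od_range) != 2 || !all(is.finite(od_range))) {
    stop("od_range must be a finite pair")
  }
  if (od_range[1] <= 0 || od_range[2] > 4) {
    stop("od_range outside (0, 4]")
  }
  if (diff(od_range) <= 0) stop("od_range must be increasing")
  od <- seq(od_range[1], od_range[2], length.out = n_steps)
  od_cap <- log10(256)
  if (od_range[2] <= od_cap) {
    alpha <- 0; beta <- 1
  } else {
    alpha <- od_range[1]
    beta <- (od_range[2] - od_range[1]) / od_cap
  }
  gray <- 256 / 10^((od - alpha) / beta) - 1
  if (gray_noise > 0) {
    gaps <- abs(diff(gray))
    # max noise per point: 0.4 x smallest adjacent gap, so order is kept
    lim <- pmin(gray_noise, 0.4 * pmin(c(gaps, Inf), c(Inf, gaps)))
    eps <- with_local_seed(seed, runif(n_steps, -1, 1)) * lim
    gray <- gray + eps
  }
  gray <- pmin(pmax(gray, 0), 255)
  structure(data.frame(gray_level = gray, known_od = od),
            alpha = alpha, beta = beta)
}

#' Generate thickness-graded tissue standards
#'
#' Emulates brain-homogenate standards cut at graded thicknesses: the
#' spectrophotometrically determined CO activity of each standard is
#' proportional to its thickness, and its mean histochemical optical
#' density is affine in thickness plus Gaussian measurement noise. With
#' `noise_sd = 0` the OD-activity relation is exactly linear.
#'
#' @param thicknesses Section thicknesses in micrometres (>= 3 distinct
#'   positive values); default `c(10, 20, 40, 60, 80)`.
#' @param specific_activity CO activity per micrometre of tissue
#'   (umol/min/g per um); default 6.25, i.e. ~250 umol/min/g at the 40 um
#'   working thickness.
#' @param od_intercept,od_slope Affine OD model: `OD = od_intercept +
#'   od_slope * thickness`.
#' @param noise_sd Gaussian OD noise standard deviation (default 0.01 OD).
#' @param seed Integer seed.
#' @return Data frame with columns `thickness`, `spectro_activity`
#'   (umol/min/g) and `mean_od`.
#' @examples
#' std <- generate_standards(noise_sd = 0, seed = 1)
#' cor(std$mean_od, std$spectro_activity)
#' @export
generate_standards <- function(thicknesses = c(10, 20, 40, 60, 80),
                               specific_activity = 6.25,
                               od_intercept = 0.10, od_slope = 0.0075,
                               noise_sd = 0.01, seed = NULL) {
  if (any(thicknesses <= 0)) stop("thicknesses must be positive")
  if (length(unique(thicknesses)) < 3) stop("standards underdetermined")
  activity <- specific_activity * thicknesses
  od <- od_intercept + od_slope * thicknesses
  if (noise_sd > 0) {
    od <- od + with_local_seed(seed, rnorm(length(od), 0, noise_sd))
  }
  data.frame(thickness = thicknesses,
             spectro_activity = activity,
             mean_od = od)
}
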