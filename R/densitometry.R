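#' Fit the gray-level to optical-density calibration curve
#'
#' Least-squares fit of the logarithmic camera calibration model
#' `OD = alpha + beta * log10(256 / (gray + 1))` to a step tablet of known
#' densities. The model is monotone decreasing in gray for `beta > 0`,
#' finite at gray 0, and anchored at OD `alpha` for a saturated bright
#' field (gray 255 gives `log10(256/256) = 0`).
#'
#' @param tablet Data frame with columns `gray_level` in `[0, 255]`
#'   (distinct) and `known_od`.
#' @param r2_warn Warn (do not fail) when the fit r-squared falls below
#'   this value (default 0.99).
#' @return An object of class `calibration_curve`: list with `alpha`,
#'   `beta`, `fit_r2`, `n_points`.
#' @examples
#' tab <- generate_step_tablet(21, c(0.06, 3.05), seed = 1)
#' fit_gray_to_od(tab)
#' @export
fit_gray_to_od <- function(tablet, r2_warn = 0.99) {
  stopifnot(all(c("gray_level", "known_od") %in% names(tablet)))
  if (nrow(tablet) < 4) stop("insufficient calibration points (need >= 4)")
  g <- tablet$gray_level
  od <- tablet$known_od
  if (any(g < 0 | g > 255)) stop("gray levels must lie in [0, 255]")
  if (anyDuplicated(g)) stop("gray levels must be distinct")
  ord <- order(g)
  if (any(diff(od[ord]) > 0)) {
    stop("tablet inconsistent: OD not decreasing in gray after sorting")
  }
  x <- log10(256 / (g + 1))
  fit <- lm(od ~ x)
  beta <- unname(coef(fit)[2])
  if (!is.finite(beta) || beta <= 0) {
    stop("tablet inconsistent: fitted OD is not decreasing in gray")
  }
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((od - mean(od))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (r2 < r2_warn) {
    warning(sprintf("calibration fit r-squared %.4f below %.2f", r2, r2_warn))
  }
  structure(list(alpha = unname(coef(fit)[1]), beta = beta,
                 fit_r2 = r2, n_points = nrow(tablet)),
            class = "calibration_curve")
}

#' Convert gray levels to optical density under a fitted calibration
#'
#' @param curve A `calibration_curve` from [fit_gray_to_od()].
#' @param gray Numeric vector/matrix of gray levels in `[0, 255]`.
#' @return Optical densities with the shape of `gray`.
#' @export
gray_to_od <- function(curve, gray) {
  stopifnot(inherits(curve, "calibration_curve"))
  od <- curve$alpha + curve$beta * log10(256 / (gray + 1))
  if (is.matrix(gray)) dim(od) <- dim(gray)
  od
}

# Inverse of gray_to_od; used by the synthetic image renderer.
od_to_gray <- function(curve, od) {
  stopifnot(inherits(curve, "calibration_curve"))
  256 / 10^((od - curve$alpha) / curve$beta) - 1
}

#' Background subtraction in OD space
#'
#' Subtracts the mean optical density of a blank region (slide/light-box
#' reference) from every pixel, clamping negative results at zero. This is
#' a constant (flat-field) correction for slide and illuminator artifacts.
#'
#' @param image_od Numeric matrix of per-pixel optical densities.
#' @param blank_region Polygon (list with a `vertices` matrix of 0-based
#'   `(row, col)` coordinates) delimiting the blank region; must contain at
#'   least `min_pixels` pixel centers.
#' @param tissue_rois Optional list of tissue ROI polygons; a warning with
#'   the overlap fraction is raised if the blank region overlaps any.
#' @param min_pixels Minimum blank-region pixel count (default 50).
#' @return The corrected OD matrix, with attribute `background_od`
#'   recording the subtracted constant.
#' @export
subtract_background <- function(image_od, blank_region, tissue_rois = NULL,
                                min_pixels = 50) {
  mask <- polygon_mask(nrow(image_od), ncol(image_od), blank_region)
  n <- sum(mask)
  if (n == 0) stop("blank region contains no pixels")
  if (n < min_pixels) {
    stop("blank region too small (", n, " px, need >= ", min_pixels, ")")
  }
  for (roi in tissue_rois %||% list()) {
    rmask <- polygon_mask(nrow(image_od), ncol(image_od), roi)
    ov <- sum(mask & rmask) / n
    if (ov > 0) {
      warning(sprintf("blank region overlaps tissue ROI '%s' (fraction %.3f)",
                      roi$roi %||% "?", ov))
    }
  }
  bg <- mean(image_od[mask])
  out <- pmax(image_od - bg, 0)
  dim(out) <- dim(image_od)
  attr(out, "background_od") <- bg
  out
}

#' Mean optical density of a polygon ROI
#'
#' Averages OD over all pixels whose centers fall inside the polygon
#' (even-odd rule, 0-based row/col coordinates, implicit closure). When a
#' lesion falls inside the ROI, lesioned pixels are included in the mean by
#' design -- the ROI is atlas-defined, not lesion-defined -- and a supplied
#' lesion mask is used only to annotate the lesion overlap fraction.
#'
#' @param image_od OD matrix.
#' @param outline Polygon list: `roi`, `hemisphere` ("L"/"R"),
#'   `section` (1-3), `vertices` (n x 2, 0-based `(row, col)`, n >= 3).
#' @param lesion_mask Optional logical matrix of lesioned pixels.
#' @param subject_id Optional subject identifier carried into the record.
#' @return An object of class `roi_measurement`: list with `subject_id`,
#'   `roi_name`, `hemisphere`, `section_index`, `mean_od`, `pixel_count`,
#'   `lesion_overlap`.
#' @export
measure_roi_od <- function(image_od, outline, lesion_mask = NULL,
                           subject_id = NA_character_) {
  mask <- polygon_mask(nrow(image_od), ncol(image_od), outline)
  n <- sum(mask)
  if (n == 0) stop("empty ROI: polygon contains no pixel centers")
  overlap <- if (is.null(lesion_mask)) NA_real_ else {
    sum(mask & lesion_mask) / n
  }
  structure(list(subject_id = subject_id,
                 roi_name = outline$roi %||% NA_character_,
                 hemisphere = outline$hemisphere %||% NA_character_,
                 section_index = outline$section %||% NA_integer_,
                 mean_od = mean(image_od[mask]),
                 pixel_count = n,
                 lesion_overlap = overlap),
            class = "roi_measurement")
}

#' Fit the OD to CO-activity calibration line
#'
#' Ordinary least-squares regression of spectrophotometric CO activity on
#' mean histochemical optical density across tissue standards. The fit is
#' accepted only if the correlation exceeds a linearity threshold
#' (default `r >= 0.95`), promoting the method's reported calibration
#' quality to a pipeline contract.
#'
#' @param standards Data frame with columns `mean_od` and
#'   `spectro_activity` (>= 3 standards with distinct OD).
#' @param r_threshold Minimum acceptable Pearson r (default 0.95); set to
#'   `-Inf` to disable the gate.
#' @return Object of class `activity_curve`: `intercept`, `slope`, `r`
#'   (signed), `od_domain` (fitted OD range).
#' @export
fit_od_to_activity <- function(standards, r_threshold = 0.95) {
  stopifnot(all(c("mean_od", "spectro_activity") %in% names(standards)))
  od <- standards$mean_od
  act <- standards$spectro_activity
  if (length(unique(od)) < 3) stop("standards underdetermined")
  if (sd(od) == 0) stop("standards underdetermined")
  r <- cor(od, act)
  if (r < r_threshold) {
    stop(sprintf("calibration linearity below threshold (r = %.4f < %.2f)",
                 r, r_threshold))
  }
  fit <- lm(act ~ od)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r = r,
                 od_domain = range(od)),
            class = "activity_curve")
}

#' Convert mean OD to CO activity
#'
#' Affine transform through a fitted [fit_od_to_activity()] line. Values
#' outside the fitted OD domain are returned unchanged but flagged as
#' extrapolations -- never silently clamped.
#'
#' @param mean_od Numeric vector of ODs.
#' @param curve An `activity_curve`.
#' @return List with `activity` (umol/min/g) and logical `extrapolated`.
#' @export
convert_od_to_activity <- function(mean_od, curve) {
  stopifnot(inherits(curve, "activity_curve"))
  act <- curve$intercept + curve$slope * mean_od
  extr <- mean_od < curve$od_domain[1] | mean_od > curve$od_domain[2]
  list(activity = act, extrapolated = extr)
}

#' Aggregate section/hemisphere measurements into one ROI activity
#'
#' Takes up to six `roi_measurement`s (three adjacent sections per
#' hemisphere) for a single subject x ROI, averages their mean ODs with
#' equal weight, and converts the aggregate OD to CO activity. Fewer than
#' six available measurements triggers a completeness warning, not an
#' error.
#'
#' @param measurements List of `roi_measurement` objects for one subject
#'   and ROI (1-6 entries, at most 3 per hemisphere).
#' @param curve An `activity_curve` for the OD to activity conversion.
#' @return List with `subject_id`, `roi_name`, `mean_od`, `activity`,
#'   `extrapolated`, `n_measurements`.
#' @export
aggregate_subject_roi <- function(measurements, curve) {
  stopifnot(length(measurements) >= 1,
            all(vapply(measurements, inherits, TRUE, "roi_measurement")))
  subj <- unique(vapply(measurements, `[[`, "", "subject_id"))
  roi <- unique(vapply(measurements, `[[`, "", "roi_name"))
  if (length(subj) != 1 || length(roi) != 1) {
    stop("inconsistent aggregation set: measurements span multiple ",
         "subjects or ROIs")
  }
  hemi <- vapply(measurements, `[[`, "", "hemisphere")
  if (any(table(hemi) > 3)) {
    stop("inconsistent aggregation set: more than 3 sections per hemisphere")
  }
  n <- length(measurements)
  if (n < 6) {
    warning(sprintf("subject %s ROI %s: only %d of 6 section x hemisphere %s",
                    subj, roi, n, "measurements available"))
  }
  od <- mean(vapply(measurements, `[[`, 0, "mean_od"))
  conv <- convert_od_to_activity(od, curve)
  list(subject_id = subj, roi_name = roi, mean_od = od,
       activity = conv$activity, extrapolated = conv$extrapolated,
       n_measurements = n)
}
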