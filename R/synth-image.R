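# Synthetic section-image renderer.

# Deterministic ordered dithering (8x8 Bayer matrix) used when quantising
# continuous gray levels to 8 bits: the spatial mean of a dithered uniform
# region tracks the continuous target to ~1/64 gray level, so noiseless
# round-trip densitometry is not biased by quantisation.
bayer8 <- local({
  b2 <- matrix(c(0, 2, 3, 1), 2, 2)
  up <- function(b) {
    n <- nrow(b)
    rbind(cbind(4 * b + 0, 4 * b + 2),
          cbind(4 * b + 3, 4 * b + 1))
  }
  b <- up(up(b2))
  (b + 0.5) / 64
})

quantise_gray <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  thr <- bayer8[(seq_len(nr) - 1) %% 8 + 1, (seq_len(nc) - 1) %% 8 + 1]
  f <- gray - floor(gray)
  out <- floor(gray) + (f > thr)
  pmin(pmax(out, 0), 255)
}

#' Render a synthetic CO-stained section image
#'
#' Paints each ROI polygon at the gray level corresponding to its CO
#' activity under the supplied calibration curves (activity -> OD through
#' the inverse activity line, OD -> gray through the inverse camera
#' calibration), optionally adds Gaussian OD noise and lesions, and
#' quantises to an 8-bit image with deterministic ordered dithering.
#' Lesioned pixels are rendered at a configurable fraction of the
#' white-matter OD -- inside the 85-98% band for degenerated-but-present
#' tissue, or below it when `tissue_loss` is set.
#'
#' @param activity_map Named numeric vector ROI name -> CO activity
#'   (umol/min/g) for the ROIs in `layout`.
#' @param layout List of ROI polygons (see [make_roi_layout()]).
#' @param calib A `calibration_curve` (gray -> OD).
#' @param act_curve An `activity_curve` (OD -> activity); its inverse maps
#'   activities to target ODs.
#' @param dims Image dimensions `c(nrow, ncol)`.
#' @param background_od OD of the unstained slide background (default
#'   0.02).
#' @param od_overrides Named ODs for layout entries rendered at a direct
#'   OD rather than via an activity (e.g. `c(WM = 0.30)` for a
#'   white-matter reference patch).
#' @param lesion_spec Optional list of lesions, each a list with
#'   `vertices` (0-based `(row, col)` polygon), optional `od_frac`
#'   (fraction of `wm_od`; default 0.915, the middle of the 85-98% band),
#'   and optional `tissue_loss` flag (renders at `0.3 * wm_od`).
#'   Requires `wm_od`.
#' @param wm_od White-matter reference OD used to place lesion gray
#'   levels (default the `WM` entry of `od_overrides`, if present).
#' @param noise_sd Per-pixel Gaussian OD noise (default 0).
#' @param seed Integer seed (noise only).
#' @param subject_id Identifier carried in the output.
#' @return List with `image` (integer gray matrix), `od_truth` (continuous
#'   OD matrix before noise/quantisation), `lesion_mask` (logical matrix),
#'   `layout`, `subject_id`.
#' @export
generate_section_image <- function(activity_map, layout, calib, act_curve,
                                   dims = c(160, 320),
                                   background_od = 0.02,
                                   od_overrides = NULL,
                                   lesion_spec = NULL,
                                   wm_od = unname(od_overrides["WM"]),
                                   noise_sd = 0, seed = NULL,
                                   subject_id = NA_character_) {
  stopifnot(inherits(calib, "calibration_curve"),
            inherits(act_curve, "activity_curve"))
  od_field <- matrix(background_od, dims[1], dims[2])
  for (p in layout) {
    od <- if (!is.null(od_overrides) && p$roi %in% names(od_overrides)) {
      od_overrides[[p$roi]]
    } else if (p$roi %in% names(activity_map)) {
      (activity_map[[p$roi]] - act_curve$intercept) / act_curve$slope
    } else {
      stop("no activity or OD given for layout entry '", p$roi, "'")
    }
    g <- od_to_gray(calib, od)
    if (!is.finite(g) || g < 0 || g > 255) {
      stop("activity not invertible under calibration (ROI '", p$roi,
           "', target OD ", signif(od, 4), ")")
    }
    od_field[polygon_mask(dims[1], dims[2], p)] <- od
  }
  lesion_mask <- matrix(FALSE, dims[1], dims[2])
  for (les in lesion_spec %||% list()) {
    if (is.null(wm_od)) stop("lesion rendering requires wm_od")
    frac <- if (isTRUE(les$tissue_loss)) 0.3 else les$od_frac %||% 0.915
    m <- polygon_mask(dims[1], dims[2], les)
    od_field[m] <- frac * wm_od
    lesion_mask <- lesion_mask | m
  }
  od_noisy <- od_field
  if (noise_sd > 0) {
    od_noisy <- od_noisy +
      with_local_seed(seed, rnorm(length(od_field), 0, noise_sd))
    od_noisy <- pmax(od_noisy, 0)
    dim(od_noisy) <- dim(od_field)
  }
  gray <- od_to_gray(calib, od_noisy)
  gray <- pmin(pmax(gray, 0), 255)
  dim(gray) <- dim(od_field)
  list(image = quantise_gray(gray),
       od_truth = od_field,
       lesion_mask = lesion_mask,
       layout = layout,
       subject_id = subject_id)
}
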