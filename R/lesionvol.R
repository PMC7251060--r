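#' Mean white-matter reference OD
#'
#' Measures the mean optical density of a white-matter polygon (the
#' reference anchoring the lesion segmentation band). A crude bimodality
#' heuristic -- two-cluster separation exceeding 20% of the mean --
#' triggers a warning that the region may straddle gray matter.
#'
#' @param image_od OD matrix.
#' @param wm_region White-matter polygon (>= `min_pixels` pixel centers).
#' @param min_pixels Minimum pixel count (default 50).
#' @return Mean OD, with attribute `pixel_count`.
#' @export
wm_reference_od <- function(image_od, wm_region, min_pixels = 50) {
  mask <- polygon_mask(nrow(image_od), ncol(image_od), wm_region)
  n <- sum(mask)
  if (n == 0) stop("white-matter region contains no pixels")
  if (n < min_pixels) {
    stop("white-matter region too small (", n, " px, need >= ",
         min_pixels, ")")
  }
  px <- image_od[mask]
  m <- mean(px)
  if (length(unique(px)) > 1) {
    km <- suppressWarnings(kmeans(px, centers = 2, nstart = 1))
    if (abs(diff(km$centers)) > 0.2 * m) {
      warning(sprintf("white-matter region looks bimodal %s",
                      sprintf("(cluster separation %.3f OD, mean %.3f)",
                              abs(diff(km$centers)), m)))
    }
  }
  structure(m, pixel_count = n)
}

#' Segment a lesion by white-matter-referenced OD thresholding
#'
#' Highlights pixels inside an approximate lesion outline whose OD falls
#' in a band referenced to white matter: `[0.85, 0.98] * wm_od` by default
#' (darker than unstained fibre tracts, lighter than healthy gray matter).
#' With `tissue_loss = TRUE` the upper bound is set equal to the
#' white-matter OD and no lower bound is applied, so regions with missing
#' tissue are still captured. Pure thresholding -- no morphological
#' cleanup is applied.
#'
#' @param image_od OD matrix.
#' @param wm_od White-matter reference OD (> 0).
#' @param roi_scope Approximate lesion outline polygon restricting the
#'   threshold (never applied whole-image).
#' @param tissue_loss Capture missing-tissue pixels (see above).
#' @param pixel_size Pixel edge length in micrometres (required for the
#'   area).
#' @param band Threshold fractions of `wm_od` (default `c(0.85, 0.98)`).
#' @param subject_id,section_index Identifiers carried in the record.
#' @return Object of class `lesion_section`: `subject_id`,
#'   `section_index`, `wm_mean_od`, `threshold_lo`, `threshold_hi`,
#'   `mask` (logical matrix, subset of the outline), `area_mm2`,
#'   `outline_used`.
#' @export
segment_lesion <- function(image_od, wm_od, roi_scope, tissue_loss = FALSE,
                           pixel_size = 10, band = c(0.85, 0.98),
                           subject_id = NA_character_,
                           section_index = NA_integer_) {
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size missing or invalid")
  }
  if (!is.finite(wm_od) || wm_od <= 0) stop("wm_od must be > 0")
  if (band[1] >= band[2]) stop("threshold fractions must be increasing")
  scope <- polygon_mask(nrow(image_od), ncol(image_od), roi_scope)
  if (!any(scope)) stop("roi_scope contains no pixels")
  if (tissue_loss) {
    lo <- 0; hi <- wm_od
  } else {
    lo <- band[1] * wm_od; hi <- band[2] * wm_od
  }
  mask <- scope & image_od >= lo & image_od <= hi
  area <- sum(mask) * (pixel_size / 1000)^2
  structure(list(subject_id = subject_id, section_index = section_index,
                 wm_mean_od = as.numeric(wm_od),
                 threshold_lo = lo, threshold_hi = hi,
                 mask = mask, area_mm2 = area, outline_used = roi_scope),
            class = "lesion_section")
}

#' Serial-section lesion volume
#'
#' Volume from per-section lesion areas. The default Cavalieri mode
#' extrudes each section's area over one inter-section spacing:
#' `V = sum(A) * T`. A `literal_d` mode instead applies
#' `d = T * (n_designated - 1)` as a single factor,
#' `V = sum(A) * d` -- the two readings of the serial-section formula
#' differ, so the mode used is always recorded and the alternative value
#' reported alongside.
#'
#' @param areas Per-section lesion areas in mm^2 (non-negative).
#' @param T_um Inter-section spacing in micrometres (default 80).
#' @param literal_d Use the literal `d = T x (n_designated - 1)` mode.
#' @param n_designated Number of designated sections (literal mode;
#'   default `length(areas)`).
#' @param subject_id Identifier carried in the record.
#' @return Object of class `lesion_volume`: `volume_mm3`, `volume_cm3`,
#'   `d_mm`, `mode`, `alt_volume_mm3` (the other mode's value), `areas`,
#'   `T_um`.
#' @examples
#' lesion_volume(c(0.5, 0.7, 0.3), T_um = 80)$volume_mm3   # 0.12
#' @export
lesion_volume <- function(areas, T_um = 80, literal_d = FALSE,
                          n_designated = length(areas),
                          subject_id = NA_character_) {
  if (any(areas < 0)) stop("areas must be non-negative")
  if (T_um <= 0) stop("T must be > 0")
  d_cav <- T_um / 1000
  v_cav <- sum(areas) * d_cav
  if (literal_d) {
    if (n_designated < 1) stop("n_designated must be >= 1 in literal mode")
    d_lit <- d_cav * (n_designated - 1)
    v_lit <- sum(areas) * d_lit
  }
  v <- if (literal_d) v_lit else v_cav
  structure(list(subject_id = subject_id,
                 volume_mm3 = v, volume_cm3 = v / 1000,
                 d_mm = if (literal_d) d_lit else d_cav,
                 mode = if (literal_d) "literal" else "cavalieri",
                 alt_volume_mm3 = if (literal_d) v_cav else {
                   sum(areas) * d_cav * (n_designated - 1)
                 },
                 areas = areas, T_um = T_um),
            class = "lesion_volume")
}

# Default ROI -> lesion type mapping built from the anatomical grouping.
roi_lesion_types <- function() {
  g <- co_roi_groups()
  c(setNames(rep("neocortical", length(unique(c(g$prefrontal, g$neocortical)))),
             unique(c(g$prefrontal, g$neocortical))),
    setNames(rep("hippocampal", length(g$hippocampal)), g$hippocampal),
    setNames(rep("striatal", length(g$striatal)), g$striatal),
    setNames(rep("perirhinal", length(g$perirhinal)), g$perirhinal))
}

#' Classify lesion type and laterality
#'
#' Assigns anatomical type labels (neocortical, striatal, hippocampal,
#' perirhinal) when the lesion mask overlaps the corresponding atlas ROI
#' polygons by more than a minimum fraction of the ROI's area on any
#' section, and determines laterality from the hemispheres of the
#' overlapped ROIs (bilateral iff ROIs in both hemispheres are hit).
#'
#' @param masks List of logical lesion masks (one per section), in the
#'   same pixel frame as `roi_layout`.
#' @param roi_layout List of ROI polygons with `roi`, `hemisphere`,
#'   `vertices`.
#' @param min_overlap Minimum lesion/ROI overlap as a fraction of the
#'   ROI's pixel area (default 0.05).
#' @param type_map Named character vector ROI -> type label; defaults to
#'   the package's anatomical grouping.
#' @return List with `types` (character, possibly empty), `laterality`
#'   (`"unilateral-L"`, `"unilateral-R"`, `"bilateral"`, or `NA` when no
#'   lesion), and `rois_hit`.
#' @export
classify_lesion <- function(masks, roi_layout, min_overlap = 0.05,
                            type_map = roi_lesion_types()) {
  if (!is.list(masks)) masks <- list(masks)
  dims <- dim(masks[[1]])
  hit <- character(0); hemis <- character(0)
  for (p in roi_layout) {
    rmask <- polygon_mask(dims[1], dims[2], p)
    a <- sum(rmask)
    if (a == 0) next
    for (m in masks) {
      if (!all(dim(m) == dims)) stop("frame mismatch between masks")
      if (sum(m & rmask) / a > min_overlap) {
        hit <- c(hit, p$roi)
        hemis <- c(hemis, p$hemisphere %||% NA_character_)
        break
      }
    }
  }
  if (length(hit) == 0) {
    return(list(types = character(0), laterality = NA_character_,
                rois_hit = character(0)))
  }
  types <- sort(unique(stats::na.omit(type_map[hit])))
  hemis <- unique(hemis[!is.na(hemis)])
  lat <- if (all(c("L", "R") %in% hemis)) "bilateral"
         else if (identical(hemis, "L")) "unilateral-L"
         else if (identical(hemis, "R")) "unilateral-R"
         else NA_character_
  list(types = unname(types), laterality = lat, rois_hit = unique(hit))
}

#' Lesion volume vs behavior relation
#'
#' Pearson correlation (two-tailed) and least-squares line between lesion
#' volumes and behavior scores across lesioned subjects. The study-level
#' expectation -- larger lesions, worse performance -- corresponds to
#' `r < 0` under this sign convention.
#'
#' @param volumes Lesion volumes (mm^3) of the lesioned subjects.
#' @param vwt_scores Matching behavior scores.
#' @return List with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
lesion_behavior_relation <- function(volumes, vwt_scores) {
  stopifnot(length(volumes) == length(vwt_scores))
  if (length(volumes) < 3) stop("insufficient lesioned subjects (n < 3)")
  if (sd(volumes) == 0) stop("zero variance in lesion volumes")
  if (sd(vwt_scores) == 0) stop("zero variance in behavior scores")
  ct <- cor.test(volumes, vwt_scores)
  fit <- lm(vwt_scores ~ volumes)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(volumes))
}
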