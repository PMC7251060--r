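#' Block-structured ROI correlation matrix
#'
#' Builds a positive semi-definite correlation matrix over ROIs as a sum of
#' compound-symmetric pieces: a weak global background, stronger
#' within-block correlation for named anatomical blocks, and optional extra
#' coupling between ROI sets (used, e.g., to plant a strengthened
#' visual-hippocampal association in one group). Because every piece is a
#' non-negative multiple of an indicator outer product plus a positive
#' diagonal remainder, the result is PSD by construction provided the
#' summed off-diagonal weights stay below 1.
#'
#' @param roi_names Character vector of ROI names.
#' @param blocks Named list of character vectors (subsets of `roi_names`);
#'   default is the visual / hippocampal / prefrontal grouping of
#'   [co_roi_groups()].
#' @param base_r Background correlation shared by all ROI pairs.
#' @param block_r Additional correlation within each block.
#' @param coupling Optional list of `list(rois =, r =)` entries adding `r`
#'   to every pair within the union `rois` (a rank-one coupling).
#' @return A `length(roi_names)` square correlation matrix with unit
#'   diagonal.
#' @examples
#' R <- block_correlation(c("V1", "V2", "SC", "CPu"),
#'                        blocks = list(vis = c("V1", "V2", "SC")))
#' @export
block_correlation <- function(roi_names,
                              blocks = co_roi_groups()[c("visual",
                                                         "hippocampal",
                                                         "prefrontal")],
                              base_r = 0.15, block_r = 0.45,
                              coupling = NULL) {
  p <- length(roi_names)
  stopifnot(p >= 1, base_r >= 0, block_r >= 0)
  R <- matrix(base_r, p, p, dimnames = list(roi_names, roi_names))
  add_block <- function(R, members, r) {
    idx <- which(roi_names %in% members)
    R[idx, idx] <- R[idx, idx] + r
    R
  }
  for (b in blocks) R <- add_block(R, b, block_r)
  for (cp in coupling %||% list()) R <- add_block(R, cp$rois, cp$r)
  diag(R) <- 1
  if (any(R[upper.tri(R)] >= 1)) {
    stop("block/coupling weights sum to >= 1 off-diagonal; reduce base_r, ",
         "block_r or coupling r")
  }
  R
}

#' Specification of a synthetic 2x2 CO-mapping cohort
#'
#' Bundles everything the cohort generator needs: the four group labels and
#' sizes, the 44 ROI names, per-group cell means and SEMs, per-group
#' within-group inter-ROI correlation matrices, the fraction of occluded
#' (2VO) subjects carrying lesions, and target brain-behavior correlations.
#' Defaults reproduce the reference cohort: groups sham+saline, sham+MB,
#' 2VO+saline, 2VO+MB with n = (9, 9, 9, 8), cell moments from
#' [co_cohort_reference()], a block-structured correlation matrix shared by
#' all groups, lesions in one third of 2VO subjects, and a behavior score
#' most strongly coupled to perirhinal cortex.
#'
#' @param group_labels Four `<surgery>+<drug>` labels.
#' @param group_sizes Four positive integers; default `c(9, 9, 9, 8)`.
#' @param roi_names ROI abbreviations (rows of the cell-mean matrices).
#' @param cell_means,cell_sems Numeric matrices, ROIs x groups.
#' @param within_group_corr A single correlation matrix shared by all
#'   groups, or a list of four (one per group).
#' @param lesion_fraction Fraction of 2VO subjects with lesions, in `[0,1]`.
#' @param behavior_corr_targets Named numeric vector, ROI -> target Pearson
#'   correlation with the behavior score, each in `(-1, 1)`.
#' @param seed Integer seed consumed by [generate_cohort()].
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(group_labels = co_group_labels(),
                        group_sizes = c(9L, 9L, 9L, 8L),
                        roi_names = co_cohort_reference()$abbrev,
                        cell_means = NULL,
                        cell_sems = NULL,
                        within_group_corr = NULL,
                        lesion_fraction = 1 / 3,
                        behavior_corr_targets = c(PRh = 0.526, M2 = 0.461,
                                                  CA1A = 0.455, V1 = 0.432,
                                                  V2 = 0.410),
                        seed = 1L) {
  ref <- co_cohort_reference()
  if (is.null(cell_means) || is.null(cell_sems)) {
    stopifnot(all(roi_names %in% ref$abbrev))
    r <- ref[match(roi_names, ref$abbrev), ]
    if (is.null(cell_means)) {
      cell_means <- as.matrix(r[, c("mean_sham_saline", "mean_sham_mb",
                                    "mean_vo_saline", "mean_vo_mb")])
      dimnames(cell_means) <- list(roi_names, group_labels)
    }
    if (is.null(cell_sems)) {
      cell_sems <- as.matrix(r[, c("sem_sham_saline", "sem_sham_mb",
                                   "sem_vo_saline", "sem_vo_mb")])
      dimnames(cell_sems) <- list(roi_names, group_labels)
    }
  }
  if (is.null(within_group_corr)) {
    within_group_corr <- block_correlation(roi_names)
  }
  if (!is.list(within_group_corr)) {
    within_group_corr <- rep(list(within_group_corr), length(group_labels))
  }
  names(within_group_corr) <- group_labels
  spec <- structure(
    list(group_labels = group_labels,
         group_sizes = as.integer(group_sizes),
         roi_names = roi_names,
         cell_means = cell_means,
         cell_sems = cell_sems,
         within_group_corr = within_group_corr,
         lesion_fraction = lesion_fraction,
         behavior_corr_targets = behavior_corr_targets,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks group sizes, dimensional consistency of the cell moment matrices,
#' positivity of SEMs, the lesion fraction range, and that every
#' within-group correlation matrix is symmetric with unit diagonal and
#' positive semi-definite.
#'
#' @param spec A `cohort_spec`.
#' @param tol Eigenvalue tolerance for the PSD check.
#' @return `spec`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort_spec <- function(spec, tol = 1e-8) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- length(spec$group_labels)
  p <- length(spec$roi_names)
  if (length(spec$group_sizes) != g || any(spec$group_sizes < 1)) {
    stop("group_sizes must be ", g, " positive integers")
  }
  if (!all(dim(spec$cell_means) == c(p, g)) ||
      !all(dim(spec$cell_sems) == c(p, g))) {
    stop("cell_means/cell_sems must be ", p, " x ", g, " matrices")
  }
  if (any(spec$cell_sems <= 0)) stop("cell_sems must be > 0")
  if (spec$lesion_fraction < 0 || spec$lesion_fraction > 1) {
    stop("lesion_fraction must lie in [0, 1]")
  }
  if (any(abs(spec$behavior_corr_targets) >= 1)) {
    stop("behavior correlation targets must satisfy |r| < 1")
  }
  parse_group_labels(spec$group_labels)  # errors on malformed labels
  for (lbl in spec$group_labels) {
    R <- spec$within_group_corr[[lbl]]
    if (is.null(R) || !all(dim(R) == c(p, p))) {
      stop("within_group_corr for ", lbl, " must be ", p, " x ", p)
    }
    if (max(abs(R - t(R))) > tol) {
      stop("within_group_corr for ", lbl, " is not symmetric")
    }
    if (max(abs(diag(R) - 1)) > tol) {
      stop("within_group_corr for ", lbl, " must have unit diagonal")
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
      stop("correlation matrix not positive semi-definite (group ", lbl,
           "); pass it through nearest_psd() explicitly if repair is wanted")
    }
  }
  invisible(spec)
}

#' Nearest positive semi-definite repair of a correlation matrix
#'
#' Explicit (never silent) repair for nearly-PSD correlation matrices via
#' [Matrix::nearPD()] with `corr = TRUE`.
#'
#' @param R A symmetric matrix intended as a correlation matrix.
#' @return The nearest correlation matrix as a base matrix, with the
#'   original dimnames.
#' @export
nearest_psd <- function(R) {
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  dimnames(out) <- dimnames(R)
  out
}
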