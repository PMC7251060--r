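#' Generate a synthetic cohort table of per-subject ROI activities
#'
#' For each group the subject x ROI activity block is drawn from a
#' multivariate normal with mean equal to the group's cell means, marginal
#' standard deviations `SEM * sqrt(n)` (so that group means have the
#' specified SEM in expectation), and the group's within-group inter-ROI
#' correlation matrix. Lesion flags are planted deterministically in the
#' occluded (2VO) groups: `round(lesion_fraction * n)` randomly chosen
#' subjects per 2VO group.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. Identical seeds give
#'   bit-identical tables.
#' @return A data frame of class `cohort_table`: columns `subject_id`,
#'   `group`, `surgery`, `drug`, `lesioned`, then one column per ROI
#'   (CO activity, umol/min/g).
#' @examples
#' ct <- generate_cohort(cohort_spec(seed = 42))
#' dim(ct)   # 35 subjects x (5 + 44) columns
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  p <- length(spec$roi_names)
  fac <- parse_group_labels(spec$group_labels)
  blocks <- with_local_seed(seed, {
    lapply(seq_along(spec$group_labels), function(g) {
      n <- spec$group_sizes[g]
      sds <- spec$cell_sems[, g] * sqrt(n)
      Sigma <- diag(sds) %*% spec$within_group_corr[[g]] %*% diag(sds)
      x <- MASS::mvrnorm(n, mu = spec$cell_means[, g], Sigma = Sigma)
      x <- matrix(x, nrow = n)  # mvrnorm drops dims when n = 1
      colnames(x) <- spec$roi_names
      is_vo <- fac$surgery[g] != "sham"
      n_les <- if (is_vo) round(spec$lesion_fraction * n) else 0L
      lesioned <- rep(FALSE, n)
      if (n_les > 0) lesioned[sample.int(n, n_les)] <- TRUE
      list(x = x, lesioned = lesioned)
    })
  })
  act <- do.call(rbind, lapply(blocks, `[[`, "x"))
  n_tot <- sum(spec$group_sizes)
  out <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_tot)),
    group = rep(spec$group_labels, spec$group_sizes),
    surgery = rep(fac$surgery, spec$group_sizes),
    drug = rep(fac$drug, spec$group_sizes),
    lesioned = unlist(lapply(blocks, `[[`, "lesioned")),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(act))
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "roi_names") <- spec$roi_names
  out
}

# ROI activity sub-matrix of a cohort table.
cohort_activity <- function(cohort, roi_names = attr(cohort, "roi_names")) {
  if (is.null(roi_names)) {
    meta <- c("subject_id", "group", "surgery", "drug", "lesioned",
              "vwt_score")
    roi_names <- setdiff(names(cohort), meta)
  }
  missing <- setdiff(roi_names, names(cohort))
  if (length(missing)) {
    stop("cohort table is missing ROI column(s): ",
         paste(missing, collapse = ", "))
  }
  as.matrix(cohort[, roi_names, drop = FALSE])
}

#' Generate behavior scores coupled to selected ROI activities
#'
#' Constructs a visual-water-task style performance score (percent
#' correct, bounded `[0, 100]`) as a linear blend of standardized target
#' ROI activities plus independent Gaussian noise, with the blend weights
#' solved from the empirical ROI correlation matrix so realized
#' cohort-level correlations approach the requested targets. The score is
#' centred at `center` with spread `scale` and clipped to `[0, 100]`.
#' Because the target ROIs themselves differ between groups, group
#' ordering of the scores (2VO+saline lowest) emerges from the ROI
#' coupling; explicit additive `group_effects` can be supplied on top.
#'
#' @param cohort A `cohort_table`.
#' @param targets Named numeric vector ROI -> target Pearson r (each
#'   `|r| < 1`).
#' @param group_effects Optional named numeric vector of additive mean
#'   shifts per group label (applied after the blend; note they perturb
#'   realized correlations).
#' @param center,scale Location and spread of the score before clipping.
#' @param seed Integer seed.
#' @return Numeric vector of scores aligned to `cohort` rows, with
#'   attribute `noise_sd` (the solved residual standard deviation).
#' @export
generate_behavior <- function(cohort, targets = c(PRh = 0.526),
                              group_effects = NULL,
                              center = 65, scale = 12, seed = NULL) {
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  if (any(abs(targets) >= 1)) stop("behavior targets must satisfy |r| < 1")
  z <- scale(cohort_activity(cohort, names(targets)))
  R <- stats::cor(z)
  w <- solve(R, targets)
  expl <- drop(crossprod(targets, w))  # rho' R^-1 rho
  if (expl > 1) {
    stop("behavior targets infeasible: requested correlation vector lies ",
         "outside the feasible ellipsoid of the ROI covariance (rho' R^-1 ",
         "rho = ", signif(expl, 4), " > 1)")
  }
  sigma <- sqrt(1 - expl)
  y <- drop(z %*% w) + sigma * with_local_seed(seed, rnorm(nrow(cohort)))
  score <- center + scale * y
  if (!is.null(group_effects)) {
    shift <- group_effects[cohort$group]
    shift[is.na(shift)] <- 0
    score <- score + shift
  }
  score <- pmin(pmax(score, 0), 100)
  attr(score, "noise_sd") <- sigma
  score
}
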