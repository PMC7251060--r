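#' Within-group interregional correlation matrix
#'
#' Pearson correlations of CO activity between all ROI pairs across the
#' subjects of one group ("metabolic covariance" network), with two-tailed
#' p values from the exact t transform.
#'
#' @param cohort A `cohort_table`.
#' @param group Group label to subset (one of `cohort$group`); omit if
#'   `cohort` already holds a single group.
#' @return Object of class `group_corr`: list with `group_label`,
#'   `roi_names`, `r` (symmetric, unit diagonal), `p` (two-tailed,
#'   diagonal `NA`), `n`.
#' @export
group_correlation_matrix <- function(cohort, group = NULL) {
  if (!is.null(group)) {
    cohort <- cohort[cohort$group == group, , drop = FALSE]
    if (nrow(cohort) == 0) stop("no subjects in group '", group, "'")
  } else {
    group <- unique(cohort$group) %||% NA_character_
    if (length(group) > 1) stop("cohort spans several groups; pick one")
  }
  n <- nrow(cohort)
  if (n < 4) stop("group too small for correlation (n = ", n, " < 4)")
  act <- cohort_activity(cohort)
  sds <- apply(act, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI column(s): ",
         paste(colnames(act)[sds == 0], collapse = ", "))
  }
  r <- cor(act)
  # numerical guard: exactly collinear columns must report |r| = 1 so the
  # comparison stage can exclude them rather than weight them infinitely
  r <- pmin(pmax(r, -1), 1)
  r[1 - abs(r) < 1e-12] <- sign(r[1 - abs(r) < 1e-12])
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  structure(list(group_label = group, roi_names = colnames(act),
                 r = r, p = p, n = n),
            class = "group_corr")
}

#' Fisher z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform used to compare correlations across independent groups.
#'
#' @param r Correlations with `|r| < 1` (vectorised).
#' @return Transformed values.
#' @examples
#' fisher_z(0.9)   # 1.47222
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("transform undefined at |r| = 1")
  atanh(r)
}

#' Compare one correlation between two independent groups
#'
#' Fisher-z comparison of `r1` (group 1, n1 subjects) with `r2` (group 2,
#' n2): `Z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`. `method = "normal"`
#' (default) refers Z to the standard normal -- the classical test, since
#' the z difference has known variance; `method = "t"` refers the same
#' statistic to a t distribution with `n1 + n2 - 6` df as a sensitivity
#' variant. The verdict is relative to group 2: `strengthened` if
#' `r2 > r1` and `p < alpha`, `weakened` if `r2 < r1` and `p < alpha`,
#' otherwise `unchanged`.
#'
#' @param r1,n1 Correlation and subject count in group 1.
#' @param r2,n2 Correlation and subject count in group 2.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param method `"normal"` or `"t"`.
#' @return Object of class `edge_comparison`: list with `r1`, `n1`, `r2`,
#'   `n2`, `z1`, `z2`, `Z`, `p`, `verdict`.
#' @examples
#' compare_edge(0.9, 12, 0.3, 12)   # Z = 2.4664, weakened
#' @export
compare_edge <- function(r1, n1, r2, n2, alpha = 0.05,
                         method = c("normal", "t")) {
  method <- match.arg(method)
  if (n1 <= 3 || n2 <= 3) stop("variance of z undefined (need n > 3)")
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  Z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (method == "normal") 2 * pnorm(-abs(Z)) else {
    2 * pt(-abs(Z), df = n1 + n2 - 6)
  }
  verdict <- if (p >= alpha) "unchanged" else if (r2 > r1) "strengthened" else "weakened"
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
                 z1 = z1, z2 = z2, Z = Z, p = p, verdict = verdict),
            class = "edge_comparison")
}

#' Edge-wise comparison of two group correlation matrices
#'
#' Compares every ROI pair of two within-group correlation matrices with
#' [compare_edge()] and reports the significantly strengthened and
#' weakened edges (group B relative to group A). Pairs where either group
#' shows `|r| = 1` (possible at small n) are excluded and listed rather
#' than infinitely weighted. Uncorrected alpha is the default; `fdr =
#' TRUE` adds a Benjamini-Hochberg verdict column alongside, never
#' substituted.
#'
#' @param matrix_a,matrix_b `group_corr` objects with identical ROI
#'   ordering, from disjoint groups.
#' @param alpha Two-tailed significance level.
#' @param method Passed to [compare_edge()].
#' @param fdr Add BH-adjusted p and verdict columns.
#' @return List of class `difference_map`: `edges` (data frame: `roi_a`,
#'   `roi_b`, `r1`, `r2`, `Z`, `p`, `verdict`, optional `p_fdr`,
#'   `verdict_fdr`), `grid` (signed significance matrix: +1 strengthened,
#'   -1 weakened, 0 unchanged), `n_strengthened`, `n_weakened`,
#'   `excluded` (perfect-correlation pairs), `alpha`.
#' @export
difference_map <- function(matrix_a, matrix_b, alpha = 0.05,
                           method = c("normal", "t"), fdr = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(matrix_a, "group_corr"), inherits(matrix_b, "group_corr"))
  if (!identical(matrix_a$roi_names, matrix_b$roi_names)) {
    stop("matrices not conformable: ROI name mismatch")
  }
  p_ <- length(matrix_a$roi_names)
  idx <- which(upper.tri(matrix(0, p_, p_)), arr.ind = TRUE)
  r1 <- matrix_a$r[idx]; r2 <- matrix_b$r[idx]
  keep <- abs(r1) < 1 & abs(r2) < 1
  excluded <- data.frame(roi_a = matrix_a$roi_names[idx[!keep, 1]],
                         roi_b = matrix_a$roi_names[idx[!keep, 2]],
                         stringsAsFactors = FALSE)
  idx <- idx[keep, , drop = FALSE]
  r1 <- r1[keep]; r2 <- r2[keep]
  denom <- sqrt(1 / (matrix_a$n - 3) + 1 / (matrix_b$n - 3))
  Z <- (atanh(r1) - atanh(r2)) / denom
  p <- if (method == "normal") 2 * pnorm(-abs(Z)) else {
    2 * pt(-abs(Z), df = matrix_a$n + matrix_b$n - 6)
  }
  verdict <- ifelse(p >= alpha, "unchanged",
                    ifelse(r2 > r1, "strengthened", "weakened"))
  edges <- data.frame(roi_a = matrix_a$roi_names[idx[, 1]],
                      roi_b = matrix_a$roi_names[idx[, 2]],
                      r1 = r1, r2 = r2, Z = Z, p = p, verdict = verdict,
                      stringsAsFactors = FALSE)
  if (fdr) {
    edges$p_fdr <- p.adjust(edges$p, "BH")
    edges$verdict_fdr <- ifelse(edges$p_fdr >= alpha, "unchanged",
                                ifelse(edges$r2 > edges$r1,
                                       "strengthened", "weakened"))
  }
  grid <- matrix(0, p_, p_,
                 dimnames = list(matrix_a$roi_names, matrix_a$roi_names))
  sig <- edges$verdict != "unchanged"
  for (k in which(sig)) {
    i <- match(edges$roi_a[k], matrix_a$roi_names)
    j <- match(edges$roi_b[k], matrix_a$roi_names)
    grid[i, j] <- grid[j, i] <- if (edges$verdict[k] == "strengthened") 1 else -1
  }
  structure(list(edges = edges, grid = grid,
                 n_strengthened = sum(edges$verdict == "strengthened"),
                 n_weakened = sum(edges$verdict == "weakened"),
                 excluded = excluded, alpha = alpha),
            class = "difference_map")
}

#' Export a correlation matrix (or signed difference grid) as heat map
#'
#' Writes a device-free diverging-colour raster PNG (blue -1, white 0,
#' red +1; values clamped) in the fixed reference ROI order, and always a
#' CSV twin holding the exact values so the figure is machine-checkable.
#' The CSV round-trips bit-exactly.
#'
#' @param matrix A `group_corr`, a `difference_map`, or a plain numeric
#'   matrix in `[-1, 1]`.
#' @param path_png,path_csv Output paths (default: `path_png` with a
#'   `.csv` extension).
#' @param cell_px Pixel edge per matrix cell (default 6).
#' @return Invisibly, a list with both paths.
#' @export
export_heatmap <- function(matrix, path_png,
                           path_csv = sub("\\.png$", ".csv", path_png),
                           cell_px = 6) {
  m <- if (inherits(matrix, "group_corr")) matrix$r
       else if (inherits(matrix, "difference_map")) matrix$grid
       else matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  v <- pmin(pmax(m, -1), 1)
  # blue (-1) -> white (0) -> red (+1)
  rch <- ifelse(v >= 0, 1, 1 + v)
  gch <- 1 - abs(v)
  bch <- ifelse(v <= 0, 1, 1 - v)
  up <- function(x) x[rep(seq_len(nrow(x)), each = cell_px),
                      rep(seq_len(ncol(x)), each = cell_px)]
  img <- array(c(up(rch), up(gch), up(bch)),
               dim = c(nrow(m) * cell_px, ncol(m) * cell_px, 3))
  png::writePNG(img, path_png)
  write_matrix_csv(m, path_csv)
  invisible(list(png = path_png, csv = path_csv))
}
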