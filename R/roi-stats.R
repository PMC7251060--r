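#' Two-way factorial ANOVA for one ROI
#'
#' Fits the full 2x2 surgery x drug linear model with sum-to-zero
#' contrasts and reports Type III F statistics and two-tailed p values for
#' both main effects and the interaction (unbalanced-safe: with unequal
#' cell sizes each effect is tested adjusting for all others, including
#' the interaction). Cohen's d is attached for the surgery main effect
#' (pooled groups) and for the simple 2VO-saline vs 2VO-MB effect, the
#' natural effect size for a cross-over interaction.
#'
#' @param values Numeric vector of per-subject activities.
#' @param surgery,drug Factors (or coercibles) of length `length(values)`,
#'   two levels each.
#' @return Object of class `factorial_result`: list with `F_surgery`,
#'   `F_drug`, `F_interaction`, matching `p_*`, `df` (`c(1, N - 4)`),
#'   `d_surgery`, `d_interaction`, `cell_means`, `cell_sds`, `cell_ns`.
#' @examples
#' set.seed(1)
#' g <- expand.grid(surgery = c("sham", "2VO"), drug = c("saline", "MB"))
#' d <- g[rep(1:4, each = 5), ]
#' two_way_anova(rnorm(20, 200, 10), d$surgery, d$drug)
#' @export
two_way_anova <- function(values, surgery, drug) {
  surgery <- droplevels(as.factor(surgery))
  drug <- droplevels(as.factor(drug))
  stopifnot(length(values) == length(surgery),
            length(values) == length(drug))
  if (nlevels(surgery) != 2 || nlevels(drug) != 2) {
    stop("incomplete factorial design: each factor needs exactly 2 levels")
  }
  tab <- table(surgery, drug)
  if (any(tab == 0)) stop("incomplete factorial design: empty cell")
  if (any(tab < 2)) stop("incomplete factorial design: need >= 2 per cell")
  cell_means <- tapply(values, list(surgery, drug), mean)
  cell_sds <- tapply(values, list(surgery, drug), sd)
  cell_ns <- tapply(values, list(surgery, drug), length)
  if (all(cell_sds == 0)) stop("degenerate error term: zero within-cell variance")
  d <- data.frame(y = values, surgery = surgery, drug = drug)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(y ~ surgery * drug, data = d)
  a <- car::Anova(fit, type = 3)
  pick <- function(term, col) a[term, col]
  n <- length(values)
  d_surg <- cohens_d(values[surgery == levels(surgery)[1]],
                     values[surgery == levels(surgery)[2]])
  vo <- levels(surgery)[levels(surgery) != "sham"][1] %||% levels(surgery)[2]
  sal <- if ("saline" %in% levels(drug)) "saline" else levels(drug)[1]
  other <- setdiff(levels(drug), sal)[1]
  d_int <- cohens_d(values[surgery == vo & drug == sal],
                    values[surgery == vo & drug == other])
  structure(list(
    F_surgery = pick("surgery", "F value"),
    F_drug = pick("drug", "F value"),
    F_interaction = pick("surgery:drug", "F value"),
    p_surgery = pick("surgery", "Pr(>F)"),
    p_drug = pick("drug", "Pr(>F)"),
    p_interaction = pick("surgery:drug", "Pr(>F)"),
    df = c(1L, n - 4L),
    d_surgery = d_surg$d, d_surgery_label = d_surg$label,
    d_interaction = d_int$d, d_interaction_label = d_int$label,
    cell_means = cell_means, cell_sds = cell_sds, cell_ns = cell_ns),
    class = "factorial_result")
}

#' Cohen's d with magnitude label
#'
#' `d = (mean_a - mean_b) / s_pooled`, with the pooled standard deviation
#' weighted by degrees of freedom. Accepts raw samples or
#' `(mean, sd, n)` moment triples. The magnitude label follows the
#' conventional cutpoints: `|d| < 0.2` small, `0.2 <= |d| <= 0.8` medium,
#' `|d| > 0.8` large.
#'
#' @param group_a,group_b Numeric vectors of observations, or lists
#'   `list(mean =, sd =, n =)`.
#' @return List with `d` (signed) and `label`.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))
#' cohens_d(list(mean = 1, sd = 1, n = 10), list(mean = 0, sd = 1, n = 10))
#' @export
cohens_d <- function(group_a, group_b) {
  mom <- function(g) {
    if (is.list(g)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(g)), g$n >= 2)
      g
    } else {
      if (length(g) < 2) stop("need n >= 2 per group (or supply moments)")
      list(mean = mean(g), sd = sd(g), n = length(g))
    }
  }
  a <- mom(group_a); b <- mom(group_b)
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  if (sp == 0) stop("undefined effect size: pooled SD is zero")
  d <- (a$mean - b$mean) / sp
  label <- if (abs(d) < 0.2) "small" else if (abs(d) > 0.8) "large" else "medium"
  list(d = d, label = label)
}

#' Composite visual water task performance score
#'
#' Arithmetic mean of the final-probe percent-correct scores of the two
#' discrimination problems (elemental and transverse).
#'
#' @param probe_elemental,probe_transverse Percent correct in `[0, 100]`;
#'   vectorised, no missing values.
#' @return Numeric vector of composite scores.
#' @export
composite_vwt_score <- function(probe_elemental, probe_transverse) {
  if (anyNA(probe_elemental) || anyNA(probe_transverse)) {
    stop("incomplete behavior record: missing probe score")
  }
  stopifnot(length(probe_elemental) == length(probe_transverse))
  if (any(probe_elemental < 0 | probe_elemental > 100 |
          probe_transverse < 0 | probe_transverse > 100)) {
    stop("probe scores must lie in [0, 100]")
  }
  (probe_elemental + probe_transverse) / 2
}

#' Brain-behavior correlations across ROIs
#'
#' Pearson correlation (two-tailed p from the exact t transform) between
#' the behavior score and each ROI's CO activity, over the full cohort or
#' with lesioned subjects excluded. No multiplicity correction is applied
#' by default; `fdr = TRUE` adds a Benjamini-Hochberg column alongside the
#' raw p values (never substituted).
#'
#' @param cohort A `cohort_table`.
#' @param scores Behavior scores aligned to `cohort` rows; defaults to the
#'   `vwt_score` column.
#' @param exclude_lesioned Drop subjects flagged `lesioned`.
#' @param fdr Add a `p_fdr` column.
#' @return Data frame with `roi`, `r`, `n`, `p`, `lesioned_excluded`
#'   (and `p_fdr` when requested).
#' @export
brain_behavior_correlations <- function(cohort, scores = cohort$vwt_score,
                                        exclude_lesioned = FALSE,
                                        fdr = FALSE) {
  if (is.null(scores)) stop("no behavior scores supplied or found")
  stopifnot(length(scores) == nrow(cohort))
  keep <- rep(TRUE, nrow(cohort))
  if (exclude_lesioned) {
    if (is.null(cohort$lesioned)) stop("no lesion flags in cohort")
    keep <- !cohort$lesioned
  }
  if (sum(keep) < 3) stop("insufficient n: fewer than 3 included subjects")
  s <- as.numeric(scores)[keep]
  if (sd(s) == 0) stop("behavior variance zero")
  act <- cohort_activity(cohort)[keep, , drop = FALSE]
  n <- length(s)
  res <- lapply(colnames(act), function(roi) {
    r <- cor(act[, roi], s)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(roi = roi, r = r, n = n,
               p = 2 * pt(-abs(tt), df = n - 2),
               lesioned_excluded = exclude_lesioned,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (fdr) out$p_fdr <- p.adjust(out$p, "BH")
  out
}

#' Per-ROI factorial statistics table for a cohort
#'
#' Runs [two_way_anova()] on every ROI column and assembles a flat results
#' table (cell means/SEMs, F and p per effect, both Cohen's d variants).
#' No correction across ROIs is applied by default, mirroring common
#' practice in CO-mapping studies; `fdr = TRUE` appends Benjamini-Hochberg
#' columns for audit.
#'
#' @param cohort A `cohort_table` with `surgery` and `drug` columns.
#' @param fdr Append `p_*_fdr` columns.
#' @return Data frame, one row per ROI.
#' @export
roi_stats_table <- function(cohort, fdr = FALSE) {
  act <- cohort_activity(cohort)
  surgery <- factor(cohort$surgery, levels = unique(cohort$surgery))
  drug <- factor(cohort$drug, levels = unique(cohort$drug))
  rows <- lapply(colnames(act), function(roi) {
    fr <- two_way_anova(act[, roi], surgery, drug)
    cm <- fr$cell_means; cs <- fr$cell_sds; cn <- fr$cell_ns
    cells <- expand.grid(s = rownames(cm), d = colnames(cm),
                         stringsAsFactors = FALSE)
    stats <- setNames(
      as.list(c(cm[as.matrix(cells)],
                cs[as.matrix(cells)] / sqrt(cn[as.matrix(cells)]))),
      c(paste0("mean_", cells$s, "_", cells$d),
        paste0("sem_", cells$s, "_", cells$d)))
    cbind(data.frame(roi = roi,
                     F_surgery = fr$F_surgery, p_surgery = fr$p_surgery,
                     F_drug = fr$F_drug, p_drug = fr$p_drug,
                     F_interaction = fr$F_interaction,
                     p_interaction = fr$p_interaction,
                     d_surgery = fr$d_surgery,
                     d_interaction = fr$d_interaction,
                     df_error = fr$df[2],
                     stringsAsFactors = FALSE),
          as.data.frame(stats))
  })
  out <- do.call(rbind, rows)
  if (fdr) {
    for (eff in c("surgery", "drug", "interaction")) {
      out[[paste0("p_", eff, "_fdr")]] <-
        p.adjust(out[[paste0("p_", eff)]], "BH")
    }
  }
  out
}

#' Reconstruct per-subject data matching printed cell moments
#'
#' Builds a dataset whose four cells exactly match given means and
#' standard deviations (any such dataset yields identical F statistics,
#' since the factorial ANOVA depends on the data only through cell
#' moments). Used to audit printed F values against reported
#' means +/- SEM tables: cell SDs are `SEM * sqrt(n)`.
#'
#' @param cell_means,cell_sems Numeric length-4 vectors in group order.
#' @param group_sizes Integer length-4 vector (default `c(9, 9, 9, 8)`).
#' @param group_labels `<surgery>+<drug>` labels defining the factors.
#' @return Data frame with `y`, `surgery`, `drug`.
#' @examples
#' ref <- co_cohort_reference()
#' v2 <- ref[ref$abbrev == "V2", ]
#' d <- moment_matched_cells(unlist(v2[, grep("mean_", names(v2))]),
#'                           unlist(v2[, grep("sem_", names(v2))]))
#' two_way_anova(d$y, d$surgery, d$drug)$F_surgery
#' @export
moment_matched_cells <- function(cell_means, cell_sems,
                                 group_sizes = c(9L, 9L, 9L, 8L),
                                 group_labels = co_group_labels()) {
  stopifnot(length(cell_means) == 4, length(cell_sems) == 4,
            length(group_sizes) == 4)
  fac <- parse_group_labels(group_labels)
  out <- lapply(1:4, function(i) {
    n <- group_sizes[i]
    z <- as.numeric(scale(seq_len(n)))  # exact mean 0, sd 1
    data.frame(y = cell_means[i] + cell_sems[i] * sqrt(n) * z,
               surgery = fac$surgery[i], drug = fac$drug[i],
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, out)
  d$surgery <- factor(d$surgery, levels = unique(fac$surgery))
  d$drug <- factor(d$drug, levels = unique(fac$drug))
  d
}
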