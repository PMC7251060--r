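# Independent oracles and small fixture builders used across the suite.

# Type III F statistics by brute force: residual sum of squares of the
# full sum-to-zero 2x2 model vs the model with one column dropped.
# Independent of two_way_anova(), which goes through car::Anova.
oracle_type3_F <- function(y, A, B) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- model.matrix(~ A * B)
  rss <- function(M) sum(lm.fit(M, y)$residuals^2)
  full <- rss(X)
  dfe <- length(y) - ncol(X)
  out <- vapply(2:4, function(j) {
    (rss(X[, -j, drop = FALSE]) - full) / (full / dfe)
  }, 0)
  names(out) <- c("A", "B", "AB")
  out
}

# Brute-force per-pixel point-in-polygon mask using pracma::inpolygon
# (independent of the scanline rasteriser). Vertices 0-based (row, col).
oracle_polygon_mask <- function(nrow, ncol, vertices) {
  centers <- expand.grid(row = 0:(nrow - 1), col = 0:(ncol - 1))
  inside <- pracma::inpolygon(centers$col, centers$row,
                              vertices[, 2], vertices[, 1])
  matrix(inside, nrow = nrow, ncol = ncol)
}

# Minimal cohort table around an activity matrix (one group).
make_cohort_df <- function(mat, group = "g1+x", lesioned = FALSE) {
  fac <- strsplit(group, "+", fixed = TRUE)[[1]]
  df <- cbind(data.frame(subject_id = sprintf("S%03d", seq_len(nrow(mat))),
                         group = group, surgery = fac[1], drug = fac[2],
                         lesioned = lesioned, stringsAsFactors = FALSE),
              as.data.frame(mat))
  attr(df, "roi_names") <- colnames(mat)
  class(df) <- c("cohort_table", "data.frame")
  df
}

# A fitted calibration pair (camera curve + activity line) built from
# noiseless synthetic materials; shared by densitometry fixtures.
fixture_curves <- function() {
  tablet <- generate_step_tablet(12, c(0.05, 1.2), gray_noise = 0)
  standards <- generate_standards(noise_sd = 0)
  list(calib = fit_gray_to_od(tablet),
       act = fit_od_to_activity(standards))
}

# Rectangle polygon helper, 0-based (row, col), half-integer corners.
rect_poly <- function(top, left, height, width, ...) {
  list(vertices = rbind(c(top, left), c(top, left + width),
                        c(top + height, left + width), c(top + height, left)),
       ...)
}
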