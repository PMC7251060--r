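test_that("Fisher z transform matches closed forms and is antisymmetric", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  expect_equal(fisher_z(-0.3), -0.30952, tolerance = 1e-4)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1), "undefined at \\|r\\| = 1")
  z <- seq(-4.9, 4.9, length.out = 101)
  expect_equal(fisher_z(tanh(z)), z, tolerance = 1e-12)
})

test_that("edge comparison reproduces the closed-form Z test and its antisymmetry", {
  e <- compare_edge(0.9, 12, 0.3, 12)
  expect_equal(e$Z, (atanh(0.9) - atanh(0.3)) / sqrt(2 / 9))
  expect_equal(e$Z, 2.4664, tolerance = 1e-4)
  expect_equal(e$p, 0.013646, tolerance = 1e-4)
  expect_equal(e$verdict, "weakened")
  sw <- compare_edge(0.3, 12, 0.9, 12)
  expect_equal(sw$Z, -e$Z)
  expect_equal(sw$verdict, "strengthened")
  same <- compare_edge(0.8, 10, 0.8, 25)
  expect_equal(same$Z, 0)
  expect_equal(same$verdict, "unchanged")
  expect_error(compare_edge(0.5, 3, 0.5, 10), "variance of z undefined")
  tt <- compare_edge(0.9, 12, 0.3, 12, method = "t")
  expect_gt(tt$p, e$p)   # heavier tails than the normal reference
})

test_that("group correlation matrices are symmetric, unit-diagonal, and guarded", {
  set.seed(5)
  mat <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("R", 1:6)))
  mat[, 2] <- mat[, 1]            # duplicate column
  ct <- make_cohort_df(mat)
  g <- group_correlation_matrix(ct)
  expect_equal(g$r, t(g$r))
  expect_equal(unname(diag(g$r)), rep(1, 6))
  expect_equal(g$r[1, 2], 1.0)
  expect_true(all(g$p[upper.tri(g$p)] > 0 & g$p[upper.tri(g$p)] <= 1))
  # independent columns: weak mean absolute off-diagonal correlation
  set.seed(5)
  mat2 <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(NULL, paste0("R", 1:10)))
  g2 <- group_correlation_matrix(make_cohort_df(mat2))
  expect_lt(mean(abs(g2$r[upper.tri(g2$r)])), 0.25)
  mat3 <- mat2; mat3[, 4] <- 7
  colnames(mat3)[4] <- "FLAT"
  expect_error(group_correlation_matrix(make_cohort_df(mat3)), "FLAT")
  expect_error(group_correlation_matrix(make_cohort_df(mat2[1:3, ])),
               "too small")
})

test_that("self-comparison yields no significant edges at any alpha", {
  set.seed(9)
  mat <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("R", 1:8)))
  g <- group_correlation_matrix(make_cohort_df(mat))
  for (alpha in c(0.01, 0.05, 0.5, 0.99)) {
    dm <- difference_map(g, g, alpha = alpha)
    expect_equal(dm$n_strengthened + dm$n_weakened, 0)
  }
})

test_that("difference map flags a planted edge and controls the false-positive rate", {
  p <- 20
  hits <- 0
  fps <- numeric(40)
  for (s in 1:40) {
    set.seed(s)
    R1 <- diag(p); R1[1, 2] <- R1[2, 1] <- 0.9
    x1 <- MASS::mvrnorm(30, rep(0, p), R1)
    x2 <- MASS::mvrnorm(30, rep(0, p), diag(p))
    colnames(x1) <- colnames(x2) <- paste0("R", 1:p)
    dm <- difference_map(
      group_correlation_matrix(make_cohort_df(x1, "A+x")),
      group_correlation_matrix(make_cohort_df(x2, "B+x")))
    planted <- dm$edges$roi_a == "R1" & dm$edges$roi_b == "R2"
    hits <- hits + (dm$edges$verdict[planted] == "weakened")
    fps[s] <- sum(dm$edges$verdict[!planted] != "unchanged")
  }
  expect_gte(hits / 40, 0.8)
  n_null <- choose(p, 2) - 1
  expect_lt(abs(mean(fps) - 0.05 * n_null),
            3 * sqrt(0.05 * 0.95 * n_null / 40))
})

test_that("difference map requires conformable ROI sets and excludes perfect edges", {
  set.seed(2)
  m1 <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  m2 <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, c("A", "B", "D")))
  g1 <- group_correlation_matrix(make_cohort_df(m1))
  g2 <- group_correlation_matrix(make_cohort_df(m2))
  expect_error(difference_map(g1, g2), "not conformable")
  m3 <- m1; m3[, 2] <- 2 * m3[, 1] + 5   # perfectly correlated pair
  colnames(m3) <- colnames(m1)
  g3 <- group_correlation_matrix(make_cohort_df(m3))
  dm <- difference_map(g3, g1)
  expect_equal(nrow(dm$excluded), 1)
  expect_equal(nrow(dm$edges), 2)
})

test_that("planted visual-hippocampal coupling concentrates significant edges there", {
  rois <- co_cohort_reference()$abbrev
  vis_hip <- c(co_roi_groups()$visual, co_roi_groups()$hippocampal)
  R_base <- block_correlation(rois)
  R_mb <- block_correlation(rois,
                            coupling = list(list(rois = vis_hip, r = 0.38)))
  spec <- cohort_spec(
    group_sizes = c(9L, 9L, 30L, 30L),
    within_group_corr = list(R_base, R_base, R_base, R_mb),
    seed = 11)
  ct <- generate_cohort(spec)
  dm <- difference_map(group_correlation_matrix(ct, "2VO+saline"),
                       group_correlation_matrix(ct, "2VO+MB"),
                       alpha = 0.01)
  sig <- dm$edges[dm$edges$verdict == "strengthened", ]
  in_block <- sig$roi_a %in% vis_hip & sig$roi_b %in% vis_hip
  expect_gt(nrow(sig), 0)
  expect_gt(mean(in_block), 0.5)
  # the planted block is uniformly positive in the MB group's heat map
  gmb <- group_correlation_matrix(ct, "2VO+MB")
  expect_gt(min(gmb$r[vis_hip, vis_hip]), 0)
})

test_that("heat-map export writes a diverging PNG and a bit-exact CSV twin", {
  m <- diag(5)
  dimnames(m) <- list(paste0("R", 1:5), paste0("R", 1:5))
  png_path <- withr::local_tempfile(fileext = ".png")
  out <- export_heatmap(m, png_path)
  img <- png::readPNG(out$png)
  # diagonal cells are saturated red; off-diagonal the white midpoint
  expect_equal(img[1, 1, ], c(1, 0, 0))
  expect_equal(img[1, 10, ], c(1, 1, 1))
  ones <- matrix(1, 4, 4, dimnames = list(paste0("A", 1:4), paste0("A", 1:4)))
  out2 <- export_heatmap(ones, withr::local_tempfile(fileext = ".png"))
  img2 <- png::readPNG(out2$png)
  expect_true(all(img2[, , 1] == 1) && all(img2[, , 2] == 0) &&
                all(img2[, , 3] == 0))
  # CSV twin round-trips bit-exactly for generic correlations
  set.seed(3)
  g <- group_correlation_matrix(make_cohort_df(
    matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0("R", 1:6)))))
  out3 <- export_heatmap(g, withr::local_tempfile(fileext = ".png"))
  back <- cohmap:::read_matrix_csv(out3$csv)
  expect_identical(unname(back), unname(g$r))
})

test_that("edge comparison holds its nominal type-I error rate", {
  set.seed(7)
  rej <- mean(vapply(1:1500, function(i) {
    x1 <- MASS::mvrnorm(20, c(0, 0), matrix(c(1, .5, .5, 1), 2))
    x2 <- MASS::mvrnorm(20, c(0, 0), matrix(c(1, .5, .5, 1), 2))
    compare_edge(cor(x1)[1, 2], 20, cor(x2)[1, 2], 20)$p < 0.05
  }, TRUE))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})
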