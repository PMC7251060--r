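test_that("step tablet spans the requested density range with monotone gray", {
  tab <- generate_step_tablet(21, c(0.06, 3.05), seed = 1)
  expect_equal(nrow(tab), 21)
  expect_equal(min(tab$known_od), 0.06)
  expect_equal(max(tab$known_od), 3.05)
  expect_true(all(diff(tab$known_od) > 0))
  expect_true(all(diff(tab$gray_level) < 0))
  expect_true(all(tab$gray_level >= 0 & tab$gray_level <= 255))
})

test_that("noiseless tablet inverts the reference camera model exactly", {
  tab <- generate_step_tablet(5, c(0.1, 2.0), gray_noise = 0)
  expect_equal(tab$gray_level, 256 / 10^tab$known_od - 1)
  fit <- fit_gray_to_od(tab)
  expect_equal(fit$alpha, 0, tolerance = 1e-10)
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  expect_gt(fit$fit_r2, 0.999)
})

test_that("step tablet rejects degenerate requests", {
  expect_error(generate_step_tablet(3, c(0.1, 1)), "insufficient calibration")
  expect_error(generate_step_tablet(4, c(0.5, 0.5)), "increasing")
  expect_error(generate_step_tablet(4, c(0, 1)), "\\(0, 4]")
  expect_error(generate_step_tablet(4, c(0.1, 4.5)), "\\(0, 4]")
})

test_that("tissue standards are exactly linear without noise and near-linear with it", {
  std0 <- generate_standards(noise_sd = 0)
  expect_equal(nrow(std0), 5)
  expect_equal(cor(std0$mean_od, std0$spectro_activity), 1.0)
  std <- generate_standards(noise_sd = 0.01, seed = 7)
  expect_gte(cor(std$mean_od, std$spectro_activity), 0.95)
  expect_error(generate_standards(c(10, 10, 10)), "underdetermined")
})

test_that("cohort generation matches the requested design and is seed-reproducible", {
  spec <- cohort_spec(seed = 42)
  ct <- generate_cohort(spec)
  expect_equal(nrow(ct), 35)
  expect_equal(length(attr(ct, "roi_names")), 44)
  expect_equal(as.vector(table(ct$group)[co_group_labels()]), c(9, 9, 9, 8))
  # lesions only in occluded groups, one third of each
  expect_equal(sum(ct$lesioned[ct$surgery == "sham"]), 0)
  expect_equal(sum(ct$lesioned[ct$group == "2VO+saline"]), 3)
  expect_equal(sum(ct$lesioned[ct$group == "2VO+MB"]), 3)
  expect_identical(ct, generate_cohort(spec))
  expect_false(identical(ct$PRh, generate_cohort(spec, seed = 43)$PRh))
})

test_that("generator targets reproduce the reference V2 cell means", {
  spec <- cohort_spec()
  expect_equal(unname(spec$cell_means["V2", ]),
               c(249.72, 249.49, 206.10, 239.80))
})

test_that("zero-variance limit collapses subjects onto their cell means", {
  spec <- cohort_spec(
    within_group_corr = diag(44),
    cell_sems = matrix(1e-9, 44, 4,
                       dimnames = list(co_cohort_reference()$abbrev,
                                       co_group_labels())),
    seed = 3)
  ct <- generate_cohort(spec)
  act <- as.matrix(ct[, spec$roi_names])
  for (g in seq_len(4)) {
    sub <- act[ct$group == spec$group_labels[g], ]
    expect_equal(sub, matrix(spec$cell_means[, g], nrow(sub), 44,
                             byrow = TRUE, dimnames = dimnames(sub)),
                 tolerance = 1e-5)
  }
})

test_that("sample cell means concentrate on targets across seeds", {
  spec <- cohort_spec(seed = 42)
  frac <- mean(vapply(1:200, function(s) {
    ct <- generate_cohort(spec, seed = s)
    ok <- vapply(seq_along(spec$group_labels), function(g) {
      sub <- as.matrix(ct[ct$group == spec$group_labels[g], spec$roi_names])
      mean(abs(colMeans(sub) - spec$cell_means[, g]) <= 2 * spec$cell_sems[, g])
    }, 0)
    mean(ok)
  }, 0))
  expect_gte(frac, 0.95)
})

test_that("non-PSD correlation input is rejected, with explicit repair available", {
  R <- diag(44)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9   # impossible triangle
  expect_error(cohort_spec(within_group_corr = R),
               "not positive semi-definite")
  R2 <- nearest_psd(R)
  expect_gte(min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_silent(validate_cohort_spec(cohort_spec(within_group_corr = R2)))
})

test_that("block correlation matrix is PSD with unit diagonal and planted coupling", {
  R <- block_correlation(co_cohort_reference()$abbrev,
                         coupling = list(list(rois = c("V1", "V2", "CA1A"),
                                              r = 0.2)))
  expect_equal(diag(R), setNames(rep(1, 44), co_cohort_reference()$abbrev))
  expect_equal(R, t(R))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(R["V1", "CA1A"], R["V1", "CPu"])
})

test_that("behavior scores realize a planted target correlation on average", {
  spec <- cohort_spec(seed = 42)
  rs <- vapply(1:400, function(s) {
    ct <- generate_cohort(spec, seed = s)
    y <- generate_behavior(ct, c(PRh = 0.526), seed = s + 20000L)
    cor(y, ct$PRh)
  }, 0)
  expect_lt(abs(mean(rs) - 0.526), 0.08)
})

test_that("behavior generator limits behave: near-deterministic and null targets", {
  ct <- generate_cohort(cohort_spec(seed = 42))
  y <- generate_behavior(ct, c(PRh = 0.999), seed = 1)
  expect_gt(cor(y, ct$PRh), 0.99)
  # with all-zero targets each ROI's |r| exceeds the 2/sqrt(n) null bound
  # only at the nominal few-percent rate
  viol <- vapply(1:100, function(s) {
    y0 <- generate_behavior(ct, c(PRh = 0), seed = s)
    mean(abs(cor(y0, as.matrix(ct[, attr(ct, "roi_names")]))) > 2 / sqrt(35))
  }, 0)
  expect_lt(mean(viol), 0.10)
  expect_true(all(y >= 0 & y <= 100))
})

test_that("jointly infeasible behavior targets are refused", {
  spec <- cohort_spec(seed = 42)
  ct <- generate_cohort(spec)
  expect_error(generate_behavior(ct, c(V1 = 0.9, V2 = -0.9)), "infeasible")
  expect_error(generate_behavior(ct, c(PRh = 1.2)), "\\|r\\| < 1")
})

test_that("rendered lesions hit their target area and stay in the OD band", {
  cur <- fixture_curves()
  layout <- make_roi_layout(c("CPu", "V1"), dims = c(120, 240))
  act <- c(CPu = 195, V1 = 240)
  wm_od <- 0.30
  # 50 x 100 px at 10 um/px = 0.5 mm^2
  les <- rect_poly(60.5, 20.5, 50, 100)
  sec <- generate_section_image(act, layout, cur$calib, cur$act,
                                dims = c(120, 240), lesion_spec = list(les),
                                wm_od = wm_od)
  px_area <- sum(sec$lesion_mask) * (10 / 1000)^2
  expect_lt(abs(px_area - 0.5), 100 * (10 / 1000)^2)  # within one pixel row
  od <- gray_to_od(cur$calib, sec$image)
  band <- range(od[sec$lesion_mask])
  expect_gte(band[1], 0.85 * wm_od - 0.01)
  expect_lte(band[2], 0.98 * wm_od + 0.01)
})

test_that("identical seeds give bit-identical section images", {
  cur <- fixture_curves()
  layout <- make_roi_layout(c("A", "B"), dims = c(60, 120))
  act <- c(A = 200, B = 300)
  s1 <- generate_section_image(act, layout, cur$calib, cur$act,
                               dims = c(60, 120), noise_sd = 0.01, seed = 9)
  s2 <- generate_section_image(act, layout, cur$calib, cur$act,
                               dims = c(60, 120), noise_sd = 0.01, seed = 9)
  expect_identical(s1$image, s2$image)
})

test_that("activities outside the calibrated range are refused", {
  cur <- fixture_curves()
  layout <- make_roi_layout(c("A"), dims = c(60, 120))
  expect_error(
    generate_section_image(c(A = 1e5), layout, cur$calib, cur$act,
                           dims = c(60, 120)),
    "not invertible")
})

test_that("ROI layout JSON round-trips", {
  layout <- make_roi_layout(c("V1", "V2"), dims = c(80, 160))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_layout(layout, path)
  back <- read_roi_layout(path)
  expect_equal(length(back), length(layout))
  expect_equal(back[[1]]$roi, layout[[1]]$roi)
  expect_equal(back[[1]]$vertices, unname(layout[[1]]$vertices))
})
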