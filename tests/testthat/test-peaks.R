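grid_fixture <- function(shape = c(10, 10, 10), voxel_mm = 3) {
  ijk <- as.matrix(expand.grid(i = 1:shape[1], j = 1:shape[2], k = 1:shape[3]))
  affine <- polarisc:::.default_affine(shape, voxel_mm)
  list(ijk = ijk, affine = affine)
}

bump <- function(ijk, center, height = 1, width = 1.5) {
  d2 <- rowSums(sweep(ijk, 2, center)^2)
  height * exp(-d2 / (2 * width^2))
}

test_that("peak extraction finds planted maxima at the right locations", {
  g <- grid_fixture()
  vals <- bump(g$ijk, c(3, 3, 3), 0.3)
  sig <- vals > 0.05
  pk <- extract_peaks(vals, sig, g$ijk, g$affine)
  expect_equal(nrow(pk), 1)
  expect_equal(unlist(pk[1, c("i", "j", "k")]), c(i = 3, j = 3, k = 3))
  expect_equal(pk$d, max(vals))
  # mm coordinates through the affine
  expect_equal(c(pk$x_mm, pk$y_mm, pk$z_mm),
               as.numeric(polarisc:::.ijk_to_mm(matrix(c(3, 3, 3), 1),
                                                g$affine)))

  # two regions 30 mm apart (10 voxels at 3 mm) -> 2 peaks
  vals2 <- bump(g$ijk, c(2, 2, 2), 0.3) + bump(g$ijk, c(9, 9, 9), 0.2)
  pk2 <- extract_peaks(vals2, vals2 > 0.03, g$ijk, g$affine)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$d[1], max(vals2))  # sorted by height

  # maxima closer than min_distance_mm merge, keeping the larger
  vals3 <- bump(g$ijk, c(4, 4, 4), 0.3) + bump(g$ijk, c(6, 4, 4), 0.28)
  pk3 <- extract_peaks(vals3, vals3 > 0.03, g$ijk, g$affine,
                       min_distance_mm = 10)
  expect_equal(nrow(pk3), 1)
})

test_that("peak extraction handles empty masks and flat maps", {
  g <- grid_fixture(c(5, 5, 5))
  vals <- bump(g$ijk, c(3, 3, 3))
  empty <- extract_peaks(vals, rep(FALSE, nrow(g$ijk)), g$ijk, g$affine)
  expect_s3_class(empty, "peak_table")
  expect_equal(nrow(empty), 0)
  expect_error(extract_peaks(rep(1, nrow(g$ijk)), rep(TRUE, nrow(g$ijk)),
                             g$ijk, g$affine), "flat")
})

test_that("peak extraction is translation-equivariant", {
  g <- grid_fixture(c(12, 12, 12))
  vals <- bump(g$ijk, c(4, 5, 6), 0.3)
  pk <- extract_peaks(vals, vals > 0.05, g$ijk, g$affine)
  shift <- c(3, 2, 1)
  vals_s <- bump(g$ijk, c(4, 5, 6) + shift, 0.3)
  pk_s <- extract_peaks(vals_s, vals_s > 0.05, g$ijk, g$affine)
  expect_equal(c(pk_s$x_mm, pk_s$y_mm, pk_s$z_mm),
               c(pk$x_mm, pk$y_mm, pk$z_mm) + shift * 3)
})

# A handmade peak-scores fixture: 2 peaks, 10 subjects in two groups.
scores_fixture <- function(more_shift = 0, seed = 31) {
  set.seed(seed)
  ids <- sprintf("s%02d", 1:10)
  asg <- data.frame(subject_id = ids,
                    group = rep(c("more_supportive", "less_supportive"),
                                each = 5))
  within <- matrix(rnorm(10 * 4, 0.3, 0.05), 10, 4,
                   dimnames = list(ids, NULL))
  between <- matrix(rnorm(10 * 4, 0.1, 0.05), 10, 4,
                    dimnames = list(ids, NULL))
  within[asg$group == "more_supportive", ] <-
    within[asg$group == "more_supportive", ] + more_shift
  maps <- structure(list(within = within, between = between,
                         diff = within - between,
                         average_diff = colMeans(within - between),
                         assignment = asg, narrative = "all"),
                    class = "polarization_maps")
  pk <- data.frame(x_mm = c(0, 3), y_mm = c(0, 0), z_mm = c(0, 0),
                   i = c(1, 2), j = 1, k = 1, voxel = c(1, 3),
                   d = maps$average_diff[c(1, 3)], p = 0.001, source = "all")
  class(pk) <- c("peak_table", class(pk))
  list(maps = maps, peaks = pk, assignment = asg)
}

test_that("score_peaks reads the per-subject values at peak voxels", {
  f <- scores_fixture()
  sc <- score_peaks(f$maps, f$peaks, f$assignment)
  expect_equal(nrow(sc), 20)
  expect_equal(sc$diff[sc$peak == 1], unname(f$maps$diff[, 1]))
  expect_equal(sc$within_R[sc$peak == 2], unname(f$maps$within[, 3]))
  bad <- f$peaks; bad$voxel[1] <- 99
  expect_error(score_peaks(f$maps, bad, f$assignment), "outside")
})

test_that("peak-level tests reproduce hand-computed t statistics", {
  f <- scores_fixture()
  sc <- score_peaks(f$maps, f$peaks, f$assignment)
  out <- peak_level_tests(sc)
  expect_equal(out$df_more, c(4, 4))
  expect_equal(out$df_between, c(8, 8))
  # hand computation for peak 1
  more <- f$maps$diff[f$assignment$group == "more_supportive", 1]
  less <- f$maps$diff[f$assignment$group == "less_supportive", 1]
  expect_equal(out$t_more[1], mean(more) / (sd(more) / sqrt(5)),
               tolerance = 1e-12)
  sp <- sqrt((4 * var(more) + 4 * var(less)) / 8)
  expect_equal(out$t_between[1],
               (mean(more) - mean(less)) / (sp * sqrt(2 / 5)),
               tolerance = 1e-12)
  # zero-variance group -> t = 0
  f0 <- f
  f0$maps$diff[f$assignment$group == "more_supportive", ] <- 0
  sc0 <- score_peaks(f0$maps, f0$peaks, f0$assignment)
  expect_equal(peak_level_tests(sc0)$t_more, c(0, 0))
})

test_that("symmetric planted polarization rarely separates the groups", {
  sig <- vapply(1:10, function(s) {
    f <- scores_fixture(more_shift = 0, seed = 600 + s)
    sc <- score_peaks(f$maps, f$peaks, f$assignment)
    any(peak_level_tests(sc)$p_between < 0.05)
  }, logical(1))
  expect_gte(mean(!sig), 0.5)  # per-peak level ~0.05, two peaks
})

test_that("pooled contrast equals single-peak test and plain averaging", {
  f <- scores_fixture(more_shift = 0.1)
  sc <- score_peaks(f$maps, f$peaks, f$assignment)
  # single-peak set identical to that peak's two-sample test
  one <- pooled_peak_contrast(sc, peak_set = 1)
  pt <- peak_level_tests(sc)
  expect_equal(one$t, pt$t_between[1], tolerance = 1e-12)
  expect_equal(one$cohens_d, pt$cohens_d[1], tolerance = 1e-12)
  # pooled mean is the arithmetic mean of per-peak diffs
  both <- pooled_peak_contrast(sc)
  expect_equal(unname(both$pooled["s01"]),
               mean(f$maps$diff["s01", c(1, 3)]), tolerance = 1e-12)
  expect_equal(both$df, 8)
  expect_error(pooled_peak_contrast(sc, peak_set = integer(0)), "empty")
})

test_that("cross-narrative contrast is a paired t with FDR over peaks", {
  f <- scores_fixture()
  sc <- score_peaks(f$maps, f$peaks, f$assignment)
  # identical frame selections -> t = 0
  same <- cross_narrative_contrast(sc, sc)
  expect_equal(same$t, c(0, 0))
  expect_equal(same$df, c(9, 9))
  # textbook paired formula on a shifted copy
  sc2 <- sc
  set.seed(32)
  sc2$diff <- sc$diff + rnorm(20, 0.05, 0.02)
  out <- cross_narrative_contrast(sc, sc2)
  d1 <- sc$diff[sc$peak == 1] - sc2$diff[sc2$peak == 1]
  expect_equal(out$t[1], mean(d1) / (sd(d1) / sqrt(10)), tolerance = 1e-12)
  expect_true(all(c("q") %in% names(out)))
  expect_error(cross_narrative_contrast(sc, sc[1:10, ]), "same subjects")
})

test_that("interaction F equals the squared two-sample t on differences", {
  set.seed(33)
  ids <- sprintf("s%02d", 1:12)
  asg <- data.frame(subject_id = ids,
                    group = rep(c("more_supportive", "less_supportive"),
                                each = 6))
  diffs <- data.frame(subject_id = ids, pro = rnorm(12, 0.2, 0.1),
                      anti = rnorm(12, 0.1, 0.1))
  out <- interaction_anova(diffs, asg)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 10)
  d <- diffs$pro - diffs$anti
  tt <- t.test(d[asg$group == "more_supportive"],
               d[asg$group == "less_supportive"], var.equal = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p, tt$p.value, tolerance = 1e-10)
  expect_error(interaction_anova(transform(diffs, pro = NA), asg), "missing")
})

test_that("a crossed group-by-type effect drives the interaction F", {
  hits <- vapply(1:10, function(s) {
    set.seed(700 + s)
    ids <- sprintf("s%02d", 1:20)
    asg <- data.frame(subject_id = ids,
                      group = rep(c("more_supportive", "less_supportive"),
                                  each = 10))
    g <- ifelse(asg$group == "more_supportive", 1, -1)
    diffs <- data.frame(subject_id = ids,
                        pro = 0.2 + 0.15 * g + rnorm(20, 0, 0.08),
                        anti = 0.2 - 0.15 * g + rnorm(20, 0, 0.08))
    interaction_anova(diffs, asg)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("between-group sign comparison pools subjects over peak sets", {
  f <- scores_fixture()
  sc <- score_peaks(f$maps, f$peaks, f$assignment)
  # identical distributions -> |t| small
  out <- between_group_sign_comparison(sc, sc)
  expect_equal(out$t, 0, tolerance = 1e-12)
  expect_equal(out$df, 18)  # 10 + 10 - 2
  # pooled-variance formula on a planted sign difference
  sc_neg <- sc
  sc_neg$between_R <- sc$between_R - 0.3
  out2 <- between_group_sign_comparison(sc_neg, sc)
  a <- tapply(sc_neg$between_R, sc_neg$subject_id, mean)
  b <- tapply(sc$between_R, sc$subject_id, mean)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(out2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_lt(out2$p, 0.01)
  expect_lt(out2$mean_a, out2$mean_b)
})

test_that("neural-behavioral correlations report both families with q", {
  set.seed(34)
  ids <- sprintf("s%02d", 1:15)
  ias <- stats::setNames(seq(-2, 2, length.out = 15), ids)
  lin <- stats::setNames(3 * ias + 1, ids)
  out <- correlate_peaks_with_behavior(list(peak = lin), list(ias = ias))
  expect_equal(out$pearson_r, 1, tolerance = 1e-12)
  # monotone nonlinear: Spearman 1, Pearson < 1
  mono <- stats::setNames(exp(ias), ids)
  out2 <- correlate_peaks_with_behavior(list(peak = mono), list(ias = ias))
  expect_equal(out2$spearman_rho, 1, tolerance = 1e-12)
  expect_lt(out2$pearson_r, 1)
  # independent scores: uncorrected rate ~ alpha, q-significant ~ none
  set.seed(35)
  measures <- lapply(1:40, function(i) stats::setNames(rnorm(15), ids))
  names(measures) <- paste0("m", 1:40)
  out3 <- correlate_peaks_with_behavior(
    list(peak = stats::setNames(rnorm(15), ids)), measures)
  expect_lt(mean(out3$pearson_p < 0.05), 0.2)
  expect_lte(mean(out3$pearson_q <= 0.05), 0.05)
})
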