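types22 <- rep(c("pro", "anti"), each = 22)

test_that("IAS scoring matches direct arithmetic and the scale endpoints", {
  # extremes: all pro 5, all anti 1 -> +4
  r <- ratings_from_matrix(matrix(c(rep(5, 22), rep(1, 22)), 1), types22)
  expect_equal(compute_ias(r)$ias, 4)

  # symmetry: identical pro and anti ratings -> 0
  r0 <- ratings_from_matrix(matrix(rep(3, 44), 1), types22)
  expect_equal(compute_ias(r0)$ias, 0)

  # integer fixture checked by direct sums: pro mean 4.5, anti mean 2 -> 2.5
  pro <- c(rep(4, 11), rep(5, 11))
  anti <- c(rep(1, 11), rep(3, 11))
  r2 <- ratings_from_matrix(matrix(c(pro, anti), 1), types22)
  out <- compute_ias(r2)
  expect_equal(out$mean_pro, sum(pro) / 22)
  expect_equal(out$mean_anti, sum(anti) / 22)
  expect_equal(out$ias, sum(pro) / 22 - sum(anti) / 22)

  # invariant ias = mean_pro - mean_anti and |ias| <= 4 on random tables
  set.seed(1)
  m <- matrix(sample(1:5, 5 * 44, replace = TRUE), 5)
  out3 <- compute_ias(ratings_from_matrix(m, types22))
  expect_equal(out3$ias, out3$mean_pro - out3$mean_anti)
  expect_true(all(abs(out3$ias) <= 4))

  # errors: incomplete table, out-of-range rating
  two <- ratings_from_matrix(matrix(3, 2, 44), types22)
  expect_error(compute_ias(two[-1, ]), "exactly once")
  bad <- r; bad$rating[1] <- 6L
  expect_error(compute_ias(bad), "1..5")
})

test_that("median split halves the sample and respects the tie rule", {
  sc <- data.frame(subject_id = c("a", "b", "c", "d"), ias = c(1, 2, 3, 4))
  sp <- median_split(sc)
  expect_identical(sp$group[sp$subject_id %in% c("a", "b")],
                   rep("less_supportive", 2))
  expect_identical(sp$group[sp$subject_id %in% c("c", "d")],
                   rep("more_supportive", 2))
  expect_equal(attr(sp, "split_value"), 2.5)

  # tie at the median: broken in ascending subject-id order, sizes 2/2
  tie <- data.frame(subject_id = c("a", "b", "c", "d"), ias = c(1, 2, 2, 3))
  spt <- median_split(tie)
  expect_equal(unname(table(spt$group)), c(2L, 2L), ignore_attr = TRUE)
  expect_identical(spt$group[spt$subject_id == "b"], "less_supportive")
  expect_identical(spt$group[spt$subject_id == "c"], "more_supportive")
  # every more-supportive IAS >= every less-supportive IAS
  expect_gte(min(spt$ias[spt$group == "more_supportive"]),
             max(spt$ias[spt$group == "less_supportive"]))

  # invariance to row order apart from the documented tie rule
  perm <- sc[c(3, 1, 4, 2), ]
  spp <- median_split(perm)
  expect_identical(spp$group[order(spp$subject_id)],
                   sp$group[order(sp$subject_id)])

  # 40 distinct scores -> 20/20
  set.seed(2)
  big <- data.frame(subject_id = sprintf("s%02d", 1:40),
                    ias = sample(seq(0.1, 4, 0.1)))
  expect_equal(unname(table(median_split(big)$group)), c(20L, 20L),
               ignore_attr = TRUE)

  expect_error(median_split(data.frame(subject_id = c("a", "b"),
                                       ias = c(2, 2))), "identical")
})

test_that("scale scoring reflects reverse-keyed items correctly", {
  d <- scale_definition("toy", c("i1", "i2", "i3"), reverse_items = "i2",
                        range_min = 1, range_max = 7)
  resp <- responses_from_matrix(matrix(c(7, 7, 7), 1), c("i1", "i2", "i3"))
  # reversed 7 -> 1; mean of (7, 1, 7) = 5
  expect_equal(unname(score_scale(resp, d)), 5)

  # all items at the midpoint: reversal is a no-op
  mid <- responses_from_matrix(matrix(c(4, 4, 4), 1), c("i1", "i2", "i3"))
  expect_equal(unname(score_scale(mid, d)), 4)

  # hand-computed 3-item fixture with one reversal
  resp2 <- responses_from_matrix(matrix(c(2, 6, 5), 1), c("i1", "i2", "i3"))
  expect_equal(unname(score_scale(resp2, d)), mean(c(2, 8 - 6, 5)))

  bad <- resp; bad$response[1] <- 9L
  expect_error(score_scale(bad, d), "bounds")
})

test_that("Cronbach's alpha matches the variance formula", {
  items <- c("i1", "i2", "i3", "i4")
  d <- scale_definition("toy", items, range_min = 1, range_max = 7)

  # k identical items -> alpha = 1
  set.seed(3)
  base <- sample(1:7, 6, replace = TRUE)
  ident <- responses_from_matrix(matrix(base, 6, 4), items)
  expect_equal(cronbach_alpha(ident, d), 1)

  # two items with zero sample covariance -> alpha = 0
  d2 <- scale_definition("toy2", c("i1", "i2"), range_min = 1, range_max = 7)
  m0 <- cbind(c(1, 1, 7, 7), c(1, 7, 1, 7))  # cov = 0
  expect_equal(cov(m0)[1, 2], 0)
  expect_equal(cronbach_alpha(responses_from_matrix(m0, c("i1", "i2")), d2), 0)

  # 5 x 4 fixture against a brute-force evaluation of the formula
  set.seed(4)
  m <- matrix(sample(1:7, 20, replace = TRUE), 5, 4)
  got <- cronbach_alpha(responses_from_matrix(m, items), d)
  k <- 4
  expected <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("Cohen's d convention reproduces printed t/d pairs and round-trips", {
  expect_equal(round(cohens_d_from_t(3.119, 20, 20), 3), 0.986)
  expect_equal(round(cohens_d_from_t(-3.636, 20, 20), 3), -1.150)
  expect_equal(cohens_d_from_t(0, 10, 14), 0)
  # round trip d -> t for arbitrary sizes
  for (t in c(-2.5, 0.3, 4.1)) {
    d <- cohens_d_from_t(t, 13, 21)
    expect_equal(d / sqrt(1 / 13 + 1 / 21), t, tolerance = 1e-12)
  }
  expect_error(cohens_d_from_t(1, 1, 20), "at least 2")
})

test_that("minimal detectable effect solves the noncentral-t power equation", {
  d1 <- minimal_detectable_effect(40, design = "one_sample")
  d2 <- minimal_detectable_effect(20, 20, design = "two_sample")
  expect_equal(round(d1, 2), 0.45)
  expect_equal(round(d2, 2), 0.91)

  # monotonicity: doubling n shrinks the detectable effect
  expect_lt(minimal_detectable_effect(80, design = "one_sample"), d1)
  expect_lt(minimal_detectable_effect(40, 40, design = "two_sample"), d2)

  # Monte-Carlo power at the returned d is the target power within 0.02
  set.seed(5)
  expect_lt(abs(mc_power_one_sample(d1, 40) - 0.80), 0.02)
  expect_lt(abs(mc_power_two_sample(d2, 20, 20) - 0.80), 0.02)

  # unequal-group solver agrees with the equal-group closed path
  expect_equal(minimal_detectable_effect(20, 20, design = "two_sample"),
               minimal_detectable_effect(20, n2 = 20L, design = "two_sample"),
               tolerance = 1e-6)
  expect_error(minimal_detectable_effect(40, power = 0.04, alpha = 0.05),
               "infeasible")
})

test_that("group comparisons use pooled-variance t with df = n1 + n2 - 2", {
  ids <- sprintf("s%02d", 1:10)
  asg <- data.frame(subject_id = ids,
                    group = rep(c("more_supportive", "less_supportive"),
                                each = 5))
  # fixture with known group values: hand-computed pooled t
  a <- c(3, 4, 5, 4, 4); b <- c(2, 2, 3, 3, 2)
  sc <- list(fix = stats::setNames(c(a, b), ids))
  out <- compare_groups_on_scales(sc, asg)
  sp <- sqrt((4 * var(a) + 4 * var(b)) / 8)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 5 + 1 / 5))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 8)
  expect_equal(out$cohens_d, cohens_d_from_t(t_hand, 5, 5))

  # identical distributions -> t = 0, d = 0
  sc0 <- list(flat = stats::setNames(rep(c(1, 2, 3, 4, 2), 2), ids))
  out0 <- compare_groups_on_scales(sc0, asg)
  expect_equal(out0$t, 0)
  expect_equal(out0$cohens_d, 0)
})

test_that("a planted 1.15-SD group shift is recovered by the comparison", {
  # simulation over seeds: estimated |d| for the RWA-like scale near 1.15
  d_hat <- numeric(6)
  for (s in seq_along(d_hat)) {
    coh <- generate_cohort(simulation_config(
      n_per_group = 20, grid_shape = c(3, 3, 3), n_statements = 8,
      polarized_region_spec = list(list(center = c(2, 2, 2), radius = 1,
                                        type = "both")),
      common_region_spec = list(), seed = 300 + s))
    asg <- truth_assignment(coh)
    resp <- coh$questionnaires$responses
    defs <- coh$questionnaires$definitions
    sc <- list(rwa = score_scale(resp, defs$rwa))
    d_hat[s] <- compare_groups_on_scales(sc, asg)$cohens_d
  }
  expect_lt(abs(mean(abs(d_hat)) - 1.15), 0.35)
})

test_that("correlation with the IAS matches the product-moment formula", {
  ias <- data.frame(subject_id = sprintf("s%02d", 1:10), ias = seq(0.2, 2, 0.2))
  x <- stats::setNames(ias$ias * 2 + 1, ias$subject_id)
  out <- correlate_with_ias(list(lin = x), ias)
  expect_equal(out$r, 1)
  out_neg <- correlate_with_ias(list(neg = stats::setNames(-x + 7,
                                                           names(x))), ias)
  expect_equal(out_neg$r, -1)

  set.seed(6)
  y <- stats::setNames(rnorm(10), ias$subject_id)
  got <- correlate_with_ias(list(r = y), ias)
  num <- sum((y - mean(y)) * (ias$ias - mean(ias$ias)))
  den <- sqrt(sum((y - mean(y))^2) * sum((ias$ias - mean(ias$ias))^2))
  expect_equal(got$r, num / den, tolerance = 1e-12)
  # uncorrected variant omits q (as for the political-inclination report)
  expect_false("q" %in% names(correlate_with_ias(list(r = y), ias,
                                                 fdr = FALSE)))
  # Spearman equals Pearson on ranks
  sp <- correlate_with_ias(list(r = y), ias, method = "spearman")
  expect_equal(sp$r, cor(rank(y), rank(ias$ias)), tolerance = 1e-12)
})

test_that("IAS regression reports OLS F, adjusted R2 and flags collinearity", {
  set.seed(7)
  n <- 24
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(sprintf("s%02d", 1:n),
                                                  c("a", "b")))
  # exact linear dependence, no noise -> adjusted R2 = 1
  ias <- data.frame(subject_id = rownames(x), ias = 1 + 2 * x[, 1] - x[, 2])
  fit <- suppressWarnings(regress_ias_on_scales(x, ias))  # perfect-fit note
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)
  # coefficients match the normal-equations solution
  xm <- cbind(1, x)
  beta <- solve(t(xm) %*% xm, t(xm) %*% ias$ias)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-9)
  expect_equal(fit$df1, 2)

  # collinear design is rejected with the offending column named
  x2 <- cbind(x, c = x[, 1] * 2)
  ias2 <- data.frame(subject_id = rownames(x), ias = rnorm(n))
  expect_error(regress_ias_on_scales(x2, ias2), "collinear")

  # null predictors: overall F rarely significant
  pvals <- vapply(1:20, function(s) {
    set.seed(700 + s)
    xn <- matrix(rnorm(40 * 13), 40, 13,
                 dimnames = list(sprintf("s%02d", 1:40), paste0("v", 1:13)))
    iasn <- data.frame(subject_id = rownames(xn), ias = rnorm(40))
    regress_ias_on_scales(xn, iasn)$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})
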