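two_method_tables <- function(n_arrays = 3, seed = 5) {
  coh <- generate_cohort(spiral_cohort_config(n_arrays = n_arrays, seed = seed))
  list(auto = coh$measurements[coh$measurements$method == "auto", ],
       manual = coh$measurements[coh$measurements$method == "manual_rater1", ])
}

test_that("paired differences join on (array, electrode) and pool across arrays", {
  tabs <- two_method_tables()
  pd <- paired_differences(tabs$auto, tabs$manual, "emd")
  expect_equal(nrow(pd), 3 * 12)
  expect_equal(pd$diff, pd$a - pd$b)
  expect_equal(pd$mean, (pd$a + pd$b) / 2)

  same <- paired_differences(tabs$manual, tabs$manual, "adoi")
  expect_true(all(same$diff == 0))

  shifted <- tabs$manual
  shifted$emd_mm <- shifted$emd_mm + 0.5
  pd2 <- paired_differences(shifted, tabs$manual, "emd")
  expect_equal(pd2$diff, rep(0.5, nrow(pd2)))
  expect_equal(pd2$mean, pd2$b + 0.25)

  expect_error(paired_differences(tabs$auto[-1, ], tabs$manual, "emd"),
               class = "cochloc_pairing_error")
})

test_that("a full 50x12 cohort yields 600 analyzed electrode pairs", {
  tabs <- two_method_tables(n_arrays = 50, seed = 1)
  pd <- paired_differences(tabs$auto, tabs$manual, "emd")
  expect_equal(nrow(pd), 600)
})

test_that("Bland-Altman uses the sample SD and 1.96 limits", {
  ba <- bland_altman(c(-1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2.7719, tolerance = 1e-4)
  expect_equal(ba$loa_low, -ba$loa_high)

  const <- bland_altman(rep(0.3, 10))
  expect_equal(const$bias, 0.3)
  expect_equal(const$loa_high - const$loa_low, 0)

  expect_error(bland_altman(1), class = "cochloc_insufficient_data")
})

test_that("interrater-calibrated noise reproduces the closed-form limits", {
  # differences of two independent N(0, sigma) draws: LoA = 1.96*sqrt(2)*sigma
  sigma <- 3.61
  set.seed(1234)
  d <- rnorm(5000, 0, sigma) - rnorm(5000, 0, sigma)
  ba <- bland_altman(d)
  expect_equal(ba$loa_high, 1.96 * sqrt(2) * sigma, tolerance = 0.05)
})

test_that("limits of agreement cover about 95% of normal differences", {
  set.seed(600)
  d <- rnorm(600, 0.1, 0.25)
  ba <- bland_altman(d)
  coverage <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("percentage error follows its definition and is scale invariant", {
  expect_equal(percentage_error(-0.7, 0.7, 2.0), 70)
  expect_equal(percentage_error(-0.8, 0.6, 2.5), 56)
  L <- 0.42
  expect_equal(percentage_error(-L, L, 1.7), 100 * 2 * L / 1.7)
  for (c_scale in c(0.1, 3, 42)) {
    expect_equal(percentage_error(-0.8 * c_scale, 0.6 * c_scale, 2.5 * c_scale),
                 56, tolerance = 1e-12)
  }
  expect_error(percentage_error(-1, 1, 0), class = "cochloc_invalid_reference")
})

test_that("Pearson correlation handles exact linear relations and rejects constants", {
  x <- c(1, 2, 3, 4, 5, 7)
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_with_ci(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_with_ci(x, rep(1, 6)),
               class = "cochloc_undefined_correlation")
  expect_error(pearson_with_ci(1:3, 1:3), class = "cochloc_insufficient_data")
  r <- pearson_with_ci(x, x + c(0.1, -0.2, 0.3, 0, -0.1, 0.2))
  expect_lte(r$ci_low, r$r)
  expect_gte(r$ci_high, r$r)
})

test_that("Fisher-z interval agrees with a bootstrap oracle", {
  set.seed(77)
  n <- 150
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, 0.7)
  fz <- pearson_with_ci(x, y)
  boot <- replicate(10000, {
    idx <- sample.int(n, replace = TRUE)
    cor(x[idx], y[idx])
  })
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  expect_lt(abs(fz$ci_low - ci[1]), 0.02)
  expect_lt(abs(fz$ci_high - ci[2]), 0.02)
})

test_that("ICC(A,k) matches an independent aov mean-squares oracle", {
  # fixed 6 subjects x 2 raters table
  ratings <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(2, 1, 4, 1, 5, 2))
  got_k <- icc_two_way_mixed_absolute(ratings, type = "A,k")
  got_1 <- icc_two_way_mixed_absolute(ratings, type = "A,1")

  long <- data.frame(y = as.vector(ratings),
                     subject = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  tab <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- 6; k <- 2
  expect_equal(got_k, (msr - mse) / (msr + (msc - mse) / n),
               tolerance = 1e-9)
  expect_equal(got_1,
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
               tolerance = 1e-9)
})

test_that("ICC is 1 for duplicated raters and near 0 for pure noise", {
  v <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  expect_equal(icc_two_way_mixed_absolute(cbind(v, v)), 1, tolerance = 1e-12)

  set.seed(99)
  noise <- matrix(rnorm(2000), ncol = 2)
  expect_lt(abs(icc_two_way_mixed_absolute(noise)), 0.1)

  # adding independent noise strictly decreases the ICC
  set.seed(5)
  for (s in 1:5) {
    subj <- rnorm(50, sd = 2)
    clean <- cbind(subj, subj)
    noisy <- clean + matrix(rnorm(100, sd = 0.5), ncol = 2)
    expect_lt(icc_two_way_mixed_absolute(noisy),
              icc_two_way_mixed_absolute(clean))
  }

  expect_error(icc_two_way_mixed_absolute(cbind(c(1, NA, 3, 4, 5),
                                                c(1, 2, 3, 4, 5))),
               class = "cochloc_incomplete_matrix")
  expect_error(icc_two_way_mixed_absolute(cbind(1:3, 1:3)),
               class = "cochloc_insufficient_data")
})

test_that("normality check accepts normal samples and rejects uniform ones", {
  set.seed(31)
  ks_n <- ks_normality(rnorm(600))
  expect_true(ks_n$normal)
  ks_u <- ks_normality(runif(600))
  expect_false(ks_u$normal)
  expect_lt(ks_u$p, 0.001)

  deg <- ks_normality(rep(2, 10))
  expect_true(deg$degenerate)
  expect_false(deg$normal)
  expect_error(ks_normality(c(1, 2)), class = "cochloc_insufficient_data")
})

test_that("confounder tests pick Wilcoxon for 2 groups and ANOVA beyond", {
  set.seed(41)
  bias <- rnorm(50, 0.05, 0.1)
  g2 <- rep(c("0.2", "0.25"), c(15, 35))
  w <- group_bias_tests(bias, g2, precision_criterion = 0.2)
  expect_equal(w$test, "wilcoxon")
  expect_gt(w$p, 0.05)
  expect_false(w$exceeds_criterion)

  # two groups separated by 5 SD: overwhelming evidence
  shifted <- bias + ifelse(g2 == "0.2", 0, 0.5)
  w2 <- group_bias_tests(shifted, g2, precision_criterion = 0.2)
  expect_lt(w2$p, 0.001)
  expect_true(w2$exceeds_criterion)

  # five image-quality groups with the cohort's frequencies, shared bias
  iq <- sample(4:8, 50, replace = TRUE, prob = c(0.10, 0.28, 0.26, 0.24, 0.12))
  a <- group_bias_tests(bias, iq)
  expect_equal(a$test, "anova")
  expect_gt(a$p, 0.05)

  expect_error(group_bias_tests(bias, rep(c("a", "b", "c"), c(46, 2, 2))),
               class = "cochloc_insufficient_group")
})

test_that("the agreement report assembles a coherent battery", {
  tabs <- two_method_tables(n_arrays = 10, seed = 23)
  rep <- agreement_report(tabs$auto, tabs$manual, "emd")
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$n_pairs, 120)
  expect_lte(rep$loa_low, rep$bias)
  expect_gte(rep$loa_high, rep$bias)
  expect_lte(rep$r_ci_low, rep$pearson_r)
  expect_gte(rep$r_ci_high, rep$pearson_r)
  expect_lte(rep$icc, 1)
  expect_gt(rep$percentage_error, 0)

  # a method compared against itself: bias 0, limits 0, percentage error 0
  self <- agreement_report(tabs$manual, tabs$manual, "emd")
  expect_equal(self$bias, 0)
  expect_equal(self$loa_high - self$loa_low, 0)
  expect_equal(self$percentage_error, 0)
})
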