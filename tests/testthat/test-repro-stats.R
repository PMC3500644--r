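test_that("paired t-test handles regular and degenerate input", {
  x <- c(1011, 1020, 990, 1015)
  expect_equal(paired_t(x, x), list(t = 0, df = 3L, p = 1, mean_diff = 0,
                                    n = 4L, degenerate = FALSE))
  expect_warning(deg <- paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_equal(deg$mean_diff, -1)

  y <- c(1002, 1005, 1001, 995)
  res <- paired_t(x, y)
  ref <- oracle_paired_t(x, y)
  expect_equal(res$t, ref$t, tolerance = 1e-12)
  expect_equal(res$p, ref$p, tolerance = 1e-12)
  # pair-order invariance
  ord <- c(4, 2, 1, 3)
  res2 <- paired_t(x[ord], y[ord])
  expect_equal(res2$t, res$t, tolerance = 1e-12)
})

test_that("ICC(2,1) matches the ANOVA-table oracle", {
  x <- c(10, 12, 14, 16, 18)
  y <- c(11, 14, 13, 18, 17)
  res <- icc_two_way_random(x, y)
  # frozen hand/aov decomposition: MSR 17.15, MSC 0.9, MSE 1.15
  expect_equal(res$msr, 17.15, tolerance = 1e-10)
  expect_equal(res$msc, 0.9, tolerance = 1e-10)
  expect_equal(res$mse, 1.15, tolerance = 1e-10)
  expect_equal(res$icc, 0.879120879121, tolerance = 1e-9)
  expect_equal(res$icc, oracle_icc_aov(x, y), tolerance = 1e-12)
  # identical exams
  expect_equal(icc_two_way_random(x, x)$icc, 1.0)
  expect_error(icc_two_way_random(1:2, 2:3), "3 units")
  # pair-order invariance
  expect_equal(icc_two_way_random(rev(x), rev(y))$icc, res$icc,
               tolerance = 1e-12)
})

test_that("shuffled pairings destroy the ICC on average", {
  withr::with_seed(21, {
    x <- rnorm(400, 100, 10)
    iccs <- replicate(500, icc_two_way_random(x, sample(x))$icc)
  })
  expect_lt(abs(mean(iccs)), 0.02)
})

test_that("ICC decreases as independent exam-2 noise grows", {
  mean_icc <- vapply(c(1, 4, 10, 25), function(s) {
    mean(vapply(1:10, function(i) {
      withr::with_seed(1000 + i, {
        x <- rnorm(50, 100, 10)
        icc_two_way_random(x, x + rnorm(50, 0, s))$icc
      })
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_icc) < 0))
})

test_that("Bland-Altman bias and limits follow the definition", {
  x <- c(5, 7, 9)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  # differences {-2, 2}: limits +/- 1.96 * sd = +/- 5.5437
  ba <- bland_altman(c(8, 12), c(10, 10))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 5.543717, tolerance = 1e-6)
  expect_equal(ba$loa_low, -5.543717, tolerance = 1e-6)
  # translation equivariance
  y <- c(4, 8, 7)
  b1 <- bland_altman(x, y)
  b2 <- bland_altman(x + 3, y)
  expect_equal(b2$bias, b1$bias + 3, tolerance = 1e-12)
  expect_equal(b2$loa_high - b2$loa_low, b1$loa_high - b1$loa_low,
               tolerance = 1e-12)
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  withr::with_seed(8, {
    x <- rnorm(1000, 50, 5)
    y <- x + rnorm(1000, 0, 2)
  })
  ba <- bland_altman(x, y)
  inside <- mean(ba$data$difference >= ba$loa_low &
                   ba$data$difference <= ba$loa_high)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("the combined agreement summary is consistent with its parts", {
  x <- c(0.38, 0.42, 0.41, 0.45, 0.44)
  y <- c(0.39, 0.41, 0.42, 0.44, 0.43)
  ag <- agreement(x, y)
  expect_equal(ag$icc, icc_two_way_random(x, y)$icc)
  expect_equal(ag$bias, bland_altman(x, y)$bias)
  expect_lte(ag$loa_low, ag$bias)
  expect_lte(ag$bias, ag$loa_high)
})

test_that("the mixed model is invariant where it must be", {
  d <- expand.grid(subject = 1:6, minutes = c(5, 30, 60), exam = 1)
  withr::with_seed(12, {
    d$t1 <- 400 * exp(rnorm(nrow(d), 0, 0.05) + 0.02 * as.numeric(factor(d$subject)))
  })
  # same data relabelled as the second group: group effect exactly 0
  d2 <- d; d2$exam <- 2
  both <- rbind(d, d2)
  res <- mixed_model_compare(both, response = "t1")
  expect_lt(abs(res$group_estimate), 1e-8)
  # rescaling the response leaves the exam comparison untouched (log scale);
  # checked on a non-degenerate dataset with independent exam-2 noise
  d3 <- d; d3$exam <- 2
  withr::with_seed(13, d3$t1 <- d3$t1 * exp(rnorm(nrow(d3), 0, 0.01)))
  noisy <- rbind(d, d3)
  res_n <- mixed_model_compare(noisy, response = "t1")
  noisy_k <- noisy; noisy_k$t1 <- noisy_k$t1 * 3.2
  res_k <- mixed_model_compare(noisy_k, response = "t1")
  expect_equal(res_k$group_estimate, res_n$group_estimate, tolerance = 1e-6)
  expect_equal(res_k$group_p, res_n$group_p, tolerance = 1e-6)
  expect_error(mixed_model_compare(d, response = "t1"), "2 groups")
})

test_that("the mixed model separates a genuine between-exam shift", {
  st <- make_invivo_study(study_truth(n_subjects = 6, seed = 3),
                          resolution = "roi", magnitude = FALSE)
  tc <- study_timecourse(st)
  d <- tc$records[tc$records$minutes > 0, ]
  # inject a 10% prolongation in exam 2
  d$t1_myo[d$exam == 2] <- d$t1_myo[d$exam == 2] * 1.10
  res <- mixed_model_compare(d, response = "t1_myo")
  expect_lt(res$group_p, 0.001)
  expect_equal(abs(res$group_estimate), log(1.10), tolerance = 0.05)
})
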