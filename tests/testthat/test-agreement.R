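test_that("Bland-Altman matches closed forms", {
  x <- c(25, 30, 20, 35)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_halfwidth, 0)

  ba <- bland_altman(c(1, 3), c(2, 2))   # differences -1, +1
  expect_equal(ba$sd_diff, sqrt(2), tolerance = 1e-9)
  expect_equal(ba$loa_halfwidth, 1.96 * sqrt(2), tolerance = 1e-9)
  expect_equal(ba$loa_upper - ba$mean_diff, ba$loa_halfwidth)
  expect_equal(ba$mean_diff - ba$loa_lower, ba$loa_halfwidth)

  expect_error(bland_altman(1, 1), "2 pairs")
  expect_error(bland_altman(c(1, NA), c(1, 2)), "complete")
})

test_that("Bland-Altman is antisymmetric in its arguments", {
  set.seed(3)
  a <- rnorm(20, 25, 5); b <- a + rnorm(20, 0.5, 2)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(r$mean_diff, -f$mean_diff)
  expect_equal(r$loa_halfwidth, f$loa_halfwidth)
})

test_that("simulated differences recover a known limit of agreement", {
  set.seed(12)
  hw <- replicate(40, {
    d <- rnorm(34, 0, 4.63 / 1.96)
    bland_altman(d, rep(0, 34))$loa_halfwidth
  })
  expect_lt(abs(mean(hw) - 4.63), 0.25 * 4.63)
})

test_that("ICC(2,1) matches an independent ANOVA oracle", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  expect_equal(icc(m)$icc, icc_a1_oracle(m), tolerance = 1e-9)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:12, 1); k <- sample(2:4, 1)
    subj <- rnorm(n, 20, 5)
    mm <- matrix(rnorm(n * k, subj, 2), n, k)
    expect_equal(icc(mm)$icc, icc_a1_oracle(mm), tolerance = 1e-9)
  }
})

test_that("ICC behaves at the reliability extremes and under shifts", {
  subj <- c(12, 18, 25, 31, 9, 22)
  perfect <- cbind(subj, subj, subj)
  expect_equal(icc(perfect)$icc, 1)
  # constant column offsets penalize agreement but not consistency
  offset <- cbind(subj, subj + 4)
  expect_lt(icc(offset, type = "agreement")$icc, 1)
  expect_equal(icc(offset, type = "consistency")$icc, 1, tolerance = 1e-12)
  # shifting every entry leaves the ICC unchanged
  m <- cbind(subj + rnorm(6, 0, 1), subj + rnorm(6, 0, 1))
  expect_equal(icc(m + 100)$icc, icc(m)$icc, tolerance = 1e-12)
  # no subject variance: ICC near zero
  set.seed(8)
  noise <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(icc(noise)$icc), 0.15)
  expect_error(icc(cbind(c(1, NA), c(1, 2))), "complete")
})

test_that("ICC confidence interval brackets the estimate", {
  set.seed(14)
  subj <- rnorm(20, 25, 6)
  m <- matrix(rnorm(40, subj, 2), 20, 2)
  r <- icc(m)
  expect_lt(r$ci_low, r$icc)
  expect_gt(r$ci_high, r$icc)
  expect_lte(r$ci_high, 1)
})

test_that("pearson agrees with the covariance-formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x), -1, tolerance = 1e-12)
  a <- c(2.4, 3.1, 5.9, 4.2, 7.7); b <- c(12, 9, 21, 14, 23)
  expect_equal(pearson(a, b), pearson_oracle(a, b), tolerance = 1e-12)
  expect_error(pearson(c(1, 1), c(1, 2)), "variance")
})

test_that("difference categorization reproduces printed clinical tables", {
  tab <- bin_percentages(c(28, 4, 2))
  expect_equal(tab$percent, c(82.4, 11.7, 5.9))
  expect_equal(attr(tab, "cum_percent")[2], 94.1)

  zero <- categorize_differences(rep(0, 10))
  expect_equal(zero$count, c(10L, 0L, 0L))
  expect_equal(zero$percent, c(100, 0, 0))

  # boundary convention: the middle bin is closed on both ends
  edge <- categorize_differences(c(2.9, 3.0, 5.0, 5.1))
  expect_equal(edge$count, c(1L, 2L, 1L))
})

test_that("categorization counts and percentages are consistent", {
  set.seed(4)
  for (i in 1:20) {
    d <- rnorm(sample(5:60, 1), 0, 4)
    tab <- categorize_differences(d)
    expect_equal(sum(tab$count), length(d))
    expect_equal(sum(tab$percent), 100)
  }
})

test_that("the bundled agreement report is coherent", {
  set.seed(2)
  apct <- runif(34, 12, 45)
  vog <- apct + rnorm(34, 0, 2.5)
  rep <- agreement_report(apct, vog, "APCT", "VOG")
  expect_equal(rep$n, 34)
  expect_equal(rep$bland_altman$loa_halfwidth,
               1.96 * sd(apct - vog), tolerance = 1e-12)
  expect_equal(rep$pearson_r, cor(apct, vog))
  expect_equal(sum(rep$categories$count), 34)
})
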