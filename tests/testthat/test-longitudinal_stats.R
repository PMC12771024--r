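test_that("percent change follows its algebraic definition", {
  expect_equal(percentChange(100, 90), -10)
  expect_equal(percentChange(50, 50), 0)
  set.seed(1)
  for (x in runif(20, -0.9, 2)) {
    v1 <- runif(1, 1, 100)
    expect_equal(percentChange(v1, v1 * (1 + x)), 100 * x, tolerance = 1e-9)
  }
  expect_error(percentChange(0, 5), "zero baseline")
})

test_that("the normality screen rejects uniform data and is calibrated under the null", {
  set.seed(21)
  rej <- vapply(1:40, function(i) normalityCheck(runif(500))$p < 0.05,
                logical(1))
  expect_gte(mean(rej), 0.95)

  ps <- vapply(1:200, function(i) normalityCheck(rnorm(500))$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  deg <- normalityCheck(rep(3, 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(normalityCheck(c(1, 2)), "n >= 3")
})

test_that("Mann-Whitney U and its exact p match enumeration and wilcox.test", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)                 # 2 / choose(6,3) * 1
  expect_true(mw$exact)

  x <- c(2.2, 5.5, 7.7, 9.9)
  expect_equal(mannWhitneyU(x, x)$U, length(x)^2 / 2)

  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    mwi <- mannWhitneyU(a, b)
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mwi$U, unname(wt$statistic))
    expect_equal(mwi$p, wt$p.value, tolerance = 1e-12)
  }

  # U(a,b) + U(b,a) = n*m also under ties
  a <- c(1, 2, 2, 3, 7); b <- c(2, 3, 3, 9)
  expect_equal(mannWhitneyU(a, b)$U + mannWhitneyU(b, a)$U, 20)

  # p invariant under common monotone transforms
  set.seed(32)
  a <- rlnorm(15); b <- rlnorm(18) * 1.4
  expect_equal(mannWhitneyU(a, b)$p, mannWhitneyU(log(a), log(b))$p)
  expect_equal(mannWhitneyU(a, b)$p, mannWhitneyU(sqrt(a), sqrt(b))$p)

  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("the large-sample approximation agrees with wilcox.test's corrected p", {
  set.seed(33)
  a <- rnorm(25); b <- rnorm(30, 0.4)
  mw <- mannWhitneyU(a, b)
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_false(mw$exact)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-9)
})

test_that("mean and SEM use the sample standard deviation", {
  expect_equal(meanSem(c(1, 1, 1)), list(mean = 1, sem = 0))
  expect_equal(meanSem(c(0, 2)), list(mean = 1, sem = 1))
  set.seed(5)
  x <- rnorm(40)
  ms <- meanSem(x)
  expect_equal(ms$mean, sum(x) / 40, tolerance = 1e-12)
  expect_equal(ms$sem, sqrt(sum((x - mean(x))^2) / 39) / sqrt(40),
               tolerance = 1e-12)
  expect_error(meanSem(5), "n < 2")
})

test_that("significance stars follow the three-level mapping", {
  expect_identical(significanceStars(0.2), "ns")
  expect_identical(significanceStars(0.04), "*")
  expect_identical(significanceStars(0.009), "**")
  expect_identical(significanceStars(0.0009), "***")
  expect_identical(significanceStars(0.05), "ns")   # strict inequality
})

test_that("session comparison is symmetric-null, order-invariant and detects effects", {
  set.seed(41)
  s1 <- list(diameter = rnorm(40, 6), length = rnorm(40, 100, 10),
             vesselVolume = 5000)
  cmpSame <- compareSessions(s1, s1)
  dist <- cmpSame[cmpSame$type == "distribution", ]
  expect_true(all(dist$p > 0.05))
  expect_true(all(dist$stars == "ns"))
  expect_true(all(cmpSame$percentChange == 0))

  s2 <- lapply(s1, sample)
  cmpPerm <- compareSessions(s1, s2)
  expect_equal(cmpPerm$p, cmpSame$p)
  expect_equal(cmpPerm$U, cmpSame$U)

  s3 <- list(diameter = s1$diameter * 0.6, length = s1$length,
             vesselVolume = 2500)
  cmpEff <- compareSessions(s1, s3)
  expect_lt(cmpEff$p[cmpEff$metric == "diameter"], 0.001)
  expect_identical(cmpEff$stars[cmpEff$metric == "diameter"], "***")
  expect_equal(cmpEff$percentChange[cmpEff$metric == "vesselVolume"], -50)

  expect_error(compareSessions(s1, s1[1:2]), "different metric sets")
})
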