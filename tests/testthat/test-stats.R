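test_that("stratification joins metadata and assigns groups deterministically", {
  man <- data.frame(scan_id = c("s1", "s2"), age_years = c(3, 10.5),
                    sex = c("F", "M"), exclusion_flag = "none")
  rec <- data.frame(scan_id = rep(c("s1", "s2"), each = 3),
                    level_index = rep(c(2, 6, 15), 2), H_mm = 5)
  tab <- stratify(rec, man)
  expect_equal(as.character(tab$level_group),
               rep(c("upper_thoracic", "mid_thoracic", "lumbar"), 2))
  expect_equal(as.character(tab$age_group[tab$scan_id == "s1"]),
               rep("infantile", 3))
  expect_equal(as.character(tab$age_group[tab$scan_id == "s2"]),
               rep("juvenile", 3))  # 10.5 floors to 10
  man$age_years[1] <- 19
  expect_error(stratify(rec, man), "0, 18")
})

test_that("LOESS is exact on lines and locally adapts on curvature", {
  x <- seq(0, 18, length.out = 40)
  y <- 2 * x + 1
  for (sp in c(0.3, 0.75, 1)) {
    fit <- loess_fit(x, y, span = sp, degree = 1, query = c(0, 4.5, 18))
    expect_equal(fit$fitted, 2 * c(0, 4.5, 18) + 1, tolerance = 1e-9)
  }
  # on a parabola, a small-span local fit beats the global least-squares line
  y2 <- x^2
  ols <- lm(y2 ~ x)
  interior <- x[x > 3 & x < 15]
  fit2 <- loess_fit(x, y2, span = 0.3, degree = 1, query = interior)
  err_loess <- max(abs(fit2$fitted - interior^2))
  err_ols <- max(abs(predict(ols, data.frame(x = interior)) - interior^2))
  expect_lt(err_loess, err_ols)
  expect_error(loess_fit(1:2, 1:2, degree = 1), "at least")
})

test_that("percent change follows the final-as-percent-of-initial convention", {
  x <- seq(0, 18, length.out = 30)
  fit <- loess_fit(x, 100 + 20 * x, span = 0.75)
  expect_equal(percent_change(fit, 0, 18), 460, tolerance = 1e-6)
  flat <- loess_fit(x, rep(7, 30) + rnorm(30, sd = 1e-9), span = 1)
  expect_equal(percent_change(flat, 0, 18), 100, tolerance = 1e-3)
  # "height increased from 4 to 7 mm" corresponds to 175%
  hfit <- loess_fit(x, 4 + (7 - 4) * x / 18, span = 0.75)
  expect_equal(percent_change(hfit, 0, 18), 175, tolerance = 1e-6)
})

test_that("ICC equals 1 on duplicated raters and matches the ANOVA oracle", {
  set.seed(14)
  truth <- rnorm(12, 50, 10)
  dup <- cbind(truth, truth, truth)
  r <- icc_two_way(dup)
  expect_equal(r$estimate, 1)
  expect_true(r$lower <= r$estimate && r$estimate <= r$upper)

  # oracle: mean squares from aov() on the long two-way layout
  m <- matrix(rnorm(24, 10, 2), 6, 4) + truth[1:6]
  long <- data.frame(y = as.vector(m),
                     item = factor(rep(1:6, 4)), rater = factor(rep(1:4, each = 6)))
  ms <- summary(aov(y ~ item + rater, data = long))[[1]][["Mean Sq"]]
  n <- 6; k <- 4
  oracle <- (ms[1] - ms[3]) /
    (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
  expect_equal(icc_two_way(m)$estimate, oracle, tolerance = 1e-10)

  # invariance to adding a constant to every cell
  expect_equal(icc_two_way(m + 100)$estimate, icc_two_way(m)$estimate,
               tolerance = 1e-10)

  # independent noise: ICC concentrates near zero
  noise <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(icc_two_way(noise)$estimate), 0.05)

  expect_error(icc_two_way(matrix(1, 5, 1)), "2 items and 2 raters")
  expect_error(icc_two_way(matrix(3, 5, 4)), "zero total variance")
})

test_that("Welch t is antisymmetric and detects the printed slenderness gap", {
  a <- c(1, 2, 3, 4)
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(9)
  b <- rnorm(10, 1)
  d <- rnorm(12, 2)
  expect_equal(welch_t(b, d)$t, -welch_t(d, b)$t, tolerance = 1e-12)
  expect_equal(welch_t(b, d)$p, welch_t(d, b)$p, tolerance = 1e-12)
  expect_error(welch_t(1, a), "at least 2")
  # power check mirroring girls 0.23 vs boys 0.27 (sd 0.02, n = 40/group)
  set.seed(100)
  hits <- sum(replicate(100, {
    welch_t(rnorm(40, 0.23, 0.02), rnorm(40, 0.27, 0.02))$p < 0.001
  }))
  expect_gte(hits, 95)
})

test_that("trend regression recovers linear age effects and is calibrated under the null", {
  tab <- data.frame(age_years = seq(0, 18, length.out = 50),
                    sex = rep(c("M", "F"), 25))
  set.seed(3)
  tab$y <- 3 + 0.4 * tab$age_years + rnorm(50, sd = 1e-7)
  tr <- trend_fit(tab, "y")
  expect_equal(tr$slope, 0.4, tolerance = 1e-7)
  expect_lt(tr$p, 1e-12)
  tab$y2 <- tab$y + 5
  tr2 <- trend_fit(tab, "y2")
  expect_equal(tr2$slope, tr$slope, tolerance = 1e-9)
  expect_equal(tr2$intercept, tr$intercept + 5, tolerance = 1e-9)
  tr3 <- trend_fit(tab, "y", adjust_for_sex = TRUE)
  expect_equal(tr3$slope, 0.4, tolerance = 1e-6)
  const <- tab; const$age_years <- 5
  expect_error(trend_fit(const, "y"), "constant")

  # null calibration: p-values on permuted outcomes are uniform
  set.seed(77)
  base <- data.frame(age_years = runif(200, 0, 18), sex = "M")
  y <- rnorm(200)
  ps <- replicate(500, trend_fit(transform(base, y = sample(y)), "y")$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
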