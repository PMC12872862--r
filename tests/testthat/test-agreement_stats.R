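test_that("ICC models match the ANOVA variance-components oracle", {
  for (sd in c(1, 7, 23)) {
    set.seed(sd)
    m <- matrix(rnorm(20, mean = 100, sd = 15), nrow = 10, ncol = 2)
    for (model in c("oneway_random", "twoway_random",
                    "twoway_mixed_consistency")) {
      # iid draws can land at ICC <= 0; the low-variance warning is expected
      expect_equal(suppressWarnings(icc(m, model = model)$value),
                   aov_icc(m, model), tolerance = 1e-10)
    }
  }
})

test_that("consistency ICC ignores a fixed rater offset; absolute model does not", {
  a <- c(10, 14, 11, 19, 22, 8, 15)
  expect_equal(icc(a, a + 5, model = "twoway_mixed_consistency")$value, 1)
  expect_lt(icc(a, a + 5, model = "twoway_random")$value, 1)
  # identical raters: perfect agreement under every model
  for (model in c("oneway_random", "twoway_random",
                  "twoway_mixed_consistency"))
    expect_equal(icc(a, a, model = model)$value, 1)
})

test_that("zero between-subject variance yields a flagged non-positive ICC", {
  # identical subject means, all disagreement within subjects
  m <- cbind(c(1, 2, 3, 1, 2, 3), c(3, 2, 1, 3, 2, 1))
  expect_warning(res <- icc(m, model = "oneway_random"), "variance")
  expect_lte(res$value, 0)
  expect_true(res$low_variance)
})

test_that("Bland-Altman bias, SD and limits follow their definitions", {
  a <- c(10, 12, 15, 13, 18)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba5 <- bland_altman(a + 5, a)
  expect_equal(ba5$bias, 5); expect_equal(ba5$sd_diff, 0)
  set.seed(99)
  d <- rnorm(1000, mean = -549, sd = 774)
  ba <- bland_altman(d, rep(0, 1000))
  # standard-error bound: SE of the mean is 774/sqrt(1000) ~ 24.5
  expect_lt(abs(ba$bias + 549), 50)
  expect_identical(ba$loa_low, ba$bias - 1.96 * ba$sd_diff)
  expect_identical(ba$loa_high, ba$bias + 1.96 * ba$sd_diff)
  # swap: bias flips sign, LOA width is invariant
  ba_sw <- bland_altman(rep(0, 1000), d)
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(ba_sw$loa_high - ba_sw$loa_low, ba$loa_high - ba$loa_low)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("OLS fit matches the normal-equations oracle", {
  expect_equal(ols_fit(1:10, 2 * (1:10) + 1),
               list(slope = 2, intercept = 1, pearson_r = 1, n = 10L),
               tolerance = 1e-12)
  expect_equal(ols_fit(1:10, -(1:10))$pearson_r, -1)
  set.seed(5)
  x <- rnorm(40); y <- 3.2 * x - 1.4 + rnorm(40, sd = 0.3)
  fit <- ols_fit(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit$slope, beta[2], tolerance = 1e-9)
  expect_equal(fit$pearson_r,
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_error(ols_fit(rep(1, 5), 1:5), class = "pvloopr_degenerate_input")
})

test_that("paired comparisons match the textbook statistic and flag degeneracy", {
  a <- c(3, 5, 9, 4, 7, 8)
  expect_equal(paired_compare(a, a, "t")$statistic, 0)
  shifted <- paired_compare(a + 2, a, "t")
  expect_true(shifted$degenerate)        # zero variance of differences
  set.seed(13)
  x <- rnorm(15); y <- x + rnorm(15, 0.4)
  res <- paired_compare(y, x, "t")
  d <- y - x
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-9)
  expect_false(res$degenerate)
  w <- paired_compare(y, x, "wilcoxon")
  expect_equal(w$statistic, unname(wilcox.test(y, x, paired = TRUE)$statistic))
})

test_that("the full agreement report is self-consistent", {
  set.seed(3)
  ref <- rnorm(30, 13000, 2500)
  est <- 0.9 * ref + 1800 + rnorm(30, sd = 600)
  rep <- agreement(est, ref)
  expect_equal(rep$loa_low, rep$bias - 1.96 * rep$sd_diff)
  expect_equal(rep$loa_high, rep$bias + 1.96 * rep$sd_diff)
  expect_true(abs(rep$pearson_r) <= 1)
  self <- agreement(ref, ref)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$bias, 0)
  expect_equal(self$icc, 1)
  # table layout: one row per metric
  tab <- agreement_table(data.frame(SW = est, Ees = est / 5000),
                         data.frame(SW = ref, Ees = ref / 5000))
  expect_equal(tab$metric, c("SW", "Ees"))
  expect_equal(tab$pearson_r[1], rep$pearson_r)
})
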