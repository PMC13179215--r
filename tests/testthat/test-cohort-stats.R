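test_that("descriptive moments use the bias-corrected conventions", {
  d <- describe(1:5)
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2.5))
  expect_equal(d$skewness, 0)
  # adjusted Fisher-Pearson skewness of {1,1,1,5} is exactly 2
  expect_equal(describe(c(1, 1, 1, 5))$skewness, 2)
  expect_error(describe(rep(4, 6)), "constant")
  expect_error(describe(2), "at least 2")
})

test_that("describe matches a brute-force moment oracle", {
  set.seed(5)
  for (i in 1:15) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    d <- describe(x)
    n <- length(x); m <- mean(x)
    g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
    g2 <- mean((x - m)^4) / (mean((x - m)^2))^2 - 3
    kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    expect_equal(d$skewness, skew, tolerance = 1e-10)
    expect_equal(d$kurtosis, kurt, tolerance = 1e-10)
  }
})

test_that("the Lilliefors D statistic matches independent references", {
  rep_ <- lilliefors_normality(1:5, n_mc = 1000)
  # brute-force sup over both sides of every ECDF jump
  expect_equal(rep_$d_statistic, 0.1364554, tolerance = 1e-6)
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(sample(10:80, 1), 5, 2)
    ours <- lilliefors_normality(x, n_mc = 1000)$d_statistic
    expect_equal(ours, unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-10)
  }
  expect_error(lilliefors_normality(1:3), "at least 5")
  expect_error(lilliefors_normality(1:20, n_mc = 10), "at least 1000")
})

test_that("Monte-Carlo p-values are calibrated under the null", {
  n <- 20L
  null_d <- lilliefors_null(n, n_mc = 10000L, seed = 31)
  set.seed(99)
  p <- replicate(2000, {
    lilliefors_normality(rnorm(n), null_d = null_d)$p_value
  })
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.01)
  # uniformity across the whole unit interval (ties from the shared
  # finite null table are harmless here)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("normality classification applies the approximate-normal rule", {
  mk <- function(p) structure(list(d_statistic = 0.1, p_value = p, n = 60,
                                   classification = NA_character_),
                              class = "rn_normality")
  s1 <- list(skewness = 0.207, kurtosis = 1.246)
  expect_equal(classify_normality(mk(0.195), s1)$classification, "normal")
  s2 <- list(skewness = -0.066, kurtosis = -0.508)
  expect_equal(classify_normality(mk(0.038), s2)$classification,
               "approximately_normal")
  s3 <- list(skewness = 5, kurtosis = 2)
  expect_equal(classify_normality(mk(0.01), s3)$classification,
               "non_normal")
})

test_that("group comparisons reproduce the published summary t-tests", {
  # sex difference in AA-Ol: pooled t from the printed summaries
  cmp <- compare_from_summaries(29.54, 1.77, 40, 27.48, 1.61, 20)
  expect_equal(abs(cmp$t_statistic), 4.3753, tolerance = 1e-3)
  expect_equal(cmp$df, 58)
  expect_lt(cmp$p_value, 0.05)
  # sex difference in AA-LEH
  cmp <- compare_from_summaries(29.34, 2.33, 40, 26.98, 1.44, 20)
  expect_equal(abs(cmp$t_statistic), 4.1414, tolerance = 1e-3)
  expect_lt(cmp$p_value, 0.05)
  # side difference in IPA-Ol is not significant
  cmp <- compare_from_summaries(17.05, 2.29, 30, 17.54, 1.98, 30)
  expect_gt(cmp$p_value, 0.05)
})

test_that("raw-data and summary t-tests agree exactly", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1), 10, 2)
    b <- rnorm(sample(5:30, 1), 11, 3)
    c1 <- compare_groups(a, b)
    c2 <- compare_from_summaries(mean(a), sd(a), length(a),
                                 mean(b), sd(b), length(b))
    expect_equal(c1$t_statistic, c2$t_statistic, tolerance = 1e-9)
    expect_equal(c1$p_value, c2$p_value, tolerance = 1e-9)
    expect_equal(c1$df, c2$df)
  }
  same <- c(1, 2, 3, 4)
  c0 <- compare_groups(same, same)
  expect_equal(c0$t_statistic, 0)
  expect_equal(c0$p_value, 1)
  expect_error(compare_groups(c(0, 0, 0), c(1, 1, 1)), "degenerate")
})

test_that("ratio regression recovers slopes and flags perfect fits", {
  co <- make_cohort(r_a = c(0.2, 0.4, 0.6), r_b = c(0.1, 0.3, 0.5))
  fit <- suppressWarnings(fit_ratio_regression(co))  # perfect-fit warning
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.1, tolerance = 1e-12)
  expect_true(fit$perfect_fit)
  expect_equal(fit$slope_t, Inf)

  co2 <- make_cohort(r_a = rep(0.5, 4), r_b = c(0.2, 0.3, 0.4, 0.5))
  expect_error(fit_ratio_regression(co2), "zero variance")

  cfg <- default_config(); cfg$n_cadavers <- 5000L
  big <- simulate_cohort(cfg, seed = 8)
  fit <- fit_ratio_regression(big)
  expect_equal(fit$slope, 0.593, tolerance = 0.02 / 0.593)
  expect_lt(fit$slope_p, 1e-10)
  expect_equal(fit$pearson_r, 0.557, tolerance = 0.05)
})

test_that("the implied slope t reproduces the published statistic", {
  expect_equal(implied_slope_t(0, 0.1, 0.1, 30), 0)
  expect_equal(implied_slope_t(0.593, 0.062, 0.066, 60), 5.107,
               tolerance = 0.01 / 5.107)
  # when the SDs are equal the slope is the correlation itself
  r <- 0.4
  expect_equal(implied_slope_t(r, 0.05, 0.05, 25),
               r * sqrt(23) / sqrt(1 - r^2))
  expect_error(implied_slope_t(1.2, 0.1, 0.1, 30), "inconsistent")
})

test_that("cohort-level report tables cover all nine items", {
  co <- simulate_cohort(seed = 21)
  nt <- normality_table(co, n_mc = 1000, seed = 4)
  expect_equal(nrow(nt), 9L)
  expect_true(all(nt$classification %in%
                    c("normal", "approximately_normal", "non_normal")))
  sx <- sex_comparison(co)
  expect_equal(nrow(sx), 9L)
  expect_true(all(c("mean_male", "mean_female") %in% names(sx)))
  sd_ <- side_comparison(co)
  expect_equal(sd_$n_left, rep(30L, 9))
})
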