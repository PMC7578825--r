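test_that("Hotelling's T2 matches the multivariate-regression oracle and is affine-invariant", {
  a <- matrix(c(1, 2, 3, 4, 5, 2, 1, 4, 3, 5), 5, 2)
  b <- a
  r <- hotelling_t2(a, b)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(17)
  for (i in 1:10) {
    a <- matrix(rnorm(24, 0, 1), 12, 2)
    b <- matrix(rnorm(20, 0.8, 1), 10, 2)
    r <- hotelling_t2(a, b)
    # independent route: Hotelling-Lawley trace of the one-factor mlm,
    # T2 = (n1 + n2 - 2) * HL
    g <- factor(rep(c("a", "b"), c(12, 10)))
    y <- rbind(a, b)
    hl <- anova(lm(y ~ g), test = "Hotelling-Lawley")
    expect_equal(r$statistic, 20 * hl["g", "Hotelling-Lawley"], tolerance = 1e-9)
    expect_equal(r$p_value, hl["g", "Pr(>F)"], tolerance = 1e-9)

    # common affine map leaves T2 unchanged
    A <- matrix(rnorm(4), 2, 2) + diag(2) * 2
    shift <- rnorm(2)
    ra <- hotelling_t2(sweep(a %*% A, 2, shift, "+"), sweep(b %*% A, 2, shift, "+"))
    expect_equal(ra$statistic, r$statistic, tolerance = 1e-8)
  }
})

test_that("residual permutation test behaves at the extremes", {
  set.seed(23)
  a <- cbind(rnorm(12), rnorm(12))

  # identical clouds: no signal
  r <- rpp_test(a, a, "CD", B = 199, seed = 1)
  expect_gt(r$p_value, 0.5)

  # maximal separation: p hits the add-one floor exactly
  b <- sweep(a, 2, c(10, 10), "+")
  r <- rpp_test(a, b, "centroid_distance", B = 999, seed = 2)
  expect_equal(r$p_value, 1 / 1000)

  # the floor holds for every metric
  for (m in c("CD", "MNND", "centroid_distance")) {
    r <- rpp_test(a, b, m, B = 99, seed = 3)
    expect_gte(r$p_value, 1 / 100)
  }

  expect_error(rpp_test(a, b, "CD", B = 10, seed = 1), "99")
  expect_error(rpp_test(a, b, "CD", B = 199), "seed")
  expect_identical(rpp_test(a, b, "MNND", B = 199, seed = 9)$p_value,
                   rpp_test(a, b, "MNND", B = 199, seed = 9)$p_value)
})

test_that("Pearson test equals the textbook formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_test(x, 2 * x)$statistic, 1, tolerance = 1e-12)
  expect_equal(pearson_test(c(1, 2, 3), c(1, 0, 1))$statistic, 0, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    r <- pearson_test(x, y)
    rr <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tt <- rr * sqrt(10 / (1 - rr^2))
    expect_equal(r$statistic, rr, tolerance = 1e-12)
    expect_equal(r$p_value, 2 * pt(-abs(tt), 10), tolerance = 1e-12)
  }
})

test_that("mixed model collapses to OLS when the season variance is zero", {
  cfg <- fullness_sim_config(group_effects = c(a = 0, b = 0.5), season_sd = 0,
                             residual_sd = 1, n_per_cell = 4, seed = 12)
  ft <- simulate_fullness(cfg)
  fit <- fit_ff_lmm(ft, "additive")
  expect_lt(fit$season_sd, 0.01)
  ols <- lm(as.numeric(ff) ~ group + time_h, data = as.data.frame(ft))
  expect_equal(unname(fit$fixef), unname(coef(ols)), tolerance = 1e-6)
  # deterministic: refitting gives the identical likelihood
  expect_equal(fit$logLik, fit_ff_lmm(ft, "additive")$logLik, tolerance = 1e-12)
})

test_that("mixed model recovers simulated fixed effects within 2 SE", {
  te <- setNames(c(0, -0.6, -0.3, 0.3, 0.9, 0.6, 0.3, -0.3),
                 c("01", "04", "07", "10", "13", "16", "19", "22"))
  cfg <- fullness_sim_config(time_effects = te,
                             group_effects = c(a = 0, b = 0.4),
                             season_sd = 0.5, residual_sd = 1,
                             n_per_cell = 4, n_seasons = 4, seed = 33)
  ft <- simulate_fullness(cfg)
  fit <- fit_ff_lmm(ft, "additive")
  sm <- summary(fit$model)$coefficients
  # group-b contrast
  expect_lt(abs(sm["groupb", "Estimate"] - 0.4) / sm["groupb", "Std. Error"], 2.5)
  # a couple of time contrasts (relative to hour 01)
  for (h in c("13", "22")) {
    nm <- paste0("time_h", h)
    expect_lt(abs(sm[nm, "Estimate"] - (te[h] - te["01"])) / sm[nm, "Std. Error"], 3)
  }
})

test_that("likelihood-ratio chain is non-negative, additive, and null on identical models", {
  ft <- simulate_fullness(fullness_sim_config(seed = 3))
  fits <- lapply(c(full = "full", additive = "additive", time = "time",
                   null = "null"), function(t) fit_ff_lmm(ft, t))
  same <- lrt_compare(fits$additive, fits$additive)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  c1 <- lrt_compare(fits$full, fits$additive)$statistic
  c2 <- lrt_compare(fits$additive, fits$time)$statistic
  c3 <- lrt_compare(fits$time, fits$null)$statistic
  tot <- lrt_compare(fits$full, fits$null)$statistic
  expect_gte(c1, 0); expect_gte(c2, 0); expect_gte(c3, 0)
  expect_equal(c1 + c2 + c3, tot, tolerance = 1e-6)

  expect_error(lrt_compare(fits$additive, fits$full), "more fixed effects")
})
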