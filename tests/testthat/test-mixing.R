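test_that("degenerate and symmetric mixtures are handled exactly", {
  one <- source_set(data.frame(source = "only", d13C_mean = -25, d13C_sd = 1,
                               d15N_mean = 10, d15N_sd = 1, tef_d13C_mean = 1.3,
                               tef_d13C_sd = 0.3, tef_d15N_mean = 2.3,
                               tef_d15N_sd = 0.18))
  cons <- simulate_consumers(mix_sim_config(one, 1, n = 5, seed = 1))
  fit <- fit_mixing_model(mixing_model_spec(one, cons, seed = 1))
  expect_equal(fit$sources$mean, 1)
  expect_equal(fit$sources$ci_low, 1)

  # two sources placed symmetrically about the consumers: posterior ~ (1/2, 1/2)
  two <- source_set(data.frame(source = c("a", "b"), d13C_mean = c(-30, -20),
                               d13C_sd = 1, d15N_mean = c(5, 15), d15N_sd = 1,
                               tef_d13C_mean = 0, tef_d13C_sd = 0,
                               tef_d15N_mean = 0, tef_d15N_sd = 0))
  cons <- simulate_consumers(mix_sim_config(two, c(0.5, 0.5), n = 40,
                                            residual_sd = c(0.3, 0.3), seed = 2))
  fit <- suppressWarnings(fit_mixing_model(
    mixing_model_spec(two, cons, chains = 2, iter = 6000, burn = 3000, seed = 3)))
  expect_equal(fit$sources$mean, c(0.5, 0.5), tolerance = 0.05)
})

test_that("posterior draws live on the simplex and CIs bracket the means", {
  src <- three_source_set()
  cons <- simulate_consumers(mix_sim_config(src, c(0.6, 0.3, 0.1), n = 30,
                                            residual_sd = c(0.3, 0.3), seed = 5))
  fit <- suppressWarnings(fit_mixing_model(
    mixing_model_spec(src, cons, chains = 2, iter = 4000, burn = 2000, seed = 6)))
  expect_true(all(abs(rowSums(fit$draws) - 1) < 1e-9))
  expect_true(all(fit$draws >= 0))
  expect_true(all(fit$sources$ci_low <= fit$sources$mean + 1e-9))
  expect_true(all(fit$sources$mean <= fit$sources$ci_high + 1e-9))
  expect_true(is.finite(fit$diagnostics$acceptance))
})

test_that("sampler is seed-reproducible and stable under longer runs", {
  src <- three_source_set()
  cons <- simulate_consumers(mix_sim_config(src, c(0.5, 0.3, 0.2), n = 30,
                                            residual_sd = c(0.3, 0.3), seed = 8))
  s1 <- mixing_model_spec(src, cons, chains = 2, iter = 4000, burn = 2000, seed = 10)
  f1 <- suppressWarnings(fit_mixing_model(s1))
  f1b <- suppressWarnings(fit_mixing_model(s1))
  expect_identical(f1$sources, f1b$sources)

  s2 <- mixing_model_spec(src, cons, chains = 2, iter = 8000, burn = 4000, seed = 10)
  f2 <- suppressWarnings(fit_mixing_model(s2))
  expect_equal(f1$sources$mean, f2$sources$mean, tolerance = 0.01)
})

test_that("an under-determined 12-source model shrinks toward the prior mean", {
  src <- bream_prey_sources()
  cons <- simulate_isotopes(isotope_sim_config(bream_isotope_groups()[4, ], seed = 5))
  fit <- suppressWarnings(fit_mixing_model(
    mixing_model_spec(src, cons, chains = 2, iter = 12000, burn = 6000,
                      thin = 6, seed = 9)))
  # 12 sources vs 2 tracers: individual proportions stay near 1/12 and every
  # lower credible bound collapses to ~0
  expect_equal(mean(fit$sources$mean), 1 / 12, tolerance = 1e-6)
  expect_true(all(fit$sources$mean > 0.005 & fit$sources$mean < 0.35))
  expect_true(all(fit$sources$ci_low < 0.05))
  # the terrestrial C4-plant end-member stays a minor contributor
  expect_lt(fit$sources$mean[fit$sources$source == "C4_P"], 1 / 12)
})

test_that("consumers far outside the source polygon trigger a geometry warning", {
  src <- three_source_set()
  outside <- make_isotopes(cbind(rnorm(5, -45, 0.1), rnorm(5, 40, 0.1)))
  expect_warning(fit_mixing_model(
    mixing_model_spec(src, outside, chains = 1, iter = 500, burn = 250, thin = 1,
                      seed = 2)), "polygon")
})

test_that("prior predictive reflects the prior's mixing geometry", {
  two <- source_set(data.frame(source = c("a", "b"), d13C_mean = c(-30, -20),
                               d13C_sd = 0.5, d15N_mean = c(5, 15), d15N_sd = 0.5,
                               tef_d13C_mean = 1.3, tef_d13C_sd = 0.1,
                               tef_d15N_mean = 2.3, tef_d15N_sd = 0.1))
  cons <- simulate_consumers(mix_sim_config(two, c(0.5, 0.5), n = 5, seed = 1))
  spec <- mixing_model_spec(two, cons, residual_error = FALSE, seed = 77)
  pp <- prior_predictive(spec, ndraws = 4000)
  # uniform Dirichlet: predictive mean ~ average of TEF-shifted source means
  expect_equal(unname(pp$summary$mean["d13C"]), -25 + 1.3, tolerance = 0.15)
  expect_equal(unname(pp$summary$mean["d15N"]), 10 + 2.3, tolerance = 0.15)
  expect_identical(prior_predictive(spec, ndraws = 100),
                   prior_predictive(spec, ndraws = 100))

  # predictive SD cannot fall below the residual noise floor
  spec_res <- mixing_model_spec(two, cons, residual_error = TRUE, seed = 78)
  pp_res <- prior_predictive(spec_res, ndraws = 4000)
  expect_true(all(pp_res$summary$sd >= pp$summary$sd - 0.2))
})
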