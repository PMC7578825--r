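test_that("percent by weight and number recover hand-computed proportions", {
  dm <- make_diet(rbind(c(9, 1)), masses = rbind(c(9, 1)))
  pw <- percent_by_weight(dm)
  expect_equal(unname(as.numeric(pw$mean)), c(0.9, 0.1))

  # two opposite specialists: mean (0.5, 0.5), SD 1/sqrt(2)
  dm <- make_diet(rbind(c(1, 0), c(0, 1)))
  pw <- percent_by_weight(dm)
  expect_equal(unname(as.numeric(pw$mean)), c(0.5, 0.5))
  expect_equal(unname(pw$sd), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  cnt <- c(536, 125, 117, 93, 44, 59, 10, 16)
  dm <- make_diet(matrix(cnt, 1))
  pn <- percent_by_number(dm, exclude = character())
  expect_equal(unname(as.numeric(pn$mean)), cnt / 1000)

  # an individual with only detritus drops out of percent-by-number
  dm <- diet_matrix(data.frame(
    individual_id = c("a", "a", "b"), group = "g",
    prey_taxon = c("detritus", "algae", "detritus"),
    count = c(10, 5, 8), mass = c(1, 0.1, 0.9)))
  expect_warning(pn <- percent_by_number(dm), "excluded")
  expect_equal(pn$n, 1)
})

test_that("condition indices are simple biomass percentages", {
  expect_equal(gsi(4.5, 100), 4.5)
  expect_equal(gsi(0, 50), 0)
  expect_equal(fullness_index(c(2, 5), c(100, 100)), c(2, 5))
  expect_error(gsi(1, 0), "Wt")
})

test_that("Morisita overlap is symmetric, bounded, order-invariant", {
  p <- diet_profile(c(a = 0.7, b = 0.2, c = 0.1))
  expect_equal(morisita_index(p, p), 1)
  q <- diet_profile(c(d = 0.5, e = 0.5))
  expect_equal(morisita_index(p, q), 0)

  set.seed(42)
  for (i in 1:25) {
    x <- rgamma(5, 1); x <- diet_profile(setNames(x / sum(x), letters[1:5]))
    y <- rgamma(5, 1); y <- diet_profile(setNames(y / sum(y), letters[1:5]))
    cxy <- morisita_index(x, y)
    expect_equal(cxy, morisita_index(y, x), tolerance = 1e-12)
    expect_gte(cxy, 0); expect_lte(cxy, 1 + 1e-12)
    perm <- sample(5)
    expect_equal(morisita_index(x[perm], y[perm]), cxy, tolerance = 1e-12)
  }

  expect_true(overlap_significant(0.61))
  expect_false(overlap_significant(0.6))   # strictly greater than 0.6
})

test_that("TNW/WIC matches hand arithmetic and degenerate conventions", {
  # identical individuals: no between-individual variance, WIC/TNW = 1
  dm <- make_diet(rbind(c(3, 2, 1), c(6, 4, 2)))
  sp <- tnw_wic(dm, basis = "count", exclude = character())
  expect_equal(sp$wic_over_tnw, 1, tolerance = 1e-12)
  expect_equal(sp$BIC, 0, tolerance = 1e-12)

  # perfect specialists on distinct taxa with equal totals
  dm <- make_diet(diag(3) * 10)
  sp <- tnw_wic(dm, basis = "count", exclude = character())
  expect_equal(sp$TNW, log(3), tolerance = 1e-12)
  expect_equal(sp$WIC, 0)
  expect_equal(sp$wic_over_tnw, 0)

  # mirrored 80/20 diets, equal totals
  dm <- make_diet(rbind(c(8, 2), c(2, 8)))
  sp <- tnw_wic(dm, basis = "count", exclude = character())
  expect_equal(sp$TNW, log(2), tolerance = 1e-12)
  expect_equal(sp$WIC, -(0.8 * log(0.8) + 0.2 * log(0.2)), tolerance = 1e-12)
  expect_equal(sp$wic_over_tnw, 0.7219, tolerance = 1e-4)

  # single shared resource: TNW = 0, ratio degenerates to 1 with a flag
  dm <- make_diet(rbind(10, 20))
  sp <- tnw_wic(dm, basis = "count", exclude = character())
  expect_true(sp$degenerate)
  expect_equal(sp$wic_over_tnw, 1)
})

test_that("entropy decomposition TNW = WIC + BIC holds against the brute-force oracle", {
  set.seed(99)
  for (i in 1:50) {
    m <- random_diet_counts(sample(3:10, 1), sample(2:8, 1))
    dm <- make_diet(m)
    sp <- tnw_wic(dm, basis = "count", exclude = character())
    or <- shannon_oracle(m[rowSums(m) > 0, , drop = FALSE])
    expect_equal(sp$TNW, or$TNW, tolerance = 1e-9)
    expect_equal(sp$WIC, or$WIC, tolerance = 1e-9)
    expect_equal(sp$TNW, sp$WIC + sp$BIC, tolerance = 1e-9)
    expect_gte(sp$BIC, -1e-12)
  }
})

test_that("diet similarity averages pairwise proportional similarity", {
  dm <- make_diet(rbind(c(3, 2), c(6, 4)))
  expect_equal(mean_diet_similarity(dm, basis = "count", exclude = character()), 1)
  dm <- make_diet(diag(2) * 5)
  expect_equal(mean_diet_similarity(dm, basis = "count", exclude = character()), 0)
  # (1,0), (0,1), (0.5,0.5): pairwise PS 0, 0.5, 0.5
  dm <- make_diet(rbind(c(2, 0), c(0, 2), c(1, 1)))
  expect_equal(mean_diet_similarity(dm, basis = "count", exclude = character()),
               1 / 3, tolerance = 1e-12)
})

test_that("diet similarity and WIC/TNW rise together across simulated groups", {
  alphas <- rep(c(0.2, 1, 5, 25), each = 5)
  stats <- t(vapply(seq_along(alphas), function(i) {
    cfg <- diet_sim_config(group_sizes = c(g = 20), q = rep(0.2, 5),
                           alpha = alphas[i], items_per_individual = 80,
                           seed = 300 + i)
    sp <- tnw_wic(simulate_diet(cfg), basis = "count", exclude = character())
    c(sp$wic_over_tnw, sp$mean_diet_similarity)
  }, c(0, 0)))
  expect_gt(cor(stats[, 1], stats[, 2], method = "spearman"), 0.5)
})

test_that("taxonomic richness counts taxa with positive counts", {
  dm <- make_diet(rbind(c(1, 2, 3)))
  r <- taxonomic_richness(dm)
  expect_equal(r$mean, 3); expect_equal(r$sd, 0)
  dm <- make_diet(rbind(c(0, 0, 0), c(2, 2, 0)))
  r <- taxonomic_richness(dm)
  expect_equal(sort(unname(r$per_individual)), c(0, 2))
})
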