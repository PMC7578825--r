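as_xy <- function(a) {
  if (inherits(a, "isotope_table")) return(group_xy(a))
  m <- as.matrix(a)
  if (ncol(m) != 2L) stop_validation("expected a two-column (d13C, d15N) sample")
  storage.mode(m) <- "double"
  m
}

test_result <- function(method, statistic, p_value, n1, n2 = NA_integer_,
                        permutations = NA_integer_, seed = NA_integer_,
                        extra = NULL) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value), n1 = n1, n2 = n2,
                   permutations = permutations, seed = seed), extra),
            class = "test_result")
}

#' Two-sample Hotelling's T-squared test
#'
#' Parametric test that two bivariate samples (points on the d13C/d15N
#' biplot) share a mean vector, using the pooled sample covariance. The
#' p-value comes from the exact F transform
#' \eqn{F = T^2 (n_1+n_2-p-1)/((n_1+n_2-2)p)} with \eqn{p = 2} dimensions
#' and \eqn{(p, n_1+n_2-p-1)} degrees of freedom.
#'
#' @param a,b two-column matrices/data frames (or [isotope_table()]s).
#' @return A `test_result` with the T-squared statistic and p-value.
#' @export
hotelling_t2 <- function(a, b) {
  a <- as_xy(a); b <- as_xy(b)
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 + n2 < 4L) stop_validation("Hotelling's T^2 needs n1 + n2 >= 4")
  d <- colMeans(a) - colMeans(b)
  Sp <- ((n1 - 1) * stats::cov(a) + (n2 - 1) * stats::cov(b)) / (n1 + n2 - 2)
  if (!is.finite(det(Sp)) || det(Sp) <= 0) {
    stop_validation("pooled covariance is singular")
  }
  t2 <- (n1 * n2 / (n1 + n2)) * as.numeric(crossprod(d, solve(Sp, d)))
  p <- 2
  f <- t2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)
  pv <- stats::pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE)
  test_result("hotelling_t2", t2, pv, n1, n2)
}

rpp_metric <- function(xy, metric) {
  switch(metric,
    CD = mean(sqrt(rowSums(sweep(xy, 2, colMeans(xy))^2))),
    MNND = {
      D <- as.matrix(stats::dist(xy)); diag(D) <- Inf
      mean(apply(D, 1, min))
    },
    centroid = colMeans(xy))
}

#' Residual permutation procedure for niche dispersion and location
#'
#' Nonparametric test for a difference between two groups in a
#' dispersion-type metric (CD: mean distance to centroid; MNND: mean
#' nearest-neighbour distance) or in centroid location. The observed
#' statistic is |metric(a) - metric(b)| (Euclidean distance between
#' centroids for `metric = "centroid_distance"`). The null distribution is
#' built from residuals: each group is centered on its own centroid, the
#' residuals are pooled, randomly reassigned to two groups of the original
#' sizes, shifted back onto the grand centroid, and the statistic is
#' recomputed. The p-value uses the add-one estimator
#' \eqn{(1 + \#\{null \ge obs\})/(B+1)}, so it is never below 1/(B+1).
#'
#' For `metric = "centroid_distance"`, `residual = FALSE` switches to a raw
#' label permutation of the original points.
#'
#' @param a,b two-column samples.
#' @param metric `"CD"`, `"MNND"` or `"centroid_distance"`.
#' @param B number of permutations (>= 99; default 9999).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param residual use the residual-permutation null (default TRUE).
#' @return A `test_result`.
#' @export
rpp_test <- function(a, b, metric = c("CD", "MNND", "centroid_distance"),
                     B = 9999L, seed, residual = TRUE) {
  metric <- match.arg(metric)
  if (missing(seed)) stop_validation("`seed` is required for rpp_test")
  if (B < 99L) stop_validation("use at least B = 99 permutations")
  a <- as_xy(a); b <- as_xy(b)
  n1 <- nrow(a); n2 <- nrow(b)
  min_n <- if (metric == "centroid_distance") 1L else 2L
  if (n1 < min_n || n2 < min_n) {
    stop_validation("metric `%s` needs >= %d points per group", metric, min_n)
  }
  mkey <- if (metric == "centroid_distance") "centroid" else metric
  stat_fun <- function(x, y) {
    if (mkey == "centroid") {
      sqrt(sum((rpp_metric(x, "centroid") - rpp_metric(y, "centroid"))^2))
    } else {
      abs(rpp_metric(x, mkey) - rpp_metric(y, mkey))
    }
  }
  obs <- stat_fun(a, b)
  if (residual) {
    # centering on the group mean deflates residual variance by (1 - 1/n);
    # rescaling by sqrt(n/(n-1)) keeps null dispersion statistics on the same
    # scale as the observed ones (the permuted groups are centered again)
    f1 <- if (n1 > 1L) sqrt(n1 / (n1 - 1)) else 1
    f2 <- if (n2 > 1L) sqrt(n2 / (n2 - 1)) else 1
    pool <- rbind(sweep(a, 2, colMeans(a)) * f1,
                  sweep(b, 2, colMeans(b)) * f2)
    grand <- colMeans(rbind(a, b))
  } else {
    pool <- rbind(a, b)
    grand <- c(0, 0)
  }
  null_stats <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n1 + n2)
      x <- pool[idx[seq_len(n1)], , drop = FALSE]
      y <- pool[idx[(n1 + 1L):(n1 + n2)], , drop = FALSE]
      if (residual) {
        x <- sweep(x, 2, grand, "+")
        y <- sweep(y, 2, grand, "+")
      }
      stat_fun(x, y)
    }, 0)
  })
  pv <- (1 + sum(null_stats >= obs)) / (B + 1)
  test_result(paste0("rpp_", metric), obs, pv, n1, n2,
              permutations = B, seed = seed)
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with the two-sided t-test on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `test_result` whose `statistic` is r (the t value is in
#'   `$t_value`).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_validation("`x` and `y` must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_validation("zero variance in `x` or `y`")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("pearson", unname(ct$estimate), ct$p.value, length(x),
              extra = list(t_value = unname(ct$statistic),
                           df = unname(ct$parameter)))
}

rhythm_formulas <- list(
  full = ff ~ group * time_h + (1 | season),
  additive = ff ~ group + time_h + (1 | season),
  time = ff ~ time_h + (1 | season),
  group = ff ~ group + (1 | season),
  null = ff ~ 1 + (1 | season)
)

#' Random-intercept mixed model for diel feeding rhythm
#'
#' Fits fullness level (treated as numeric 0-5) on size group and sampling
#' time with a season random intercept, by maximum likelihood (ML, not
#' REML) so that nested models can be compared with likelihood-ratio tests.
#' Model tags: `"full"` (group * time), `"additive"` (group + time),
#' `"time"`, `"group"`, `"null"`.
#'
#' @param ft a [fullness_table()].
#' @param formula_tag which fixed-effect structure to fit.
#' @return An `lmm_fit`: fixed effects, season-intercept SD, residual SD,
#'   ML log-likelihood, the number of fixed-effect parameters, and the
#'   underlying `lme4` fit in `$model`.
#' @export
fit_ff_lmm <- function(ft, formula_tag = c("full", "additive", "time",
                                           "group", "null")) {
  formula_tag <- match.arg(formula_tag)
  stopifnot(inherits(ft, "fullness_table"))
  if (nlevels(ft$season) < 2L) {
    stop_validation("the season random intercept needs >= 2 seasons")
  }
  d <- as.data.frame(ft)
  d$ff <- as.numeric(d$ff)
  fit <- lme4::lmer(rhythm_formulas[[formula_tag]], data = d, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X)) {
    stop_validation("rank-deficient fixed-effect design for tag `%s`", formula_tag)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    formula_tag = formula_tag,
    fixef = lme4::fixef(fit),
    season_sd = vc$sdcor[vc$grp == "season"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    logLik = as.numeric(stats::logLik(fit)),
    n_fixef = length(lme4::fixef(fit)),
    n = nrow(d),
    model = fit
  ), class = "lmm_fit")
}

#' Likelihood-ratio test between nested feeding-rhythm models
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in
#' fixed-effect parameter counts. Both fits must be ML fits to the same
#' data.
#'
#' @param full,reduced `lmm_fit` objects, `reduced` nested in `full`.
#' @return A `test_result` with `statistic` = chi-squared and `df`.
#' @export
lrt_compare <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$n != reduced$n) stop_validation("fits are not on the same data")
  df <- full$n_fixef - reduced$n_fixef
  if (df < 0L) stop_validation("`reduced` has more fixed effects than `full`")
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  pv <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  test_result("lrt", chi2, pv, full$n, extra = list(df = df))
}

#' Step-down likelihood-ratio tests for the feeding-rhythm model
#'
#' Fits the full model (group * time + season intercept) and its step-down
#' reductions, then tests (i) the interaction: full vs additive, (ii) the
#' time-of-day effect: additive vs group-only, and (iii) the size-group
#' effect: additive vs time-only.
#'
#' @param ft a [fullness_table()].
#' @return Named list of `test_result`s (`interaction`, `time`, `group`)
#'   plus the four `lmm_fit`s in `$fits`.
#' @export
ff_rhythm_tests <- function(ft) {
  fits <- lapply(c(full = "full", additive = "additive", time = "time",
                   group = "group"), function(tag) fit_ff_lmm(ft, tag))
  list(
    interaction = lrt_compare(fits$full, fits$additive),
    time = lrt_compare(fits$additive, fits$group),
    group = lrt_compare(fits$additive, fits$time),
    fits = fits
  )
}
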