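group_xy <- function(it, group = NULL) {
  stopifnot(inherits(it, "isotope_table"))
  d <- as.data.frame(it)
  if (!is.null(group)) {
    d <- d[d$group %in% group, , drop = FALSE]
    if (!nrow(d)) stop_validation("group `%s` not present", paste(group, collapse = ","))
  }
  cbind(d13C = d$d13C, d15N = d$d15N)
}

#' Layman community-wide isotope metrics for one group
#'
#' On the (d13C, d15N) biplot: NR is the d15N range (trophic-level
#' diversity), CR the d13C range (carbon-source diversity), CD the mean
#' Euclidean distance of samples to the group centroid (trophic diversity),
#' and MNND the mean (and SD) of each sample's distance to its nearest
#' neighbour (trophic evenness / similarity between individuals). All in
#' per-mil.
#'
#' @param it an [isotope_table()].
#' @param group optional group label.
#' @return List with `NR`, `CR`, `CD`, `MNND_mean`, `MNND_sd`, `n`.
#' @export
layman_metrics <- function(it, group = NULL) {
  xy <- group_xy(it, group)
  n <- nrow(xy)
  if (n < 2L) stop_validation("Layman metrics need n >= 2 (got %d)", n)
  ctr <- colMeans(xy)
  cd <- mean(sqrt(rowSums(sweep(xy, 2, ctr)^2)))
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  nnd <- apply(D, 1, min)
  list(NR = diff(range(xy[, "d15N"])), CR = diff(range(xy[, "d13C"])),
       CD = cd, MNND_mean = mean(nnd),
       MNND_sd = if (n > 1L) stats::sd(nnd) else 0, n = n)
}

#' Convex hull (total area) of the isotopic niche
#'
#' Area of the smallest convex polygon bounding a group's points on the
#' (d13C, d15N) biplot, in per-mil squared. Collinear point sets get area 0
#' with a `degenerate` attribute.
#'
#' @inheritParams layman_metrics
#' @return Hull area (per-mil^2); attribute `degenerate` TRUE when the
#'   points are collinear.
#' @export
hull_area <- function(it, group = NULL) {
  xy <- group_xy(it, group)
  if (nrow(xy) < 3L) stop_validation("hull area needs n >= 3 (got %d)", nrow(xy))
  polygon_area_xy(xy)
}

# shoelace area of the convex hull of a 2-column coordinate matrix
polygon_area_xy <- function(xy) {
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  k <- nrow(v)
  if (k < 3L) return(structure(0, degenerate = TRUE))
  j <- c(2:k, 1L)
  a <- abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  structure(a, degenerate = a == 0)
}

#' Standard ellipse area of a bivariate isotope distribution
#'
#' The standard ellipse is the 1-SD ellipse of the sample covariance (it
#' contains about 40% of a bivariate-normal population) and its area is
#' \deqn{SEA = \pi \sqrt{\lambda_1 \lambda_2}} with \eqn{\lambda} the
#' eigenvalues of the (n-1)-denominator sample covariance. The small-sample
#' corrected \deqn{SEA_c = SEA (n-1)/(n-2)} is unbiased with respect to
#' sample size.
#'
#' @inheritParams layman_metrics
#' @return A `standard_ellipse`: list with `center`, `cov`, `n`, `SEA` and
#'   `SEAc` (`SEAc` is `NA` for n < 4).
#' @export
standard_ellipse <- function(it, group = NULL) {
  xy <- group_xy(it, group)
  n <- nrow(xy)
  if (n < 3L) stop_validation("standard ellipse needs n >= 3 (got %d)", n)
  S <- stats::cov(xy)
  dt <- det(S)
  if (!is.finite(dt) || dt <= 0) stop_validation("singular sample covariance")
  sea <- pi * sqrt(dt)
  structure(list(center = colMeans(xy), cov = S, n = n, SEA = sea,
                 SEAc = if (n >= 4L) sea * (n - 1) / (n - 2) else NA_real_),
            class = "standard_ellipse")
}

#' Construct an ellipse from center and covariance
#'
#' @param center length-2 numeric (d13C, d15N).
#' @param cov symmetric positive-definite 2x2 covariance (per-mil^2).
#' @param n optional sample size behind the covariance.
#' @return A `standard_ellipse`.
#' @export
ellipse <- function(center, cov, n = NA_integer_) {
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))) || any(eigen(cov, TRUE, TRUE)$values <= 0)) {
    stop_validation("covariance must be symmetric positive definite")
  }
  sea <- pi * sqrt(det(cov))
  structure(list(center = as.numeric(center), cov = cov, n = n, SEA = sea,
                 SEAc = if (!is.na(n) && n >= 4) sea * (n - 1) / (n - 2) else NA_real_),
            class = "standard_ellipse")
}

#' Overlap area between two coverage-scaled ellipses
#'
#' The coverage-c ellipse of a bivariate normal is the Mahalanobis ball of
#' squared radius `qchisq(coverage, 2)`; `coverage = pchisq(1, 2)` (about
#' 39.35%, the default) gives the 1-SD standard ellipse whose area is SEA.
#' The intersection area is computed by deterministic grid quadrature (cell
#' centers inside both ellipses), so results are exactly reproducible at a
#' given resolution.
#'
#' @param e1,e2 `standard_ellipse` objects.
#' @param coverage fraction in (0, 1) of the bivariate normal each ellipse
#'   should enclose.
#' @param resolution grid cell side in per-mil (default 0.01).
#' @return An `ellipse_overlap` list: `area` (per-mil^2), `area1`, `area2`,
#'   `pct1` and `pct2` (overlap as a fraction of each ellipse), `pct_union`,
#'   plus the `coverage` and `resolution` used.
#' @export
ellipse_overlap <- function(e1, e2, coverage = stats::pchisq(1, 2),
                            resolution = 0.01) {
  stopifnot(inherits(e1, "standard_ellipse"), inherits(e2, "standard_ellipse"))
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1) {
    stop_validation("`coverage` must lie strictly between 0 and 1")
  }
  check_number(resolution, "resolution", 0, strict = TRUE)
  r2 <- stats::qchisq(coverage, df = 2)
  a1 <- pi * sqrt(det(e1$cov)) * r2
  a2 <- pi * sqrt(det(e2$cov)) * r2
  box <- function(e) {
    half <- sqrt(diag(e$cov) * r2)
    rbind(e$center - half, e$center + half)
  }
  b <- rbind(box(e1), box(e2))
  lo <- apply(b, 2, min); hi <- apply(b, 2, max)
  # intersection is empty unless the bounding boxes intersect
  xi <- c(max(box(e1)[1, 1], box(e2)[1, 1]), min(box(e1)[2, 1], box(e2)[2, 1]))
  yi <- c(max(box(e1)[1, 2], box(e2)[1, 2]), min(box(e1)[2, 2], box(e2)[2, 2]))
  area <- 0
  if (xi[1] < xi[2] && yi[1] < yi[2]) {
    xs <- seq(xi[1] + resolution / 2, xi[2], by = resolution)
    ys <- seq(yi[1] + resolution / 2, yi[2], by = resolution)
    g <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    inside <- function(e) {
      d <- sweep(g, 2, e$center)
      Q <- solve(e$cov)
      rowSums((d %*% Q) * d) <= r2
    }
    area <- sum(inside(e1) & inside(e2)) * resolution^2
  }
  structure(list(area = area, area1 = a1, area2 = a2,
                 pct1 = area / a1, pct2 = area / a2,
                 pct_union = area / (a1 + a2 - area),
                 coverage = coverage, resolution = resolution),
            class = "ellipse_overlap")
}

#' Full bivariate niche-metric panel for one group
#'
#' Convenience wrapper returning the seven standard metrics (NR, CR, CD,
#' MNND, TA, SEA, SEAc) for a group of an isotope table.
#'
#' @inheritParams layman_metrics
#' @return A `niche_metrics` list.
#' @export
niche_metrics <- function(it, group = NULL) {
  lay <- layman_metrics(it, group)
  ta <- as.numeric(hull_area(it, group))
  se <- standard_ellipse(it, group)
  structure(c(list(group = if (is.null(group)) "all" else group), lay[c("n")],
              lay[c("NR", "CR", "CD", "MNND_mean", "MNND_sd")],
              list(TA = ta, SEA = se$SEA, SEAc = se$SEAc)),
            class = "niche_metrics")
}

#' Ordinary least-squares regression of an isotope on standard length
#'
#' Fits `tracer ~ SL` by OLS over samples with a recorded standard length
#' and reports the slope, intercept, R-squared and the two-sided p-value of
#' the slope t-test.
#'
#' @param it an [isotope_table()] with an `SL` column.
#' @param tracer `"d15N"` or `"d13C"`.
#' @return A `regression_fit` list: `tracer`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
isotope_length_regression <- function(it, tracer = c("d15N", "d13C")) {
  tracer <- match.arg(tracer)
  d <- as.data.frame(it)
  d <- d[!is.na(d$SL), , drop = FALSE]
  if (nrow(d) < 3L) stop_validation("regression needs >= 3 samples with SL")
  fit <- stats::lm(stats::reformulate("SL", tracer), data = d)
  sm <- summary(fit)
  structure(list(tracer = tracer,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients["SL", "Pr(>|t|)"]),
                 n = nrow(d)),
            class = "regression_fit")
}
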