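# Independent oracles and fixture builders used across the suite.

# Brute-force Shannon decomposition of a counts matrix (individuals x taxa):
# pooled-niche entropy (TNW), weighted mean individual entropy (WIC).
shannon_oracle <- function(m) {
  tot <- rowSums(m)
  q <- colSums(m) / sum(m)
  tnw <- 0
  for (k in seq_along(q)) if (q[k] > 0) tnw <- tnw - q[k] * log(q[k])
  wic <- 0
  for (i in seq_len(nrow(m))) {
    p <- m[i, ] / tot[i]
    h <- 0
    for (k in seq_along(p)) if (p[k] > 0) h <- h - p[k] * log(p[k])
    wic <- wic + (tot[i] / sum(tot)) * h
  }
  list(TNW = tnw, WIC = wic)
}

# Brute-force convex hull area: identify hull vertices as the points not
# strictly inside any triangle of other points, order them by angle around
# their centroid, apply the shoelace formula. Independent of chull().
hull_oracle <- function(xy) {
  n <- nrow(xy)
  cross3 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  in_tri <- function(p, a, b, c) {
    d1 <- cross3(a, b, p); d2 <- cross3(b, c, p); d3 <- cross3(c, a, p)
    (d1 >= 0 && d2 >= 0 && d3 >= 0) || (d1 <= 0 && d2 <= 0 && d3 <= 0)
  }
  keep <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    for (tri in utils::combn(others, 3, simplify = FALSE)) {
      a <- xy[tri[1], ]; b <- xy[tri[2], ]; c <- xy[tri[3], ]
      if (abs(cross3(a, b, c)) > 1e-12 && in_tri(xy[p, ], a, b, c) &&
          abs(cross3(a, b, xy[p, ])) > 1e-12 && abs(cross3(b, c, xy[p, ])) > 1e-12 &&
          abs(cross3(c, a, xy[p, ])) > 1e-12) {
        keep[p] <- FALSE
        break
      }
    }
  }
  v <- unique(xy[keep, , drop = FALSE])
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  k <- nrow(v); j <- c(2:k, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Closed-form intersection area of two unit circles with centers `d` apart.
circle_lens <- function(d) {
  if (d >= 2) return(0)
  2 * acos(d / 2) - (d / 2) * sqrt(4 - d^2)
}

# small-fixture builders ----------------------------------------------------

make_diet <- function(counts, group = "g1", masses = counts,
                      taxa = paste0("t", seq_len(ncol(counts)))) {
  rows <- expand.grid(i = seq_len(nrow(counts)), k = seq_len(ncol(counts)))
  diet_matrix(data.frame(
    individual_id = paste0("ind", rows$i),
    group = rep_len(group, nrow(rows)),
    prey_taxon = taxa[rows$k],
    count = counts[cbind(rows$i, rows$k)],
    mass = masses[cbind(rows$i, rows$k)]))
}

make_isotopes <- function(xy, group = "g1") {
  isotope_table(data.frame(
    sample_id = paste0("s", seq_len(nrow(xy))), group = group,
    d13C = xy[, 1], d15N = xy[, 2]))
}

random_diet_counts <- function(n, K) {
  m <- matrix(rpois(n * K, lambda = 3), n, K)
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  m
}

three_source_set <- function() {
  source_set(data.frame(
    source = c("algae", "mussel", "shrimp"),
    d13C_mean = c(-30, -22, -14), d13C_sd = 0.5,
    d15N_mean = c(5, 15, 8), d15N_sd = 0.5,
    tef_d13C_mean = 1.3, tef_d13C_sd = 0.3,
    tef_d15N_mean = 2.3, tef_d15N_sd = 0.18))
}
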