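#' Build a diet-proportion profile
#'
#' A profile is a named simplex of resource-use proportions on a given basis
#' (mass for %W-type profiles, count for %N-type profiles). Vectors that sum
#' to 1 within 1e-9 are accepted as-is; anything else is renormalized with a
#' warning (printed composition tables often omit minor items, so their rows
#' do not sum exactly to 100).
#'
#' @param proportions non-negative numeric vector.
#' @param labels taxon names; defaults to `names(proportions)`.
#' @param basis `"mass"` or `"count"`.
#' @return A `diet_profile`: named proportion vector with a `basis` attribute.
#' @export
diet_profile <- function(proportions, labels = names(proportions),
                         basis = c("mass", "count")) {
  basis <- match.arg(basis)
  if (is.null(labels)) stop_validation("diet profiles need taxon labels")
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_validation("proportions must be finite and non-negative")
  }
  s <- sum(p)
  if (s <= 0) stop_validation("a diet profile cannot be the zero vector")
  if (abs(s - 1) > 1e-9) {
    warning("proportions sum to ", format(s), "; renormalizing", call. = FALSE)
    p <- p / s
  }
  names(p) <- labels
  structure(p, basis = basis, class = "diet_profile")
}

# Individuals-by-taxa value matrix on one basis, over the full shared taxon
# vocabulary of `dm`. NA values contribute nothing to this basis.
diet_value_matrix <- function(dm, basis = c("count", "mass"), group = NULL,
                              exclude = NULL) {
  basis <- match.arg(basis)
  stopifnot(inherits(dm, "diet_matrix"))
  if (is.null(exclude)) exclude <- if (basis == "count") "detritus" else character()
  taxa <- setdiff(unique(dm$prey_taxon), exclude)
  if (!length(taxa)) stop_validation("no taxa left after exclusion")
  d <- as.data.frame(dm)
  if (!is.null(group)) {
    d <- d[d$group %in% group, , drop = FALSE]
    if (!nrow(d)) stop_validation("group `%s` not present", paste(group, collapse = ","))
  }
  ids <- unique(d$individual_id)   # before taxon filtering: individuals with
  d <- d[d$prey_taxon %in% taxa, , drop = FALSE]  # only excluded taxa keep a zero row
  m <- matrix(0, length(ids), length(taxa), dimnames = list(ids, taxa))
  v <- d[[basis]]
  v[is.na(v)] <- 0
  m[cbind(match(d$individual_id, ids), match(d$prey_taxon, taxa))] <- v
  m
}

# Row-normalize, dropping empty individuals with a warning.
proportion_matrix <- function(m, basis) {
  tot <- rowSums(m)
  if (all(tot == 0)) {
    stop_validation("all individuals have zero total %s", basis)
  }
  if (any(tot == 0)) {
    warning(sum(tot == 0), " individual(s) with zero total ", basis,
            " excluded", call. = FALSE)
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(m, 1, tot, "/")
}

profile_set <- function(m, basis) {
  p <- proportion_matrix(m, basis)
  sd_col <- if (nrow(p) > 1L) apply(p, 2, stats::sd) else rep(0, ncol(p))
  structure(list(
    basis = basis,
    per_individual = p,
    mean = diet_profile(colMeans(p), colnames(p), basis),
    sd = stats::setNames(sd_col, colnames(p)),
    n = nrow(p)
  ), class = "diet_profile_set")
}

#' Percent-by-weight diet composition
#'
#' Per-individual mass proportions of each prey taxon and the group mean and
#' SD across individuals (the %W convention: each individual is first
#' normalized to its own gut-content mass, then averaged).
#'
#' @param dm a [diet_matrix()].
#' @param group optional group label(s) to subset to.
#' @param exclude taxa to drop beforehand (none by default: detritus counts
#'   towards mass-based composition).
#' @return A `diet_profile_set` with elements `per_individual` (matrix, rows
#'   sum to 1), `mean` (a [diet_profile()]), `sd` and `n`.
#' @export
percent_by_weight <- function(dm, group = NULL, exclude = character()) {
  profile_set(diet_value_matrix(dm, "mass", group, exclude), "mass")
}

#' Percent-by-number diet composition
#'
#' As [percent_by_weight()] but on item counts. Detritus is excluded by
#' default: its item number cannot be determined, so percentage by number
#' conventionally omits it. Individuals whose guts contain only excluded
#' taxa are dropped with a warning.
#'
#' @inheritParams percent_by_weight
#' @param exclude taxa excluded from counting (default `"detritus"`).
#' @return A `diet_profile_set`.
#' @export
percent_by_number <- function(dm, group = NULL, exclude = "detritus") {
  profile_set(diet_value_matrix(dm, "count", group, exclude), "count")
}

#' Gonadosomatic and fullness indices
#'
#' `gsi()` is 100 * gonad mass / body mass; `fullness_index()` is
#' 100 * gut mass / body mass. Both are percentages and vectorized.
#'
#' @param Wg,Wgut,Wt gonad / gut / total body wet mass in grams.
#' @return Numeric vector of percentages.
#' @export
gsi <- function(Wg, Wt) {
  if (any(!is.finite(Wt)) || any(Wt <= 0)) stop_validation("`Wt` must be > 0")
  if (any(Wg < 0, na.rm = TRUE)) stop_validation("`Wg` must be >= 0")
  100 * Wg / Wt
}

#' @rdname gsi
#' @export
fullness_index <- function(Wgut, Wt) {
  if (any(!is.finite(Wt)) || any(Wt <= 0)) stop_validation("`Wt` must be > 0")
  if (any(Wgut < 0, na.rm = TRUE)) stop_validation("`Wgut` must be >= 0")
  100 * Wgut / Wt
}

profile_vector <- function(p) {
  if (inherits(p, "diet_profile_set")) p <- p$mean
  if (inherits(p, "diet_profile")) return(stats::setNames(as.numeric(p), names(p)))
  if (is.numeric(p) && !is.null(names(p))) return(p)
  stop_validation("expected a diet_profile, diet_profile_set, or named numeric vector")
}

#' Simplified Morisita dietary overlap index
#'
#' \deqn{C_{ij} = 2 \sum_k p_{ik} p_{jk} / (\sum_k p_{ik}^2 + \sum_k p_{jk}^2)}
#' where \eqn{p_{ik}} is the proportion of prey \eqn{k} in the diet of
#' predator (or group) \eqn{i}. Lies in [0, 1]: 1 for identical diets, 0 for
#' disjoint ones. Profiles are aligned on the union of their taxa (absent
#' taxon = 0).
#'
#' @param p,q diet profiles ([diet_profile()], [percent_by_weight()] output,
#'   or named proportion vectors).
#' @return The overlap index, a number in [0, 1].
#' @export
morisita_index <- function(p, q) {
  p <- profile_vector(p); q <- profile_vector(q)
  taxa <- union(names(p), names(q))
  pv <- stats::setNames(numeric(length(taxa)), taxa)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  if (sum(pv) <= 0 || sum(qv) <= 0) stop_validation("zero-vector profile")
  2 * sum(pv * qv) / (sum(pv^2) + sum(qv^2))
}

#' Pairwise Morisita overlap between all groups of a diet matrix
#'
#' Group profiles default to the group-mean percent-by-weight composition
#' (`pool = FALSE`); `pool = TRUE` instead pools raw masses/counts across a
#' group's individuals before normalizing.
#'
#' @param dm a [diet_matrix()].
#' @param basis `"mass"` or `"count"`.
#' @param pool pool individuals before normalizing instead of averaging
#'   individual proportions.
#' @param exclude taxa to drop (defaults per basis, see
#'   [percent_by_number()]).
#' @return An `overlap_matrix`: symmetric matrix with unit diagonal, groups
#'   ordered by first appearance.
#' @export
morisita_matrix <- function(dm, basis = c("mass", "count"), pool = FALSE,
                            exclude = NULL) {
  basis <- match.arg(basis)
  groups <- levels(dm$group)
  profs <- lapply(groups, function(g) {
    m <- diet_value_matrix(dm, basis, g, exclude)
    if (pool) {
      diet_profile(colSums(m) / sum(m), colnames(m), basis)
    } else {
      profile_set(m, basis)$mean
    }
  })
  k <- length(groups)
  C <- diag(1, k)
  dimnames(C) <- list(groups, groups)
  if (k > 1L) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      C[i, j] <- C[j, i] <- morisita_index(profs[[i]], profs[[j]])
    }
  }
  structure(C, class = c("overlap_matrix", "matrix"))
}

#' Is a dietary overlap ecologically significant?
#'
#' By convention an overlap index strictly above 0.6 flags significant
#' dietary overlap between two predators.
#'
#' @param C_ij overlap index value(s) in [0, 1].
#' @return Logical vector.
#' @export
overlap_significant <- function(C_ij) C_ij > 0.6

#' Total niche width and its within-individual component
#'
#' Shannon-entropy decomposition of a group's resource-use niche
#' (Roughgarden): \deqn{TNW = -\sum_k q_k \ln q_k} with \eqn{q_k} the pooled
#' proportion of resource \eqn{k}, and
#' \deqn{WIC = \sum_i p_i ( -\sum_k p_{ik} \ln p_{ik} )} the weighted mean of
#' individual diet entropies, where \eqn{p_i} is individual \eqn{i}'s share
#' of the group's total resource use and \eqn{p_{ik}} its own diet
#' proportions (0 ln 0 := 0). BIC = TNW - WIC is the between-individual
#' component, non-negative by construction, and WIC/TNW in [0, 1] measures
#' individual specialization: values near 0 mean strong specialization.
#' All entropies are in nats.
#'
#' @param dm a [diet_matrix()].
#' @param group optional group subset.
#' @param basis resource-use currency, `"count"` (default, the proportional
#'   numerical abundance convention) or `"mass"`.
#' @param exclude taxa to drop (defaults per basis).
#' @param equal_weights weight every individual equally (normalize each to 1
#'   before pooling) instead of by its actual resource total.
#' @return A `specialization_result`: list with `TNW`, `WIC`, `BIC`,
#'   `wic_over_tnw`, `mean_diet_similarity`, `n`, `basis` and a `degenerate`
#'   flag (TRUE when the group uses a single resource so TNW = 0 and the
#'   ratio is reported as 1).
#' @export
tnw_wic <- function(dm, group = NULL, basis = c("count", "mass"),
                    exclude = NULL, equal_weights = FALSE) {
  basis <- match.arg(basis)
  m <- diet_value_matrix(dm, basis, group, exclude)
  tot <- rowSums(m)
  m <- m[tot > 0, , drop = FALSE]
  if (nrow(m) < 2L) stop_validation("TNW/WIC needs >= 2 individuals with positive totals")
  if (equal_weights) m <- sweep(m, 1, rowSums(m), "/")
  tot <- rowSums(m)
  p_i <- tot / sum(tot)
  q_k <- colSums(m) / sum(m)
  p_ik <- sweep(m, 1, tot, "/")
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  TNW <- -sum(xlogx(q_k))
  WIC <- sum(p_i * (-rowSums(xlogx(p_ik))))
  degenerate <- TNW < .Machine$double.eps^0.5
  structure(list(
    group = if (is.null(group)) "all" else paste(group, collapse = "+"),
    basis = basis, n = nrow(m),
    TNW = TNW, WIC = WIC, BIC = TNW - WIC,
    wic_over_tnw = if (degenerate) 1 else WIC / TNW,
    mean_diet_similarity = mean_pairwise_ps(p_ik),
    degenerate = degenerate
  ), class = "specialization_result")
}

mean_pairwise_ps <- function(p_ik) {
  n <- nrow(p_ik)
  if (n < 2L) return(NA_real_)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sum(pmin(p_ik[i, ], p_ik[j, ]))
  }
  s / choose(n, 2)
}

#' Mean pairwise diet similarity within a group
#'
#' Mean over all unordered pairs of individuals of the proportional
#' similarity \eqn{PS_{ij} = \sum_k \min(p_{ik}, p_{jk})}: 1 when all
#' individuals share the same diet, 0 when they are disjoint specialists.
#'
#' @inheritParams tnw_wic
#' @return A number in [0, 1].
#' @export
mean_diet_similarity <- function(dm, group = NULL, basis = c("count", "mass"),
                                 exclude = NULL) {
  basis <- match.arg(basis)
  m <- diet_value_matrix(dm, basis, group, exclude)
  p <- proportion_matrix(m, basis)
  if (nrow(p) < 2L) stop_validation("diet similarity needs >= 2 individuals")
  mean_pairwise_ps(p)
}

#' Taxonomic richness per gut
#'
#' Number of prey taxa with a positive item count in each individual gut,
#' summarized as mean and SD across individuals.
#'
#' @param dm a [diet_matrix()].
#' @param group optional group subset.
#' @return List with `mean`, `sd`, `per_individual`, `n`.
#' @export
taxonomic_richness <- function(dm, group = NULL) {
  m <- diet_value_matrix(dm, "count", group, exclude = character())
  rich <- rowSums(m > 0)
  list(mean = mean(rich), sd = if (length(rich) > 1L) stats::sd(rich) else 0,
       per_individual = rich, n = length(rich))
}
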