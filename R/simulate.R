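#' Configuration for the diet simulator
#'
#' Individuals in group g draw their personal diet-proportion vector from
#' Dirichlet(alpha_g * q_g): small `alpha` produces strong individual
#' specialization (individuals concentrate on few resources), large `alpha`
#' makes every individual's diet converge to the group baseline `q_g`.
#' Gut counts are then Multinomial over those proportions.
#'
#' @param group_sizes named vector of individuals per group.
#' @param q baseline diet proportions: a vector (shared) or a
#'   groups-by-taxa matrix; rows must each sum to 1.
#' @param alpha Dirichlet concentration, one value or one per group (> 0).
#' @param items_per_individual items counted per gut (scalar or one per
#'   individual).
#' @param unit_mass per-taxon unit mass in grams (default 1, so %W tracks
#'   %N unless configured otherwise).
#' @param taxa taxon names.
#' @param seed integer RNG seed.
#' @return A `diet_sim_config` list.
#' @export
diet_sim_config <- function(group_sizes = c(small_juvenile = 9, large_juvenile = 6,
                                            sub_adult = 15, adult = 7),
                            q = NULL, alpha = 1, items_per_individual = 100,
                            unit_mass = NULL, taxa = NULL, seed = 1L) {
  if (any(group_sizes < 1)) stop_validation("group sizes must be positive")
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("group_", seq_along(group_sizes))
  }
  if (is.null(q)) q <- rep(1 / 8, 8)
  if (is.null(dim(q))) {
    q <- matrix(q, nrow = length(group_sizes), ncol = length(q), byrow = TRUE)
  }
  if (nrow(q) != length(group_sizes)) {
    stop_validation("`q` must have one row per group")
  }
  if (any(q < 0) || any(abs(rowSums(q) - 1) > 1e-9)) {
    stop_validation("each row of `q` must be a probability simplex")
  }
  if (any(alpha <= 0)) stop_validation("`alpha` must be > 0")
  alpha <- rep_len(alpha, length(group_sizes))
  K <- ncol(q)
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(K))
  if (is.null(unit_mass)) unit_mass <- rep(1, K)
  if (length(unit_mass) != K || any(unit_mass < 0)) {
    stop_validation("`unit_mass` needs one non-negative value per taxon")
  }
  structure(list(group_sizes = group_sizes, q = q, alpha = alpha,
                 items_per_individual = items_per_individual,
                 unit_mass = unit_mass, taxa = taxa, seed = seed),
            class = "diet_sim_config")
}

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) { g <- as.numeric(shape == max(shape)) }  # extreme sparsity guard
  g / sum(g)
}

#' Simulate a per-individual diet matrix
#'
#' @param cfg a [diet_sim_config()].
#' @return A [diet_matrix()], deterministic given `cfg$seed`.
#' @export
simulate_diet <- function(cfg) {
  stopifnot(inherits(cfg, "diet_sim_config"))
  with_seed(cfg$seed, {
    rows <- list()
    idx <- 0L
    for (g in seq_along(cfg$group_sizes)) {
      gname <- names(cfg$group_sizes)[g]
      for (i in seq_len(cfg$group_sizes[g])) {
        idx <- idx + 1L
        p_i <- rdirichlet1(cfg$alpha[g] * cfg$q[g, ])
        items <- rep_len(cfg$items_per_individual, sum(cfg$group_sizes))[idx]
        cnt <- as.integer(stats::rmultinom(1, size = items, prob = p_i))
        rows[[idx]] <- data.frame(
          individual_id = sprintf("%s_%02d", gname, i),
          group = gname, prey_taxon = cfg$taxa,
          count = cnt, mass = cnt * cfg$unit_mass,
          stringsAsFactors = FALSE)
      }
    }
    diet_matrix(do.call(rbind, rows))
  })
}

#' Configuration for the per-group bivariate isotope simulator
#'
#' Defaults reproduce the published per-size-group muscle d13C/d15N means,
#' SDs and sample sizes for black amur bream (independent tracers).
#'
#' @param groups data frame with columns `group`, `n`, `d13C_mean`,
#'   `d13C_sd`, `d15N_mean`, `d15N_sd` and optionally `cor` (within-group
#'   tracer correlation, default 0).
#' @param seed integer RNG seed.
#' @return An `isotope_sim_config`.
#' @export
isotope_sim_config <- function(groups = bream_isotope_groups(), seed = 1L) {
  req <- c("group", "n", "d13C_mean", "d13C_sd", "d15N_mean", "d15N_sd")
  if (!all(req %in% names(groups))) {
    stop_validation("`groups` needs columns: %s", paste(req, collapse = ", "))
  }
  if (!"cor" %in% names(groups)) groups$cor <- 0
  if (any(abs(groups$cor) >= 1) || any(groups$d13C_sd < 0) || any(groups$d15N_sd < 0)) {
    stop_validation("SDs must be >= 0 and |cor| < 1")
  }
  structure(list(groups = groups, seed = seed), class = "isotope_sim_config")
}

#' Simulate a per-sample isotope table
#'
#' Each group's (d13C, d15N) values are bivariate-normal draws with the
#' configured mean vector and covariance.
#'
#' @param cfg an [isotope_sim_config()].
#' @return An [isotope_table()], deterministic given `cfg$seed`.
#' @export
simulate_isotopes <- function(cfg) {
  stopifnot(inherits(cfg, "isotope_sim_config"))
  with_seed(cfg$seed, {
    g <- cfg$groups
    out <- lapply(seq_len(nrow(g)), function(i) {
      S <- matrix(c(g$d13C_sd[i]^2,
                    g$cor[i] * g$d13C_sd[i] * g$d15N_sd[i],
                    g$cor[i] * g$d13C_sd[i] * g$d15N_sd[i],
                    g$d15N_sd[i]^2), 2, 2)
      xy <- MASS::mvrnorm(g$n[i], mu = c(g$d13C_mean[i], g$d15N_mean[i]), Sigma = S)
      xy <- matrix(xy, ncol = 2)
      data.frame(sample_id = sprintf("%s_%02d", g$group[i], seq_len(g$n[i])),
                 group = g$group[i], d13C = xy[, 1], d15N = xy[, 2],
                 SL = NA_real_, stringsAsFactors = FALSE)
    })
    isotope_table(do.call(rbind, out))
  })
}

#' Configuration for the mixing-model consumer simulator
#'
#' @param sources a [source_set()].
#' @param p true source proportions (simplex over the sources).
#' @param n number of consumers.
#' @param residual_sd per-tracer residual SD in per-mil (length 2:
#'   d13C, d15N).
#' @param group group label for the simulated consumers.
#' @param seed integer RNG seed.
#' @return A `mix_sim_config`.
#' @export
mix_sim_config <- function(sources, p, n = 50L, residual_sd = c(0.5, 0.5),
                           group = "consumers", seed = 1L) {
  stopifnot(inherits(sources, "source_set"))
  if (length(p) != nrow(sources)) stop_validation("`p` needs one entry per source")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) stop_validation("`p` must be a simplex")
  if (n < 1) stop_validation("`n` must be >= 1")
  residual_sd <- rep_len(residual_sd, 2)
  if (any(residual_sd < 0)) stop_validation("residual SDs must be >= 0")
  structure(list(sources = sources, p = as.numeric(p), n = as.integer(n),
                 residual_sd = residual_sd, group = group, seed = seed),
            class = "mix_sim_config")
}

# per-tracer mixture mean and variance implied by proportions p
mixture_moments <- function(sources, p, residual_sd = c(0, 0)) {
  mu <- cbind(sources$d13C_mean + sources$tef_d13C_mean,
              sources$d15N_mean + sources$tef_d15N_mean)
  v <- cbind(sources$d13C_sd^2 + sources$tef_d13C_sd^2,
             sources$d15N_sd^2 + sources$tef_d15N_sd^2)
  list(mean = as.numeric(crossprod(p, mu)),
       var = as.numeric(crossprod(p^2, v)) + residual_sd^2)
}

#' Simulate consumers from known source proportions
#'
#' Generates consumer tracer values under the standard mixing-model
#' generative assumption: tracer j of each consumer is Normal with mean
#' \eqn{\sum_k p_k (\mu_{jk} + \lambda_{jk})} and variance
#' \eqn{\sum_k p_k^2 (\omega_{jk}^2 + \tau_{jk}^2) + \sigma_j^2}, where
#' \eqn{\mu/\omega} are source signature means/SDs and
#' \eqn{\lambda/\tau} TEF means/SDs.
#'
#' @param cfg a [mix_sim_config()].
#' @return An [isotope_table()] of consumers.
#' @export
simulate_consumers <- function(cfg) {
  stopifnot(inherits(cfg, "mix_sim_config"))
  with_seed(cfg$seed, {
    mm <- mixture_moments(cfg$sources, cfg$p, cfg$residual_sd)
    isotope_table(data.frame(
      sample_id = sprintf("%s_%03d", cfg$group, seq_len(cfg$n)),
      group = cfg$group,
      d13C = stats::rnorm(cfg$n, mm$mean[1], sqrt(mm$var[1])),
      d15N = stats::rnorm(cfg$n, mm$mean[2], sqrt(mm$var[2])),
      SL = NA_real_, stringsAsFactors = FALSE))
  })
}

#' Configuration for the gut-fullness simulator
#'
#' Fullness is generated on a latent continuous scale —
#' baseline + time-of-day effect + group effect + season random intercept +
#' residual — then clipped to [0, 5] and rounded onto the ordinal 0-5 scale.
#'
#' @param time_effects named numeric, one per sampling hour (default 8
#'   3-hourly hauls over a diel cycle, no rhythm).
#' @param group_effects named numeric, one per size group.
#' @param baseline latent-scale grand mean.
#' @param season_sd SD of the season random intercept (>= 0).
#' @param residual_sd latent residual SD (> 0).
#' @param n_seasons number of seasons.
#' @param n_per_cell fish sampled per (group, time, season) cell.
#' @param seed integer RNG seed.
#' @return A `fullness_sim_config`.
#' @export
fullness_sim_config <- function(time_effects = stats::setNames(rep(0, 8),
                                  c("01", "04", "07", "10", "13", "16", "19", "22")),
                                group_effects = c(small_juvenile = 0, large_juvenile = 0,
                                                  sub_adult = 0, adult = 0),
                                baseline = 2.5, season_sd = 0.5, residual_sd = 1,
                                n_seasons = 4L, n_per_cell = 2L, seed = 1L) {
  check_number(season_sd, "season_sd", 0)
  check_number(residual_sd, "residual_sd", 0, strict = TRUE)
  if (n_seasons < 1 || n_per_cell < 1) stop_validation("n_seasons and n_per_cell must be >= 1")
  structure(list(time_effects = time_effects, group_effects = group_effects,
                 baseline = baseline, season_sd = season_sd,
                 residual_sd = residual_sd, n_seasons = as.integer(n_seasons),
                 n_per_cell = as.integer(n_per_cell), seed = seed),
            class = "fullness_sim_config")
}

#' Simulate a gut-fullness observation table
#'
#' @param cfg a [fullness_sim_config()].
#' @return A [fullness_table()], deterministic given `cfg$seed`. Body mass
#'   is drawn per group on a log-normal scale; gut mass tracks the realized
#'   fullness level so the fullness index stays consistent with `ff`.
#' @export
simulate_fullness <- function(cfg) {
  stopifnot(inherits(cfg, "fullness_sim_config"))
  with_seed(cfg$seed, {
    grid <- expand.grid(group = names(cfg$group_effects),
                        time_h = names(cfg$time_effects),
                        season = paste0("season_", seq_len(cfg$n_seasons)),
                        rep = seq_len(cfg$n_per_cell),
                        stringsAsFactors = FALSE)
    season_int <- stats::setNames(stats::rnorm(cfg$n_seasons, 0, cfg$season_sd),
                                  paste0("season_", seq_len(cfg$n_seasons)))
    latent <- cfg$baseline +
      cfg$time_effects[grid$time_h] +
      cfg$group_effects[grid$group] +
      season_int[grid$season] +
      stats::rnorm(nrow(grid), 0, cfg$residual_sd)
    ff <- round(pmin(5, pmax(0, latent)))
    wt_mean <- stats::setNames(seq(60, 60 * length(cfg$group_effects),
                                   length.out = length(cfg$group_effects)),
                               names(cfg$group_effects))
    Wt <- exp(stats::rnorm(nrow(grid), log(wt_mean[grid$group]), 0.2))
    Wgut <- Wt * (0.01 + 0.015 * ff)
    Wg <- Wt * 0.02
    fullness_table(data.frame(
      individual_id = sprintf("fish_%04d", seq_len(nrow(grid))),
      group = grid$group, season = grid$season, time_h = grid$time_h,
      ff = ff, Wt = Wt, Wgut = Wgut, Wg = Wg, stringsAsFactors = FALSE))
  })
}
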