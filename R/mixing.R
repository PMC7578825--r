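#' Specify a Bayesian stable-isotope mixing model
#'
#' Estimates the simplex of dietary source proportions p for one consumer
#' group from two tracers (d13C, d15N). The likelihood of consumer value
#' x_ij for tracer j is Normal with mean
#' \eqn{\sum_k p_k(\mu_{jk} + \lambda_{jk})} and variance
#' \eqn{\sum_k p_k^2(\omega_{jk}^2 + \tau_{jk}^2) + \sigma_j^2}, where
#' \eqn{\mu_{jk}/\omega_{jk}} are source signature means/SDs,
#' \eqn{\lambda_{jk}/\tau_{jk}} trophic-enrichment-factor means/SDs, and
#' \eqn{\sigma_j} an optional residual SD with a half-Normal(0, 2 per-mil)
#' prior. The prior on p is Dirichlet(`prior`).
#'
#' @param sources a [source_set()].
#' @param consumers an [isotope_table()]; subset with `group` if it holds
#'   several groups.
#' @param group optional consumer group label.
#' @param prior Dirichlet concentration, scalar or one value per source
#'   (default 1: uniform over the simplex).
#' @param residual_error include the per-tracer residual SD (default TRUE;
#'   requires >= 2 consumers).
#' @param chains,iter,burn,thin MCMC controls (defaults 4 chains of 20000
#'   iterations, 10000 burn-in, thinning 10).
#' @param seed integer seed driving all chains.
#' @return A `mixing_model_spec`.
#' @export
mixing_model_spec <- function(sources, consumers, group = NULL, prior = 1,
                              residual_error = TRUE, chains = 4L,
                              iter = 20000L, burn = 10000L, thin = 10L,
                              seed = 1L) {
  stopifnot(inherits(sources, "source_set"))
  d <- as.data.frame(consumers)
  if (!is.null(group)) d <- d[d$group %in% group, , drop = FALSE]
  if (!nrow(d)) stop_validation("no consumer samples selected")
  if (residual_error && nrow(d) < 2L) {
    stop_validation("residual-error model needs >= 2 consumer samples")
  }
  K <- nrow(sources)
  prior <- rep_len(prior, K)
  if (any(prior <= 0)) stop_validation("Dirichlet concentrations must be > 0")
  if (burn >= iter) stop_validation("`burn` must be smaller than `iter`")
  structure(list(sources = sources, consumers = d, prior = prior,
                 residual_error = residual_error,
                 chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 seed = seed),
            class = "mixing_model_spec")
}

softmax_full <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0), 0))
  e / sum(e)
}

# split-chain potential-scale-reduction factor for one scalar quantity
split_rhat <- function(draw_list) {
  halves <- unlist(lapply(draw_list, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the stable-isotope mixing model by MCMC
#'
#' Random-walk Metropolis on the softmax-transformed proportion simplex
#' (last coordinate pinned at zero) plus, when the residual-error model is
#' on, the log residual SD of each tracer. The proposal scale adapts only
#' during burn-in. Runs `spec$chains` independent chains from over-dispersed
#' starts; convergence is summarized by split-chain R-hat per source
#' proportion, with a warning above 1.1. A warning is also raised when the
#' consumer centroid falls outside the convex hull of the TEF-shifted source
#' means (the classic non-closing mixing-polygon geometry problem).
#'
#' @param spec a [mixing_model_spec()].
#' @return A `mix_result`: `sources` data frame (`source`, `mean`,
#'   `ci_low`, `ci_high` — central 95% interval), `diagnostics` (acceptance
#'   rate, max R-hat, chain/iteration settings, residual-SD posterior
#'   means), and `draws`, the retained posterior proportion draws (each row
#'   sums to 1).
#' @export
fit_mixing_model <- function(spec) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  src <- spec$sources
  K <- nrow(src)
  x <- cbind(spec$consumers$d13C, spec$consumers$d15N)
  n <- nrow(x)
  xbar <- colMeans(x)
  SS <- colSums(sweep(x, 2, xbar)^2)
  mu <- cbind(src$d13C_mean + src$tef_d13C_mean, src$d15N_mean + src$tef_d15N_mean)
  vsrc <- cbind(src$d13C_sd^2 + src$tef_d13C_sd^2, src$d15N_sd^2 + src$tef_d15N_sd^2)

  check_mixing_geometry(mu, xbar, K)

  if (K == 1L) {
    return(structure(list(
      sources = data.frame(source = src$source, mean = 1, ci_low = 1, ci_high = 1),
      diagnostics = list(acceptance = NA_real_, rhat_max = 1,
                         chains = 0L, iter = 0L, burn = 0L, thin = 1L,
                         residual_sd = c(d13C = NA_real_, d15N = NA_real_)),
      draws = matrix(1, 1, 1, dimnames = list(NULL, src$source))),
      class = "mix_result"))
  }

  J <- 2L
  use_sigma <- isTRUE(spec$residual_error)
  np <- (K - 1L) + if (use_sigma) J else 0L
  prior <- spec$prior

  log_post <- function(theta) {
    z <- theta[seq_len(K - 1L)]
    p <- softmax_full(z)
    sig2 <- if (use_sigma) exp(2 * theta[K:(K + 1L)]) else c(0, 0)
    m <- as.numeric(crossprod(p, mu))
    v <- as.numeric(crossprod(p^2, vsrc)) + sig2
    if (any(v <= 0)) return(-Inf)
    ll <- -0.5 * sum(n * log(2 * pi * v) + (SS + n * (xbar - m)^2) / v)
    lp <- sum(prior * log(p))                       # Dirichlet + softmax Jacobian
    if (use_sigma) {
      sig <- sqrt(sig2)
      lp <- lp + sum(-sig2 / (2 * 4) + log(sig))    # half-Normal(0,2) + log Jacobian
    }
    ll + lp
  }

  keep_iters <- seq(spec$burn + spec$thin, spec$iter, by = spec$thin)
  p_draws <- vector("list", spec$chains)
  sig_draws <- vector("list", spec$chains)
  acc_total <- 0L

  for (ch in seq_len(spec$chains)) {
    with_seed(child_seed(spec$seed, ch), {
      theta <- c(stats::rnorm(K - 1L, 0, 1.5),
                 if (use_sigma) stats::rnorm(J, log(1), 0.5))
      lp_cur <- log_post(theta)
      scale <- 0.4
      P <- matrix(NA_real_, length(keep_iters), K)
      Sg <- matrix(NA_real_, length(keep_iters), J)
      kept <- 0L
      acc_win <- 0L
      for (t in seq_len(spec$iter)) {
        prop <- theta + stats::rnorm(np, 0, scale)
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
          theta <- prop; lp_cur <- lp_prop
          acc_win <- acc_win + 1L
          if (t > spec$burn) acc_total <- acc_total + 1L
        }
        if (t <= spec$burn && t %% 100L == 0L) {
          # Robbins-Monro step toward ~30% acceptance; frozen after burn-in
          scale <- scale * exp((acc_win / 100 - 0.3))
          acc_win <- 0L
        }
        if (t > spec$burn && (t - spec$burn) %% spec$thin == 0L) {
          kept <- kept + 1L
          P[kept, ] <- softmax_full(theta[seq_len(K - 1L)])
          if (use_sigma) Sg[kept, ] <- exp(theta[K:(K + 1L)])
        }
      }
      p_draws[[ch]] <- P
      sig_draws[[ch]] <- Sg
    })
  }

  draws <- do.call(rbind, p_draws)
  colnames(draws) <- src$source
  rhat <- vapply(seq_len(K), function(k) {
    split_rhat(lapply(p_draws, function(P) P[, k]))
  }, 0)
  rhat_max <- max(rhat, na.rm = TRUE)
  if (is.finite(rhat_max) && rhat_max > 1.1) {
    warning(sprintf("possible non-convergence: max split R-hat = %.3f", rhat_max),
            call. = FALSE)
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  res_sd <- if (use_sigma) {
    colMeans(do.call(rbind, sig_draws))
  } else c(0, 0)
  structure(list(
    sources = data.frame(source = src$source, mean = colMeans(draws),
                         ci_low = qs[1, ], ci_high = qs[2, ],
                         row.names = NULL),
    diagnostics = list(
      acceptance = acc_total / (spec$chains * (spec$iter - spec$burn)),
      rhat = stats::setNames(rhat, src$source), rhat_max = rhat_max,
      chains = spec$chains, iter = spec$iter, burn = spec$burn,
      thin = spec$thin,
      residual_sd = stats::setNames(res_sd, c("d13C", "d15N"))),
    draws = draws),
    class = "mix_result")
}

check_mixing_geometry <- function(mu, xbar, K) {
  if (K >= 3L) {
    h0 <- sort(grDevices::chull(mu))
    h1 <- sort(grDevices::chull(rbind(mu, xbar)))
    if ((K + 1L) %in% h1 || !identical(h0, setdiff(h1, K + 1L))) {
      warning("consumer centroid lies outside the TEF-shifted source polygon; ",
              "proportions may be poorly identified", call. = FALSE)
    }
  } else if (K == 2L) {
    lo <- pmin(mu[1, ], mu[2, ]); hi <- pmax(mu[1, ], mu[2, ])
    if (any(xbar < lo - 1e-9) || any(xbar > hi + 1e-9)) {
      warning("consumer centroid lies outside the segment between the two ",
              "TEF-shifted sources", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Prior-predictive check for a mixing model
#'
#' Draws source proportions from the Dirichlet prior (and residual SDs from
#' their half-Normal prior when enabled), pushes them through the mixing
#' likelihood's mean/variance, and simulates one consumer per draw. Useful
#' to overlay on the observed tracer cloud before fitting.
#'
#' @param spec a [mixing_model_spec()].
#' @param ndraws number of prior draws.
#' @return List with `draws` (simulated consumer values, columns d13C/d15N),
#'   `p` (the prior proportion draws) and `summary` (per-tracer mean and SD).
#' @export
prior_predictive <- function(spec, ndraws = 1000L) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  src <- spec$sources
  K <- nrow(src)
  mu <- cbind(src$d13C_mean + src$tef_d13C_mean, src$d15N_mean + src$tef_d15N_mean)
  vsrc <- cbind(src$d13C_sd^2 + src$tef_d13C_sd^2, src$d15N_sd^2 + src$tef_d15N_sd^2)
  with_seed(child_seed(spec$seed, 997L), {
    P <- t(vapply(seq_len(ndraws), function(i) rdirichlet1(spec$prior),
                  numeric(K)))
    sig <- if (spec$residual_error) {
      matrix(abs(stats::rnorm(2L * ndraws, 0, 2)), ndraws, 2L)
    } else matrix(0, ndraws, 2L)
    m <- P %*% mu
    v <- (P^2) %*% vsrc + sig^2
    y <- matrix(stats::rnorm(2L * ndraws, m, sqrt(v)), ndraws, 2L)
    colnames(y) <- c("d13C", "d15N")
    list(draws = y, p = P,
         summary = list(mean = colMeans(y), sd = apply(y, 2, stats::sd)))
  })
}
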