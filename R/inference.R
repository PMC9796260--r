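log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
  out
}

#' Normal-inverse-Wishart prior for the population ability distribution
#'
#' Weakly informative defaults: mu0 = 0, kappa0 = 1, nu0 = M + 2, S0 = I.
#'
#' @param M Number of dimensions.
#' @param mu0,kappa0,nu0,S0 Prior hyperparameters.
#' @return List of class `niw_prior`.
#' @export
niw_prior <- function(M, mu0 = rep(0, M), kappa0 = 1, nu0 = M + 2,
                      S0 = diag(M)) {
  if (min(eigen(S0, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("prior scale matrix must be positive definite")
  }
  structure(list(mu0 = mu0, kappa0 = kappa0, nu0 = nu0, S0 = S0),
            class = "niw_prior")
}

#' MCMC control settings
#'
#' @param iter Total iterations.
#' @param burnin Burn-in iterations (discarded; random-walk scales adapt
#'   towards a 0.44 acceptance rate during this phase only).
#' @param scale Initial random-walk SD.
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(iter = 2000L, burnin = 500L, scale = 0.5) {
  list(iter = as.integer(iter), burnin = as.integer(burnin), scale = scale)
}

#' Estimate the population ability distribution from urnings
#'
#' Treats each learner's urnings as independent Binomial(n_m,
#' logistic(theta_m)) observations of a latent ability vector theta_i
#' drawn from MVN(mu, Sigma), and samples the posterior of (mu, Sigma)
#' under a normal-inverse-Wishart prior by Metropolis-within-Gibbs:
#' per-dimension random-walk updates of the latent abilities alternate
#' with conjugate draws of (mu, Sigma). The small negative dependence
#' among urnings induced by sum conservation is ignored (the binomial
#' variance is an upper bound).
#'
#' @param r N x M matrix of learner urnings at one timepoint.
#' @param n Urn sizes: scalar or N x M matrix.
#' @param prior A [niw_prior()].
#' @param control A [mcmc_control()].
#' @return Object of class `population_estimate`: posterior draws of `mu`
#'   (draws x M) and `Sigma` (M x M x draws), summaries (`mu_mean`,
#'   `mu_ci`, `sd_mean`, `cor_mean`), acceptance rate and split-Rhat of mu.
#' @export
estimate_population <- function(r, n, prior = NULL, control = mcmc_control()) {
  r <- as.matrix(r)
  N <- nrow(r); M <- ncol(r)
  if (N < 2L) stop("need at least two learners")
  if (length(n) == 1L) n <- matrix(n, N, M)
  if (is.null(prior)) prior <- niw_prior(M)

  theta <- logit((r + 0.5) / (n + 1))
  mu <- colMeans(theta)
  Sigma <- stats::cov(theta) + diag(1e-3, M)
  scales <- rep(control$scale, M)
  acc <- numeric(M)
  n_keep <- control$iter - control$burnin
  mu_draws <- matrix(NA_real_, n_keep, M)
  Sigma_draws <- array(NA_real_, c(M, M, n_keep))
  adapt_batch <- 50L
  batch_acc <- numeric(M)

  for (it in seq_len(control$iter)) {
    Lam <- chol2inv(chol(Sigma))
    for (m in seq_len(M)) {
      cv <- 1 / Lam[m, m]
      if (M > 1) {
        dev <- sweep(theta[, -m, drop = FALSE], 2, mu[-m])
        cm <- mu[m] - cv * drop(dev %*% Lam[-m, m])
      } else {
        cm <- rep(mu[m], N)
      }
      prop <- theta[, m] + scales[m] * stats::rnorm(N)
      lr_ <- r[, m] * (prop - theta[, m]) -
        n[, m] * (log1pexp(prop) - log1pexp(theta[, m])) -
        0.5 * ((prop - cm)^2 - (theta[, m] - cm)^2) / cv
      ok <- log(stats::runif(N)) < lr_
      theta[ok, m] <- prop[ok]
      batch_acc[m] <- batch_acc[m] + mean(ok)
      if (it > control$burnin) acc[m] <- acc[m] + mean(ok)
    }
    if (it <= control$burnin && it %% adapt_batch == 0L) {
      rate <- batch_acc / adapt_batch
      scales <- pmin(5, pmax(0.01, scales * exp(rate - 0.44)))
      batch_acc[] <- 0
    } else if (it %% adapt_batch == 0L) batch_acc[] <- 0

    tbar <- colMeans(theta)
    S <- crossprod(sweep(theta, 2, tbar))
    kn <- prior$kappa0 + N
    nun <- prior$nu0 + N
    mun <- (prior$kappa0 * prior$mu0 + N * tbar) / kn
    d0 <- tbar - prior$mu0
    Sn <- prior$S0 + S + (prior$kappa0 * N / kn) * tcrossprod(d0)
    Sigma <- chol2inv(chol(stats::rWishart(1, nun, chol2inv(chol(Sn)))[, , 1]))
    mu <- drop(MASS::mvrnorm(1, mun, Sigma / kn))

    if (it > control$burnin) {
      mu_draws[it - control$burnin, ] <- mu
      Sigma_draws[, , it - control$burnin] <- Sigma
    }
  }

  sds <- t(apply(Sigma_draws, 3, function(S) sqrt(diag(S))))
  cors <- apply(Sigma_draws, 3, function(S) stats::cov2cor(S)[upper.tri(S)])
  cor_mean <- if (M > 1) {
    cm <- diag(1, M)
    cm[upper.tri(cm)] <- rowMeans(matrix(cors, ncol = n_keep))
    cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
    cm
  } else matrix(1, 1, 1)

  rhat <- split_rhat(mu_draws)
  if (any(rhat > 1.1)) {
    warning("population sampler may not have converged (split-Rhat > 1.1 for mu)")
  }
  structure(list(mu = mu_draws, Sigma = Sigma_draws,
                 mu_mean = colMeans(mu_draws),
                 mu_ci = apply(mu_draws, 2, stats::quantile, c(0.025, 0.975)),
                 sd_mean = colMeans(sds), cor_mean = cor_mean,
                 accept_rate = acc / n_keep, rhat = rhat,
                 scales = scales),
            class = "population_estimate")
}

split_rhat <- function(draws) {
  apply(draws, 2, function(x) {
    k <- floor(length(x) / 2)
    a <- x[seq_len(k)]; b <- x[k + seq_len(k)]
    W <- (stats::var(a) + stats::var(b)) / 2
    B <- k * (mean(a) - mean(b))^2 / 2  # between-variance of the two half-chains
    vhat <- (k - 1) / k * W + B / k
    if (W <= 0) return(1)
    sqrt(vhat / W)
  })
}

#' Posterior of one learner's ability vector
#'
#' Samples f(theta_i | R_i1..R_iM, mu, Sigma) -- binomial urning likelihood
#' with a multivariate normal population prior -- by the same per-dimension
#' random-walk Metropolis step used inside [estimate_population()].
#' Pooling towards the population mean makes these estimates differ from
#' the raw R/n, and the intervals are narrower than single-urning
#' intervals because the other dimensions and the population distribution
#' contribute information.
#'
#' @param r_i Integer M-vector of the learner's urnings.
#' @param n_i Urn sizes (scalar or M-vector).
#' @param mu,Sigma Population parameters (e.g. posterior means).
#' @param control A [mcmc_control()].
#' @return List with `draws` (draws x M), `mean`, `ci` (2 x M).
#' @export
individual_posterior <- function(r_i, n_i, mu, Sigma, control = mcmc_control()) {
  M <- length(r_i)
  if (length(n_i) == 1L) n_i <- rep(n_i, M)
  Lam <- chol2inv(chol(as.matrix(Sigma)))
  theta <- logit((r_i + 0.5) / (n_i + 1))
  scales <- rep(control$scale, M)
  n_keep <- control$iter - control$burnin
  draws <- matrix(NA_real_, n_keep, M)
  batch_acc <- numeric(M)
  for (it in seq_len(control$iter)) {
    for (m in seq_len(M)) {
      cv <- 1 / Lam[m, m]
      cm <- if (M > 1) mu[m] - cv * sum(Lam[-m, m] * (theta[-m] - mu[-m])) else mu[m]
      prop <- theta[m] + scales[m] * stats::rnorm(1)
      lr_ <- r_i[m] * (prop - theta[m]) - n_i[m] * (log1pexp(prop) - log1pexp(theta[m])) -
        0.5 * ((prop - cm)^2 - (theta[m] - cm)^2) / cv
      if (log(stats::runif(1)) < lr_) {
        theta[m] <- prop
        batch_acc[m] <- batch_acc[m] + 1
      }
    }
    if (it <= control$burnin && it %% 50L == 0L) {
      scales <- pmin(5, pmax(0.01, scales * exp(batch_acc / 50 - 0.44)))
      batch_acc[] <- 0
    }
    if (it > control$burnin) draws[it - control$burnin, ] <- theta
  }
  list(draws = draws, mean = colMeans(draws),
       ci = apply(draws, 2, stats::quantile, c(0.025, 0.975)))
}

#' Clopper-Pearson interval for a single urning
#'
#' Exact (conservative) confidence interval for pi = logistic(theta) based
#' on one urning R out of n.
#'
#' @param r Urning (0..n).
#' @param n Urn size.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)` on the probability scale.
#' @export
urning_interval <- function(r, n, level = 0.95) {
  if (r < 0 || r > n) stop("urning outside [0, n]")
  a <- (1 - level) / 2
  lower <- if (r == 0) 0 else stats::qbeta(a, r, n - r + 1)
  upper <- if (r == n) 1 else stats::qbeta(1 - a, r + 1, n - r)
  c(lower = lower, upper = upper)
}
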