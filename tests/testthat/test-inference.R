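test_that("single-urning intervals are exact Clopper-Pearson with correct bounds", {
  expect_equal(urning_interval(15, 15)[["upper"]], 1)
  expect_equal(urning_interval(0, 15)[["lower"]], 0)
  ci <- urning_interval(9, 15)
  bt <- stats::binom.test(9, 15)$conf.int
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-9)
  # exact coverage at n=15, pi=0.6 (summing over the binomial) is conservative
  cover <- sum(vapply(0:15, function(r) {
    ci <- urning_interval(r, 15)
    stats::dbinom(r, 15, 0.6) * (ci[1] <= 0.6 && 0.6 <= ci[2])
  }, numeric(1)))
  expect_gte(cover, 0.95)
})

test_that("individual posterior matches a quadrature oracle for M = 1", {
  set.seed(415)
  post <- individual_posterior(11, 15, mu = 0.3, Sigma = matrix(1.2, 1, 1),
                               control = mcmc_control(60000, 5000))
  grid <- oracle_posterior_grid(11, 15, 0.3, sqrt(1.2))
  # compare binned draws with the quadrature density
  br <- seq(-8, 8, by = 0.25)
  emp <- hist(post$draws[, 1], breaks = br, plot = FALSE)$counts
  emp <- emp / sum(emp)
  theo <- vapply(seq_len(length(br) - 1), function(k) {
    sum(grid$dens[grid$theta >= br[k] & grid$theta < br[k + 1]])
  }, numeric(1))
  expect_lt(0.5 * sum(abs(emp - theo)), 0.02)
  # posterior mean between the urn estimate and the population mean (shrinkage)
  raw <- logit((11 + 0.5) / 16)
  expect_true(post$mean > min(raw, 0.3) && post$mean < max(raw, 0.3))
})

test_that("with a diagonal covariance each dimension's posterior ignores the others", {
  set.seed(416)
  Sig <- diag(c(1, 2, 0.5))
  a <- individual_posterior(c(8, 2, 14), 15, mu = c(0, 0, 0), Sigma = Sig,
                            control = mcmc_control(4000, 1000))
  set.seed(416)
  b <- individual_posterior(c(8, 14, 2), 15, mu = c(0, 0, 0), Sigma = Sig,
                            control = mcmc_control(4000, 1000))
  # permuting the other dimensions' urnings cannot move dimension 1
  expect_equal(a$draws[, 1], b$draws[, 1])
})

test_that("shrinkage pulls posterior means toward the population mean", {
  set.seed(417)
  for (k in 1:20) {
    n <- sample(c(10, 20, 45), 1)
    r <- sample(0:n, 1)
    mu <- stats::rnorm(1)
    post <- individual_posterior(r, n, mu = mu, Sigma = matrix(1, 1, 1),
                                 control = mcmc_control(3000, 500))
    raw <- logit((r + 0.5) / (n + 1))
    expect_true(post$mean >= min(raw, mu) - 0.15 && post$mean <= max(raw, mu) + 0.15)
  }
})

test_that("population sampler is symmetric and matches strong data", {
  set.seed(418)
  # all urns half full: posterior mean of mu concentrates at zero
  r <- matrix(10L, 150, 1)
  est <- estimate_population(r, 20, control = mcmc_control(1500, 400))
  expect_lt(abs(est$mu_mean), 0.1)

  # informative urnings: posterior tracks the sample moments of the truth
  M <- 2
  Sig <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  th <- MASS::mvrnorm(400, c(0.3, -0.2), Sig)
  r <- matrix(stats::rbinom(400 * M, 500, logistic(th)), 400, M)
  est <- estimate_population(r, 500, control = mcmc_control(1500, 400))
  expect_equal(est$mu_mean, colMeans(th), tolerance = 0.07)
  expect_equal(est$cor_mean[1, 2], stats::cor(th)[1, 2], tolerance = 0.05)
  expect_equal(est$sd_mean, apply(th, 2, stats::sd), tolerance = 0.07)
})

test_that("a tight covariance prior dominates while the mean is still recovered", {
  set.seed(419)
  M <- 2
  Sig0 <- diag(2)
  th <- MASS::mvrnorm(200, c(0.5, 0.5), Sig0)
  r <- matrix(stats::rbinom(200 * M, 45, logistic(th)), 200, M)
  prior <- niw_prior(M, nu0 = 1e5, S0 = Sig0 * (1e5 - M - 1))
  est <- estimate_population(r, 45, prior = prior, control = mcmc_control(1200, 300))
  expect_equal(est$sd_mean, c(1, 1), tolerance = 0.02)
  expect_equal(abs(est$cor_mean[1, 2]), 0, tolerance = 0.02)
  expect_equal(est$mu_mean, c(0.5, 0.5), tolerance = 0.25)
  expect_error(niw_prior(2, S0 = matrix(c(1, 2, 2, 1), 2, 2)), "positive definite")
})

test_that("credible intervals narrow with urn size and beat single-urning intervals", {
  set.seed(420)
  Sig <- diag(2) * 0.8 + 0.2
  th <- MASS::mvrnorm(60, c(0, 0), Sig)
  widths <- sapply(c(5, 45), function(n) {
    mean(vapply(seq_len(60), function(i) {
      r <- stats::rbinom(2, n, logistic(th[i, ]))
      post <- individual_posterior(r, n, c(0, 0), Sig,
                                   control = mcmc_control(1200, 300))
      mean(post$ci[2, ] - post$ci[1, ])
    }, numeric(1)))
  })
  expect_lt(widths[2], widths[1])

  # Bayesian interval narrower on average than the logit-mapped exact interval
  n <- 15
  w_bayes <- w_freq <- numeric(40)
  for (i in 1:40) {
    r <- stats::rbinom(2, n, logistic(th[i, ]))
    post <- individual_posterior(r, n, c(0, 0), Sig,
                                 control = mcmc_control(1200, 300))
    w_bayes[i] <- post$ci[2, 1] - post$ci[1, 1]
    ci <- urning_interval(r[1], n)
    ci <- pmin(pmax(ci, 1e-4), 1 - 1e-4)
    w_freq[i] <- logit(ci[["upper"]]) - logit(ci[["lower"]])
  }
  expect_lt(mean(w_bayes), mean(w_freq))
})
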