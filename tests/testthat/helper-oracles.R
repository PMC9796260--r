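# Independent oracles, kept deliberately separate from the implementation:
# hypergeometric pmfs from stats::dhyper, literal rejection sampling, and
# direct enumeration of invariant distributions.

# Probability that Step 2 ends learner-green, from the without-replacement
# sampling process: condition the one-round outcome probabilities (product
# of hypergeometric pmfs) on the stopping event.
oracle_green_prob <- function(r_star, r_star_j, n_learner, n_item, w) {
  W <- sum(w)
  p_a <- stats::dhyper(0, r_star_j, n_item + W - r_star_j, W)
  p_b <- stats::dhyper(W, r_star_j, n_item + W - r_star_j, W)
  for (m in seq_along(w)) {
    if (w[m] == 0) next
    p_a <- p_a * stats::dhyper(w[m], r_star[m], n_learner[m] + w[m] - r_star[m], w[m])
    p_b <- p_b * stats::dhyper(0, r_star[m], n_learner[m] + w[m] - r_star[m], w[m])
  }
  if (p_a == 0 && p_b == 0) return(NA_real_)
  p_a / (p_a + p_b)
}

# Literal repeat-until response process on infinite urns.
oracle_sample_response <- function(pi_learner, pi_item, w) {
  W <- sum(w)
  repeat {
    y <- sum(stats::rbinom(length(w), w, pi_learner))
    yj <- stats::rbinom(1, W, pi_item)
    if (y == W && yj == 0) return(1L)
    if (y == 0 && yj == W) return(0L)
  }
}

# Enumerate the conditional product-binomial invariant distribution of a
# single learner-item pair given the conserved totals implied by the
# starting state. Returns data.frame over reachable item urnings.
oracle_pair_invariant <- function(n_learner, n_item, w, pi_learner, pi_item,
                                  r0, r0_j) {
  W <- sum(w)
  rj <- seq(0, n_item, by = W)
  keep <- rep(TRUE, length(rj))
  prob <- stats::dbinom(rj, n_item, pi_item)
  rmat <- matrix(NA_integer_, length(rj), length(w))
  for (m in seq_along(w)) {
    shift <- (w[m] / W) * (r0_j - rj)
    rm <- r0[m] + shift
    ok <- abs(rm - round(rm)) < 1e-9 & rm >= 0 & rm <= n_learner[m]
    keep <- keep & ok
    rm <- round(rm)
    prob <- prob * ifelse(ok, stats::dbinom(rm, n_learner[m], pi_learner[m]), 0)
    rmat[, m] <- as.integer(rm)
  }
  data.frame(r_j = rj[keep], prob = prob[keep] / sum(prob[keep]),
             r = I(rmat[keep, , drop = FALSE]))
}

# Grid-quadrature posterior density for one urning with a normal prior
# (M = 1 oracle for the individual-ability sampler).
oracle_posterior_grid <- function(r, n, mu, sigma, grid = seq(-8, 8, by = 0.01)) {
  logd <- r * grid - n * log1p(exp(-abs(grid))) - n * pmax(grid, 0) +
    stats::dnorm(grid, mu, sigma, log = TRUE)
  # r*theta - n*log(1+exp(theta)) computed stably
  d <- exp(logd - max(logd))
  data.frame(theta = grid, dens = d / sum(d))
}

make_item <- function(w, n, r, id = 1L) item_state(w, n, r, item_id = id)
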