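#' Numerically safe logistic and logit
#'
#' `logistic()` maps the logit scale to probabilities without overflow for
#' |x| up to ~700; `logit()` is its inverse.
#'
#' @param x Numeric vector (logit scale for `logistic`, probabilities in
#'   (0,1) for `logit`).
#' @return Numeric vector of the same length.
#' @export
logistic <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  attributes(out) <- attributes(x)
  out
}

#' @rdname logistic
#' @export
logit <- function(x) log(x) - log1p(-x)

#' Validate an integer weight vector
#'
#' An item's weight vector holds one non-negative integer per ability
#' dimension; at least one weight must be positive. The total weight W is
#' the number of balls drawn from the item's urn in one update.
#'
#' @param w Non-negative integer vector, length M.
#' @return Object of class `weight_vector`: list with `w` (integer vector)
#'   and `W` (total weight).
#' @export
weight_vector <- function(w) {
  if (length(w) < 1L || anyNA(w) || !is.numeric(w)) {
    stop("weights must be a non-empty numeric vector without NAs")
  }
  if (any(w < 0) || any(w != round(w))) {
    stop("weights must be non-negative integers")
  }
  if (all(w == 0)) {
    stop("invalid weights: all-zero weight vector")
  }
  w <- as.integer(round(w))
  structure(list(w = w, W = sum(w)), class = "weight_vector")
}

as_weights <- function(w) {
  if (inherits(w, "weight_vector")) w else weight_vector(w)
}

#' Probability of a correct response under the compensatory model
#'
#' The probability that a learner with abilities `theta` answers an item
#' with difficulty `delta` and integer weights `w` correctly:
#' logistic(sum_m w_m theta_m - delta). Equivalent to the urn-ratio form
#' in terms of pi = logistic(theta), pi_j = logistic(delta).
#'
#' @param theta Numeric M-vector of abilities on the logit scale.
#' @param delta Item difficulty on the logit scale (scalar).
#' @param w Weight vector (integer vector or `weight_vector`).
#' @return Probability in (0,1).
#' @export
prob_correct <- function(theta, delta, w) {
  w <- as_weights(w)
  if (length(theta) != length(w$w)) {
    stop("theta and weights must have the same length")
  }
  if (!all(is.finite(theta)) || !is.finite(delta)) stop("inputs must be finite")
  logistic(sum(w$w * theta) - delta)
}

#' Urn-ratio form of the response probability
#'
#' The probability of a correct response expressed through the urn
#' proportions: prod_m pi_m^w_m (1-pi_j)^W /
#' [prod_m pi_m^w_m (1-pi_j)^W + pi_j^W prod_m (1-pi_m)^w_m].
#' Identical to [prob_correct()] under pi_m = logistic(theta_m) and
#' pi_j = logistic(delta_j / W): the item urn proportion lives on the
#' difficulty scale divided by the total weight, which is what the item
#' urning R_j/n_j estimates.
#'
#' @param pi_learner M-vector of learner urn proportions in (0,1).
#' @param pi_item Item urn proportion in (0,1).
#' @param w Weight vector.
#' @return Probability in (0,1).
#' @export
prob_correct_urn <- function(pi_learner, pi_item, w) {
  w <- as_weights(w)
  if (any(pi_learner <= 0) || any(pi_learner >= 1) || pi_item <= 0 || pi_item >= 1) {
    stop("probabilities must be strictly inside (0,1)")
  }
  a <- prod(pi_learner^w$w) * (1 - pi_item)^w$W
  b <- pi_item^w$W * prod((1 - pi_learner)^w$w)
  a / (a + b)
}

#' Sample a binary response
#'
#' Draws a Bernoulli response with the closed-form success probability
#' [prob_correct_urn()], given urn proportions. Distributionally
#' equivalent to the repeat-until urn process in which w_m balls are drawn
#' from each learner urn and W from the item urn until the learner's balls
#' share one colour different from all the item's balls.
#'
#' @param pi_learner M-vector of learner urn proportions in (0,1).
#' @param pi_item Item urn proportion in (0,1).
#' @param w Weight vector.
#' @return 0 or 1.
#' @export
sample_response <- function(pi_learner, pi_item, w) {
  p <- prob_correct_urn(pi_learner, pi_item, w)
  as.integer(stats::runif(1L) < p)
}
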