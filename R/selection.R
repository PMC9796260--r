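#' Item selection probabilities
#'
#' Adaptive mode weights each candidate proportionally to the expected
#' variance of its score, p(1-p), where p is the model probability of a
#' correct response evaluated at smoothed urn proportions
#' pi-hat = (R+1)/(n+2) for both the learner and the item; the smoothing
#' keeps urns pegged at 0 or n selectable so the Metropolis ratio below is
#' always defined. Random mode is uniform.
#'
#' @param learner A `learner_state`.
#' @param items Non-empty list of `item_state` candidates.
#' @param mode "adaptive" or "random".
#' @return Probability vector over the candidates (sums to 1).
#' @export
selection_probabilities <- function(learner, items, mode = c("adaptive", "random")) {
  mode <- match.arg(mode)
  if (length(items) == 0L) stop("empty candidate set")
  if (mode == "random") return(rep(1 / length(items), length(items)))
  theta_hat <- logit((learner$urnings + 1) / (learner$urn_sizes + 2))
  v <- vapply(items, function(it) {
    # the item urn proportion estimates logistic(delta / W)
    delta_hat <- it$weights$W * logit((it$urning + 1) / (it$urn_size + 2))
    p <- logistic(sum(it$weights$w * theta_hat) - delta_hat)
    p * (1 - p)
  }, numeric(1))
  v / sum(v)
}

#' Build a selection context for [update_pair()]
#'
#' @param items Candidate item list.
#' @param j Index of the administered item within `items`.
#' @param mode Selection mode used to pick the item.
#' @return List consumed by [update_pair()].
#' @export
selection_context <- function(items, j, mode = c("adaptive", "random")) {
  mode <- match.arg(mode)
  if (j < 1L || j > length(items)) stop("item index outside candidate set")
  list(items = items, j = j, mode = mode)
}

#' Metropolis correction for adaptive item selection
#'
#' Adaptive selection matched to the learner's current rating inflates the
#' variance of the ratings; the proposed urnings are therefore accepted
#' with probability min(1, S_proposed / S_current), where S is the
#' selection probability of the administered item evaluated at the proposed
#' and current urnings respectively.
#'
#' @param s_current Selection probability at the current urnings (> 0).
#' @param s_proposed Selection probability at the proposed urnings.
#' @return Logical: accept the proposed urnings?
#' @export
adaptivity_correction <- function(s_current, s_proposed) {
  if (s_current <= 0) stop("selected item had zero selection probability")
  if (s_proposed >= s_current) return(TRUE)
  stats::runif(1L) < s_proposed / s_current
}
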