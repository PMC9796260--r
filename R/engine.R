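#' Learner state: one tracking urn per ability dimension
#'
#' @param urn_sizes Positive integer M-vector of urn sizes n_m.
#' @param urnings Integer M-vector of green-ball counts R_m, 0 <= R_m <= n_m.
#' @param learner_id Optional identifier.
#' @return Object of class `learner_state`.
#' @export
learner_state <- function(urn_sizes, urnings, learner_id = NA_integer_) {
  if (length(urn_sizes) != length(urnings)) {
    stop("urn_sizes and urnings must have the same length")
  }
  if (any(urn_sizes < 1) || any(urn_sizes != round(urn_sizes))) {
    stop("urn sizes must be positive integers")
  }
  if (any(urnings < 0) || any(urnings > urn_sizes) || any(urnings != round(urnings))) {
    stop("urnings must be integers in [0, urn size]")
  }
  structure(list(learner_id = learner_id,
                 urn_sizes = as.integer(urn_sizes),
                 urnings = as.integer(urnings)),
            class = "learner_state")
}

#' Item state: a single tracking urn plus an integer weight vector
#'
#' The item urning changes only in steps of 0 or +/- W, so it stays
#' divisible by W provided the initial value is; the urn size must be
#' divisible by W for the half-full symmetric initialization to exist.
#'
#' @param weights Integer weight vector (or `weight_vector`) over M dims.
#' @param urn_size Positive integer n_j, divisible by total weight W.
#' @param urning Integer R_j in [0, n_j], divisible by W.
#' @param item_id Optional identifier.
#' @return Object of class `item_state`; `reference_dimension` is the
#'   dimension index when exactly one weight is non-zero, else NA.
#' @export
item_state <- function(weights, urn_size, urning, item_id = NA_integer_) {
  w <- as_weights(weights)
  if (urn_size < 1 || urn_size != round(urn_size)) stop("urn size must be a positive integer")
  if (urn_size %% w$W != 0) {
    stop("item urn size must be divisible by the total weight W")
  }
  if (urning < 0 || urning > urn_size || urning != round(urning)) {
    stop("item urning must be an integer in [0, urn size]")
  }
  if (urning %% w$W != 0) {
    stop("item urning must be divisible by the total weight W")
  }
  nz <- which(w$w > 0)
  structure(list(item_id = item_id, weights = w,
                 urn_size = as.integer(urn_size), urning = as.integer(urning),
                 reference_dimension = if (length(nz) == 1L) nz else NA_integer_),
            class = "item_state")
}

#' Step 1 of the two-step update: add response-matching balls
#'
#' A correct response adds w_m green balls to each learner urn; an
#' incorrect response adds W red... i.e. W balls matching the item to the
#' item urn. Dimensions with zero weight are untouched.
#'
#' @param learner A `learner_state`.
#' @param item An `item_state`.
#' @param x Observed response, 0 or 1.
#' @return List with `r_star` (learner M-vector after Step 1) and
#'   `r_star_j` (item urning after Step 1).
#' @export
step1_add <- function(learner, item, x) {
  if (!x %in% c(0L, 1L)) stop("x must be 0 or 1")
  w <- item$weights
  list(r_star = learner$urnings + w$w * as.integer(x),
       r_star_j = item$urning + w$W * (1L - as.integer(x)))
}

green_branch_products <- function(r_star, r_star_j, n_learner, n_item, w) {
  W <- w$W
  p_a <- 1
  p_b <- 1
  for (m in seq_along(w$w)) {
    wm <- w$w[m]
    if (wm == 0L) next
    for (v in seq_len(wm) - 1L) {
      p_a <- p_a * max(r_star[m] - v, 0)
      p_b <- p_b * max(n_learner[m] + wm - r_star[m] - v, 0)
    }
  }
  for (v in seq_len(W) - 1L) {
    p_a <- p_a * max(n_item + W - r_star_j - v, 0)
    p_b <- p_b * max(r_star_j - v, 0)
  }
  c(p_a, p_b)
}

#' Probability that the learner's draw wins Step 2
#'
#' After Step 1 the learner urn m holds n_m + w_m balls with r*_m green and
#' the item urn holds n_j + W balls with r*_j green. Balls are drawn
#' without replacement (w_m per learner urn, W from the item urn) until
#' either all learner balls are green and all item balls red (learner
#' green, the urnings revert towards the learner) or the reverse. This
#' returns the probability of the first outcome,
#' P_A / (P_A + P_B), where P_A and P_B are the falling-factorial products
#' of the two exclusive outcomes; any non-positive factor marks a branch
#' impossible.
#'
#' @param r_star Learner urnings after Step 1 (M-vector).
#' @param r_star_j Item urning after Step 1.
#' @param n_learner Learner urn sizes (M-vector).
#' @param n_item Item urn size.
#' @param w Weight vector.
#' @return Probability in [0,1].
#' @export
learner_green_probability <- function(r_star, r_star_j, n_learner, n_item, w) {
  w <- as_weights(w)
  if (length(r_star) != length(w$w) || length(n_learner) != length(w$w)) {
    stop("r_star, n_learner and weights must have the same length")
  }
  if (any(r_star < 0) || any(r_star > n_learner + w$w) ||
      r_star_j < 0 || r_star_j > n_item + w$W) {
    stop("post-Step-1 urnings out of bounds")
  }
  p <- green_branch_products(r_star, r_star_j, n_learner, n_item, w)
  if (p[1] == 0 && p[2] == 0) {
    stop("degenerate configuration: both Step-2 outcomes impossible")
  }
  p[1] / (p[1] + p[2])
}

#' Step 2 of the two-step update: sample and remove balls
#'
#' Simulates the outcome of the without-replacement sampling process
#' directly from its conditional probability. On the learner-green outcome
#' w_m balls leave each learner urn; otherwise W balls leave the item urn.
#'
#' @param r_star,r_star_j Post-Step-1 urnings.
#' @param p_green Probability from [learner_green_probability()].
#' @param w Weight vector.
#' @return List with `r_new` (learner), `r_new_j` (item), `learner_green`.
#' @export
step2_sample <- function(r_star, r_star_j, p_green, w) {
  w <- as_weights(w)
  g <- stats::runif(1L) < p_green
  if (g) {
    list(r_new = r_star - w$w, r_new_j = r_star_j, learner_green = TRUE)
  } else {
    list(r_new = r_star, r_new_j = r_star_j - w$W, learner_green = FALSE)
  }
}

#' One full urnings update for a learner-item pair
#'
#' Runs Step 1 and Step 2, then (when a selection context is supplied) the
#' Metropolis correction for adaptive item selection; on rejection all
#' urnings revert to their pre-update values. When an anchoring queue is
#' supplied and the item belongs to a reference subset, the accepted item
#' change is routed through the queue (the learner change is always applied
#' immediately on acceptance).
#'
#' @param learner A `learner_state`.
#' @param item An `item_state`.
#' @param x Observed response 0/1.
#' @param selection Optional selection context: a list with elements
#'   `items` (list of `item_state` for the candidate set), `j` (index of
#'   `item` within it) and `mode` ("adaptive" or "random"); built by
#'   [selection_context()]. The correction is applied only for adaptive
#'   mode.
#' @param anchor Optional `reference_queue` for paired item updates.
#' @return List of class `update_outcome` with the response, post-Step-1
#'   values, sampled outcome, proposal, acceptance decision, updated
#'   `learner` and `item` states, and any paired queue applications.
#' @export
update_pair <- function(learner, item, x, selection = NULL, anchor = NULL) {
  if (length(learner$urnings) != length(item$weights$w)) {
    stop("learner dimensions and item weights are inconsistent")
  }
  w <- item$weights
  s1 <- step1_add(learner, item, x)
  p_green <- learner_green_probability(s1$r_star, s1$r_star_j,
                                       learner$urn_sizes, item$urn_size, w)
  s2 <- step2_sample(s1$r_star, s1$r_star_j, p_green, w)

  accepted <- TRUE
  if (!is.null(selection) && identical(selection$mode, "adaptive")) {
    prop_learner <- learner
    prop_learner$urnings <- s2$r_new
    prop_item <- item
    prop_item$urning <- s2$r_new_j
    items_prop <- selection$items
    items_prop[[selection$j]] <- prop_item
    s_cur <- selection_probabilities(learner, selection$items, mode = "adaptive")[selection$j]
    s_prop <- selection_probabilities(prop_learner, items_prop, mode = "adaptive")[selection$j]
    accepted <- adaptivity_correction(s_cur, s_prop)
  }

  applied_pairs <- NULL
  if (accepted) {
    new_learner <- learner
    new_learner$urnings <- as.integer(s2$r_new)
    delta_j <- s2$r_new_j - item$urning
    new_item <- item
    if (delta_j != 0L && !is.null(anchor) && !is.na(item$reference_dimension)) {
      applied_pairs <- route_item_update(item, delta_j, anchor)
      if (nrow(applied_pairs) > 0L) {
        self <- applied_pairs$item_id == item$item_id
        if (any(self)) new_item$urning <- new_item$urning + sum(applied_pairs$delta[self])
      }
    } else {
      new_item$urning <- as.integer(s2$r_new_j)
    }
  } else {
    new_learner <- learner
    new_item <- item
  }

  structure(list(x = as.integer(x),
                 r_star = as.integer(s1$r_star), r_star_j = as.integer(s1$r_star_j),
                 p_green = p_green, learner_green = s2$learner_green,
                 proposed = list(r = as.integer(s2$r_new), r_j = as.integer(s2$r_new_j)),
                 accepted = accepted,
                 learner = new_learner, item = new_item,
                 applied_pairs = applied_pairs),
            class = "update_outcome")
}

#' Legacy unidimensional update (sample-then-replace with acceptance step)
#'
#' The original algorithm for M = 1, w = 1: sample one ball from each
#' tracking urn with replacement until the colours differ, propose
#' replacing them with response-matching balls, and accept with probability
#' min(1, [R_i(n_j - R_j) + (n_i - R_i)R_j] /
#'         [R*_i(n_j - R*_j) + (n_i - R*_i)R*_j]).
#'
#' @param r_i,r_j Current urnings.
#' @param n_i,n_j Urn sizes.
#' @param x Observed response 0/1.
#' @return List with updated `r_i`, `r_j` and `accepted`.
#' @export
legacy_unidim_update <- function(r_i, r_j, n_i, n_j, x) {
  num_ig <- r_i * (n_j - r_j)           # learner ball green, item ball red
  num_ir <- (n_i - r_i) * r_j
  y_i <- as.integer(stats::runif(1L) < num_ig / (num_ig + num_ir))
  y_j <- 1L - y_i
  r_i_prop <- r_i - y_i + as.integer(x)
  r_j_prop <- r_j - y_j + (1L - as.integer(x))
  den <- r_i_prop * (n_j - r_j_prop) + (n_i - r_i_prop) * r_j_prop
  acc_p <- if (den == 0) 1 else min(1, (num_ig + num_ir) / den)
  accepted <- stats::runif(1L) < acc_p
  if (accepted) list(r_i = r_i_prop, r_j = r_j_prop, accepted = TRUE)
  else list(r_i = r_i, r_j = r_j, accepted = FALSE)
}
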