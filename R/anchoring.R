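#' Reference-subset anchoring queue
#'
#' Items loading on exactly one dimension form that dimension's reference
#' subset; their urning sum is held constant so the scale has a fixed
#' reference point over time. A reference item's accepted update is applied
#' only paired with an opposite update of equal magnitude from a reference
#' item of the same dimension (possibly a pending request of the same item,
#' which then nets to zero); unmatched requests wait in a queue, and an
#' item may hold several pending requests. Queues are keyed by (dimension,
#' magnitude |delta|) so a +2 can only pair with a -2 and the subset sum
#' is conserved exactly.
#'
#' @param M Number of dimensions.
#' @return Mutable queue object (class `reference_queue`).
#' @export
reference_queue <- function(M) {
  e <- new.env(parent = emptyenv())
  e$M <- as.integer(M)
  e$up <- list()    # key -> integer vector of item ids awaiting +mag
  e$down <- list()  # key -> integer vector awaiting -mag
  class(e) <- "reference_queue"
  e
}

queue_key <- function(dim, mag) paste0("d", dim, "w", mag)

#' Route an accepted item update through the anchoring queue
#'
#' Non-reference items are applied immediately. For a reference item, if
#' the opposite-direction queue for the (dimension, magnitude) key holds
#' applicable entries, one is popped uniformly at random and both updates
#' are applied together (conserving the subset sum; popping the item's own
#' pending request nets to zero); otherwise the request is enqueued. The
#' learner side of the triggering update is never queued -- learners are
#' updated directly after the response.
#'
#' @param item An `item_state`.
#' @param delta Requested urning change, +/- W (non-zero).
#' @param queue A `reference_queue`.
#' @param partner_ok Optional predicate `function(item_id)`; a queued entry
#'   is only popped if this returns TRUE (used to re-validate urn bounds
#'   for entries that went stale while waiting).
#' @return data.frame with columns `item_id`, `delta` of the updates to
#'   apply now (possibly zero rows), with attribute `status` one of
#'   "applied", "paired", "queued".
#' @export
route_item_update <- function(item, delta, queue, partner_ok = NULL) {
  stopifnot(inherits(queue, "reference_queue"))
  if (delta == 0) stop("delta must be non-zero")
  with_status <- function(x, s) { attr(x, "status") <- s; x }
  if (is.na(item$reference_dimension)) {
    return(with_status(data.frame(item_id = item$item_id,
                                  delta = as.integer(delta)), "applied"))
  }
  mag <- abs(delta)
  key <- queue_key(item$reference_dimension, mag)
  same <- if (delta > 0) "up" else "down"
  opp <- if (delta > 0) "down" else "up"

  opp_ids <- queue[[opp]][[key]]
  usable <- if (is.null(partner_ok)) seq_along(opp_ids) else
    which(vapply(opp_ids, partner_ok, logical(1)))
  if (length(usable) > 0L) {
    pick <- usable[if (length(usable) == 1L) 1L else sample.int(length(usable), 1L)]
    partner <- opp_ids[pick]
    queue[[opp]][[key]] <- opp_ids[-pick]
    return(with_status(data.frame(item_id = c(item$item_id, partner),
                                  delta = c(as.integer(delta), -as.integer(delta))),
                       "paired"))
  }
  queue[[same]][[key]] <- c(queue[[same]][[key]], item$item_id)
  with_status(data.frame(item_id = integer(0), delta = integer(0)), "queued")
}

#' Pending queue entries
#'
#' @param queue A `reference_queue`.
#' @return data.frame with columns `key`, `direction`, `item_id`, `delta`
#'   (the signed magnitude still pending).
#' @export
queue_pending <- function(queue) {
  out <- list()
  for (dir in c("up", "down")) {
    for (key in names(queue[[dir]])) {
      ids <- queue[[dir]][[key]]
      if (length(ids) == 0L) next
      mag <- as.integer(sub(".*w", "", key))
      out[[length(out) + 1L]] <- data.frame(
        key = key, direction = dir, item_id = ids,
        delta = if (dir == "up") mag else -mag)
    }
  }
  if (length(out) == 0L) {
    data.frame(key = character(0), direction = character(0),
               item_id = integer(0), delta = integer(0))
  } else {
    do.call(rbind, out)
  }
}
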