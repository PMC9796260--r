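#' Read and validate an item bank file
#'
#' Comma-separated with header: `item_id`, weight columns `w1..wM`,
#' `urn_size`, `urning`. Weights must be non-negative integers, not all
#' zero; the urn size and the initial urning must be divisible by the
#' total weight W and the urning must lie in [0, urn size]. Violations
#' raise an error naming the offending record.
#'
#' @param path File path.
#' @return Item-bank list (`weights`, `W`, `ref_dim`, `urn_size`,
#'   `urning`, `item_id`) as used by the engine.
#' @export
read_item_bank <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0L) stop("empty item bank file: ", path)
  wcols <- grep("^w[0-9]+$", names(d), value = TRUE)
  need <- c("item_id", "urn_size", "urning")
  if (length(wcols) == 0L || !all(need %in% names(d))) {
    stop("item bank must have columns item_id, w1..wM, urn_size, urning")
  }
  weights <- as.matrix(d[wcols])
  storage.mode(weights) <- "integer"
  for (k in seq_len(nrow(d))) {
    w <- weights[k, ]
    if (any(w < 0) || all(w == 0)) {
      stop(sprintf("item bank row %d (item %s): invalid weights", k, d$item_id[k]))
    }
    W <- sum(w)
    if (d$urn_size[k] < 1 || d$urn_size[k] %% W != 0) {
      stop(sprintf("item bank row %d (item %s): urn size %d not divisible by W=%d",
                   k, d$item_id[k], d$urn_size[k], W))
    }
    if (d$urning[k] < 0 || d$urning[k] > d$urn_size[k] || d$urning[k] %% W != 0) {
      stop(sprintf("item bank row %d (item %s): urning %d invalid (bounds or divisibility by W=%d)",
                   k, d$item_id[k], d$urning[k], W))
    }
  }
  nz <- rowSums(weights > 0)
  list(item_id = d$item_id, weights = weights, W = as.integer(rowSums(weights)),
       ref_dim = ifelse(nz == 1L, max.col(weights > 0), NA_integer_),
       urn_size = as.integer(d$urn_size), urning = as.integer(d$urning))
}

#' Read and validate a learner table
#'
#' Columns: `learner_id`, `urn_size_1..M`, `urning_1..M`.
#'
#' @param path File path.
#' @return List with `learner_id`, `urn_sizes` (N x M), `urnings` (N x M).
#' @export
read_learners <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0L) stop("empty learner file: ", path)
  ncols <- grep("^urn_size_[0-9]+$", names(d), value = TRUE)
  rcols <- grep("^urning_[0-9]+$", names(d), value = TRUE)
  if (length(ncols) == 0L || length(ncols) != length(rcols)) {
    stop("learner table must have columns learner_id, urn_size_1..M, urning_1..M")
  }
  n <- as.matrix(d[ncols]); r <- as.matrix(d[rcols])
  storage.mode(n) <- "integer"; storage.mode(r) <- "integer"
  bad <- which(r < 0 | r > n, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("learner table row %d (learner %s): urning outside [0, urn size]",
                 bad[1, 1], d$learner_id[bad[1, 1]]))
  }
  list(learner_id = d$learner_id, urn_sizes = n, urnings = r)
}

#' Read an event log
#'
#' @param path File path (CSV written by [write_events()]).
#' @return data.frame in the [run_system()] event format.
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t", "learner", "item", "mode", "x", "learner_green", "accepted",
            "r_star_j", "partner")
  if (nrow(d) == 0L) stop("empty event log: ", path)
  if (!all(need %in% names(d))) {
    stop("event log missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  d
}

#' @rdname read_events
#' @param events Event data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write urning snapshots as delimited text
#'
#' Long format: `t`, `entity_type` ("learner"/"item"), `id`, `dimension`
#' (0 for items), `urning`, `urn_size`.
#'
#' @param run An `urnings_run`.
#' @param path Output file.
#' @export
write_snapshots <- function(run, path) {
  N <- dim(run$learner_urnings)[1]; M <- dim(run$learner_urnings)[2]
  Tn <- length(run$snapshot_t); J <- nrow(run$item_urnings)
  lt <- data.frame(
    t = rep(run$snapshot_t, each = N * M),
    entity_type = "learner",
    id = rep(rep(seq_len(N), M), Tn),
    dimension = rep(rep(seq_len(M), each = N), Tn),
    urning = as.vector(run$learner_urnings),
    urn_size = run$config$learner_urn_size)
  it <- data.frame(
    t = rep(run$snapshot_t, each = J),
    entity_type = "item",
    id = rep(seq_len(J), Tn),
    dimension = 0L,
    urning = as.vector(run$item_urnings),
    urn_size = run$config$item_urn_size)
  utils::write.csv(rbind(lt, it), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an item bank table
#'
#' @param bank Item bank list with current `urning` values.
#' @param path Output file.
#' @export
write_item_bank <- function(bank, path) {
  d <- data.frame(item_id = bank$item_id %||% seq_len(nrow(bank$weights)))
  for (m in seq_len(ncol(bank$weights))) d[[paste0("w", m)]] <- bank$weights[, m]
  d$urn_size <- bank$urn_size
  d$urning <- bank$urning
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministically replay a recorded event stream
#'
#' Applies the engine to an existing event log without regenerating
#' responses or redrawing any random quantity: the recorded response,
#' Step-2 outcome, acceptance decision and queue pairing are applied as
#' logged. Replaying the log of a [run_system()] call started from the
#' same initial urnings reproduces its final state exactly.
#'
#' @param events Event data.frame.
#' @param learner_urnings N x M matrix of initial learner urnings.
#' @param item_urnings Initial item urnings (length J).
#' @param bank Item bank (weights, reference dimensions).
#' @return List with final `learner_urnings`, `item_urnings` and the
#'   pending `queue` data.frame.
#' @export
replay_events <- function(events, learner_urnings, item_urnings, bank) {
  lr <- learner_urnings
  ir <- item_urnings
  q <- list()  # key -> item ids; key includes direction
  for (e in seq_len(nrow(events))) {
    if (!events$accepted[e]) next
    i <- events$learner[e]; j <- events$item[e]
    w <- bank$weights[j, ]; W <- bank$W[j]
    x <- events$x[e]; green <- events$learner_green[e] == 1L
    if (green) {
      lr[i, ] <- lr[i, ] + w * (x - 1L)
      dj <- W * (1L - x)
    } else {
      lr[i, ] <- lr[i, ] + w * x
      dj <- -W * x
    }
    if (dj == 0L) next
    p <- events$partner[e]
    if (p == -9L) {
      ir[j] <- ir[j] + dj
    } else if (p > 0L) {
      ir[j] <- ir[j] + dj
      ir[p] <- ir[p] - dj
      key <- paste0(bank$ref_dim[j], ":", abs(dj), ":", if (dj > 0) "down" else "up")
      idx <- match(p, q[[key]])          # remove one pending entry of the partner
      if (!is.na(idx)) q[[key]] <- q[[key]][-idx]
    } else if (p == 0L) {
      key <- paste0(bank$ref_dim[j], ":", abs(dj), ":", if (dj > 0) "up" else "down")
      q[[key]] <- c(q[[key]], j)
    }
  }
  pend <- data.frame(key = character(0), item_id = integer(0))
  for (key in names(q)) {
    if (length(q[[key]])) pend <- rbind(pend, data.frame(key = key, item_id = q[[key]]))
  }
  list(learner_urnings = lr, item_urnings = ir, queue = pend)
}
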