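#' Canonical item-type table
#'
#' The default bank mixes between-item and within-item multidimensionality
#' over three dimensions: 9 single-dimension types (weights 1, 2, 3 in each
#' dimension), 12 two-dimension types (each dimension pair with weight
#' pairs (1,1), (2,1), (1,2), (2,2)) and 4 three-dimension types ((1,1,1),
#' (2,1,1), (1,2,1), (1,1,2)) -- 25 types in total, every total weight W
#' dividing the default item urn size 204.
#'
#' @return data.frame with columns `w1`, `w2`, `w3`.
#' @export
item_type_table <- function() {
  single <- do.call(rbind, lapply(1:3, function(m) {
    t(vapply(1:3, function(v) { w <- c(0L, 0L, 0L); w[m] <- v; w }, integer(3)))
  }))
  pairs <- do.call(rbind, lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    t(vapply(list(c(1, 1), c(2, 1), c(1, 2), c(2, 2)), function(v) {
      w <- c(0L, 0L, 0L); w[pr] <- as.integer(v); w
    }, integer(3)))
  }))
  triple <- rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(1L, 2L, 1L), c(1L, 1L, 2L))
  out <- as.data.frame(rbind(single, pairs, triple))
  names(out) <- c("w1", "w2", "w3")
  out
}

#' Simulation configuration
#'
#' Defaults mirror the simulated adaptive learning system studied in the
#' methods vignette: three correlated dimensions, a 500-item bank of 25
#' item types (20 items each), item urn size 204, one randomly and the rest
#' adaptively selected items per learner per timepoint, the Metropolis
#' correction for adaptive selection, and reference-subset anchoring.
#'
#' @param num_learners Number of learners.
#' @param num_items Number of items (multiple of the number of types).
#' @param item_types data.frame of integer weight columns, one row per type.
#' @param learner_urn_size Urn size n for every learner dimension.
#' @param item_urn_size Item urn size (divisible by every W in the bank).
#' @param T Number of sessions/timepoints.
#' @param g_random,g_adaptive Items per learner per session by selection mode.
#' @param abilities List describing the ability distribution. Static:
#'   `list(type="static", mean=0, sd=1, cor=0.5)`. Dynamic:
#'   `list(type="dynamic", mu0=0, mu1=1, sd0=1, sd1=1.5, cor0=0.5, cor1=0.7)`
#'   -- linear parameter paths; the population is exactly multivariate
#'   normal on the logit scale at every timepoint with increasing means,
#'   SDs and correlations.
#' @param difficulties List: static `list(type="static")` (standard-normal
#'   quantile grid) or drifting `list(type="drift", frac_up=.25,
#'   frac_down=.25, magnitude=.5)` (linear drift, balanced within each
#'   reference subset; the quantile grid is attained at t = T/2).
#' @param correct_adaptivity Apply the Metropolis correction to adaptively
#'   selected interactions?
#' @param anchor Use reference-subset anchoring for item updates?
#' @param seed Optional integer seed applied by [run_system()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(num_learners = 200L, num_items = 500L,
                       item_types = item_type_table(),
                       learner_urn_size = 15L, item_urn_size = 204L,
                       T = 200L, g_random = 1L, g_adaptive = 14L,
                       abilities = list(type = "dynamic", mu0 = 0, mu1 = 1,
                                        sd0 = 1, sd1 = 1.5, cor0 = 0.5, cor1 = 0.7),
                       difficulties = list(type = "drift", frac_up = 0.25,
                                           frac_down = 0.25, magnitude = 0.5),
                       correct_adaptivity = TRUE, anchor = TRUE, seed = NULL) {
  M <- ncol(item_types)
  if (num_items %% nrow(item_types) != 0) {
    stop("num_items must be a multiple of the number of item types")
  }
  W <- rowSums(item_types)
  if (any(item_urn_size %% W != 0)) {
    stop("item urn size must be divisible by every total weight in the bank")
  }
  structure(list(M = M, num_learners = as.integer(num_learners),
                 num_items = as.integer(num_items), item_types = item_types,
                 learner_urn_size = as.integer(learner_urn_size),
                 item_urn_size = as.integer(item_urn_size),
                 T = as.integer(T), g_random = as.integer(g_random),
                 g_adaptive = as.integer(g_adaptive),
                 abilities = abilities, difficulties = difficulties,
                 correct_adaptivity = isTRUE(correct_adaptivity),
                 anchor = isTRUE(anchor), seed = seed),
            class = "sim_config")
}

#' Item bank implied by a configuration
#'
#' Items are grouped by type (`count = num_items / n_types` each); items
#' with exactly one non-zero weight form the reference subset of that
#' dimension. Baseline difficulties are the equally spaced quantiles of the
#' standard normal, assigned so each type spans the difficulty range.
#'
#' @param config A `sim_config`.
#' @return List with `weights` (J x M integer matrix), `W`, `ref_dim`
#'   (dimension index or NA), `delta0` (baseline difficulty), `drift`
#'   (-1/0/+1 drift direction per item).
#' @export
build_item_bank <- function(config) {
  types <- as.matrix(config$item_types)
  per <- config$num_items / nrow(types)
  weights <- types[rep(seq_len(nrow(types)), each = per), , drop = FALSE]
  storage.mode(weights) <- "integer"
  J <- nrow(weights)
  nz <- rowSums(weights > 0)
  ref_dim <- ifelse(nz == 1L, max.col(weights > 0), NA_integer_)

  # quantile grid interleaved across types (items are stored type-major):
  # item i of type k gets rank (i-1)*n_types + k, so every type covers the
  # whole difficulty range
  qrank <- as.vector(vapply(seq_len(nrow(types)), function(k) {
    (seq_len(per) - 1L) * nrow(types) + k
  }, integer(per)))
  delta0 <- stats::qnorm(qrank / (J + 1))

  # spread n_up +1s and n_down -1s evenly over k slots
  drift_pattern <- function(k, n_up, n_down) {
    d <- integer(k)
    if (n_up > 0) d[floor(seq(0, k - 1, length.out = n_up)) + 1L] <- 1L
    free <- which(d == 0L)
    if (n_down > 0) d[free[floor(seq(0, length(free) - 1, length.out = n_down)) + 1L]] <- -1L
    d
  }
  drift <- integer(J)
  if (identical(config$difficulties$type, "drift")) {
    f_up <- config$difficulties$frac_up
    f_down <- config$difficulties$frac_down
    for (m in seq_len(config$M)) {
      idx <- which(!is.na(ref_dim) & ref_dim == m)
      n_up <- floor(length(idx) * f_up)   # equal up/down within a reference
      drift[idx] <- drift_pattern(length(idx), n_up, n_up)  # subset: sum constant
    }
    idx <- which(is.na(ref_dim))
    n_up <- round(J * f_up) - sum(drift == 1L)
    n_down <- round(J * f_down) - sum(drift == -1L)
    drift[idx] <- drift_pattern(length(idx), n_up, n_down)
  }
  list(weights = weights, W = as.integer(rowSums(weights)),
       ref_dim = ref_dim, delta0 = delta0, drift = drift)
}

#' Generate true parameters for a static population
#'
#' Abilities are multivariate normal on the logit scale (equicorrelated by
#' default); difficulties are the equally spaced quantiles of N(0,1).
#'
#' @param config A `sim_config` with `abilities$type == "static"`.
#' @param bank Optional pre-built item bank.
#' @return List of class `true_parameters` with `theta` (N x M), `delta`
#'   (length J), and the generating `mu`/`Sigma`.
#' @export
generate_static_population <- function(config, bank = build_item_bank(config)) {
  ab <- config$abilities
  M <- config$M
  mu <- rep(ab$mean %||% 0, M)
  sd <- rep(ab$sd %||% 1, M)
  P <- matrix(ab$cor %||% 0.5, M, M); diag(P) <- 1
  if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("invalid correlation matrix")
  }
  Sigma <- diag(sd, M) %*% P %*% diag(sd, M)
  theta <- MASS::mvrnorm(config$num_learners, mu, Sigma)
  structure(list(type = "static", theta = theta, delta = bank$delta0,
                 mu = mu, Sigma = Sigma),
            class = "true_parameters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population parameter paths for the dynamic design
#'
#' @param config A `sim_config` with dynamic abilities.
#' @param t Vector of timepoints in 1..T.
#' @return List with `mu` (length(t) x M), `sd` (length(t) x M), `cor`
#'   (length(t)) for the equicorrelation.
#' @export
population_path <- function(config, t = seq_len(config$T)) {
  ab <- config$abilities
  s <- t / config$T
  M <- config$M
  list(mu = outer(ab$mu0 + s * (ab$mu1 - ab$mu0), rep(1, M)),
       sd = outer(ab$sd0 + s * (ab$sd1 - ab$sd0), rep(1, M)),
       cor = ab$cor0 + s * (ab$cor1 - ab$cor0))
}

#' Generate smoothly changing true abilities
#'
#' Each learner keeps a fixed standard-normal factor score z_i; the ability
#' at timepoint t is theta_i(t) = mu(t) + L(t) z_i with L(t) the Cholesky
#' factor of Sigma(t). The population is therefore exactly multivariate
#' normal at every timepoint, with means, SDs and correlations following
#' the configured monotone paths (an increasing-variance Matthew effect and
#' an increasing positive manifold).
#'
#' @param config A `sim_config` with `abilities$type == "dynamic"`.
#' @return List of class `true_parameters` with `theta` (N x M x T array),
#'   `z` (the factor scores) and the parameter paths.
#' @export
generate_dynamic_abilities <- function(config) {
  M <- config$M; N <- config$num_learners; T <- config$T
  z <- matrix(stats::rnorm(N * M), N, M)
  path <- population_path(config)
  theta <- array(NA_real_, c(N, M, T))
  for (t in seq_len(T)) {
    P <- matrix(path$cor[t], M, M); diag(P) <- 1
    Sigma <- diag(path$sd[t, ], M) %*% P %*% diag(path$sd[t, ], M)
    L <- t(chol(Sigma))
    theta[, , t] <- matrix(path$mu[t, ], N, M, byrow = TRUE) + z %*% t(L)
  }
  structure(list(type = "dynamic", theta = theta, z = z, path = path),
            class = "true_parameters")
}

#' Generate drifting item difficulties
#'
#' Half the items keep constant difficulty; a quarter increase and a
#' quarter decrease linearly by the configured magnitude from t = 0 to
#' t = T. At t = T/2 all difficulties equal the standard-normal quantile
#' grid, and the drift directions are balanced within every reference
#' subset so each subset's average difficulty is constant over time.
#'
#' @param config A `sim_config`.
#' @param bank Item bank from [build_item_bank()].
#' @return J x T matrix of difficulties.
#' @export
generate_drifting_difficulties <- function(config, bank = build_item_bank(config)) {
  T <- config$T
  t <- seq_len(T)
  if (!identical(config$difficulties$type, "drift")) {
    return(matrix(bank$delta0, config$num_items, T))
  }
  mag <- config$difficulties$magnitude %||% 0.5
  outer(bank$delta0, rep(1, T)) +
    outer(bank$drift * mag, (t - T / 2) / T)
}

#' Run a full simulated adaptive learning system
#'
#' Initializes learner urnings as Binomial(n, 1/2) and item urnings as
#' W * Binomial(n_j/W, 1/2) (symmetric cold start preserving divisibility),
#' then processes sessions in order: every learner answers `g_random`
#' randomly and `g_adaptive` adaptively selected items (no repeats within a
#' session), responses are sampled from the true parameters, and the
#' two-step update is applied with the Metropolis correction for adaptive
#' selection and queued paired updates for reference items.
#'
#' @param config A `sim_config`.
#' @param truth Optional pre-generated `true_parameters` (so several
#'   systems can share one set of underlying abilities).
#' @param true_weights Optional J x M integer matrix of the weights
#'   generating the responses, when different from the weights the system
#'   uses (for studying weight misspecification).
#' @param record_events Keep the full update-outcome stream (needed for
#'   item-fit diagnostics)?
#' @param snapshot_every Keep urning snapshots every so many sessions.
#' @return List of class `urnings_run`: `config`, `bank`, `truth`,
#'   `learner_urnings` (N x M x n_snapshots), `item_urnings`
#'   (J x n_snapshots), `snapshot_t`, `events` (data.frame or NULL),
#'   `queue` (pending entries at the end), final states.
#' @export
run_system <- function(config, truth = NULL, true_weights = NULL,
                       record_events = FALSE, snapshot_every = 1L) {
  if (!is.null(config$seed)) set.seed(config$seed)
  bank <- build_item_bank(config)
  M <- config$M; N <- config$num_learners; J <- config$num_items
  if (is.null(truth)) {
    truth <- if (identical(config$abilities$type, "static")) {
      generate_static_population(config, bank)
    } else {
      generate_dynamic_abilities(config)
    }
  }
  delta <- if (identical(truth$type, "static")) {
    matrix(truth$delta, J, config$T)
  } else {
    generate_drifting_difficulties(config, bank)
  }
  w_sys <- bank$weights
  w_true <- if (is.null(true_weights)) w_sys else {
    storage.mode(true_weights) <- "integer"
    true_weights
  }

  ln <- matrix(config$learner_urn_size, N, M)
  lr <- matrix(stats::rbinom(N * M, config$learner_urn_size, 0.5), N, M)
  storage.mode(ln) <- "integer"; storage.mode(lr) <- "integer"
  item_n <- rep(config$item_urn_size, J)
  # item urnings start at their invariant distribution given the initial
  # difficulties: anchoring freezes every reference class's sum at its
  # initial value, so a mis-calibrated item start would permanently offset
  # the anchored scale (learners, not being anchored, may cold-start at 1/2)
  item_r <- as.integer(bank$W *
    stats::rbinom(J, item_n %/% bank$W, logistic(delta[, 1] / bank$W)))
  # force copies: the C++ session updates lr / item_r in place
  init_learner <- lr + 0L
  init_item <- item_r + 0L
  ref0 <- ifelse(is.na(bank$ref_dim), -1L, bank$ref_dim - 1L)
  max_w <- max(bank$W)
  nkeys <- M * max_w
  q_up <- rep(list(integer(0)), nkeys)
  q_down <- rep(list(integer(0)), nkeys)

  snap_t <- seq(snapshot_every, config$T, by = snapshot_every)
  lsnap <- array(NA_integer_, c(N, M, length(snap_t)))
  isnap <- matrix(NA_integer_, J, length(snap_t))
  ev_acc <- if (record_events) vector("list", config$T) else NULL

  si <- 0L
  for (t in seq_len(config$T)) {
    theta_t <- if (identical(truth$type, "static")) truth$theta else truth$theta[, , t]
    res <- cpp_session(lr, ln, w_sys, w_true, item_r, rep(as.integer(config$item_urn_size), J),
                       as.integer(ref0), theta_t, delta[, t],
                       config$g_random, config$g_adaptive,
                       config$correct_adaptivity, config$anchor,
                       q_up, q_down, as.integer(max_w), record_events, t)
    q_up <- res$queue_up; q_down <- res$queue_down
    if (record_events) ev_acc[[t]] <- res$events
    if (t %in% snap_t) {
      si <- si + 1L
      lsnap[, , si] <- lr
      isnap[, si] <- item_r
    }
  }

  events <- NULL
  if (record_events) {
    events <- data.frame(
      t = unlist(lapply(ev_acc, `[[`, "t")),
      learner = unlist(lapply(ev_acc, `[[`, "learner")),
      item = unlist(lapply(ev_acc, `[[`, "item")),
      mode = unlist(lapply(ev_acc, `[[`, "mode")),
      x = unlist(lapply(ev_acc, `[[`, "x")),
      learner_green = unlist(lapply(ev_acc, `[[`, "learner_green")),
      accepted = unlist(lapply(ev_acc, `[[`, "accepted")),
      r_star_j = unlist(lapply(ev_acc, `[[`, "r_star_j")),
      partner = unlist(lapply(ev_acc, `[[`, "partner")))
    rs <- do.call(rbind, lapply(ev_acc, `[[`, "r_star"))
    colnames(rs) <- paste0("r_star_", seq_len(M))
    events <- cbind(events, as.data.frame(rs))
  }

  pending <- data.frame(dimension = integer(0), magnitude = integer(0),
                        direction = character(0), item_id = integer(0))
  for (k in seq_len(nkeys)) {
    dm <- (k - 1L) %/% max_w + 1L
    mg <- (k - 1L) %% max_w + 1L
    if (length(q_up[[k]])) {
      pending <- rbind(pending, data.frame(dimension = dm, magnitude = mg,
                                           direction = "up", item_id = q_up[[k]]))
    }
    if (length(q_down[[k]])) {
      pending <- rbind(pending, data.frame(dimension = dm, magnitude = mg,
                                           direction = "down", item_id = q_down[[k]]))
    }
  }

  structure(list(config = config, bank = bank, truth = truth, delta = delta,
                 learner_urnings = lsnap, item_urnings = isnap,
                 snapshot_t = snap_t, events = events, queue = pending,
                 init_learner = init_learner, init_item = init_item,
                 final_learner = lr, final_item = item_r),
            class = "urnings_run")
}

#' Per-dimension conserved totals
#'
#' With anchoring disabled every update conserves, for each dimension m,
#' sum_i R_im + sum_j (w_jm / W_j) R_j; with anchoring the identity holds
#' up to the net signed magnitude of pending queue entries.
#'
#' @param learner_urnings N x M matrix.
#' @param item_urnings Length-J vector.
#' @param bank Item bank (for weights).
#' @return Numeric M-vector.
#' @export
dimension_totals <- function(learner_urnings, item_urnings, bank) {
  frac <- bank$weights / bank$W
  colSums(learner_urnings) + colSums(frac * item_urnings)
}
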