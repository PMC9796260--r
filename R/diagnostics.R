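#' Accumulate item-fit cells from an update stream
#'
#' Under random item selection and a correctly specified model, the
#' probability of a correct response given the post-Step-1 urning values
#' equals the probability that the learner's draw wins Step 2. Fit cells
#' therefore tabulate, per item, dimension and combination of post-Step-1
#' learner urning r and item urning t: the number of updates, correct
#' responses, and learner-green outcomes. Only randomly selected
#' interactions are used (the identity does not hold under adaptive
#' selection).
#'
#' @param events Event data.frame from [run_system()] (`record_events=TRUE`).
#' @param bank Item bank of the run (for the weights).
#' @param items Optional vector of item ids to restrict to.
#' @return data.frame with columns `item`, `dimension`, `r`, `t`,
#'   `n_updates`, `n_correct`, `n_learner_green`, `p_obs`, `p_emp`
#'   (the empirical expected probability, share of learner-green updates).
#'   Zero rows (with a warning) when the stream holds no random-selection
#'   interactions.
#' @export
accumulate_fit <- function(events, bank, items = NULL) {
  ev <- events[events$mode == 0L, , drop = FALSE]
  if (!is.null(items)) ev <- ev[ev$item %in% items, , drop = FALSE]
  empty <- data.frame(item = integer(0), dimension = integer(0), r = integer(0),
                      t = integer(0), n_updates = integer(0), n_correct = integer(0),
                      n_learner_green = integer(0), p_obs = numeric(0), p_emp = numeric(0))
  if (nrow(ev) == 0L) {
    warning("no randomly selected interactions in the event stream; empty fit table")
    return(empty)
  }
  M <- sum(grepl("^r_star_[0-9]+$", names(ev)))
  out <- vector("list", M)
  for (m in seq_len(M)) {
    keep <- bank$weights[ev$item, m] > 0L
    if (!any(keep)) next
    sub <- ev[keep, , drop = FALSE]
    key <- interaction(sub$item, sub[[paste0("r_star_", m)]], sub$r_star_j, drop = TRUE)
    n <- rowsum(rep(1L, nrow(sub)), key)
    nc <- rowsum(sub$x, key)
    ng <- rowsum(sub$learner_green, key)
    parts <- do.call(rbind, strsplit(rownames(n), ".", fixed = TRUE))
    out[[m]] <- data.frame(item = as.integer(parts[, 1]), dimension = m,
                           r = as.integer(parts[, 2]), t = as.integer(parts[, 3]),
                           n_updates = as.integer(n[, 1]),
                           n_correct = as.integer(nc[, 1]),
                           n_learner_green = as.integer(ng[, 1]))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out$p_obs <- out$n_correct / out$n_updates
  out$p_emp <- out$n_learner_green / out$n_updates
  rownames(out) <- NULL
  out[order(out$item, out$dimension, out$r, out$t), ]
}

#' Expected cell probability
#'
#' Adds the closed-form expected probability of a correct response for
#' cells of items loading on a single dimension (where conditioning on
#' that dimension's urning is conditioning on the full learner state);
#' cells of multidimensional items keep only the empirical approximation
#' `p_emp` (NA in `p_exact`), since the closed form would require the
#' full joint combination of urning values.
#'
#' @param cells Fit-cell table from [accumulate_fit()].
#' @param learner_urn_size Learner urn size n (scalar; the cells must come
#'   from learners sharing one urn size).
#' @param item_urn_size Item urn size.
#' @param bank Item bank of the run.
#' @return `cells` with an added `p_exact` column.
#' @export
expected_cell_probability <- function(cells, learner_urn_size, item_urn_size, bank) {
  if (nrow(cells) == 0L) stop("no cells to evaluate")
  if (any(cells$n_updates == 0L)) stop("undefined cell: zero updates")
  cells$p_exact <- NA_real_
  single <- !is.na(bank$ref_dim[cells$item])
  if (any(single)) {
    idx <- which(single)
    w <- bank$weights[cbind(cells$item[idx], cells$dimension[idx])]
    p <- cpp_green_prob_batch(matrix(cells$r[idx], ncol = 1),
                              cells$t[idx],
                              matrix(rep(learner_urn_size, length(idx)), ncol = 1),
                              rep(item_urn_size, length(idx)),
                              matrix(w, ncol = 1))
    cells$p_exact[idx] <- p
  }
  cells
}

midp_hyper <- function(a, b, n) {
  # exact conditional two-proportion test: given s = a + b successes over
  # two Binomial(n, p) samples with common p, A ~ Hypergeometric; mid-p
  s <- a + b
  lo <- stats::phyper(a, n, n, s) - 0.5 * stats::dhyper(a, n, n, s)
  hi <- 1 - stats::phyper(a - 1, n, n, s) - 0.5 * stats::dhyper(a, n, n, s)
  pmin(1, 2 * pmin(lo, hi))
}

midp_binom <- function(x, n, p) {
  lo <- stats::pbinom(x, n, p) - 0.5 * stats::dbinom(x, n, p)
  hi <- 1 - stats::pbinom(x - 1, n, p) - 0.5 * stats::dbinom(x, n, p)
  pmin(1, 2 * pmin(lo, hi))
}

#' Flag misfitting cells
#'
#' Compares the observed proportion correct with the expected proportion
#' per cell. Against the empirical Theorem-2 estimator (itself a
#' proportion over the same updates) the default is the exact conditional
#' two-proportion test (hypergeometric null, mid-p), which attains the
#' nominal rate under the correct model; against a known closed-form
#' probability (`expected = "exact"`) an exact binomial mid-p test is
#' used. Cells with fewer than `min_count` updates are skipped
#' (flag NA). Optionally Benjamini-Hochberg adjusted.
#'
#' @param cells Fit-cell table (with `p_exact` when `expected="exact"`).
#' @param alpha Significance level.
#' @param min_count Minimum updates per tested cell.
#' @param expected "empirical" or "exact".
#' @param adjust Apply Benjamini-Hochberg across tested cells?
#' @return `cells` with `p_value`, `flag` in {"over","under","none"} (NA
#'   where skipped); "over" means observed significantly above expected.
#' @export
flag_misfit <- function(cells, alpha = 0.05, min_count = 20L,
                        expected = c("empirical", "exact"), adjust = FALSE) {
  expected <- match.arg(expected)
  tested <- cells$n_updates >= min_count
  pv <- rep(NA_real_, nrow(cells))
  if (expected == "empirical") {
    i <- which(tested)
    pv[i] <- midp_hyper(cells$n_correct[i], cells$n_learner_green[i], cells$n_updates[i])
    exp_p <- cells$p_emp
  } else {
    if (is.null(cells$p_exact)) stop("run expected_cell_probability() first")
    i <- which(tested & !is.na(cells$p_exact))
    pv[i] <- midp_binom(cells$n_correct[i], cells$n_updates[i], cells$p_exact[i])
    exp_p <- cells$p_exact
  }
  if (adjust) pv[!is.na(pv)] <- stats::p.adjust(pv[!is.na(pv)], "BH")
  flag <- ifelse(is.na(pv), NA_character_,
                 ifelse(pv < alpha,
                        ifelse(cells$p_obs > exp_p, "over", "under"),
                        "none"))
  cells$p_value <- pv
  cells$flag <- flag
  cells
}

#' Bias and RMSE of tracked estimates against the truth
#'
#' bias = mean(estimate - truth), RMSE = sqrt(mean((estimate - truth)^2)),
#' pooled over all supplied elements, optionally within groups.
#'
#' @param estimate,truth Numeric vectors/arrays of equal length.
#' @param group Optional grouping vector (same length).
#' @return data.frame with `group` (if given), `bias`, `rmse`, `n`.
#' @export
bias_rmse <- function(estimate, truth, group = NULL) {
  if (length(estimate) != length(truth)) stop("misaligned estimate/truth series")
  d <- as.numeric(estimate) - as.numeric(truth)
  if (is.null(group)) {
    return(data.frame(bias = mean(d), rmse = sqrt(mean(d^2)), n = length(d)))
  }
  sp <- split(d, group)
  data.frame(group = names(sp),
             bias = vapply(sp, mean, numeric(1)),
             rmse = vapply(sp, function(z) sqrt(mean(z^2)), numeric(1)),
             n = lengths(sp), row.names = NULL)
}
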