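test_that("Step 1 adds response-matching balls and leaves zero-weight dims untouched", {
  l <- learner_state(6, 3)
  it <- make_item(1, 6, 5)
  s <- step1_add(l, it, 1)
  expect_equal(s$r_star, 4L)
  expect_equal(s$r_star_j, 5L)

  l2 <- learner_state(c(9, 9), c(4, 2))
  it2 <- make_item(c(2, 1), 6, 6)
  s2 <- step1_add(l2, it2, 0)
  expect_equal(s2$r_star, c(4L, 2L))
  expect_equal(s2$r_star_j, 9L)

  l3 <- learner_state(c(8, 8, 8), c(3, 5, 2))
  it3 <- make_item(c(1, 1, 0), 8, 4)   # a within-item multidimensional type
  s3 <- step1_add(l3, it3, 1)
  expect_equal(s3$r_star, c(4L, 6L, 2L))
  expect_equal(s3$r_star_j, 4L)
})

test_that("learner-green probability matches hand-derived and boundary values", {
  # 3-ball urns: (2/3 * 2/3) / (2/3 * 2/3 + 1/3 * 1/3) = 4/5
  expect_equal(learner_green_probability(2, 1, 2, 2, 1), 0.8, tolerance = 1e-12)
  expect_equal(oracle_green_prob(2, 1, 2, 2, 1), 0.8, tolerance = 1e-12)
  # item urn all red: learner must win
  expect_equal(learner_green_probability(c(1, 1), 0, c(1, 1), 2, c(1, 1)), 1)
  # a learner urn without green balls in a weighted dimension: cannot win
  expect_equal(learner_green_probability(c(0, 2), 2, c(2, 2), 2, c(1, 1)), 0)
  # both outcomes impossible cannot follow a valid Step 1 and is an error
  expect_error(learner_green_probability(c(0, 3), 4, c(2, 2), 2, c(1, 1)),
               "degenerate")
})

test_that("learner-green probability equals the hypergeometric oracle on random configurations", {
  set.seed(403)
  for (k in 1:400) {
    M <- sample(1:3, 1)
    w <- numeric(M)
    while (all(w == 0)) w <- sample(0:3, M, replace = TRUE)
    W <- sum(w)
    n <- sample(2:8, M, replace = TRUE)
    nj <- W * sample(1:4, 1)
    r_star <- vapply(seq_len(M), function(m) sample(0:(n[m] + w[m]), 1), numeric(1))
    r_star_j <- sample(0:(nj + W), 1)
    o <- oracle_green_prob(r_star, r_star_j, n, nj, w)
    if (is.na(o)) {
      expect_error(learner_green_probability(r_star, r_star_j, n, nj, w), "degenerate")
    } else {
      expect_equal(learner_green_probability(r_star, r_star_j, n, nj, w), o,
                   tolerance = 1e-12)
      expect_equal(cpp_green_prob(as.integer(r_star), as.integer(r_star_j),
                                  as.integer(n), as.integer(nj), as.integer(w)),
                   o, tolerance = 1e-12)
    }
  }
})

test_that("Step 2 conserves r_+ and reverts the urnings on a correct-response learner win", {
  set.seed(404)
  for (k in 1:200) {
    M <- sample(1:2, 1)
    w <- sample(1:3, M, replace = TRUE)
    W <- sum(w)
    n <- sample(4:10, M, replace = TRUE)
    nj <- W * sample(2:4, 1)
    r <- vapply(seq_len(M), function(m) sample(0:n[m], 1), numeric(1))
    rj <- W * sample(0:(nj / W), 1)
    l <- learner_state(n, r)
    it <- make_item(w, nj, rj)
    x <- sample(0:1, 1)
    out <- update_pair(l, it, x)
    # conservation per dimension (no selection, no anchoring)
    expect_equal(out$learner$urnings + (w / W) * out$item$urning,
                 r + (w / W) * rj)
    # bounds and divisibility
    expect_true(all(out$learner$urnings >= 0 & out$learner$urnings <= n))
    expect_true(out$item$urning >= 0 && out$item$urning <= nj)
    expect_equal(out$item$urning %% W, 0)
    if (x == 1 && out$learner_green) {
      expect_equal(out$learner$urnings, r)   # X=1 then learner green: no change
      expect_equal(out$item$urning, rj)
    }
    if (x == 1 && !out$learner_green) {
      expect_equal(out$learner$urnings, r + w)
      expect_equal(out$item$urning, rj - W)
    }
  }
})

test_that("a rejected adaptivity correction leaves all urnings unchanged", {
  set.seed(405)
  l <- learner_state(c(10, 10), c(5, 5))
  items <- list(make_item(c(1, 1), 8, 4, id = 1L), make_item(c(1, 0), 8, 2, id = 2L))
  seen_reject <- FALSE
  for (k in 1:400) {
    out <- update_pair(l, items[[1]], sample(0:1, 1),
                       selection = selection_context(items, 1, "adaptive"))
    if (!out$accepted) {
      seen_reject <- TRUE
      expect_equal(out$learner$urnings, l$urnings)
      expect_equal(out$item$urning, items[[1]]$urning)
    }
  }
  expect_true(seen_reject)
})

test_that("long-run state distribution of the R-level update matches the enumerated invariant", {
  set.seed(406)
  n <- 6L; pi_i <- 0.6; pi_j <- 0.4
  inv <- oracle_pair_invariant(n, n, 1, pi_i, pi_j, 3L, 3L)
  l <- learner_state(n, 3L)
  it <- make_item(1, n, 3L)
  counts <- numeric(n + 1)
  p_true <- prob_correct_urn(pi_i, pi_j, 1)
  for (k in 1:20000) {
    x <- as.integer(stats::runif(1) < p_true)
    out <- update_pair(l, it, x)
    l <- out$learner; it <- out$item
    counts[it$urning + 1] <- counts[it$urning + 1] + 1
  }
  emp <- counts[inv$r_j + 1] / sum(counts)
  expect_lt(0.5 * sum(abs(emp - inv$prob)), 0.05)
  # stationary mean of R/n close to pi
  mean_ri <- sum((3 + 3 - inv$r_j) * inv$prob) / n
  expect_lt(abs(mean_ri - pi_i), 0.02)
})

test_that("legacy unidimensional update keeps bounds, conserves the total, and accepts identity proposals", {
  set.seed(407)
  r_i <- 3L; r_j <- 4L
  for (k in 1:2000) {
    out <- legacy_unidim_update(r_i, r_j, 8, 8, sample(0:1, 1))
    expect_true(out$r_i >= 0 && out$r_i <= 8)
    expect_true(out$r_j >= 0 && out$r_j <= 8)
    expect_equal(out$r_i + out$r_j, 7)
    r_i <- out$r_i; r_j <- out$r_j
  }
})

test_that("urnings stay inside their urns over random multidimensional streams", {
  set.seed(408)
  for (rep in 1:5) {
    l <- learner_state(c(5, 9), c(2, 4))
    items <- list(make_item(c(1, 1), 6, 4, 1L), make_item(c(2, 1), 6, 3, 2L),
                  make_item(c(0, 3), 6, 6, 3L))
    for (k in 1:300) {
      it <- items[[sample(3, 1)]]
      out <- update_pair(l, it, sample(0:1, 1))
      l <- out$learner
      items[[out$item$item_id]] <- out$item
      expect_true(all(l$urnings >= 0 & l$urnings <= l$urn_sizes))
      expect_true(out$item$urning >= 0 && out$item$urning <= out$item$urn_size)
      expect_equal(out$item$urning %% out$item$weights$W, 0)
    }
  }
})
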