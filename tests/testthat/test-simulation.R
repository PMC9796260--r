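test_that("the canonical item-type table has 25 valid types with reference coverage", {
  tt <- item_type_table()
  expect_equal(nrow(tt), 25L)
  expect_equal(anyDuplicated(tt), 0L)
  W <- rowSums(tt)
  expect_true(all(204 %% W == 0))
  single <- rowSums(tt > 0) == 1
  # every dimension has single-loading types (reference subsets exist)
  for (m in 1:3) expect_true(any(single & tt[[m]] > 0))
  expect_true(all(c("1.1.0", "2.1.0") %in% paste(tt$w1, tt$w2, tt$w3, sep = ".")))
})

test_that("static difficulties are the equally spaced standard-normal quantiles", {
  cfg <- sim_config(num_learners = 10, num_items = 3,
                    item_types = data.frame(w1 = 1L, w2 = 0L, w3 = 0L),
                    item_urn_size = 10, T = 5,
                    abilities = list(type = "static", mean = 0, sd = 1, cor = 0.5),
                    difficulties = list(type = "static"))
  bank <- build_item_bank(cfg)
  expect_equal(sort(bank$delta0), stats::qnorm((1:3) / 4), tolerance = 1e-12)
  expect_equal(sort(bank$delta0)[2], 0)
})

test_that("static populations have the configured moments", {
  set.seed(421)
  cfg <- sim_config(num_learners = 5000, num_items = 25, T = 1,
                    item_urn_size = 24,
                    abilities = list(type = "static", mean = 0, sd = 1, cor = 0.5),
                    difficulties = list(type = "static"))
  pop <- generate_static_population(cfg)
  expect_equal(dim(pop$theta), c(5000L, 3L))
  se_m <- 1 / sqrt(5000)
  expect_true(all(abs(colMeans(pop$theta)) < 3 * se_m))
  expect_true(all(abs(apply(pop$theta, 2, stats::sd) - 1) < 3 * se_m))
  cors <- stats::cor(pop$theta)[upper.tri(diag(3))]
  expect_true(all(abs(cors - 0.5) < 3 * (1 - 0.5^2) / sqrt(5000)))
  expect_error(generate_static_population(
    sim_config(num_items = 25, item_urn_size = 24,
               abilities = list(type = "static", mean = 0, sd = 1, cor = -0.9),
               difficulties = list(type = "static"))), "correlation")
})

test_that("dynamic abilities follow monotone mean/SD/correlation paths and stay MVN", {
  set.seed(422)
  cfg <- sim_config(num_learners = 1000, num_items = 25, T = 50,
                    item_urn_size = 24)
  dyn <- generate_dynamic_abilities(cfg)
  sds <- apply(dyn$theta, 3, function(th) mean(apply(th, 2, stats::sd)))
  cors <- apply(dyn$theta, 3, function(th) mean(stats::cor(th)[upper.tri(diag(3))]))
  mus <- apply(dyn$theta, 3, function(th) mean(colMeans(th)))
  expect_true(all(diff(sds) > 0))
  expect_true(all(diff(cors) > 0))
  expect_true(all(diff(mus) > 0))
  # exact MVN construction: sample moments match the configured path closely
  path <- population_path(cfg)
  expect_equal(mus[50], mean(path$mu[50, ]), tolerance = 4 / sqrt(1000))
  expect_equal(sds[50], mean(path$sd[50, ]), tolerance = 4 / sqrt(1000))
  # marginal normality at the final timepoint
  expect_gt(stats::shapiro.test(dyn$theta[1:1000, 1, 50])$p.value, 1e-4)
})

test_that("difficulty drift is linear, balanced in reference subsets, centred at T/2", {
  cfg <- sim_config(num_learners = 10, num_items = 100, T = 200,
                    item_urn_size = 24)
  bank <- build_item_bank(cfg)
  dd <- generate_drifting_difficulties(cfg, bank)
  expect_equal(mean(bank$drift == 0), 0.5, tolerance = 0.02)
  expect_equal(sum(bank$drift), 0L)
  up <- which(bank$drift == 1)[1]
  expect_equal(dd[up, 200] - dd[up, 1], 0.5 * 199 / 200, tolerance = 1e-9)
  expect_equal(dd[, 100], bank$delta0, tolerance = 1e-12)
  for (m in 1:3) {
    ref <- which(!is.na(bank$ref_dim) & bank$ref_dim == m)
    expect_equal(mean(dd[ref, 1]), mean(dd[ref, 200]), tolerance = 1e-9)
    expect_equal(mean(dd[ref, 1]), mean(bank$delta0[ref]), tolerance = 1e-9)
  }
})

test_that("runs are bit-reproducible from the seed", {
  cfg <- sim_config(num_learners = 20, num_items = 25, T = 15,
                    learner_urn_size = 8, item_urn_size = 24,
                    g_random = 1, g_adaptive = 3, seed = 99L)
  a <- run_system(cfg, record_events = TRUE)
  b <- run_system(cfg, record_events = TRUE)
  expect_identical(a$events, b$events)
  expect_identical(a$learner_urnings, b$learner_urnings)
  expect_identical(a$item_urnings, b$item_urnings)
})

test_that("stationary system tracks learner urning means near n * pi", {
  set.seed(423)
  cfg <- sim_config(num_learners = 300, num_items = 100, T = 600,
                    learner_urn_size = 20, item_urn_size = 204,
                    g_random = 1, g_adaptive = 9,
                    abilities = list(type = "static", mean = 0, sd = 1, cor = 0.5),
                    difficulties = list(type = "static"))
  run <- run_system(cfg)
  pi_l <- logistic(run$truth$theta)
  emp <- apply(run$learner_urnings[, , 201:600], c(1, 2), mean) / 20
  # across-session mean of R/n close to pi for nearly all learners
  err <- abs(emp - pi_l)
  tol <- 3 * sqrt(pi_l * (1 - pi_l) / (20 * 15))  # ~15 effective draws
  expect_gt(mean(err < pmax(tol, 0.05)), 0.9)
  expect_lt(mean(err), 0.05)
})
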