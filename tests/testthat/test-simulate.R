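test_that("the drawn truth matches the scenario design", {
  set.seed(1)
  truth <- make_truth(scenario_spec("Homo-S"))
  expect_identical(truth$true_features, 1L + (0:9) * 200L)
  nz <- truth$beta_true[truth$true_features, ]
  expect_true(all(nz[1:5, ] == -1) && all(nz[6:10, ] == 1))
  expect_true(all(truth$beta_true[-truth$true_features, ] == 0))
  expect_identical(truth$lambda0, rep(1, 5))
  expect_identical(truth$censor_rate, rep(0.2, 5))

  set.seed(1)
  tw <- make_truth(scenario_spec("Homo-W"))
  expect_equal(sort(unique(as.vector(tw$beta_true[tw$true_features, ]))),
               c(-0.5, 0.5))
})

test_that("heterogeneous truths perturb effects but never the sparsity pattern", {
  spec <- scenario_spec("Hetero-S", p = 40, s = 4, K = 5)
  set.seed(2)
  draws <- replicate(1000, make_truth(spec)$beta_true[1 + (0:3) * 10, 1])
  expect_equal(rowMeans(draws), c(-1, -1, 1, 1), tolerance = 0.02)
  expect_equal(apply(draws, 1, sd), rep(0.2, 4), tolerance = 0.02)
  set.seed(3)
  t1 <- make_truth(spec)
  expect_true(all(t1$beta_true[-t1$true_features, ] == 0))
  expect_true(all(t1$censor_rate %in% c(0.1, 0.3, 0.5)))
  expect_true(all(t1$lambda0 > 0))
})

test_that("features follow the AR(1) correlation structure", {
  spec <- scenario_spec("custom", n = 2000, p = 10, K = 1, s = 2)
  sim <- simulate_scenario(spec, seed = 4)
  X <- sim$data$studies[[1]]$features
  lag1 <- vapply(1:9, function(j) cor(X[, j], X[, j + 1]), 0)
  expect_true(all(abs(lag1 - 0.5) < 0.05))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 0.05))
  lag4 <- cor(X[, 1], X[, 5])
  expect_lt(abs(lag4 - 0.5^4), 0.05)
})

test_that("null censoring fraction matches the competing-exponentials formula", {
  # beta = 0, lambda0 = 1, censor rate 0.2: P(censored) = 0.2 / 1.2 = 1/6
  spec <- scenario_spec("custom", n = 2000, p = 4, K = 1, s = 2,
                        mu_abs = 1e-8)
  sim <- simulate_scenario(spec, seed = 5)
  cens <- mean(sim$data$studies[[1]]$event == 0)
  expect_lt(abs(cens - 1 / 6), 0.03)
  expect_true(all(sim$data$studies[[1]]$time > 0))
})

test_that("simulation is reproducible and studies differ", {
  spec <- scenario_spec("Hetero-W", n = 30, p = 20, s = 4, K = 3)
  a <- simulate_scenario(spec, seed = 6)
  b <- simulate_scenario(spec, seed = 6)
  expect_identical(a$truth, b$truth)
  expect_identical(a$data$studies[[2]]$time, b$data$studies[[2]]$time)
  expect_identical(a$data$studies[[3]]$features, b$data$studies[[3]]$features)
  expect_false(identical(a$data$studies[[1]]$features,
                         a$data$studies[[2]]$features))
})

test_that("replications are seed-determined end to end", {
  spec <- scenario_spec("custom", n = 50, p = 40, K = 2, s = 4, mu_abs = 1)
  r1 <- run_replication(spec, methods = "Cox-TOTEM", seed = 7, nfolds = 3)
  r2 <- run_replication(spec, methods = "Cox-TOTEM", seed = 7, nfolds = 3)
  expect_identical(r1$sensitivity, r2$sensitivity)
  expect_identical(attr(r1, "selections"), attr(r2, "selections"))
})
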