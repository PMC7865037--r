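test_that("selection metrics count exactly", {
  set.seed(1)
  truth <- make_truth(scenario_spec("Homo-S"))      # p = 2000, s = 10
  perfect <- selection_metrics(truth$true_features, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_identical(perfect$n_selected, 10L)
  empty <- selection_metrics(integer(0), truth)
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$specificity, 1)
  mixed <- selection_metrics(c(truth$true_features[1:8], 2:5), truth)
  expect_equal(mixed$sensitivity, 0.8)
  expect_equal(mixed$specificity, 1986 / 1990)
  expect_identical(mixed$n_selected, 12L)
  # degenerate truth: no true predictors
  set.seed(1)
  t0 <- make_truth(scenario_spec("custom", p = 50, s = 0, mu_abs = 1))
  m0 <- selection_metrics(integer(0), t0)
  expect_true(is.na(m0$sensitivity))
  expect_equal(m0$specificity, 1)
})

test_that("post-selection SSE plugs in zeros for unselected features", {
  sim <- simulate_scenario(scenario_spec("custom", n = 60, p = 50, K = 2,
                                         s = 4, mu_abs = 1), seed = 81)
  # nothing selected: SSE is the squared mass of the truth (4 x 2 x 1)
  expect_equal(post_selection_sse(sim$data, integer(0), sim$truth),
               sum(sim$truth$beta_true^2))
  expect_equal(sum(sim$truth$beta_true^2), 8)
  # all-zero truth with empty selection
  sim0 <- simulate_scenario(scenario_spec("custom", n = 40, p = 30, K = 2,
                                          s = 0, mu_abs = 1), seed = 82)
  expect_identical(post_selection_sse(sim0$data, integer(0), sim0$truth), 0)
})

test_that("estimation error shrinks with sample size under perfect selection", {
  spec_small <- scenario_spec("custom", n = 100, p = 50, K = 2, s = 4,
                              mu_abs = 1)
  spec_big <- scenario_spec("custom", n = 2000, p = 50, K = 2, s = 4,
                            mu_abs = 1)
  s1 <- simulate_scenario(spec_small, seed = 83)
  s2 <- simulate_scenario(spec_big, seed = 83)
  sse1 <- post_selection_sse(s1$data, s1$truth$true_features, s1$truth)
  sse2 <- post_selection_sse(s2$data, s2$truth$true_features, s2$truth)
  expect_lt(sse2, sse1)
})

test_that("lambda sweep tables have one row per method and penalty fraction", {
  spec <- scenario_spec("custom", n = 60, p = 50, K = 2, s = 4, mu_abs = 1)
  grid <- c(0.2, 0.5, 0.8)
  sw <- lambda_sweep_curves(spec, methods = c("Cox-TOTEM", "InterCoxLasso"),
                            lambda_scaled = grid, n_reps = 2, seed = 84)
  expect_identical(nrow(sw), 6L)
  expect_identical(sort(unique(sw$lambda_scaled)), grid)
  expect_true(all(sw$mean_sensitivity >= 0 & sw$mean_sensitivity <= 1))
  expect_true(all(sw$mean_specificity >= 0 & sw$mean_specificity <= 1))
})
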