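test_that("fold assignment partitions every study with events in each fold", {
  data <- make_test_msdata(K = 3, n = 45, d = 3, seed = 61)
  folds <- make_cv_folds(data, nfolds = 5, seed = 7)
  expect_identical(attr(folds, "nfolds"), 5L)
  for (k in 1:3) {
    f <- folds[[k]]
    expect_identical(length(f), 45L)
    expect_true(all(f %in% 1:5))
    ev <- data$studies[[k]]$event == 1
    expect_true(all(tabulate(f[ev], 5) >= 1))
  }
  # same seed, same folds
  expect_identical(folds, make_cv_folds(data, nfolds = 5, seed = 7))
})

test_that("fold construction fails cleanly when events cannot be spread", {
  data <- make_test_msdata(K = 2, n = 20, d = 2, seed = 62)
  # one event in the whole collection: no fold split can work
  data$studies[[1]]$event <- c(1L, rep(0L, 19))
  data$studies[[2]]$event <- rep(0L, 20)
  expect_error(make_cv_folds(data, nfolds = 5, seed = 1),
               "insufficient_events")
  # a nearly-eventless study alone does not abort multi-study folds
  data$studies[[2]]$event <- rep(c(1L, 0L), 10)
  folds <- make_cv_folds(data, nfolds = 5, seed = 1)
  expect_identical(attr(folds, "nfolds"), 5L)
})

test_that("harrell_c matches the survival package on continuous data", {
  skip_if_not_installed("survival")
  set.seed(63)
  for (i in 1:5) {
    n <- 40
    tt <- rexp(n); d <- rbinom(n, 1, 0.6); eta <- rnorm(n)
    ref <- survival::concordance(survival::Surv(tt, d) ~ eta,
                                 reverse = TRUE)$concordance
    expect_equal(harrell_c(tt, d, eta), unname(ref), tolerance = 1e-12)
  }
  expect_identical(harrell_c(1:4, c(1, 1, 1, 1), rep(2, 4)), 0.5)
  expect_identical(harrell_c(1:4, rep(0, 4), rnorm(4)), 0.5)
})

test_that("cross-validation criteria behave at the null end and are reproducible", {
  sim <- simulate_scenario(scenario_spec("custom", n = 60, p = 40, K = 2,
                                         s = 4, mu_abs = 1), seed = 64)
  scr <- screen_features(marginal_scan(sim$data))
  sub <- restrict_features(sim$data, scr$retained_idx)
  cvc <- cv_group_cox(sub, nfolds = 3, nlambda = 12, seed = 5)
  # at lambda_max the fitted model is empty: held-out concordance is exactly 1/2
  expect_true(all(cvc$fold_matrix[, 1] == 0.5))
  # bit-reproducibility under the same seed
  cvc2 <- cv_group_cox(sub, nfolds = 3, nlambda = 12, seed = 5)
  expect_identical(cvc$fold_assignments, cvc2$fold_assignments)
  expect_identical(cvc$lambda_opt, cvc2$lambda_opt)
  expect_identical(cvc$cv_criterion, cvc2$cv_criterion)
  # V&VH criterion at lambda_max equals the null-model held-out likelihood
  cvl <- cv_group_cox(sub, nfolds = 3, nlambda = 12, seed = 5,
                      type = "loglik")
  folds <- cvl$fold_assignments
  null_crit <- vapply(1:3, function(f) {
    sum(vapply(seq_len(2), function(k) {
      s <- sub$studies[[k]]
      keep <- folds[[k]] != f
      rs_full <- vapply(s$time[s$event == 1],
                        function(t) sum(s$time >= t), 0)
      tt <- s$time[keep]
      rs_tr <- vapply(tt[s$event[keep] == 1],
                      function(t) sum(tt >= t), 0)
      -sum(log(rs_full)) + sum(log(rs_tr))
    }, 0))
  }, 0)
  expect_equal(cvl$fold_matrix[, 1], null_crit, tolerance = 1e-8)
})

test_that("pipeline cross-validation finds signal below lambda_max", {
  sim <- simulate_scenario(scenario_spec("custom", n = 80, p = 60, K = 3,
                                         s = 4, mu_abs = 1), seed = 65)
  cv <- cv_mscox(sim$data, nfolds = 3, nlambda = 15, seed = 9,
                 lambda_max = 10)
  expect_lt(cv$t_opt, 1)
  expect_equal(cv$lambda_opt, cv$t_opt * 10)
  expect_gt(max(cv$cv_criterion), 0.5)
  # criterion invariant to study order given the same folds
  perm <- c(3, 1, 2)
  simp <- ms_data(sim$data$studies[perm])
  cvp <- cv_mscox(simp, nfolds = 3, nlambda = 15,
                  folds = structure(cv$fold_assignments[perm], nfolds = 3L),
                  lambda_max = 10)
  expect_equal(cvp$cv_criterion, cv$cv_criterion, tolerance = 1e-10)
})
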