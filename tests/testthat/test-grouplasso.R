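# shared small multi-study problem with genuine signal
gl_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_scenario(scenario_spec("custom", n = 80, p = 60, K = 3,
                                             s = 4, mu_abs = 1), seed = 5)
      scr <- screen_features(marginal_scan(sim$data))
      cache <<- list(sim = sim,
                     sub = restrict_features(sim$data, scr$retained_idx),
                     scr = scr)
    }
    cache
  }
})

test_that("the stacked objective matches its closed-form pieces", {
  fx <- gl_fixture()
  sub <- fx$sub
  d <- n_features(sub); K <- n_studies(sub)
  # beta = 0: sum of null partial log-likelihoods, -sum log |risk set|
  null_ll <- sum(vapply(sub$studies, function(s) {
    rs <- vapply(s$time[s$event == 1], function(t) sum(s$time >= t), 0)
    -sum(log(rs))
  }, 0))
  expect_equal(stacked_objective(sub, matrix(0, d, K), lambda = 7), null_ll)
  # lambda = 0 reduces to the sum of unpenalized partial log-likelihoods
  set.seed(2)
  b <- matrix(rnorm(d * K, 0, 0.1), d, K)
  expect_equal(stacked_objective(sub, b, 0),
               sum(vapply(seq_len(K), function(k)
                 cox_partial_loglik(sub$studies[[k]], b[, k]), 0)))
  # K = 1: group norm degenerates to the ordinary lasso penalty
  one <- ms_data(sub$studies[1])
  b1 <- b[, 1, drop = FALSE]
  expect_equal(stacked_objective(one, b1, 3),
               cox_partial_loglik(one$studies[[1]], b1) - 3 * sum(abs(b1)))
})

test_that("lambda_max is the exact boundary of the all-zero solution", {
  fx <- gl_fixture()
  lmax <- compute_lambda_max(fx$sub)
  expect_identical(group_cox_admm(fx$sub, 1.01 * lmax)$d2, 0L)
  expect_gt(group_cox_admm(fx$sub, 0.5 * lmax)$d2, 0L)
  # invariant under study reordering
  perm <- ms_data(fx$sub$studies[c(3, 1, 2)])
  expect_equal(compute_lambda_max(perm), lmax, tolerance = 1e-10)
})

test_that("the penalty-free limit matches per-study unpenalized fits", {
  fx <- gl_fixture()
  f0 <- group_cox_admm(fx$sub, 0)
  ssub <- mscox:::standardize_ms(fx$sub)
  for (k in 1:3)
    expect_equal(unname(f0$beta[, k]),
                 unname(cox_fit(ssub$studies[[k]])$beta), tolerance = 1e-3)
})

test_that("selection is all-in-or-all-out and satisfies the group KKT conditions", {
  fx <- gl_fixture()
  lmax <- compute_lambda_max(fx$sub)
  for (frac in c(0.7, 0.4, 0.2)) {
    fit <- group_cox_admm(fx$sub, frac * lmax)
    rn <- rowSums(fit$beta != 0)
    expect_true(all(rn %in% c(0L, n_studies(fx$sub))))
    expect_true(fit$converged)
    expect_true(fit$kkt$pass)
    # returned solution beats random nearby points
    ssub <- mscox:::standardize_ms(fx$sub)
    obj <- stacked_objective(ssub, fit$beta, fit$lambda)
    set.seed(99)
    for (i in 1:100) {
      pert <- matrix(rnorm(length(fit$beta)), nrow(fit$beta))
      pert <- 0.01 * pert / sqrt(sum(pert^2))
      expect_lte(stacked_objective(ssub, fit$beta + pert, fit$lambda),
                 obj + 1e-8)
    }
  }
})

test_that("the objective trace settles monotonically after burn-in", {
  fx <- gl_fixture()
  lmax <- compute_lambda_max(fx$sub)
  fit <- group_cox_admm(fx$sub, 0.3 * lmax)
  tr <- fit$objective_trace
  burn <- ceiling(length(tr) / 2)
  expect_true(all(diff(tr[burn:length(tr)]) <= 1e-6))
})

test_that("pathwise fits start empty, trend monotone and are warm-start invariant", {
  fx <- gl_fixture()
  warm <- group_cox_path(fx$sub, nlambda = 20)
  cold <- group_cox_path(fx$sub, nlambda = 20, warm = FALSE)
  expect_identical(warm$fits[[1]]$d2, 0L)
  # weak monotonicity of the selected size along the decreasing grid
  steps <- diff(warm$n_selected)
  expect_gte(mean(steps >= 0), 0.95)
  for (i in seq_along(warm$fits))
    expect_identical(warm$fits[[i]]$selected_idx, cold$fits[[i]]$selected_idx)
})

test_that("the K = 1 solver agrees with glmnet's lasso-Cox on selections", {
  skip_if_not_installed("glmnet")
  fx <- gl_fixture()
  st <- fx$sub$studies[[1]]
  one <- ms_data(list(st))
  n <- length(st$time)
  sone <- mscox:::standardize_ms(one)
  xs <- sone$studies[[1]]$features
  y <- cbind(time = st$time, status = st$event)
  gfit <- glmnet::glmnet(xs, y, family = "cox", alpha = 1,
                         standardize = FALSE)
  lmax <- compute_lambda_max(one)
  # glmnet scales the Cox log-likelihood by 1/n
  expect_equal(max(gfit$lambda) * n, lmax, tolerance = 1e-6)
  for (frac in c(0.6, 0.3)) {
    mine <- group_cox_admm(one, frac * lmax)
    b <- as.numeric(coef(gfit, s = frac * lmax / n, exact = TRUE,
                         x = xs, y = y))
    expect_identical(unname(sort(mine$selected_idx)), which(b != 0))
  }
})
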