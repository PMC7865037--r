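test_that("partial log-likelihood matches closed forms on the 3-subject example", {
  st <- tiny3_study()
  # null model: -sum over events of log |risk set|
  expect_equal(cox_partial_loglik(st, 0), -log(3) - log(2))
  # beta = 0.5 log 2, u = e^beta = sqrt(2):
  # l = -log(2 + u) + beta - log(1 + u)
  b <- 0.5 * log(2)
  expect_equal(cox_partial_loglik(st, b),
               -log(2 + sqrt(2)) + b - log(1 + sqrt(2)), tolerance = 1e-12)
  expect_lte(cox_partial_loglik(st, 0.7), 0)
  # order invariance: permuting subjects leaves the value unchanged
  perm <- c(3, 1, 2)
  st2 <- ms_study(st$time[perm], st$event[perm],
                  st$features[perm, , drop = FALSE])
  expect_equal(cox_partial_loglik(st2, b), cox_partial_loglik(st, b))
})

test_that("marginal fit solves the closed-form score equation", {
  fit <- cox_fit(tiny3_study())
  expect_equal(unname(fit$beta), 0.5 * log(2), tolerance = 1e-8)
  expect_true(fit$converged)
  # the optimum is a local maximum against coordinate perturbations
  for (eps in c(-0.01, 0.01))
    expect_lt(cox_partial_loglik(tiny3_study(), fit$beta + eps), fit$loglik)
})

test_that("multi-covariate fit agrees with coxph under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(8)
  st <- make_test_study(n = 70, d = 3, beta = c(0.6, -0.4, 0), seed = 8)
  # introduce genuine ties
  st$time <- round(st$time, 1) + 0.05
  fit <- cox_fit(st)
  ref <- survival::coxph(survival::Surv(st$time, st$event) ~ st$features,
                         ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("duplicating an event time changes the likelihood as Breslow predicts", {
  # 4 subjects, times 1 < 2 < 3 < 4, all events, covariate x
  x <- c(0.5, -0.2, 0.3, 0)
  st <- ms_study(time = 1:4, event = rep(1L, 4),
                 features = matrix(x, 4, 1, dimnames = list(NULL, "x")))
  b <- 0.4
  u <- exp(b * x)
  ll4 <- sum(b * x - log(rev(cumsum(rev(u)))))
  expect_equal(cox_partial_loglik(st, b), ll4, tolerance = 1e-12)
  # tie subject 3's time onto subject 2: both events now share the risk
  # set {2, 3, 4} in the Breslow convention
  st2 <- st
  st2$time <- c(1, 2, 2, 4)
  expected <- (b * x[1] - log(sum(u))) +
    (b * x[2] - log(u[2] + u[3] + u[4])) +
    (b * x[3] - log(u[2] + u[3] + u[4])) +
    (b * x[4] - log(u[4]))
  expect_equal(cox_partial_loglik(st2, b), expected, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected and no-event data is flagged", {
  st <- make_test_study(n = 20, d = 2, seed = 3)
  st$features[, 2] <- 1.7
  expect_error(cox_fit(st), "degenerate_covariate")
  st0 <- st
  st0$event <- rep(0L, 20)
  expect_error(cox_fit(st0, features = 1), "no_events")
  expect_warning(val <- cox_partial_loglik(st0, 0.3, features = 1),
                 "no events")
  expect_identical(as.numeric(val), 0)
})

test_that("covariate rescaling rescales beta and leaves z unchanged", {
  st <- make_test_study(n = 80, d = 1, beta = 0.8, seed = 5)
  f1 <- cox_fit(st)
  st2 <- st
  st2$features <- st2$features * 10
  f2 <- cox_fit(st2)
  expect_equal(unname(f2$beta), unname(f1$beta) / 10, tolerance = 1e-6)
  expect_equal(standardized_z(f2), standardized_z(f1), tolerance = 1e-8)
})

test_that("marginal fits agree with 1-D likelihood maximization on random data", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    st <- make_test_study(n = n, d = 1, beta = rnorm(1, 0, 0.5),
                          seed = 1000 + i)
    fit <- try(cox_fit(st), silent = TRUE)
    if (inherits(fit, "try-error") || any(fit$flagged_separation)) next
    opt <- optimize(function(b) cox_partial_loglik(st, b),
                    interval = c(-12, 12), maximum = TRUE, tol = 1e-9)
    expect_lt(abs(unname(fit$beta) - opt$maximum), 1e-4)
  }
})

test_that("monotone likelihood is detected and capped in the z scale", {
  # covariate perfectly separating early events from late survivors
  st <- ms_study(time = 1:8, event = rep(1L, 8),
                 features = matrix(c(4, 3.5, 3, 2.5, -2.5, -3, -3.5, -4),
                                   8, 1, dimnames = list(NULL, "x")))
  fit <- cox_fit(st)
  expect_true(any(fit$flagged_separation))
  expect_equal(standardized_z(fit), 37)
  expect_equal(standardized_z(fit, zcap = 10), 10)
})

test_that("consistency under the null: large-sample estimate stays near zero", {
  st <- make_test_study(n = 500, d = 1, beta = 0, seed = 11)
  fit <- cox_fit(st)
  expect_lt(abs(unname(fit$beta)), 3 * unname(fit$se))
})
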