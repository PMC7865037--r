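test_that("minimum-|z| screening ranks and truncates as specified", {
  z <- rbind(A = c(5, 4), B = c(6, 1), C = c(3, 3))
  expect_identical(min_psis_screen(z, 2), c(1L, 3L))   # min |z|: A 4, B 1, C 3
  expect_identical(min_psis_screen(z, 3), 1:3)
  # ties broken by feature order: first wins
  zt <- rbind(c(2, 2), c(2, 2), c(1, 5))
  expect_identical(min_psis_screen(zt, 1), 1L)
})

test_that("per-study penalized selection finds a strong feature and respects candidates", {
  st <- make_test_study(n = 100, d = 50, beta = c(1.5, rep(0, 49)), seed = 71)
  sel <- per_study_penalized_cox(st, penalty = "lasso", seed = 1)
  expect_true(1L %in% sel)
  cand <- c(1L, 5L, 9L, 20L)
  sel2 <- per_study_penalized_cox(st, features = cand, penalty = "elastic_net",
                                  seed = 1)
  expect_true(all(sel2 %in% cand))
})

test_that("intersection baselines intersect per-study selections", {
  data <- make_test_msdata(K = 2, n = 80, d = 30,
                           beta = c(1.2, rep(0, 29)), seed = 72)
  res <- run_baseline(data, "InterCoxLasso", seed = 2)
  expect_identical(res$selected_idx,
                   sort(Reduce(intersect, res$per_study_selected)))
  one <- ms_data(data$studies[1])
  r1 <- run_baseline(one, "InterCoxLasso", seed = 2)
  expect_identical(r1$selected_idx, sort(r1$per_study_selected[[1]]))
})

test_that("MinPSIS two-stage variants screen to d features before selecting", {
  data <- make_test_msdata(K = 2, n = 50, d = 40,
                           beta = c(1.3, rep(0, 39)), seed = 73)
  scan <- marginal_scan(data)
  res <- run_baseline(data, "MinPSIS-InterCoxNet", scan = scan, d = 10,
                      seed = 3)
  expect_identical(res$d, 10L)
  cand <- min_psis_screen(scan, 10)
  for (k in 1:2) expect_true(all(res$per_study_selected[[k]] %in% cand))
  # default d is the smallest study size
  res2 <- run_baseline(data, "MinPSIS-InterCoxLasso", scan = scan, seed = 3)
  expect_identical(res2$d, 40L)   # min(n) = 50 capped at p = 40
})

test_that("group selection beats intersection selection under heterogeneous weak signals", {
  spec <- scenario_spec("Hetero-W", n = 80, p = 200, K = 3, s = 6)
  sens <- vapply(1:3, function(i) {
    r <- run_replication(spec, methods = c("Cox-TOTEM", "InterCoxLasso"),
                         seed = 500 + i, nfolds = 3)
    c(r$sensitivity[r$method == "Cox-TOTEM"],
      r$sensitivity[r$method == "InterCoxLasso"])
  }, numeric(2))
  expect_gt(mean(sens[1, ]), mean(sens[2, ]))
})
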