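test_that("study partition thresholds at the two-sided normal quantile", {
  # alpha1 = 1e-4: threshold = qnorm(1 - 5e-5) ~ 3.89
  expect_equal(partition_studies(c(5.0, 1.0, 0.5), alpha1 = 1e-4), c(2L, 3L))
  expect_identical(partition_studies(c(10, -8, 9), alpha1 = 1e-4), integer(0))
  expect_identical(partition_studies(rep(0, 4), alpha1 = 1e-4), 1:4)
  # boundary: |z| equal to the threshold goes to the weak set
  thr <- qnorm(1 - 1e-4 / 2)
  expect_identical(partition_studies(c(thr, thr + 1e-6)), 1L)
})

test_that("the aggregate chi-square test retains strong aggregate effects", {
  # empty weak set: retained regardless of z
  r0 <- aggregate_test(c(9, 9), integer(0), alpha2 = 0.05)
  expect_true(r0$retained)
  expect_identical(r0$U, 0)
  # kappa = 2, alpha2 = 0.05: threshold qchisq(0.95, 2) ~ 5.99
  r1 <- aggregate_test(c(1.0, 0.5), 1:2, alpha2 = 0.05)
  expect_equal(r1$U, 1.25)
  expect_false(r1$retained)
  r2 <- aggregate_test(c(2.0, 1.5), 1:2, alpha2 = 0.05)
  expect_equal(r2$U, 6.25)
  expect_true(r2$retained)
  expect_equal(r2$threshold, qchisq(0.95, 2))
})

test_that("screen_features applies both steps per feature with consistent bookkeeping", {
  set.seed(12)
  z <- matrix(rnorm(500 * 5, sd = 1.5), 500, 5)
  z[1, ] <- 10                              # strong everywhere: kappa = 0
  scr <- screen_features(z, alpha1 = 1e-4, alpha2 = 0.05)
  expect_true(scr$retained[1])
  expect_identical(scr$kappa[1], 0L)
  expect_identical(scr$kappa, lengths(scr$weak_sets))
  expect_equal(scr$U, vapply(seq_len(500), function(j)
    sum(z[j, scr$weak_sets[[j]]]^2), 0))
  thr <- qchisq(0.95, df = pmax(scr$kappa, 1))
  expect_identical(scr$retained, scr$kappa == 0L | scr$U > thr)
  expect_identical(scr$d1, length(scr$retained_idx))
})

test_that("screening is monotone in alpha2 and in |z|", {
  set.seed(13)
  z <- matrix(rnorm(300 * 4, sd = 1.4), 300, 4)
  strict <- screen_features(z, alpha2 = 0.01)
  loose <- screen_features(z, alpha2 = 0.05)
  expect_true(all(strict$retained_idx %in% loose$retained_idx))
  # growing any |z| never drops a retained feature while the weak-set
  # membership is unchanged (crossing the strong-signal threshold can
  # legitimately remove the largest chi-square contribution)
  thr1 <- qnorm(1 - 1e-4 / 2)
  base <- screen_features(z, alpha2 = 0.05)
  for (i in 1:50) {
    j <- sample(300, 1); k <- sample(4, 1)
    z2 <- z
    room <- thr1 - abs(z2[j, k])
    if (room <= 0) next
    z2[j, k] <- z2[j, k] + sign(z2[j, k] + 1e-12) * runif(1, 0, room * 0.99)
    after <- screen_features(z2, alpha2 = 0.05)$retained[j]
    if (base$retained[j]) expect_true(after)
  }
  # and a feature strong in every study is always retained
  z3 <- z
  z3[7, ] <- c(5, -6, 7, 8)
  expect_true(screen_features(z3, alpha2 = 0.05)$retained[7])
})

test_that("screening is invariant under study reordering", {
  set.seed(14)
  z <- matrix(rnorm(200 * 5, sd = 1.3), 200, 5)
  perm <- c(4, 1, 5, 2, 3)
  a <- screen_features(z)
  b <- screen_features(z[, perm])
  expect_identical(a$retained, b$retained)
  expect_identical(a$kappa, b$kappa)
  expect_equal(a$U, b$U)
  # weak sets map through the permutation
  expect_identical(lapply(a$weak_sets, function(s) sort(match(s, perm))),
                   b$weak_sets)
})

test_that("the alpha2 default tightens for very large feature spaces", {
  z_small <- matrix(0, 10, 2)
  expect_equal(screen_features(z_small)$alpha2, 0.05)
  z_big <- matrix(0, 10000, 2)
  expect_equal(screen_features(z_big)$alpha2, 0.01)
})
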