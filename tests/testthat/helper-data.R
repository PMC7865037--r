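# Small simulated survival studies used across the tests. Everything is
# generated in code at test time; seeds make the suite deterministic.

make_test_study <- function(n = 60, d = 4, beta = rep(0, d), seed = 1,
                            censor_rate = 0.3, study_id = "s1") {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, sprintf("f%02d", seq_len(d))))
  tt <- rexp(n, rate = exp(drop(X %*% beta)))
  cc <- rexp(n, rate = censor_rate)
  ms_study(time = pmin(tt, cc), event = as.integer(tt <= cc), features = X,
           study_id = study_id)
}

# the worked 3-subject example: times 1 < 2 < 3, all events, covariate
# (0, 1, 0); the score equation reduces to u^2 = 2 with u = exp(beta)
tiny3_study <- function() {
  ms_study(time = c(1, 2, 3), event = c(1, 1, 1),
           features = matrix(c(0, 1, 0), 3, 1, dimnames = list(NULL, "x")))
}

make_test_msdata <- function(K = 3, n = 60, d = 5, beta = rep(0, d),
                             seed = 1) {
  ms_data(lapply(seq_len(K), function(k)
    make_test_study(n = n, d = d, beta = beta, seed = seed + k,
                    study_id = paste0("s", k))))
}

# null multi-study data (no survival-associated features)
null_scenario <- function(n = 100, p = 200, K = 5)
  scenario_spec("custom", n = n, p = p, K = K, s = 2, mu_abs = 1e-8)
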