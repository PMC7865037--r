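#' Specify a multi-study survival simulation scenario
#'
#' The four named scenarios benchmark selection methods on K studies of n
#' subjects and p AR(1)-correlated Gaussian features, of which s (evenly
#' spaced) carry nonzero Cox coefficients in every study (common sparsity).
#' Survival times follow study-specific exponential-baseline Cox models;
#' censoring times are exponential.
#'
#' * `Homo-S` / `Homo-W`: coefficients identical across studies, +-1 (strong)
#'   or +-0.5 (weak); baseline hazard 1 and censoring rate 0.2 in every
#'   study.
#' * `Hetero-S` / `Hetero-W`: per-study coefficients drawn
#'   N(mu_j, hetero_sd^2) around +-1 or +-0.5 (zeros stay exactly zero);
#'   per-study baseline hazards drawn from Exponential(1) and censoring
#'   rates from \{0.1, 0.3, 0.5\}.
#'
#' @param scenario one of `"Homo-S"`, `"Homo-W"`, `"Hetero-S"`,
#'   `"Hetero-W"`, `"custom"`.
#' @param n per-study sample size.
#' @param p number of features.
#' @param K number of studies.
#' @param s number of true predictors (even; the first s/2 get -mu_abs, the
#'   next s/2 +mu_abs).
#' @param mu_abs base effect magnitude; defaults 1 (strong) / 0.5 (weak).
#' @param hetero_sd SD of the per-study coefficient perturbation (0 for
#'   homogeneous scenarios, 0.2 for heterogeneous).
#' @param rho AR(1) correlation of adjacent features.
#' @param lambda0 baseline hazard (constant over time). Ignored when
#'   `random_hazard`.
#' @param censor_rate exponential censoring rate. Ignored when
#'   `random_censoring`.
#' @param random_hazard draw each study's baseline hazard from
#'   Exponential(1).
#' @param random_censoring draw each study's censoring rate from
#'   `censor_pool`.
#' @param censor_pool candidate censoring rates for heterogeneous studies.
#' @return A list of class `ms_scenario`.
#' @export
scenario_spec <- function(scenario = c("Homo-S", "Homo-W", "Hetero-S",
                                       "Hetero-W", "custom"),
                          n = 100L, p = 2000L, K = 5L, s = 10L,
                          mu_abs = NULL, hetero_sd = NULL, rho = 0.5,
                          lambda0 = 1, censor_rate = 0.2,
                          random_hazard = NULL, random_censoring = NULL,
                          censor_pool = c(0.1, 0.3, 0.5)) {
  scenario <- match.arg(scenario)
  hetero <- scenario %in% c("Hetero-S", "Hetero-W")
  strong <- scenario %in% c("Homo-S", "Hetero-S")
  if (is.null(mu_abs)) mu_abs <- if (scenario == "custom" || strong) 1 else 0.5
  if (is.null(hetero_sd)) hetero_sd <- if (hetero) 0.2 else 0
  if (is.null(random_hazard)) random_hazard <- hetero
  if (is.null(random_censoring)) random_censoring <- hetero
  stopifnot(s %% 2 == 0, s <= p, s >= 0, mu_abs > 0, rho >= 0, rho < 1,
            n >= 2, K >= 1)
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 K = as.integer(K), s = as.integer(s), mu_abs = mu_abs,
                 hetero_sd = hetero_sd, rho = rho, lambda0 = lambda0,
                 censor_rate = censor_rate, random_hazard = random_hazard,
                 random_censoring = random_censoring,
                 censor_pool = censor_pool),
            class = "ms_scenario")
}

#' @export
print.ms_scenario <- function(x, ...) {
  cat(sprintf("<ms_scenario %s>  n = %d, p = %d, K = %d, s = %d, |mu| = %g, hetero_sd = %g, rho = %g\n",
              x$scenario, x$n, x$p, x$K, x$s, x$mu_abs, x$hetero_sd, x$rho))
  invisible(x)
}

#' Draw the ground truth of a scenario
#'
#' Places the s true predictors at evenly spaced positions
#' `1, 1 + floor(p/s), 1 + 2*floor(p/s), ...` (far apart relative to the
#' AR(1) range, so the true features are effectively uncorrelated), assigns
#' base effects -mu_abs to the first half and +mu_abs to the second, and
#' draws per-study coefficients, baseline hazards and censoring rates as the
#' scenario prescribes. Uses the current RNG state.
#'
#' @param spec an [scenario_spec].
#' @return An object of class `ms_truth`: `true_features` (indices),
#'   `beta_true` (p x K), `lambda0` (K), `censor_rate` (K).
#' @export
make_truth <- function(spec) {
  p <- spec$p; K <- spec$K; s <- spec$s
  pos <- if (s > 0) 1L + (0:(s - 1L)) * (p %/% s) else integer(0)
  mu <- numeric(p)
  if (s > 0) mu[pos] <- rep(c(-spec$mu_abs, spec$mu_abs), each = s / 2)
  beta <- matrix(rep(mu, K), p, K)
  if (spec$hetero_sd > 0 && s > 0)
    beta[pos, ] <- matrix(rnorm(s * K, mean = rep(mu[pos], K),
                                sd = spec$hetero_sd), s, K)
  lambda0 <- if (spec$random_hazard) rexp(K, 1) else rep(spec$lambda0, K)
  cr <- if (spec$random_censoring)
    sample(spec$censor_pool, K, replace = TRUE) else rep(spec$censor_rate, K)
  structure(list(true_features = pos, beta_true = beta, lambda0 = lambda0,
                 censor_rate = cr, p = p, K = K, s = s),
            class = "ms_truth")
}

# AR(1) Gaussian features by the recursion x_j = rho x_{j-1} +
# sqrt(1-rho^2) e_j: O(np) instead of a p x p covariance factorization.
ar1_features <- function(n, p, rho) {
  X <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    w <- sqrt(1 - rho^2)
    for (j in 2:p) X[, j] <- rho * X[, j - 1] + w * X[, j]
  }
  X
}

#' Simulate one study from a drawn truth
#'
#' Features are N_p(0, Sigma) with Sigma_jj' = rho^|j-j'|; the true survival
#' time is exponential with rate lambda0 * exp(X beta) (constant baseline
#' hazard), the censoring time exponential with the study's censoring rate;
#' the observed time is the minimum and the event indicator is 1 when the
#' event precedes censoring. Uses the current RNG state.
#'
#' @param truth an `ms_truth`.
#' @param spec the matching [scenario_spec].
#' @param k study index in 1..K.
#' @return An [ms_study].
#' @export
simulate_study <- function(truth, spec, k) {
  stopifnot(k >= 1, k <= spec$K)
  n <- spec$n; p <- spec$p
  X <- ar1_features(n, p, spec$rho)
  eta <- if (truth$s > 0)
    drop(X[, truth$true_features, drop = FALSE] %*%
           truth$beta_true[truth$true_features, k]) else numeric(n)
  T <- rexp(n, rate = truth$lambda0[k] * exp(eta))
  C <- rexp(n, rate = truth$censor_rate[k])
  y <- pmin(T, C)
  delta <- as.integer(T <= C)
  ms_study(time = y, event = delta, features = X,
           feature_ids = sprintf("g%04d", seq_len(p)),
           study_id = sprintf("study%d", k))
}

#' Simulate a full multi-study dataset with known truth
#'
#' Derives one child seed per study (plus one for the truth draw) from
#' `seed`, so the dataset is fully reproducible and studies are independent
#' streams.
#'
#' @param spec an [scenario_spec].
#' @param seed integer master seed.
#' @return A list of class `ms_sim` with `data` (an [ms_data]), `truth`
#'   (an `ms_truth`) and `spec`.
#' @export
simulate_scenario <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ms_scenario"))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, spec$K + 1L)
  set.seed(seeds[1])
  truth <- make_truth(spec)
  studies <- lapply(seq_len(spec$K), function(k) {
    set.seed(seeds[k + 1L])
    simulate_study(truth, spec, k)
  })
  structure(list(data = ms_data(studies), truth = truth, spec = spec,
                 seed = seed),
            class = "ms_sim")
}

#' @export
print.ms_sim <- function(x, ...) {
  print(x$spec)
  print(x$data)
  invisible(x)
}
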