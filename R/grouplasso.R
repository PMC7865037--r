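`%||%` <- function(a, b) if (is.null(a)) b else a

#' ADMM solver control settings
#'
#' @param rho initial augmented-Lagrangian parameter (adapted at run time by
#'   residual balancing unless `adapt_rho = FALSE`).
#' @param eps_abs,eps_rel absolute / relative stopping tolerances on the
#'   primal and dual residuals.
#' @param max_iter maximum ADMM iterations.
#' @param inner_iter damped Newton steps per study per beta-update.
#' @param hess_freq iterations between refreshes of the Cholesky factor of
#'   the smooth subproblem Hessian (the Cox Hessian varies slowly, and the
#'   step is safeguarded by exact-objective step-halving).
#' @param adapt_rho residual-balancing adaptation of rho.
#' @param adapt_every iterations between residual-balancing checks.
#' @param max_halv maximum step-halvings per Newton step.
#' @param kkt_tol tolerance for the post-hoc group-KKT verification, relative
#'   to max(1, lambda).
#' @param trace record the penalized objective at every iteration
#'   (diagnostics; switched off for cross-validation fold fits).
#' @return A list of class `admm_control`.
#' @export
admm_control <- function(rho = 1, eps_abs = 1e-5, eps_rel = 1e-4,
                         max_iter = 2000L, inner_iter = 2L, hess_freq = 10L,
                         adapt_rho = TRUE, max_halv = 20L, kkt_tol = 1e-3,
                         trace = TRUE, adapt_every = 5L) {
  structure(list(rho = rho, eps_abs = eps_abs, eps_rel = eps_rel,
                 max_iter = as.integer(max_iter),
                 inner_iter = as.integer(inner_iter),
                 hess_freq = as.integer(hess_freq), adapt_rho = adapt_rho,
                 max_halv = as.integer(max_halv), kkt_tol = kkt_tol,
                 trace = isTRUE(trace),
                 adapt_every = as.integer(adapt_every)),
            class = "admm_control")
}

#' Group-lasso penalized stacked partial log-likelihood
#'
#' The stage-2 objective: the sum over studies of Cox partial
#' log-likelihoods minus a cross-study group-lasso penalty that groups the
#' coefficients of one feature across all studies,
#' \deqn{\sum_{k=1}^K l_k(\beta^{(k)}) - \lambda \sum_j \|\vec\beta_j\|_2,
#'   \qquad \vec\beta_j = (\beta_j^{(1)}, \ldots, \beta_j^{(K)}).}
#' The solver maximizes this (internally minimizing its negation).
#'
#' @param data an [ms_data] (typically restricted to the screened features).
#' @param beta d x K coefficient matrix (columns = studies).
#' @param lambda nonnegative penalty weight.
#' @return The penalized objective value.
#' @export
stacked_objective <- function(data, beta, lambda = 0) {
  beta <- as.matrix(beta)
  K <- n_studies(data)
  if (ncol(beta) != K || nrow(beta) != n_features(data))
    stop("beta must be d x K matching the data")
  stopifnot(lambda >= 0)
  ll <- 0
  for (k in seq_len(K)) {
    ss <- study_sorted(data$studies[[k]])
    ll <- ll + .cox_loglik_cpp(ss$Xt, ss$delta, ss$risk_end, beta[, k])
  }
  ll - lambda * sum(sqrt(rowSums(beta^2)))
}

# Per-study sorted design; standardization is handled by the caller.
gl_prep <- function(data) {
  lapply(data$studies, study_sorted)
}

# d x K matrix of per-study partial-likelihood score vectors at beta.
stacked_score <- function(prep, beta) {
  vapply(seq_along(prep), function(k)
    as.numeric(.cox_grad_cpp(prep[[k]]$Xt, prep[[k]]$delta,
                             prep[[k]]$risk_end, beta[, k])),
    numeric(nrow(beta)))
}

#' Smallest penalty with an all-zero solution
#'
#' By the group-KKT conditions the all-zero coefficient matrix solves the
#' penalized problem exactly when \eqn{\lambda \ge \max_j \|g_j\|_2}, where
#' \eqn{g_j} is the K-vector of per-study score components for feature j at
#' beta = 0. This is the natural top of a pathwise grid.
#'
#' @param data an [ms_data] restricted to the candidate features.
#' @param standardize standardize features within study first (the solver's
#'   default scale).
#' @return lambda_max (nonnegative scalar).
#' @export
compute_lambda_max <- function(data, standardize = TRUE) {
  if (standardize) data <- standardize_ms(data)
  prep <- gl_prep(data)
  G <- stacked_score(prep, matrix(0, n_features(data), n_studies(data)))
  max(sqrt(rowSums(as.matrix(G)^2)))
}

#' Cross-study group-lasso Cox fit at one penalty value
#'
#' Maximizes [stacked_objective] by consensus ADMM: the smooth part (sum of
#' negated partial log-likelihoods) is handled by damped Newton steps per
#' study, the penalty by a row-wise group soft-threshold, with a scaled dual
#' update and residual-balancing adaptation of rho. Selection is read off
#' the exactly-sparse thresholded iterate, so a feature is selected in all
#' studies or in none.
#'
#' @param data an [ms_data] restricted to the candidate (screened) features.
#' @param lambda nonnegative penalty.
#' @param init optional d x K warm-start matrix (standardized scale).
#' @param control an [admm_control].
#' @param standardize standardize features to unit variance within study
#'   before solving (penalty fairness across features). Coefficients are
#'   reported on the standardized scale in `beta` and back-transformed in
#'   `beta_raw`.
#' @return An object of class `group_cox_fit`: `beta` (d x K, exactly sparse
#'   rows), `beta_raw`, `selected_idx`, `selected` (ids), `d2`, `lambda`,
#'   `objective_trace` (negated penalized objective per iteration),
#'   `primal_residual`, `dual_residual`, `n_iter`, `converged`, `kkt`.
#' @export
group_cox_admm <- function(data, lambda, init = NULL,
                           control = admm_control(), standardize = TRUE) {
  stopifnot(inherits(data, "ms_data"), lambda >= 0)
  sdata <- if (standardize) standardize_ms(data) else data
  prep <- gl_prep(sdata)
  d <- n_features(data)
  K <- n_studies(data)
  if (is.null(init)) init <- matrix(0, d, K)
  fit <- admm_core(prep, lambda, init, control)
  finish_group_fit(fit, data, sdata, lambda, control)
}

admm_core <- function(prep, lambda, init, control) {
  Xts <- lapply(prep, `[[`, "Xt")
  deltas <- lapply(prep, `[[`, "delta")
  res <- lapply(prep, `[[`, "risk_end")
  B <- as.matrix(init)
  U <- attr(init, "U")
  Z <- attr(init, "Z")
  if (is.null(U)) U <- matrix(0, nrow(B), ncol(B))
  if (is.null(Z)) Z <- B
  rho0 <- attr(init, "rho")
  if (!is.null(rho0)) control$rho <- rho0   # keep dual scaling consistent
  .admm_group_cox_cpp(Xts, deltas, res, lambda, B, Z, U, control$rho,
                      control$eps_abs, control$eps_rel, control$max_iter,
                      control$inner_iter, control$hess_freq,
                      isTRUE(control$adapt_rho), control$max_halv,
                      isTRUE(control$trace),
                      as.integer(control$adapt_every %||% 5L))
}

finish_group_fit <- function(fit, data, sdata, lambda, control) {
  Z <- fit$Z
  rn <- sqrt(rowSums(Z^2))
  Z[rn < 1e-10, ] <- 0                       # hard zeroing
  dimnames(Z) <- list(data$feature_ids, names(data$studies))
  sel <- which(sqrt(rowSums(Z^2)) > 0)
  scaling <- attr(sdata, "scaling")
  beta_raw <- Z
  if (!is.null(scaling))
    for (k in seq_len(ncol(Z))) beta_raw[, k] <- Z[, k] / scaling[[k]]$scale
  out <- structure(list(beta = Z, beta_raw = beta_raw,
                        selected_idx = sel,
                        selected = data$feature_ids[sel], d2 = length(sel),
                        lambda = lambda,
                        objective_trace = fit$objective_trace,
                        primal_residual = fit$primal_residual,
                        dual_residual = fit$dual_residual,
                        n_iter = fit$n_iter, converged = isTRUE(fit$converged),
                        rho = fit$rho),
                   class = "group_cox_fit")
  # warm-start payload for pathwise fitting
  attr(out, "state") <- structure(fit$B, Z = fit$Z, U = fit$U, rho = fit$rho)
  out$kkt <- kkt_check(out, sdata, standardize = FALSE, tol = control$kkt_tol)
  out
}

#' @export
print.group_cox_fit <- function(x, ...) {
  cat(sprintf("group-lasso Cox fit: lambda = %.4g, selected d2 = %d of %d, %s in %d ADMM iter\n",
              x$lambda, x$d2, nrow(x$beta),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  residuals: primal %.3g, dual %.3g; KKT %s (max violation %.3g)\n",
              x$primal_residual, x$dual_residual,
              if (x$kkt$pass) "ok" else "VIOLATED", x$kkt$max_violation))
  invisible(x)
}

#' @export
coef.group_cox_fit <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") object$beta else object$beta_raw
}

#' Verify group-KKT conditions of a fitted group-lasso Cox model
#'
#' At an exact optimum, every selected feature j satisfies
#' \eqn{g_j(\hat\beta) = \lambda \vec\beta_j / \|\vec\beta_j\|_2} and every
#' unselected feature satisfies \eqn{\|g_j(\hat\beta)\|_2 \le \lambda}, with
#' \eqn{g_j} the K-vector of per-study score components. Violations are
#' measured relative to max(1, lambda).
#'
#' @param fit a `group_cox_fit`.
#' @param data the [ms_data] the fit was computed on.
#' @param standardize whether `data` still needs the within-study
#'   standardization used by the solver.
#' @param tol relative tolerance.
#' @return List with `pass`, `max_violation`, and per-side maxima.
#' @export
kkt_check <- function(fit, data, standardize = TRUE, tol = 1e-3) {
  sdata <- if (standardize) standardize_ms(data) else data
  prep <- gl_prep(sdata)
  G <- as.matrix(stacked_score(prep, fit$beta))
  lam <- fit$lambda
  rn <- sqrt(rowSums(fit$beta^2))
  sel <- rn > 0
  viol_sel <- 0
  if (any(sel)) {
    dir <- fit$beta[sel, , drop = FALSE] / rn[sel]
    viol_sel <- max(sqrt(rowSums((G[sel, , drop = FALSE] - lam * dir)^2)))
  }
  viol_un <- 0
  if (any(!sel)) {
    gn <- sqrt(rowSums(G[!sel, , drop = FALSE]^2))
    viol_un <- max(c(0, gn - lam))
  }
  scale <- max(1, lam)
  mv <- max(viol_sel, viol_un) / scale
  list(pass = mv <= tol, max_violation = mv,
       selected_violation = viol_sel / scale,
       unselected_violation = viol_un / scale)
}

#' Pathwise group-lasso Cox fits
#'
#' Fits [group_cox_admm] along a decreasing log-spaced grid from
#' `lambda_max` (empty selection guaranteed) down to
#' `lambda_min_ratio * lambda_max`, warm-starting each fit from the previous
#' one.
#'
#' @param data an [ms_data] restricted to the candidate features.
#' @param nlambda number of grid points.
#' @param lambda_min_ratio ratio of the smallest to the largest penalty.
#' @param lambdas optional explicit decreasing grid (overrides the above).
#' @param control an [admm_control].
#' @param standardize see [group_cox_admm].
#' @param warm warm-start along the path.
#' @return An object of class `group_cox_path`: `lambdas`, `fits` (list of
#'   `group_cox_fit`), `lambda_max`, `n_selected`.
#' @export
group_cox_path <- function(data, nlambda = 50L, lambda_min_ratio = 0.01,
                           lambdas = NULL, control = admm_control(),
                           standardize = TRUE, warm = TRUE) {
  sdata <- if (standardize) standardize_ms(data) else data
  prep <- gl_prep(sdata)
  d <- n_features(data)
  K <- n_studies(data)
  lmax <- max(sqrt(rowSums(as.matrix(stacked_score(prep, matrix(0, d, K)))^2)))
  if (is.null(lambdas)) {
    stopifnot(nlambda >= 2L, lambda_min_ratio > 0, lambda_min_ratio < 1)
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  }
  init <- matrix(0, d, K)
  fits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    raw <- admm_core(prep, lambdas[i], init, control)
    fits[[i]] <- finish_group_fit(raw, data, sdata, lambdas[i], control)
    if (warm) init <- attr(fits[[i]], "state")
  }
  structure(list(lambdas = lambdas, fits = fits, lambda_max = lmax,
                 n_selected = vapply(fits, `[[`, 0L, "d2")),
            class = "group_cox_path")
}

#' @export
print.group_cox_path <- function(x, ...) {
  cat(sprintf("group-lasso Cox path: %d lambdas in [%.4g, %.4g] (lambda_max = %.4g)\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas), x$lambda_max))
  cat("  selected sizes:", paste(x$n_selected, collapse = " "), "\n")
  invisible(x)
}

#' @rdname admm_control
#' @details `cv_admm_control()` is the default for cross-validation fold
#'   fits: looser stopping tolerances, a single damped Newton step per
#'   sweep, a rarer Hessian refresh and no objective trace. The fold
#'   criterion is statistical noise-dominated, so the last digits of the
#'   iterate are irrelevant there.
#' @export
cv_admm_control <- function(rho = 1, eps_abs = 3e-4, eps_rel = 3e-3,
                            max_iter = 2000L, inner_iter = 1L,
                            hess_freq = 20L, adapt_rho = TRUE,
                            max_halv = 20L, kkt_tol = 1e-3,
                            adapt_every = 5L) {
  admm_control(rho = rho, eps_abs = eps_abs, eps_rel = eps_rel,
               max_iter = max_iter, inner_iter = inner_iter,
               hess_freq = hess_freq, adapt_rho = adapt_rho,
               max_halv = max_halv, kkt_tol = kkt_tol, trace = FALSE,
               adapt_every = adapt_every)
}
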