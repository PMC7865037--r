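#' Cox partial log-likelihood (Breslow ties)
#'
#' Evaluates the Cox partial log-likelihood
#' \deqn{l(\beta) = \sum_i \Delta_i \big[\eta_i - \log \sum_{j \in R(Y_i)}
#'   e^{\eta_j}\big], \qquad \eta = X\beta,}
#' where the risk set \eqn{R(t) = \{j : Y_j \ge t\}} includes the subject at
#' its own event time and tied event times share one risk set (Breslow
#' convention). The value is always \eqn{\le 0}.
#'
#' @param study an [ms_study].
#' @param beta coefficient vector, one entry per element of `features`.
#' @param features columns to use (indices or identifiers); defaults to all.
#' @return The partial log-likelihood. If the study has no events the empty
#'   sum is 0 and the result carries attribute `no_events = TRUE`.
#' @export
cox_partial_loglik <- function(study, beta, features = NULL) {
  if (!is.null(features))
    features <- resolve_features(study$feature_ids, features)
  else features <- seq_along(study$feature_ids)
  if (length(beta) != length(features))
    stop("beta length must equal the number of features used")
  if (sum(study$event) == 0) {
    warning("study has no events: partial log-likelihood is an empty sum")
    return(structure(0, no_events = TRUE))
  }
  ss <- study_sorted(study, features)
  .cox_loglik_cpp(ss$Xt, ss$delta, ss$risk_end, as.numeric(beta))
}

#' Maximum partial likelihood Cox fit
#'
#' Newton-Raphson maximization of [cox_partial_loglik] with step-halving.
#' Convergence is declared when every score component is below `tol` in
#' absolute value. A monotone-likelihood (separation) fit is detected when a
#' coefficient runs past `bcap` before the score converges; the returned
#' coefficients are the last iterate and the affected coefficients are
#' flagged.
#'
#' @param study an [ms_study].
#' @param features columns to fit (indices or identifiers); defaults to all.
#' @param init optional starting coefficients (default 0).
#' @param tol score tolerance for convergence.
#' @param maxit maximum Newton iterations.
#' @param bcap divergence cap on |beta| signalling monotone likelihood.
#' @return An object of class `mscox_fit` with elements `beta`, `loglik`,
#'   `information` (observed information, i.e. negative Hessian), `se`,
#'   `converged`, `n_iter`, `flagged_separation`.
#' @export
cox_fit <- function(study, features = NULL, init = NULL, tol = 1e-8,
                    maxit = 50L, bcap = 15) {
  if (!is.null(features))
    idx <- resolve_features(study$feature_ids, features)
  else idx <- seq_along(study$feature_ids)
  if (sum(study$event) == 0) stop("no_events")
  X <- study$features[, idx, drop = FALSE]
  if (any(apply(X, 2, function(x) diff(range(x))) < 1e-12))
    stop("degenerate_covariate")
  ss <- study_sorted(study, idx)
  d <- length(idx)
  if (is.null(init)) init <- numeric(d)
  res <- .cox_newton_cpp(ss$Xt, ss$delta, ss$risk_end, as.numeric(init),
                         0, numeric(d), tol, as.integer(maxit), 20L, bcap)
  beta <- drop(res$beta)
  names(beta) <- study$feature_ids[idx]
  info <- res$neg_hessian
  dimnames(info) <- list(names(beta), names(beta))
  flagged <- rep(isTRUE(res$separation), d) & abs(beta) >= bcap
  se <- rep(NA_real_, d)
  dg <- diag(as.matrix(info))
  ok <- dg > 1e-12
  if (any(ok)) {
    vi <- try(solve(info), silent = TRUE)
    if (!inherits(vi, "try-error")) se <- sqrt(pmax(diag(as.matrix(vi)), 0))
  }
  names(se) <- names(beta)
  structure(list(beta = beta, loglik = res$loglik, information = info,
                 se = se, score = drop(res$score),
                 converged = isTRUE(res$converged), n_iter = res$n_iter,
                 flagged_separation = flagged, study_id = study$study_id,
                 bcap = bcap),
            class = "mscox_fit")
}

#' @export
print.mscox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s): %d coefficient(s), partial loglik = %.4f, %s in %d iter\n",
              x$study_id, length(x$beta),
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  print(data.frame(beta = x$beta, se = x$se,
                   z = x$beta / x$se, row.names = names(x$beta)))
  if (any(x$flagged_separation))
    cat("separation flagged for:", paste(names(x$beta)[x$flagged_separation],
                                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mscox_fit <- function(object, ...) object$beta

#' Standardized marginal coefficient
#'
#' For a marginal (single-covariate) Cox fit, returns
#' \eqn{\tilde z = I(\tilde\beta)^{1/2}\,\tilde\beta = \tilde\beta /
#' \mathrm{SE}(\tilde\beta)}, which is asymptotically standard normal when
#' the true coefficient is zero. A separation-flagged fit carries the
#' strongest possible evidence of association, so its z is reported as
#' `sign(beta) * zcap` rather than the unstable ratio.
#'
#' @param fit an `mscox_fit` from a single-feature model.
#' @param zcap value substituted for diverging fits.
#' @return The standardized coefficient (scalar).
#' @export
standardized_z <- function(fit, zcap = 37) {
  if (length(fit$beta) != 1L)
    stop("standardized_z is defined for marginal (single-covariate) fits")
  info <- as.numeric(fit$information)
  if (!is.finite(info) || info <= 1e-12) stop("degenerate_covariate")
  if (any(fit$flagged_separation)) return(sign(fit$beta[[1]]) * zcap)
  unname(fit$beta[[1]] * sqrt(info))
}
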