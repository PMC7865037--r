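#' Marginal Cox scan over all features and studies
#'
#' Fits the marginal Cox model \eqn{\lambda^{(k)}(t|x_j) = \lambda_0^{(k)}(t)
#' \exp(x_j \beta_j^{(k)})} for every feature j in every study k and returns
#' the p x K matrices of marginal estimates, standard errors and standardized
#' coefficients \eqn{\tilde z_j^{(k)} = \tilde\beta_j^{(k)} /
#' \mathrm{SE}(\tilde\beta_j^{(k)})}. Per-cell failures never abort the scan:
#' a constant covariate is flagged degenerate and contributes z = 0 (no
#' evidence of association in that study); a monotone-likelihood fit is
#' flagged and contributes z = sign(beta) * zcap.
#'
#' @param data an [ms_data]. Every study must have at least one event.
#' @param tol,maxit Newton convergence settings per marginal fit.
#' @param bcap divergence cap on |beta| (separation detection).
#' @param zcap standardized value substituted for separation fits.
#' @param allow_no_events treat a study without any events as carrying no
#'   evidence (all its cells flagged degenerate, z = 0) instead of
#'   stopping. Used by the fold-level rescans in cross-validation, where a
#'   training split of a nearly-eventless study can lose its last event.
#' @return An object of class `ms_marginal` with p x K matrices `z`, `beta`,
#'   `se`, integer matrix `flags` (0 ok, 1 degenerate, 2 separation), and
#'   `feature_ids`.
#' @export
marginal_scan <- function(data, tol = 1e-8, maxit = 50L, bcap = 15, zcap = 37,
                          allow_no_events = FALSE) {
  stopifnot(inherits(data, "ms_data"))
  ev <- vapply(data$studies, function(s) sum(s$event), 0)
  if (any(ev == 0) && !allow_no_events)
    stop("every study must contain at least one event; none in: ",
         paste(names(data$studies)[ev == 0], collapse = ", "))
  p <- n_features(data)
  K <- n_studies(data)
  dn <- list(data$feature_ids, names(data$studies))
  z <- beta <- se <- matrix(NA_real_, p, K, dimnames = dn)
  flags <- matrix(0L, p, K, dimnames = dn)
  for (k in seq_len(K)) {
    if (ev[k] == 0) {
      z[, k] <- 0
      flags[, k] <- 1L
      next
    }
    ss <- study_sorted(data$studies[[k]])
    res <- .marginal_scan_cpp(ss$X, ss$delta, ss$risk_end, tol,
                              as.integer(maxit), 20L, bcap)
    bk <- res$beta
    sk <- res$se
    fk <- res$flags
    zk <- bk / sk
    zk[fk == 1L] <- 0           # constant covariate: no evidence either way
    sep <- fk == 2L
    zk[sep] <- sign(bk[sep]) * zcap
    z[, k] <- zk
    beta[, k] <- bk
    se[, k] <- sk
    flags[, k] <- fk
  }
  structure(list(z = z, beta = beta, se = se, flags = flags,
                 feature_ids = data$feature_ids,
                 study_ids = names(data$studies), zcap = zcap),
            class = "ms_marginal")
}

#' @export
print.ms_marginal <- function(x, ...) {
  cat(sprintf("<ms_marginal>  p = %d features x K = %d studies\n",
              nrow(x$z), ncol(x$z)))
  ndeg <- sum(x$flags == 1L)
  nsep <- sum(x$flags == 2L)
  if (ndeg) cat(sprintf("  degenerate cells: %d\n", ndeg))
  if (nsep) cat(sprintf("  separation-flagged cells: %d\n", nsep))
  cat(sprintf("  max |z| per study: %s\n",
              paste(sprintf("%.2f", apply(abs(x$z), 2, max)), collapse = ", ")))
  invisible(x)
}
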