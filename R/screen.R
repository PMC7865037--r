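#' Partition studies into strong-signal and potential-zero sets
#'
#' Step 1 of the aggregation screening. For one feature, the studies whose
#' standardized marginal coefficient fails to clear the two-sided normal
#' threshold at level `alpha1` are collected as the set of studies with
#' potential zero coefficients:
#' \deqn{\hat L_j = \{k : |\tilde z_j^{(k)}| \le \Phi^{-1}(1 - \alpha_1/2)\}.}
#'
#' @param z_row numeric K-vector of standardized marginal coefficients for
#'   one feature.
#' @param alpha1 two-sided level separating strong from weak signals.
#' @return Integer vector of study indices with potential zero coefficients.
#' @export
partition_studies <- function(z_row, alpha1 = 1e-4) {
  stopifnot(alpha1 > 0, alpha1 < 1)
  which(abs(z_row) <= qnorm(1 - alpha1 / 2))
}

#' Aggregate chi-square test over the potential-zero studies
#'
#' Step 2 of the aggregation screening. The squared standardized coefficients
#' of the studies in the weak set are summed,
#' \eqn{U_j = \sum_{k \in \hat L_j} \tilde z_j^{(k)2}}, which is approximately
#' \eqn{\chi^2_{\hat\kappa_j}} under the null; the feature is retained when
#' the aggregate exceeds the upper `alpha2` quantile, or automatically when
#' the weak set is empty (every study individually strong).
#'
#' @param z_row numeric K-vector of standardized marginal coefficients.
#' @param weak_set integer indices of studies with potential zero
#'   coefficients (from [partition_studies]).
#' @param alpha2 screening level.
#' @return List with `U` (0 for an empty weak set), `threshold` and
#'   `retained`.
#' @export
aggregate_test <- function(z_row, weak_set, alpha2 = 0.05) {
  stopifnot(alpha2 > 0, alpha2 < 1)
  kappa <- length(weak_set)
  if (kappa == 0L)
    return(list(U = 0, threshold = NA_real_, retained = TRUE))
  U <- sum(z_row[weak_set]^2)
  thr <- qchisq(1 - alpha2, df = kappa)
  list(U = U, threshold = thr, retained = U > thr)
}

#' Two-step aggregation screening over all features
#'
#' Applies [partition_studies] and [aggregate_test] to every row of the
#' standardized-coefficient matrix and returns the retained feature set
#' \eqn{\hat M^{[1]}}. This is the screening stage of the two-stage
#' multi-study selection procedure: it keeps features that are either strong
#' in every study or whose aggregate evidence across their weak studies is
#' strong.
#'
#' @param stats an `ms_marginal` from [marginal_scan], or a p x K numeric
#'   matrix of standardized coefficients.
#' @param alpha1 step-1 two-sided level (default 1e-4).
#' @param alpha2 step-2 screening level. Default 0.05, tightened to 0.01 when
#'   p >= 10000 (the recommended choice for very large feature spaces).
#' @return An object of class `ms_screen` with per-feature `weak_sets`
#'   (list), `kappa`, `U`, `threshold`, logical `retained`, index set
#'   `retained_idx`, `d1 = length(retained_idx)` and the levels used.
#' @export
screen_features <- function(stats, alpha1 = 1e-4, alpha2 = NULL) {
  z <- if (inherits(stats, "ms_marginal")) stats$z else as.matrix(stats)
  p <- nrow(z)
  K <- ncol(z)
  ids <- if (inherits(stats, "ms_marginal")) stats$feature_ids else rownames(z)
  if (is.null(ids)) ids <- paste0("f", seq_len(p))
  if (is.null(alpha2)) alpha2 <- if (p >= 10000) 0.01 else 0.05
  stopifnot(alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1)
  thr1 <- qnorm(1 - alpha1 / 2)
  weak <- abs(z) <= thr1
  kappa <- rowSums(weak)
  U <- rowSums(z^2 * weak)
  thr2 <- qchisq(1 - alpha2, df = pmax(kappa, 1L))
  thr2[kappa == 0L] <- NA_real_
  retained <- kappa == 0L | U > thr2
  weak_sets <- apply(weak, 1L, which, simplify = FALSE)
  structure(list(weak_sets = weak_sets, kappa = as.integer(kappa), U = U,
                 threshold = thr2, retained = retained,
                 retained_idx = which(retained), d1 = sum(retained),
                 alpha1 = alpha1, alpha2 = alpha2, z_threshold = thr1,
                 feature_ids = ids, K = K),
            class = "ms_screen")
}

#' @export
print.ms_screen <- function(x, ...) {
  cat(sprintf("<ms_screen>  alpha1 = %g, alpha2 = %g\n", x$alpha1, x$alpha2))
  cat(sprintf("  retained d1 = %d of %d features (%.2f%%)\n", x$d1,
              length(x$retained), 100 * x$d1 / length(x$retained)))
  cat("  kappa distribution:\n")
  print(table(kappa = x$kappa))
  invisible(x)
}
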