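#' Minimum-standardized-coefficient screening (MinPSIS)
#'
#' The multi-study extension of principled Cox sure independence screening:
#' features are ranked by \eqn{\min_k |\tilde z_j^{(k)}|}, the minimum
#' absolute standardized marginal coefficient over studies, and the top d
#' are retained. Ties are broken by feature order (first wins).
#'
#' @param stats an `ms_marginal` from [marginal_scan], or a p x K matrix of
#'   standardized coefficients.
#' @param d number of features to retain (the conventional conservative
#'   choice is d = n, the per-study sample size).
#' @return Integer vector of the retained feature indices, in feature order.
#' @export
min_psis_screen <- function(stats, d) {
  z <- if (inherits(stats, "ms_marginal")) stats$z else as.matrix(stats)
  p <- nrow(z)
  stopifnot(d >= 1, d <= p)
  minz <- apply(abs(z), 1, min)
  sort(order(minz, decreasing = TRUE)[seq_len(d)])  # stable: ties -> first
}

# Event-stratified fold labels for one study (glmnet foldid).
study_foldid <- function(study, nfolds) {
  f <- integer(length(study$time))
  for (g in c(0L, 1L)) {
    idx <- which(study$event == g)
    f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  f
}

#' Single-study penalized Cox selection
#'
#' Lasso or elastic-net penalized Cox regression within one study, with the
#' penalty weight chosen by within-study cross-validated partial likelihood
#' (no one-standard-error rule), as fitted by \pkg{glmnet}. Returns the
#' features with nonzero coefficients at the optimal penalty.
#'
#' @param study an [ms_study].
#' @param features candidate columns (indices or identifiers); default all.
#' @param penalty `"lasso"` (mixing 1) or `"elastic_net"` (mixing 0.5).
#' @param nfolds folds for the within-study cross-validation.
#' @param seed seed for the fold randomization.
#' @param alpha elastic-net mixing parameter override.
#' @return Integer vector of selected feature indices (positions in the
#'   study's full feature set).
#' @export
per_study_penalized_cox <- function(study, features = NULL,
                                    penalty = c("lasso", "elastic_net"),
                                    nfolds = 5L, seed = NULL, alpha = NULL) {
  penalty <- match.arg(penalty)
  if (is.null(alpha)) alpha <- if (penalty == "lasso") 1 else 0.5
  idx <- if (is.null(features)) seq_along(study$feature_ids)
         else resolve_features(study$feature_ids, features)
  if (!is.null(seed)) set.seed(seed)
  foldid <- study_foldid(study, nfolds)
  y <- cbind(time = study$time, status = study$event)
  x <- study$features[, idx, drop = FALSE]
  # glmnet can truncate the low end of its path on ill-conditioned folds;
  # the usable fits are returned and the warning is noise here
  cvfit <- suppressWarnings(glmnet::cv.glmnet(x, y, family = "cox",
                                              alpha = alpha, foldid = foldid))
  b <- as.numeric(coef(cvfit, s = "lambda.min"))
  idx[b != 0]
}

#' Intersection-based multi-study baseline methods
#'
#' The four comparison methods: each study is analyzed separately with
#' penalized Cox regression (lasso or elastic net, CV-tuned within study)
#' and the per-study selections are intersected. The `MinPSIS-` variants
#' first reduce the feature space to the top d features by
#' [min_psis_screen] (default d = the smallest study sample size).
#'
#' @param data an [ms_data].
#' @param method one of `"InterCoxLasso"`, `"InterCoxNet"`,
#'   `"MinPSIS-InterCoxLasso"`, `"MinPSIS-InterCoxNet"`.
#' @param scan optional precomputed [marginal_scan] (used by the MinPSIS
#'   variants).
#' @param d retained screening size for the MinPSIS variants.
#' @param nfolds within-study CV folds.
#' @param seed seed controlling all fold randomizations.
#' @return An object of class `ms_baseline`: `method`,
#'   `per_study_selected` (list of index sets), `selected_idx`
#'   (intersection), `selected` (ids), `d` (screening size or NA).
#' @export
run_baseline <- function(data, method = c("InterCoxLasso", "InterCoxNet",
                                          "MinPSIS-InterCoxLasso",
                                          "MinPSIS-InterCoxNet"),
                         scan = NULL, d = NULL, nfolds = 5L, seed = NULL) {
  method <- match.arg(method)
  two_stage <- startsWith(method, "MinPSIS")
  penalty <- if (grepl("Lasso$", method)) "lasso" else "elastic_net"
  cand <- seq_along(data$feature_ids)
  if (two_stage) {
    if (is.null(scan)) scan <- marginal_scan(data)
    if (is.null(d))
      d <- min(vapply(data$studies, function(s) length(s$time), 0L))
    d <- as.integer(min(d, length(cand)))
    cand <- min_psis_screen(scan, d)
  } else d <- NA_integer_
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_studies(data))
  per <- lapply(seq_len(n_studies(data)), function(k)
    per_study_penalized_cox(data$studies[[k]], features = cand,
                            penalty = penalty, nfolds = nfolds,
                            seed = seeds[k]))
  sel <- Reduce(intersect, per)
  structure(list(method = method, per_study_selected = per,
                 selected_idx = sort(sel),
                 selected = data$feature_ids[sort(sel)], d = d),
            class = "ms_baseline")
}

#' @export
print.ms_baseline <- function(x, ...) {
  cat(sprintf("<ms_baseline %s>%s\n", x$method,
              if (!is.na(x$d)) sprintf("  (screened to d = %d)", x$d) else ""))
  cat(sprintf("  per-study selections: %s; intersection: %d feature(s)\n",
              paste(lengths(x$per_study_selected), collapse = ", "),
              length(x$selected_idx)))
  if (length(x$selected)) cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
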