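#' Two-stage selection of survival-associated features across studies
#'
#' The main fitting function. Stage 1 screens the feature space by the
#' two-step aggregation of standardized marginal Cox coefficients across
#' studies ([marginal_scan] + [screen_features]): a feature survives when it
#' is individually strong in every study, or when the aggregate chi-square
#' evidence of its weaker studies clears the `alpha2` quantile. Stage 2
#' refines the retained set by maximizing the sum of study partial
#' log-likelihoods under a cross-study group-lasso penalty
#' ([group_cox_admm]), whose all-in-or-all-out structure selects each
#' feature in every study or in none; the penalty weight is chosen by
#' multi-study cross-validation ([cv_group_cox]) unless supplied.
#'
#' @param data an [ms_data] with K aligned studies.
#' @param alpha1 stage-1 two-sided level separating strong from potentially
#'   zero signals (default 1e-4).
#' @param alpha2 stage-1 screening level; default 0.05, or 0.01 when
#'   p >= 10000.
#' @param lambda optional fixed stage-2 penalty; when `NULL` (default) it is
#'   chosen by cross-validation.
#' @param nlambda,lambda_min_ratio stage-2 penalty grid settings.
#' @param nfolds folds per study for the cross-validation.
#' @param seed seed for the fold randomization (fits themselves are
#'   deterministic).
#' @param control an [admm_control] for the stage-2 solver.
#' @param cv_control solver settings for the cross-validation fold fits;
#'   slightly looser by default, since the fold criterion is statistical
#'   noise-dominated and insensitive to the last digits of the iterate.
#' @param cv_type,cv_rule criterion and selection rule passed to the
#'   cross-validation (see [cv_group_cox]).
#' @param cv_screen cross-validate the whole pipeline, re-screening within
#'   each training fold ([cv_mscox], the default). With `FALSE` the
#'   screened set is held fixed and only stage 2 is cross-validated
#'   ([cv_group_cox]); this is cheaper but optimistic for small penalties,
#'   because full-data screening leaks outcome information into every fold.
#' @param scan optional precomputed [marginal_scan] of `data`.
#' @param keep_path keep the full-data pathwise fits in the result.
#' @return An object of class `mscox` with components `selected` (feature
#'   identifiers), `selected_idx` (positions in the full feature set),
#'   `beta` (d1 x K matrix of stage-2 coefficients on the original covariate
#'   scale; rows are the screened features, zero rows unselected),
#'   `beta_std` (standardized scale), `scan`, `screening`, `cv`, `fit`,
#'   `lambda`, `d1`, `d2`. Supports `print`, `summary`, `coef`, `plot`.
#' @examples
#' sim <- simulate_scenario(scenario_spec("Homo-S", n = 60, p = 60, s = 4,
#'                                        K = 3), seed = 1)
#' fit <- mscox(sim$data, seed = 1)
#' print(fit)
#' @export
mscox <- function(data, alpha1 = 1e-4, alpha2 = NULL, lambda = NULL,
                  nlambda = 50L, lambda_min_ratio = 0.01, nfolds = 5L,
                  seed = NULL, control = admm_control(),
                  cv_control = cv_admm_control(),
                  cv_type = c("concordance", "loglik"),
                  cv_rule = c("1se", "min"), cv_screen = TRUE, scan = NULL,
                  keep_path = FALSE) {
  stopifnot(inherits(data, "ms_data"))
  cl <- match.call()
  if (is.null(scan)) scan <- marginal_scan(data)
  screening <- screen_features(scan, alpha1 = alpha1, alpha2 = alpha2)
  out <- list(call = cl, scan = scan, screening = screening,
              feature_ids = data$feature_ids, d1 = screening$d1,
              K = n_studies(data))
  if (screening$d1 == 0L) {
    warning("screening retained no features; no stage-2 fit")
    out <- c(out, list(cv = NULL, fit = NULL, lambda = NA_real_,
                       selected = character(0), selected_idx = integer(0),
                       beta = NULL, beta_std = NULL, d2 = 0L))
    class(out) <- "mscox"
    return(out)
  }
  sub <- restrict_features(data, screening$retained_idx)
  ssub <- standardize_ms(sub)
  prep <- gl_prep(ssub)
  d1 <- screening$d1
  K <- n_studies(data)
  lmax <- max(sqrt(rowSums(as.matrix(stacked_score(prep,
                                                   matrix(0, d1, K)))^2)))
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  cv <- NULL
  if (is.null(lambda)) {
    cv <- if (cv_screen)
      cv_mscox(data, alpha1 = alpha1, alpha2 = screening$alpha2,
               nfolds = nfolds, nlambda = nlambda,
               lambda_min_ratio = lambda_min_ratio, seed = seed,
               control = cv_control, type = cv_type, rule = cv_rule,
               lambda_max = lmax)
    else
      cv_group_cox(sub, nfolds = nfolds, lambdas = grid, seed = seed,
                   control = cv_control, type = cv_type, rule = cv_rule)
    lambda <- cv$lambda_opt
  }
  # pathwise warm start down to the chosen lambda, then the final fit
  upto <- grid[grid > lambda]
  init <- matrix(0, d1, K)
  path <- NULL
  if (keep_path) {
    path <- group_cox_path(sub, lambdas = grid, control = control)
    i <- which.min(abs(grid - lambda))
    init <- attr(path$fits[[i]], "state")
  } else if (length(upto)) {
    for (l in upto) {   # warm-start sweep: loose tolerance suffices here
      raw <- admm_core(prep, l, init, cv_control)
      init <- structure(raw$B, Z = raw$Z, U = raw$U, rho = raw$rho)
    }
  }
  raw <- admm_core(prep, lambda, init, control)
  fit <- finish_group_fit(raw, sub, ssub, lambda, control)
  sel_local <- fit$selected_idx
  out <- c(out, list(cv = cv, fit = fit, path = path, lambda = lambda,
                     selected = sub$feature_ids[sel_local],
                     selected_idx = screening$retained_idx[sel_local],
                     beta = fit$beta_raw, beta_std = fit$beta,
                     d2 = fit$d2))
  class(out) <- "mscox"
  out
}

#' @export
print.mscox <- function(x, ...) {
  cat("Two-stage multi-study Cox selection\n")
  cat(sprintf("  K = %d studies, p = %d features\n", x$K,
              length(x$feature_ids)))
  cat(sprintf("  stage 1 (alpha1 = %g, alpha2 = %g): d1 = %d retained\n",
              x$screening$alpha1, x$screening$alpha2, x$d1))
  if (is.null(x$fit)) {
    cat("  stage 2: not run (empty screening set)\n")
    return(invisible(x))
  }
  cat(sprintf("  stage 2 (group lasso, lambda = %.4g%s): d2 = %d selected\n",
              x$lambda, if (!is.null(x$cv)) " by CV" else "", x$d2))
  if (x$d2) cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mscox <- function(object, ...) {
  tab <- NULL
  if (!is.null(object$fit) && object$d2 > 0) {
    b <- object$beta[object$fit$selected_idx, , drop = FALSE]
    tab <- data.frame(feature = rownames(b), b, row.names = NULL,
                      check.names = FALSE)
  }
  structure(list(object = object, coef_table = tab), class = "summary.mscox")
}

#' @export
print.summary.mscox <- function(x, ...) {
  print(x$object)
  if (!is.null(x$object$cv))
    cat(sprintf("  CV: lambda_opt = %.4g (criterion %.2f, se %.2f)\n",
                x$object$cv$lambda_opt,
                x$object$cv$cv_criterion[x$object$cv$opt_index],
                x$object$cv$cv_se[x$object$cv$opt_index]))
  if (!is.null(x$coef_table)) {
    cat("  per-study coefficients (original covariate scale):\n")
    print(x$coef_table, digits = 3)
  }
  invisible(x)
}

#' @export
#' @param scale report coefficients on the original covariate scale
#'   (`"raw"`) or the solver's standardized scale.
#' @param features return rows for all screened features or only the
#'   selected ones.
#' @rdname mscox
coef.mscox <- function(object, scale = c("raw", "standardized"),
                       features = c("screened", "selected"), ...) {
  scale <- match.arg(scale)
  features <- match.arg(features)
  if (is.null(object$fit)) return(NULL)
  b <- if (scale == "raw") object$beta else object$beta_std
  if (features == "selected") b <- b[object$fit$selected_idx, , drop = FALSE]
  b
}

#' @export
plot.mscox <- function(x, ...) {
  if (!is.null(x$cv)) plot(x$cv, main = "multi-study CV", ...)
  else if (!is.null(x$path))
    plot(log(x$path$lambdas), x$path$n_selected, type = "s",
         xlab = "log(lambda)", ylab = "selected features", ...)
  else warning("nothing to plot: no CV result or path stored")
  invisible(x)
}
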