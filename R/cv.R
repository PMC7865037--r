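#' Event-stratified cross-validation folds for a multi-study dataset
#'
#' Folds are drawn independently within each study, stratified by the event
#' indicator so events spread evenly over folds. If any fold of any study
#' ends up without an event the draw is repeated (up to 100 times), then the
#' number of folds is reduced; with no workable assignment at 2 folds an
#' "insufficient_events" error is raised.
#'
#' The per-study requirement applies to studies with at least `nfolds`
#' events; a study with fewer (possible under heavy censoring with a small
#' baseline hazard) has its events spread as evenly as the stratification
#' allows, and the pooled data must still put at least one event in every
#' fold.
#'
#' @param data an [ms_data].
#' @param nfolds number of folds.
#' @param seed integer seed for the fold randomization.
#' @return List (one element per study) of integer fold labels per subject,
#'   with attribute `nfolds`.
#' @export
make_cv_folds <- function(data, nfolds = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nfolds <- as.integer(nfolds)
  repeat {
    if (nfolds < 2L) stop("insufficient_events")
    ok <- FALSE
    for (try in seq_len(100L)) {
      folds <- lapply(data$studies, function(s) {
        f <- integer(length(s$time))
        for (g in c(0L, 1L)) {
          idx <- which(s$event == g)
          f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
        }
        f
      })
      good <- all(mapply(function(s, f)
        sum(s$event) < nfolds ||
          all(tabulate(f[s$event == 1L], nfolds) >= 1L),
        data$studies, folds))
      pooled <- rowSums(mapply(function(s, f)
        tabulate(f[s$event == 1L], nfolds), data$studies, folds))
      if (good && all(pooled >= 1L)) { ok <- TRUE; break }
    }
    if (ok) break
    nfolds <- nfolds - 1L
  }
  structure(folds, nfolds = nfolds)
}

drop_fold <- function(data, folds, f) {
  data$studies <- Map(function(s, fl) {
    keep <- fl != f
    s$time <- s$time[keep]
    s$event <- s$event[keep]
    s$features <- s$features[keep, , drop = FALSE]
    s
  }, data$studies, folds)
  data
}

#' Harrell concordance index of a risk score
#'
#' Fraction of comparable subject pairs whose risk scores order their
#' survival times correctly (higher score = earlier event); score ties
#' count 1/2. A pair is comparable when the smaller observed time belongs
#' to an event. Returns 0.5 when no information is available (no
#' comparable pairs or a constant score).
#'
#' @param time observed times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param eta risk scores (e.g. Cox linear predictors).
#' @return Concordance in [0, 1].
#' @export
harrell_c <- function(time, event, eta) {
  cm <- comparable_pairs(time, event)
  if (cm$den == 0L || length(unique(eta)) < 2L) return(0.5)
  concordance_from_pairs(eta, cm)
}

# comparable-pair structure, reusable across many scores on the same data
comparable_pairs <- function(time, event) {
  cmp <- outer(time, time, "<") & event == 1L
  list(cmp = cmp, den = sum(cmp))
}

concordance_from_pairs <- function(eta, cm) {
  if (cm$den == 0L) return(0.5)
  conc <- (outer(eta, eta, ">") + 0.5 * (outer(eta, eta, "=="))) * cm$cmp
  sum(conc) / cm$den
}

heldout_concordance <- function(time, event, eta) harrell_c(time, event, eta)

#' Multi-study cross-validation for the group-lasso penalty
#'
#' Selects the penalty weight lambda of the stage-2 group-lasso by K-fold
#' cross-validation applied within each study, with individual survival
#' prediction as the evaluation criterion: for every fold the model fitted
#' on the remaining folds of all studies assigns each held-out subject a
#' risk score, and the fold's criterion is the Harrell concordance between
#' held-out scores and outcomes, averaged over studies
#' (`type = "concordance"`, the default). The concordance curve is flat once
#' all predictive features have entered, so the reported optimum applies the
#' one-standard-error convention by default: the largest (sparsest) lambda
#' whose criterion is within one standard error of the maximum
#' (`rule = "1se"`; `rule = "min"` takes the maximizer, ties to the larger
#' lambda).
#'
#' `type = "loglik"` instead scores each lambda by the Verweij-van
#' Houwelingen cross-validated partial likelihood
#' \eqn{\sum_k [ l_k(\hat\beta_{-f}) - l_k^{-f}(\hat\beta_{-f}) ]}, the
#' held-out contribution to the full-data partial likelihood.
#'
#' Covariates are standardized once on the full data and the same scale is
#' used in every training fit, so fold fits and criterion evaluations share
#' one coordinate system; the lambda grid is anchored at the full-data
#' lambda_max.
#'
#' @param data an [ms_data] restricted to the candidate features.
#' @param nfolds folds per study (default 5).
#' @param nlambda,lambda_min_ratio,lambdas grid settings as in
#'   [group_cox_path].
#' @param seed seed for the fold randomization.
#' @param control an [admm_control] for the fold fits.
#' @param folds optional pre-computed fold assignment from [make_cv_folds].
#' @param type evaluation criterion, see above.
#' @param rule `"1se"` or `"min"`.
#' @return An object of class `cv_group_cox`: `lambdas`, `cv_criterion`
#'   (mean over folds, per lambda), `cv_se` (standard error over folds),
#'   `lambda_opt`, `opt_index`, `fold_assignments`, `fold_matrix`
#'   (fold x lambda contributions), `type`, `rule`.
#' @export
cv_group_cox <- function(data, nfolds = 5L, nlambda = 50L,
                         lambda_min_ratio = 0.01, lambdas = NULL,
                         seed = NULL, control = admm_control(),
                         folds = NULL, type = c("concordance", "loglik"),
                         rule = c("1se", "min")) {
  stopifnot(inherits(data, "ms_data"))
  type <- match.arg(type)
  rule <- match.arg(rule)
  sdata <- standardize_ms(data)
  if (is.null(folds)) folds <- make_cv_folds(data, nfolds, seed)
  nfolds <- attr(folds, "nfolds")
  prep_full <- gl_prep(sdata)
  d <- n_features(data)
  K <- n_studies(data)
  lmax <- max(sqrt(rowSums(as.matrix(stacked_score(prep_full,
                                                   matrix(0, d, K)))^2)))
  if (is.null(lambdas))
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  nl <- length(lambdas)
  fold_mat <- matrix(NA_real_, nfolds, nl)
  for (f in seq_len(nfolds)) {
    train <- drop_fold(sdata, folds, f)
    prep_train <- gl_prep(train)
    ho_X <- lapply(seq_len(K), function(k)
      sdata$studies[[k]]$features[folds[[k]] == f, , drop = FALSE])
    ho_cmp <- lapply(seq_len(K), function(k) {
      s <- sdata$studies[[k]]
      ho <- folds[[k]] == f
      comparable_pairs(s$time[ho], s$event[ho])
    })
    init <- matrix(0, d, K)
    for (i in seq_len(nl)) {
      raw <- admm_core(prep_train, lambdas[i], init, control)
      Z <- raw$Z
      Z[sqrt(rowSums(Z^2)) < 1e-10, ] <- 0
      if (type == "loglik") {
        crit <- 0
        for (k in seq_len(K)) {
          lf <- .cox_loglik_cpp(prep_full[[k]]$Xt, prep_full[[k]]$delta,
                                prep_full[[k]]$risk_end, Z[, k])
          lt <- .cox_loglik_cpp(prep_train[[k]]$Xt, prep_train[[k]]$delta,
                                prep_train[[k]]$risk_end, Z[, k])
          crit <- crit + (lf - lt)
        }
      } else {
        cks <- vapply(seq_len(K), function(k) {
          eta <- drop(ho_X[[k]] %*% Z[, k])
          if (length(unique(eta)) < 2L) return(0.5)
          concordance_from_pairs(eta, ho_cmp[[k]])
        }, 0)
        crit <- mean(cks)
      }
      fold_mat[f, i] <- crit
      init <- structure(raw$B, Z = raw$Z, U = raw$U, rho = raw$rho)
    }
  }
  cv <- colMeans(fold_mat)
  cv_se <- apply(fold_mat, 2, sd) / sqrt(nfolds)
  imax <- which.max(cv)           # grid is decreasing: first max = largest lambda
  opt <- if (rule == "min") imax
         else which(cv >= cv[imax] - cv_se[imax])[1]
  structure(list(lambdas = lambdas, cv_criterion = cv, cv_se = cv_se,
                 lambda_opt = lambdas[opt], opt_index = opt,
                 fold_assignments = folds, fold_matrix = fold_mat,
                 lambda_max = lmax, nfolds = nfolds, type = type,
                 rule = rule),
            class = "cv_group_cox")
}

#' @export
print.cv_group_cox <- function(x, ...) {
  cat(sprintf("multi-study CV (%d folds/study, %s, rule %s): lambda_opt = %.4g (index %d of %d), criterion %.4f\n",
              x$nfolds, x$type, x$rule, x$lambda_opt, x$opt_index,
              length(x$lambdas), x$cv_criterion[x$opt_index]))
  invisible(x)
}

#' @export
plot.cv_group_cox <- function(x, ...) {
  ylab <- if (x$type == "concordance") "CV concordance"
          else "CV partial likelihood"
  plot(log(x$lambdas), x$cv_criterion, type = "b", pch = 16,
       xlab = "log(lambda)", ylab = ylab, ...)
  lines(log(x$lambdas), x$cv_criterion + x$cv_se, lty = 3)
  lines(log(x$lambdas), x$cv_criterion - x$cv_se, lty = 3)
  abline(v = log(x$lambda_opt), lty = 2)
  invisible(x)
}

#' Cross-validation of the full two-stage pipeline
#'
#' Tunes the stage-2 penalty by cross-validating the *entire* two-stage
#' procedure: within each fold, screening is redone on the training part
#' alone (so held-out subjects never influence which features reach stage
#' 2), the group-lasso path is fitted over a grid of penalty fractions
#' \eqn{t = \lambda / \lambda_{max}} of the fold's own \eqn{\lambda_{max}},
#' and held-out subjects are scored. Re-screening matters: features
#' retained by screening on the full data carry chance association with
#' *all* subjects, so a criterion evaluated on folds of the same data keeps
#' improving as more of them enter and any argmax rule overselects.
#'
#' The criterion and selection rule are as in [cv_group_cox]
#' (`"concordance"` with the one-standard-error rule by default).
#'
#' @param data the full [ms_data] (all p features).
#' @param alpha1,alpha2 screening levels, as in [screen_features].
#' @param nfolds folds per study.
#' @param nlambda,lambda_min_ratio grid of penalty fractions
#'   `exp(seq(log(1), log(lambda_min_ratio), length.out = nlambda))`.
#' @param seed seed for the fold randomization.
#' @param control an [admm_control] for the fold fits.
#' @param type,rule see [cv_group_cox].
#' @param folds optional pre-computed folds.
#' @param lambda_max optional full-data lambda_max of the screened set, used
#'   to report `lambda_opt = t_opt * lambda_max`.
#' @return An object of class `cv_group_cox` whose grid is the scaled
#'   penalty `t`; extra elements `t_opt` and (when `lambda_max` is given)
#'   `lambda_opt`.
#' @export
cv_mscox <- function(data, alpha1 = 1e-4, alpha2 = NULL, nfolds = 5L,
                     nlambda = 50L, lambda_min_ratio = 0.01, seed = NULL,
                     control = cv_admm_control(),
                     type = c("concordance", "loglik"),
                     rule = c("1se", "min"), folds = NULL,
                     lambda_max = NULL) {
  type <- match.arg(type)
  rule <- match.arg(rule)
  if (is.null(folds)) folds <- make_cv_folds(data, nfolds, seed)
  nfolds <- attr(folds, "nfolds")
  K <- n_studies(data)
  tgrid <- exp(seq(0, log(lambda_min_ratio), length.out = nlambda))
  fold_mat <- matrix(NA_real_, nfolds, nlambda)
  for (f in seq_len(nfolds)) {
    train <- drop_fold(data, folds, f)
    scr_f <- screen_features(marginal_scan(train, allow_no_events = TRUE),
                             alpha1 = alpha1, alpha2 = alpha2)
    if (scr_f$d1 == 0L) { fold_mat[f, ] <- if (type == "loglik") 0 else 0.5; next }
    sub_f <- restrict_features(train, scr_f$retained_idx)
    ssub_f <- standardize_ms(sub_f)
    scaling_f <- attr(ssub_f, "scaling")
    prep_f <- gl_prep(ssub_f)
    ho_X <- lapply(seq_len(K), function(k) {
      s <- data$studies[[k]]
      scale_cols(s$features[folds[[k]] == f, scr_f$retained_idx,
                            drop = FALSE], scaling_f[[k]])
    })
    ho_cmp <- lapply(seq_len(K), function(k) {
      s <- data$studies[[k]]
      ho <- folds[[k]] == f
      comparable_pairs(s$time[ho], s$event[ho])
    })
    lmax_f <- max(sqrt(rowSums(as.matrix(
      stacked_score(prep_f, matrix(0, scr_f$d1, K)))^2)))
    init <- matrix(0, scr_f$d1, K)
    for (i in seq_len(nlambda)) {
      raw <- admm_core(prep_f, tgrid[i] * lmax_f, init, control)
      Z <- raw$Z
      Z[sqrt(rowSums(Z^2)) < 1e-10, ] <- 0
      if (type == "loglik") {
        crit <- 0
        for (k in seq_len(K)) {
          s <- data$studies[[k]]
          Xs <- scale_cols(s$features[, scr_f$retained_idx, drop = FALSE],
                           scaling_f[[k]])
          full_k <- ms_study(s$time, s$event, Xs, study_id = s$study_id)
          lf <- cox_partial_loglik(full_k, Z[, k])
          lt <- .cox_loglik_cpp(prep_f[[k]]$Xt, prep_f[[k]]$delta,
                                prep_f[[k]]$risk_end, Z[, k])
          crit <- crit + (lf - lt)
        }
      } else {
        cks <- vapply(seq_len(K), function(k) {
          eta <- drop(ho_X[[k]] %*% Z[, k])
          if (length(unique(eta)) < 2L) return(0.5)
          concordance_from_pairs(eta, ho_cmp[[k]])
        }, 0)
        crit <- mean(cks)
      }
      fold_mat[f, i] <- crit
      init <- structure(raw$B, Z = raw$Z, U = raw$U, rho = raw$rho)
    }
  }
  cv <- colMeans(fold_mat)
  cv_se <- apply(fold_mat, 2, sd) / sqrt(nfolds)
  imax <- which.max(cv)
  opt <- if (rule == "min") imax
         else which(cv >= cv[imax] - cv_se[imax])[1]
  structure(list(lambdas = tgrid, cv_criterion = cv, cv_se = cv_se,
                 t_opt = tgrid[opt],
                 lambda_opt = if (!is.null(lambda_max))
                   tgrid[opt] * lambda_max else NA_real_,
                 opt_index = opt, fold_assignments = folds,
                 fold_matrix = fold_mat, lambda_max = lambda_max,
                 nfolds = nfolds, type = type, rule = rule,
                 scaled = TRUE),
            class = "cv_group_cox")
}

scale_cols <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}
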