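#' Selection accuracy against a known truth
#'
#' Sensitivity is the fraction of true predictors selected (TP/s);
#' specificity the fraction of null features correctly excluded
#' (TN/(p - s)).
#'
#' @param selected integer indices of selected features (in 1..p).
#' @param truth an `ms_truth`.
#' @return List with `sensitivity` (NA when s = 0), `specificity`,
#'   `n_selected`, `tp`, `fp`.
#' @export
selection_metrics <- function(selected, truth) {
  p <- truth$p
  s <- truth$s
  selected <- unique(as.integer(selected))
  stopifnot(all(selected >= 1 & selected <= p))
  tp <- sum(selected %in% truth$true_features)
  fp <- length(selected) - tp
  list(sensitivity = if (s > 0) tp / s else NA_real_,
       specificity = ((p - s) - fp) / (p - s),
       n_selected = length(selected), tp = tp, fp = fp)
}

#' Post-selection estimation error (SSE)
#'
#' Refits an unpenalized Cox model per study on the selected features (on
#' the original covariate scale) and accumulates the squared error against
#' the generating coefficients over all p features and K studies, with
#' \eqn{\hat\beta_j^{(k)} = 0} for unselected features:
#' \deqn{SSE = \sum_{j=1}^p \sum_{k=1}^K (\hat\beta_j^{(k)} -
#'   \beta_j^{(k)})^2.}
#' Separation-flagged refit coefficients are capped at the divergence bound;
#' a failed refit contributes zeros for that study with a warning.
#'
#' @param data the [ms_data] the selection was made on.
#' @param selected integer indices of selected features.
#' @param truth an `ms_truth`.
#' @param bcap coefficient cap for separation-flagged refits.
#' @return The sum of squared errors (nonnegative scalar).
#' @export
post_selection_sse <- function(data, selected, truth, bcap = 15) {
  K <- n_studies(data)
  p <- truth$p
  betahat <- matrix(0, p, K)
  selected <- unique(as.integer(selected))
  if (length(selected)) {
    for (k in seq_len(K)) {
      fit <- tryCatch(cox_fit(data$studies[[k]], features = selected,
                              bcap = bcap),
                      error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("refit failed in study %d; its coefficients enter the SSE as 0", k))
        next
      }
      b <- fit$beta
      b[fit$flagged_separation] <- sign(b[fit$flagged_separation]) * bcap
      b[abs(b) > bcap] <- sign(b[abs(b) > bcap]) * bcap
      betahat[selected, k] <- b
    }
  }
  sum((betahat - truth$beta_true)^2)
}

#' Sensitivity/specificity along the penalty path
#'
#' Re-runs the stage-2 selection of each method over a common grid of
#' penalty strengths rescaled to [0, 1] by each replication's own
#' lambda_max, and averages sensitivity and specificity across
#' replications. For the two-stage group-lasso method the screening stage
#' is held fixed while lambda sweeps; for the intersection baselines each
#' study's glmnet path is swept on its own rescaled grid and the per-study
#' selections intersected per grid point.
#'
#' @param spec an [scenario_spec].
#' @param methods subset of `"Cox-TOTEM"`, `"InterCoxLasso"`,
#'   `"InterCoxNet"`, `"MinPSIS-InterCoxLasso"`, `"MinPSIS-InterCoxNet"`.
#' @param lambda_scaled increasing grid in (0, 1] of scaled penalties.
#' @param n_reps replications to average over.
#' @param seed master seed.
#' @param alpha1,alpha2 screening levels for the two-stage method.
#' @param control stage-2 solver settings.
#' @return A data.frame with one row per (method, lambda_scaled):
#'   mean/sd sensitivity and specificity across replications.
#' @export
lambda_sweep_curves <- function(spec, methods = "Cox-TOTEM",
                                lambda_scaled = seq(0.05, 1, by = 0.05),
                                n_reps = 2L, seed = 1L, alpha1 = 1e-4,
                                alpha2 = NULL, control = admm_control()) {
  stopifnot(n_reps >= 1L, all(lambda_scaled > 0), all(lambda_scaled <= 1))
  lambda_scaled <- sort(lambda_scaled)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  rows <- list()
  for (r in seq_len(n_reps)) {
    sim <- simulate_scenario(spec, seed = rep_seeds[r])
    scan <- if (any(methods != "InterCoxLasso" & methods != "InterCoxNet"))
      marginal_scan(sim$data) else NULL
    for (m in methods) {
      sel_by_lambda <- sweep_one_method(sim, m, scan, lambda_scaled,
                                        alpha1, alpha2, control,
                                        seed = rep_seeds[r])
      for (i in seq_along(lambda_scaled)) {
        met <- selection_metrics(sel_by_lambda[[i]], sim$truth)
        rows[[length(rows) + 1L]] <-
          data.frame(method = m, rep = r, lambda_scaled = lambda_scaled[i],
                     sensitivity = met$sensitivity,
                     specificity = met$specificity,
                     n_selected = met$n_selected)
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- aggregate(cbind(sensitivity, specificity) ~ method + lambda_scaled,
                   per_rep, function(v) c(mean = mean(v), sd = sd(v)))
  out <- data.frame(method = agg$method, lambda_scaled = agg$lambda_scaled,
                    mean_sensitivity = agg$sensitivity[, "mean"],
                    sd_sensitivity = agg$sensitivity[, "sd"],
                    mean_specificity = agg$specificity[, "mean"],
                    sd_specificity = agg$specificity[, "sd"])
  attr(out, "per_rep") <- per_rep
  out[order(out$method, out$lambda_scaled), ]
}

sweep_one_method <- function(sim, method, scan, lambda_scaled, alpha1,
                             alpha2, control, seed) {
  p <- sim$spec$p
  if (method == "Cox-TOTEM") {
    screening <- screen_features(scan, alpha1 = alpha1, alpha2 = alpha2)
    if (screening$d1 == 0L)
      return(rep(list(integer(0)), length(lambda_scaled)))
    sub <- restrict_features(sim$data, screening$retained_idx)
    lmax <- compute_lambda_max(sub)
    path <- group_cox_path(sub, lambdas = rev(lambda_scaled) * lmax,
                           control = control)
    sel <- lapply(path$fits, function(f)
      screening$retained_idx[f$selected_idx])
    return(rev(sel))
  }
  two_stage <- startsWith(method, "MinPSIS")
  alpha <- if (grepl("Lasso$", method)) 1 else 0.5
  cand <- seq_len(p)
  if (two_stage) {
    d <- min(vapply(sim$data$studies, function(s) length(s$time), 0L))
    cand <- min_psis_screen(scan, min(d, p))
  }
  K <- n_studies(sim$data)
  per <- vector("list", K)
  for (k in seq_len(K)) {
    st <- sim$data$studies[[k]]
    y <- cbind(time = st$time, status = st$event)
    x <- st$features[, cand, drop = FALSE]
    fit <- suppressWarnings(glmnet::glmnet(x, y, family = "cox", alpha = alpha))
    lmax_k <- max(fit$lambda)
    b <- predict(fit, s = lambda_scaled * lmax_k, type = "coefficients",
                 exact = FALSE)
    per[[k]] <- lapply(seq_along(lambda_scaled),
                       function(i) cand[which(b[, i] != 0)])
  }
  lapply(seq_along(lambda_scaled), function(i)
    Reduce(intersect, lapply(per, `[[`, i)))
}

#' @importFrom stats aggregate
NULL
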