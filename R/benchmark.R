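#' Run every method once on one simulated multi-study dataset
#'
#' Generates one replication of a scenario, runs each requested method
#' end-to-end with the standard defaults (screening levels, CV-chosen
#' penalties) and evaluates selection accuracy and post-selection
#' estimation error against the known truth. Fully determined by `seed`.
#'
#' @param spec an [scenario_spec].
#' @param methods character vector among `"Cox-TOTEM"`, `"InterCoxLasso"`,
#'   `"InterCoxNet"`, `"MinPSIS-InterCoxLasso"`, `"MinPSIS-InterCoxNet"`.
#' @param seed replication seed.
#' @param alpha1,alpha2 screening levels for the two-stage method.
#' @param nfolds CV folds (stage-2 CV and the baselines' within-study CV).
#' @param control stage-2 solver settings.
#' @return A data.frame, one row per method, with `sensitivity`,
#'   `specificity`, `n_selected`, `sse`; the selected index sets are in
#'   attribute `selections`.
#' @export
run_replication <- function(spec, methods = "Cox-TOTEM", seed = 1L,
                            alpha1 = 1e-4, alpha2 = NULL, nfolds = 5L,
                            control = admm_control()) {
  sim <- simulate_scenario(spec, seed = seed)
  # one seed stream per method so adding methods never shifts the others
  set.seed(seed + 1L)
  method_seeds <- sample.int(.Machine$integer.max, length(methods))
  needs_scan <- any(methods %in% c("Cox-TOTEM", "MinPSIS-InterCoxLasso",
                                   "MinPSIS-InterCoxNet"))
  scan <- if (needs_scan) marginal_scan(sim$data) else NULL
  rows <- list()
  selections <- list()
  for (i in seq_along(methods)) {
    m <- methods[i]
    sel <- if (m == "Cox-TOTEM") {
      fit <- mscox(sim$data, alpha1 = alpha1, alpha2 = alpha2,
                   nfolds = nfolds, seed = method_seeds[i],
                   control = control, scan = scan)
      fit$selected_idx
    } else {
      run_baseline(sim$data, method = m, scan = scan, nfolds = nfolds,
                   seed = method_seeds[i])$selected_idx
    }
    met <- selection_metrics(sel, sim$truth)
    sse <- post_selection_sse(sim$data, sel, sim$truth)
    selections[[m]] <- sel
    rows[[i]] <- data.frame(method = m, sensitivity = met$sensitivity,
                            specificity = met$specificity,
                            n_selected = met$n_selected, sse = sse)
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- selections
  out
}

#' Benchmark methods over replicated simulations
#'
#' Repeats [run_replication] B times per scenario and reports, per scenario
#' and method, the mean and standard error (sd/sqrt(B)) of sensitivity,
#' specificity, number of selected features and post-selection SSE — the
#' layout of a simulation comparison table. Replication seeds derive
#' deterministically from the master seed, so identical seeds yield
#' identical tables.
#'
#' @param scenarios a single [scenario_spec], a list of them, or scenario
#'   names (passed to [scenario_spec]).
#' @param methods methods to run (see [run_replication]).
#' @param B replications per scenario (>= 2).
#' @param seed master seed.
#' @param verbose print progress.
#' @param ... further arguments passed to [run_replication].
#' @return A data.frame of class `ms_benchmark` with one row per
#'   scenario x method; failed replications are counted in `failures` and
#'   excluded from the means. Per-replication results are kept in
#'   attribute `replications`.
#' @export
run_benchmark <- function(scenarios, methods = "Cox-TOTEM", B = 2L,
                          seed = 1L, verbose = FALSE, ...) {
  stopifnot(B >= 2L)
  if (inherits(scenarios, "ms_scenario")) scenarios <- list(scenarios)
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, scenario_spec)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)
  all_reps <- list()
  out_rows <- list()
  for (sc in scenarios) {
    name <- sc$scenario
    reps <- vector("list", B)
    nfail <- 0L
    for (b in seq_len(B)) {
      if (verbose)
        message(sprintf("[%s] replication %d/%d", name, b, B))
      reps[[b]] <- tryCatch({
        r <- run_replication(sc, methods = methods, seed = rep_seeds[b], ...)
        r$rep <- b
        r
      }, error = function(e) {
        warning(sprintf("replication %d of %s failed: %s", b, name,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(reps[[b]])) nfail <- nfail + 1L
    }
    per <- do.call(rbind, reps)
    per$scenario <- name
    all_reps[[name]] <- per
    for (m in methods) {
      sub <- per[per$method == m, , drop = FALSE]
      nb <- nrow(sub)
      mstat <- function(v) c(mean(v), sd(v) / sqrt(nb))
      se <- vapply(sub[c("sensitivity", "specificity", "n_selected", "sse")],
                   mstat, numeric(2))
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        scenario = name, method = m,
        sensitivity = se[1, 1], sensitivity_se = se[2, 1],
        specificity = se[1, 2], specificity_se = se[2, 2],
        n_selected = se[1, 3], n_selected_se = se[2, 3],
        sse = se[1, 4], sse_se = se[2, 4],
        B = nb, failures = nfail)
    }
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  attr(out, "replications") <- do.call(rbind, all_reps)
  class(out) <- c("ms_benchmark", "data.frame")
  out
}

#' Write a benchmark table as TSV
#'
#' @param bench an `ms_benchmark` from [run_benchmark].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  write.table(as.data.frame(bench), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
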