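#' Read one study from a delimited text file
#'
#' The file must have a header row with columns `time` and `event` followed
#' by feature columns. Comma and tab separators are auto-detected from the
#' extension (`.tsv`/`.txt` = tab, otherwise comma). Rows with missing time
#' or event and feature columns containing any missing value are dropped
#' with a message.
#'
#' @param file path to the file.
#' @param study_id label; defaults to the file name.
#' @return An [ms_study].
#' @export
read_study <- function(file, study_id = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  if (is.null(study_id))
    study_id <- sub("\\.[^.]*$", "", basename(file))
  sep_tab <- grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)
  df <- if (sep_tab) read.delim(file, check.names = FALSE)
        else read.csv(file, check.names = FALSE)
  if (!all(c("time", "event") %in% names(df)))
    stop("file must contain 'time' and 'event' columns: ", file)
  bad <- !df$event %in% c(0, 1) & !is.na(df$event)
  if (any(bad))
    stop(sprintf("non-{0,1} event codes in '%s', column 'event', rows %s: %s",
                 file, paste(head(which(bad), 5), collapse = ", "),
                 paste(unique(df$event[bad]), collapse = ", ")))
  keep <- !is.na(df$time) & !is.na(df$event)
  if (any(!keep))
    message(sprintf("read_study(%s): dropped %d subject(s) with missing time/event",
                    study_id, sum(!keep)))
  df <- df[keep, , drop = FALSE]
  feats <- df[, setdiff(names(df), c("time", "event")), drop = FALSE]
  na_col <- vapply(feats, anyNA, TRUE)
  if (any(na_col))
    message(sprintf("read_study(%s): dropped %d feature column(s) with missing values",
                    study_id, sum(na_col)))
  feats <- as.matrix(feats[, !na_col, drop = FALSE])
  ms_study(time = df$time, event = df$event, features = feats,
           study_id = study_id)
}

#' Load a multi-study dataset from per-study files
#'
#' @param manifest character vector of file paths (names become study
#'   labels), or a data.frame with columns `file` and optionally
#'   `study_id`.
#' @return An [ms_data]; features are aligned by identifier intersection in
#'   the order of the first study.
#' @export
load_multistudy <- function(manifest) {
  if (is.data.frame(manifest)) {
    files <- manifest$file
    ids <- if ("study_id" %in% names(manifest)) manifest$study_id else NULL
  } else {
    files <- as.character(manifest)
    ids <- names(manifest)
  }
  if (is.null(ids)) ids <- rep(NA_character_, length(files))
  studies <- Map(function(f, id)
    read_study(f, study_id = if (is.na(id) || !nzchar(id)) NULL else id),
    files, ids)
  ms_data(unname(studies))
}

#' Run the full two-stage pipeline and write its artifacts
#'
#' Runs scan, screening, cross-validation and the final group-lasso fit on
#' a multi-study dataset, then writes five artifacts into `out_dir`:
#' `selected.txt` (one feature id per line), `coefficients.tsv` (feature,
#' study, stage-2 beta, refit beta and SE), `screening.tsv` (feature,
#' kappa, U, threshold, retained), `cv.tsv` (lambda, criterion, se) and
#' `settings.tsv` (all effective settings and seeds). If screening retains
#' nothing the stage-2 artifacts record the empty result and the pipeline
#' exits gracefully.
#'
#' @param data an [ms_data] or a manifest accepted by [load_multistudy].
#' @param out_dir output directory (created if needed).
#' @param alpha1,alpha2,nfolds,nlambda,lambda_min_ratio,seed,control passed
#'   to [mscox].
#' @return The fitted [mscox] object, invisibly.
#' @export
run_pipeline <- function(data, out_dir, alpha1 = 1e-4, alpha2 = NULL,
                         nfolds = 5L, nlambda = 50L, lambda_min_ratio = 0.01,
                         seed = 1L, control = admm_control()) {
  if (!inherits(data, "ms_data")) data <- load_multistudy(data)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- mscox(data, alpha1 = alpha1, alpha2 = alpha2, nfolds = nfolds,
               nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
               seed = seed, control = control)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  writeLines(fit$selected, file.path(out_dir, "selected.txt"))
  scr <- fit$screening
  tsv(data.frame(feature = scr$feature_ids, kappa = scr$kappa,
                 U = signif(scr$U, 8), threshold = signif(scr$threshold, 8),
                 retained = scr$retained),
      "screening.tsv")
  if (!is.null(fit$cv))
    tsv(data.frame(lambda = signif(fit$cv$lambdas, 8),
                   criterion = signif(fit$cv$cv_criterion, 8),
                   se = signif(fit$cv$cv_se, 8)),
        "cv.tsv")
  else writeLines("lambda\tcriterion\tse", file.path(out_dir, "cv.tsv"))
  coefs <- data.frame(feature = character(0), study = character(0),
                      beta = numeric(0), beta_refit = numeric(0),
                      se_refit = numeric(0))
  if (fit$d2 > 0) {
    refits <- lapply(data$studies, function(s)
      tryCatch(cox_fit(s, features = fit$selected_idx),
               error = function(e) NULL))
    rows <- list()
    for (k in seq_along(data$studies)) {
      rf <- refits[[k]]
      sel_rows <- fit$fit$selected_idx
      rows[[k]] <- data.frame(
        feature = fit$selected,
        study = data$studies[[k]]$study_id,
        beta = signif(fit$beta[sel_rows, k], 8),
        beta_refit = if (!is.null(rf)) signif(unname(rf$beta), 8) else NA,
        se_refit = if (!is.null(rf)) signif(unname(rf$se), 8) else NA)
    }
    coefs <- do.call(rbind, rows)
  }
  tsv(coefs, "coefficients.tsv")
  settings <- data.frame(
    key = c("K", "p", "alpha1", "alpha2", "nfolds", "nlambda",
            "lambda_min_ratio", "seed", "lambda", "d1", "d2"),
    value = c(n_studies(data), n_features(data), alpha1,
              fit$screening$alpha2, nfolds, nlambda, lambda_min_ratio, seed,
              signif(fit$lambda, 8), fit$d1, fit$d2))
  tsv(settings, "settings.tsv")
  invisible(fit)
}
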